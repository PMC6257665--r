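## Two-phase diverse selection: "Seed" picks n compounds as small clusters
## (default 500 as clusters of 5), "Refill" tops undersized clusters up to
## the minimum cluster size and then spends the remaining budget on new,
## untouched clusters in maximally-dissimilar order (default 5,000 more).

## medoid of each cluster: member with maximal mean similarity to its
## cluster, ties broken by smallest library position
clusterMedoidPositions <- function(labels, simFun) {
  nC <- max(labels, 0L)
  med <- integer(nC)
  for (c in seq_len(nC)) {
    mem <- which(labels == c)
    if (length(mem) == 1L) { med[c] <- mem; next }
    ## blockwise row sums: large clusters must not materialize m x m
    tot <- numeric(length(mem))
    for (start in seq(1L, length(mem), by = 512L)) {
      idx <- start:min(start + 511L, length(mem))
      tot[idx] <- rowSums(simFun(mem[idx], mem))
    }
    med[c] <- mem[which.max(tot)]
  }
  med
}

## Greedy max-min ordering over medoids. `candidates` are cluster ids to
## order; `chosen` are cluster ids already in the collection (may be
## empty). With no prior chosen set the start is the cluster whose medoid
## has the lowest maximum similarity to all other candidate medoids (the
## globally least connected one); ties by smallest cluster id. Returns up
## to `steps` cluster ids.
maxMinClusterOrder <- function(medoids, simFun, candidates,
                               chosen = integer(0), steps = Inf) {
  out <- integer(0)
  remaining <- candidates
  if (length(remaining) == 0L) return(out)
  if (length(remaining) == 1L) return(remaining[seq_len(min(1, steps))])
  if (length(chosen) == 0L) {
    ## row maxima over candidate medoids, blockwise
    m <- medoids[remaining]
    rowMax <- rep(-Inf, length(m))
    for (start in seq(1L, length(m), by = 512L)) {
      idx <- start:min(start + 511L, length(m))
      s <- simFun(m[idx], m)
      s[cbind(seq_along(idx), idx)] <- -Inf  # exclude self
      rowMax[idx] <- apply(s, 1L, max)
    }
    first <- remaining[which.min(rowMax)]  # which.min takes first on ties
    out <- first
    remaining <- setdiff(remaining, first)
    d <- drop(simFun(medoids[remaining], medoids[first]))
  } else {
    d <- rep(-Inf, length(remaining))
    for (ch in chosen)
      d <- pmax(d, drop(simFun(medoids[remaining], medoids[ch])))
  }
  while (length(remaining) && length(out) < steps) {
    nxt <- which.min(d)
    cid <- remaining[nxt]
    out <- c(out, cid)
    remaining <- remaining[-nxt]
    d <- d[-nxt]
    if (length(remaining))
      d <- pmax(d, drop(simFun(medoids[remaining], medoids[cid])))
  }
  out
}

## members of cluster c ordered medoid-first, then by descending
## similarity to the medoid, ties by smallest position
.clusterPickOrder <- function(mem, medoid, simFun) {
  rest <- setdiff(mem, medoid)
  if (length(rest) == 0L) return(medoid)
  s <- drop(simFun(rest, medoid))
  c(medoid, rest[order(-s, rest)])
}

.newSelection <- function(lib, pos, phase, cluster, targetN, scheme,
                          rngSeed = NA_integer_, shortfall = FALSE,
                          parameters = list()) {
  new("SelectionResult", ids = lib@ids[pos], phase = phase,
      cluster = as.integer(cluster), rank = seq_along(pos),
      targetN = as.integer(targetN), scheme = scheme,
      rngSeed = as.integer(rngSeed), shortfall = shortfall,
      parameters = parameters)
}

#' Seed selection: diverse clusters of five
#'
#' Phase I of the acquisition protocol. The pool is clustered with
#' Jarvis-Patrick under the given scheme; each cluster is represented by
#' its medoid; clusters are visited in greedy max-min (maximally
#' dissimilar) medoid order, taking up to \code{membersPerCluster}
#' compounds from each (medoid first, then the members most similar to
#' it), until \code{n} compounds are collected. If every cluster has been
#' visited and the budget remains, the clusters are revisited in the same
#' order for further members.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param spec a \linkS4class{MetricSpec} or scheme name
#' @param n number of compounds to select (default 500)
#' @param membersPerCluster picks per cluster per round (default 5)
#' @param threshold,kCommon Jarvis-Patrick parameters (defaults 0.85, 4)
#' @param strict,allZero see \code{\link{neighborTable}}
#' @return a \linkS4class{SelectionResult} with phase "seed"
#' @export
selectSeed <- function(lib, spec, n = 500L, membersPerCluster = 5L,
                       threshold = 0.85, kCommon = 4L, strict = TRUE,
                       allZero = "one") {
  if (is.character(spec)) spec <- metricSpec(spec)
  n <- as.integer(n)
  stopifnot(length(lib) >= 1L, n >= membersPerCluster)
  shortfall <- FALSE
  if (n > length(lib)) {
    warning("requested ", n, " compounds from a pool of ", length(lib),
            "; returning the whole pool")
    shortfall <- TRUE
  }
  cl <- .poolJP(lib, spec, threshold, kCommon, strict, allZero)
  simFun <- makeSimFun(lib, spec, allZero)
  med <- clusterMedoidPositions(cl@labels, simFun)
  needClusters <- ceiling(min(n, length(lib)) / membersPerCluster)
  ord <- maxMinClusterOrder(med, simFun, seq_len(nClusters(cl)),
                            steps = needClusters)
  ## if the budget outruns the ordered clusters, extend the order
  if (length(ord) < nClusters(cl) &&
      sum(pmin(clusterSizes(cl)[ord], membersPerCluster)) < min(n, length(lib)))
    ord <- maxMinClusterOrder(med, simFun, seq_len(nClusters(cl)))
  memberOrder <- lapply(ord, function(c)
    .clusterPickOrder(which(cl@labels == c), med[c], simFun))
  pos <- integer(0); src <- integer(0)
  round <- 0L
  target <- min(n, length(lib))
  while (length(pos) < target) {
    added <- FALSE
    for (k in seq_along(ord)) {
      mo <- memberOrder[[k]]
      lo <- round * membersPerCluster + 1L
      hi <- min((round + 1L) * membersPerCluster, length(mo))
      if (lo > length(mo)) next
      take <- mo[lo:hi]
      take <- take[seq_len(min(length(take), target - length(pos)))]
      if (length(take)) {
        pos <- c(pos, take)
        src <- c(src, rep.int(ord[k], length(take)))
        added <- TRUE
      }
      if (length(pos) >= target) break
    }
    if (!added) break
    round <- round + 1L
  }
  .newSelection(lib, pos, rep("seed", length(pos)), src, n, spec@scheme,
                shortfall = shortfall,
                parameters = list(threshold = threshold, kCommon = kCommon,
                                  membersPerCluster = membersPerCluster,
                                  clustering = cl))
}

#' Refill selection: fill undersized clusters, then add new ones
#'
#' Phase II. The full pool is re-clustered under the scheme; seed picks
#' are mapped to their pool clusters. First, every cluster holding fewer
#' than \code{minSize} selected compounds (but at least one) is topped up
#' with its unselected members, by descending similarity to the cluster
#' medoid. The remaining budget is spent on clusters untouched by the
#' selection, in greedy max-min medoid order continuing from the touched
#' clusters, \code{minSize} members at a time (the last cluster takes only
#' the remainder). Clusters already at or above \code{minSize} selected
#' members never receive additions.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param seed the \linkS4class{SelectionResult} to extend
#' @param spec a \linkS4class{MetricSpec} or scheme name
#' @param nAdd number of compounds to add (default 5000)
#' @param minSize minimum selected-members-per-cluster target (default 5)
#' @param threshold,kCommon Jarvis-Patrick parameters (defaults 0.85, 4)
#' @param strict,allZero see \code{\link{neighborTable}}
#' @return a \linkS4class{SelectionResult} containing the seed picks
#'   (phase "seed") followed by the additions (phase "refill")
#' @export
refillSelection <- function(lib, seed, spec, nAdd = 5000L, minSize = 5L,
                            threshold = 0.85, kCommon = 4L, strict = TRUE,
                            allZero = "one") {
  if (is.character(spec)) spec <- metricSpec(spec)
  nAdd <- as.integer(nAdd)
  stopifnot(is(seed, "SelectionResult"), nAdd >= 1L)
  seedPos <- match(seed@ids, lib@ids)
  if (anyNA(seedPos)) stop("seed picks are not a subset of the library")
  cl <- .poolJP(lib, spec, threshold, kCommon, strict, allZero)
  simFun <- makeSimFun(lib, spec, allZero)
  labels <- cl@labels
  nC <- nClusters(cl)
  med <- clusterMedoidPositions(labels, simFun)
  sizes <- clusterSizes(cl)
  selCount <- tabulate(labels[seedPos], nC)
  selected <- logical(length(lib)); selected[seedPos] <- TRUE
  budget <- nAdd
  addPos <- integer(0); addSrc <- integer(0)
  audit <- list()
  ## phase 1: top up undersized selected clusters (cluster-id order, i.e.
  ## descending cluster size)
  for (c in which(selCount > 0L & selCount < minSize)) {
    if (budget <= 0L) break
    mem <- which(labels == c & !selected)
    if (length(mem) == 0L) next
    s <- drop(simFun(mem, med[c]))
    mem <- mem[order(-s, mem)]
    take <- mem[seq_len(min(minSize - selCount[c], length(mem), budget))]
    addPos <- c(addPos, take); addSrc <- c(addSrc, rep.int(c, length(take)))
    selected[take] <- TRUE
    budget <- budget - length(take)
    audit[[length(audit) + 1L]] <-
      data.frame(cluster = c, type = "fill", added = length(take))
  }
  ## phase 2: new clusters in max-min order from the touched ones
  if (budget > 0L) {
    touched <- which(selCount > 0L)
    newOrd <- maxMinClusterOrder(med, simFun, which(selCount == 0L),
                                 chosen = touched)
    for (c in newOrd) {
      if (budget <= 0L) break
      mem <- .clusterPickOrder(which(labels == c), med[c], simFun)
      take <- mem[seq_len(min(minSize, length(mem), budget))]
      addPos <- c(addPos, take); addSrc <- c(addSrc, rep.int(c, length(take)))
      selected[take] <- TRUE
      budget <- budget - length(take)
      audit[[length(audit) + 1L]] <-
        data.frame(cluster = c, type = "new", added = length(take))
    }
  }
  shortfall <- budget > 0L
  if (shortfall)
    warning("pool exhausted: ", budget, " of ", nAdd,
            " refill additions could not be made")
  pos <- c(seedPos, addPos)
  phase <- c(rep("seed", length(seedPos)), rep("refill", length(addPos)))
  src <- c(labels[seedPos], addSrc)
  .newSelection(lib, pos, phase, src, length(seedPos) + nAdd, spec@scheme,
                shortfall = shortfall,
                parameters = list(threshold = threshold, kCommon = kCommon,
                                  minSize = minSize, clustering = cl,
                                  audit = if (length(audit))
                                    do.call(rbind, audit)
                                  else data.frame(cluster = integer(0),
                                                  type = character(0),
                                                  added = integer(0)),
                                  seedScheme = seed@scheme))
}

#' Random selection baseline
#'
#' Uniform sample without replacement, fully determined by \code{rngSeed};
#' the global RNG state is left untouched.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param n number of compounds
#' @param rngSeed integer seed
#' @return a \linkS4class{SelectionResult} with scheme "random"
#' @export
randomSelect <- function(lib, n, rngSeed) {
  n <- as.integer(n)
  if (n > length(lib)) stop("cannot sample ", n, " from ", length(lib))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(rngSeed))
  pos <- sample.int(length(lib), n)
  .newSelection(lib, pos, rep("seed", n), rep(NA_integer_, n), n, "random",
                rngSeed = rngSeed)
}

## ---- SelectionResult accessors --------------------------------------------

#' Picked compound ids of a selection
#' @param sel a \linkS4class{SelectionResult}
#' @param phase optionally restrict to "seed" or "refill" picks
#' @export
selectedIds <- function(sel, phase = NULL) {
  if (is.null(phase)) sel@ids else sel@ids[sel@phase == phase]
}

setMethod("length", "SelectionResult", function(x) length(x@ids))

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@scheme, "): ", length(object@ids),
      " picks (", sum(object@phase == "seed"), " seed, ",
      sum(object@phase == "refill"), " refill; target ",
      object@targetN, ")",
      if (object@shortfall) " [shortfall]", "\n", sep = "")
})

#' Serialize a selection to CSV (+ JSON parameter sidecar)
#'
#' Columns rank, id, phase, source_cluster, metric; parameters go to
#' \code{<path>.json}.
#'
#' @param sel a \linkS4class{SelectionResult}
#' @param path output CSV file
#' @export
writeSelection <- function(sel, path) {
  utils::write.csv(data.frame(rank = sel@rank, id = sel@ids,
                              phase = sel@phase,
                              source_cluster = sel@cluster,
                              metric = sel@scheme),
                   path, row.names = FALSE, quote = FALSE)
  pars <- sel@parameters
  pars$clustering <- NULL
  pars$audit <- NULL
  jsonlite::write_json(c(list(scheme = sel@scheme, targetN = sel@targetN,
                              rngSeed = sel@rngSeed,
                              shortfall = sel@shortfall), pars),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
}
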