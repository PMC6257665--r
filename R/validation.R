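## Diversity-validation statistics and the benchmark grid.
##
## A selection is judged by (1) how many "valid clusters" (>= 5 members)
## it forms under an independent clustering analysis, (2) how well its
## clusters are separated (average maximal inter-cluster similarity,
## lower = better), (3) how consistent its clusters are with the
## descriptor-free SCA classes, (4) whether it oversamples the largest
## scaffold class, and (5) how much different selection methods overlap.

## neighbor table over an arbitrary position subset of a library, reusing
## the library-level descriptor cache
.subsetNeighborTable <- function(lib, pos, spec, threshold = 0.85,
                                 strict = TRUE, allZero = "one") {
  simFun <- makeSimFun(lib, spec, allZero)
  n <- length(pos)
  nbr <- vector("list", n); sim <- vector("list", n)
  for (start in seq(1L, n, by = 1024L)) {
    rows <- start:min(start + 1023L, n)
    s <- simFun(pos[rows], pos)
    for (r in seq_along(rows)) {
      i <- rows[r]
      v <- s[r, ]
      hit <- if (strict) which(v > threshold) else which(v >= threshold)
      hit <- hit[hit != i]
      o <- order(-v[hit], hit)
      nbr[[i]] <- hit[o]; sim[[i]] <- unname(v[hit[o]])
    }
  }
  new("NeighborTable", ids = lib@ids[pos], nbr = nbr, sim = sim,
      threshold = threshold, scheme = spec@scheme, strict = strict)
}

#' Cluster a selection under a validation analysis
#'
#' Re-clusters the selected compounds only (not the full pool): D1/D2 via
#' Jarvis-Patrick under that scheme, "SCA" by exact cyclicity.
#'
#' @param sel a \linkS4class{SelectionResult} or character vector of ids
#' @param lib the full \linkS4class{CompoundLibrary}
#' @param analysis "D1", "D2" (or any D-scheme) or "SCA"
#' @param threshold,kCommon Jarvis-Patrick validation parameters
#' @param fullPool cluster the selection in the context of the whole pool
#'   instead (selection compounds then keep their pool cluster labels)
#' @return a \linkS4class{ClusterResult} over the selected compounds
#' @export
analysisClustering <- function(sel, lib, analysis, threshold = 0.85,
                               kCommon = 4L, fullPool = FALSE) {
  ids <- if (is(sel, "SelectionResult")) sel@ids else sel
  pos <- match(ids, lib@ids)
  if (anyNA(pos)) stop("selection is not a subset of the library")
  if (analysis == "SCA")
    return(scaCluster(lib[pos]))
  spec <- metricSpec(analysis)
  if (fullPool) {
    cl <- .poolJP(lib, spec, threshold, kCommon)
    sub <- cl@labels[pos]
    return(new("ClusterResult", ids = ids, labels = .denseLabels(sub),
               method = paste0(analysis, "/pool"),
               parameters = cl@parameters))
  }
  nt <- .subsetNeighborTable(lib, pos, spec, threshold)
  jarvisPatrick(nt, kCommon)
}

#' Number of valid clusters in a selection
#'
#' Clusters the selected compounds under the analysis method and counts
#' clusters with at least \code{minSize} members.
#'
#' @inheritParams analysisClustering
#' @param minSize validity cutoff (default 5)
#' @return integer count
#' @export
countValidClusters <- function(sel, lib, analysis, minSize = 5L,
                               threshold = 0.85, kCommon = 4L) {
  ids <- if (is(sel, "SelectionResult")) sel@ids else sel
  if (length(ids) == 0L) return(0L)
  cl <- analysisClustering(ids, lib, analysis, threshold, kCommon)
  sum(clusterSizes(cl) >= minSize)
}

#' Average maximal inter-cluster similarity (AMIS)
#'
#' For every cluster, the similarity between its medoid and the medoid of
#' its most similar other cluster, averaged over clusters. Lower values
#' mean better-separated clusters.
#'
#' @param clustering a \linkS4class{ClusterResult}
#' @param lib the \linkS4class{CompoundLibrary} the clustering refers to
#' @param spec a \linkS4class{MetricSpec} or scheme name for the
#'   similarity measurements
#' @param allZero see \code{\link{tanimoto}}
#' @return the AMIS value in [0, 1]
#' @export
avgMaxInterclusterSimilarity <- function(clustering, lib, spec,
                                         allZero = "one") {
  if (is.character(spec)) spec <- metricSpec(spec)
  nC <- nClusters(clustering)
  if (nC < 2L)
    stop("average maximal inter-cluster similarity is undefined for fewer ",
         "than 2 clusters")
  pos <- match(clustering@ids, lib@ids)
  if (anyNA(pos)) stop("clustering ids not found in the library")
  simFun <- makeSimFun(lib, spec, allZero)
  med <- clusterMedoidPositions(clustering@labels,
                                function(i, j) simFun(pos[i], pos[j]))
  medPos <- pos[med]
  maxSim <- rep(-Inf, nC)
  for (start in seq(1L, nC, by = 512L)) {
    idx <- start:min(start + 511L, nC)
    s <- simFun(medPos[idx], medPos)
    s[cbind(seq_along(idx), idx)] <- -Inf
    maxSim[idx] <- apply(s, 1L, max)
  }
  mean(maxSim)
}

#' Scaffold-consistency histogram of a selection clustering
#'
#' For each cluster of the selection clustering, counts how many distinct
#' SCA classes its members span: 1 means the cluster agrees exactly with
#' the scaffold classification, larger numbers mean it straddles several
#' scaffold classes. Counts of five and above are pooled into "5+".
#'
#' @param selectionClustering a \linkS4class{ClusterResult}
#' @param sca an SCA \linkS4class{ClusterResult} over the same compounds
#' @return named integer vector over c("1","2","3","4","5+")
#' @export
scaConsistency <- function(selectionClustering, sca) {
  if (!setequal(selectionClustering@ids, sca@ids))
    stop("the two clusterings cover different compound sets")
  scaLab <- sca@labels[match(selectionClustering@ids, sca@ids)]
  span <- vapply(split(scaLab, selectionClustering@labels),
                 function(x) length(unique(x)), 1L)
  pooled <- pmin(span, 5L)
  out <- tabulate(pooled, 5L)
  stats::setNames(out, c("1", "2", "3", "4", "5+"))
}

#' Overlap distribution across selections
#'
#' For every compound picked by at least one selection, the number of
#' selections that picked it; returned as a histogram over 1..K for K
#' selections.
#'
#' @param selections list of \linkS4class{SelectionResult}s (or id
#'   vectors) over the same library
#' @return named integer vector; entry "k" counts compounds picked by
#'   exactly k selections
#' @export
overlapDistribution <- function(selections) {
  if (length(selections) < 2L) stop("need at least 2 selections")
  idLists <- lapply(selections, function(s)
    if (is(s, "SelectionResult")) s@ids else s)
  counts <- table(unlist(idLists, use.names = FALSE))
  k <- length(selections)
  stats::setNames(tabulate(counts, k), as.character(seq_len(k)))
}

#' Fraction of a selection inside the largest scaffold class
#'
#' The reference class is the globally largest SCA cluster of the full
#' library (dense cluster id 1). Oversampling of the dominant scaffold
#' family shows up as a large fraction.
#'
#' @param sel a \linkS4class{SelectionResult} or id vector
#' @param sca the SCA \linkS4class{ClusterResult} of the full library
#' @return fraction in [0, 1]
#' @export
largestClusterFraction <- function(sel, sca) {
  ids <- if (is(sel, "SelectionResult")) sel@ids else sel
  if (length(ids) == 0L) return(0)
  lab <- sca@labels[match(ids, sca@ids)]
  if (anyNA(lab)) stop("selection compounds missing from the SCA clustering")
  mean(lab == 1L)
}

## ---- benchmark grid --------------------------------------------------------

#' Run the full diversity benchmark grid
#'
#' Executes every cell of the selection-method grid: descriptor schemes
#' (default D1-D9) x validation analyses (D1, D2, SCA) x protocol steps
#' (seed, refill) x runs (one optimal start plus three random starts) --
#' 9 x 3 x 2 x 4 = 216 experiments with the defaults. Each cell records
#' the valid-cluster count, AMIS (for similarity-based analyses with at
#' least two clusters) and the largest-SCA-class fraction of the selection
#' it evaluates. Per-cell failures are recorded in the manifest without
#' aborting unless \code{strict}.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param schemes descriptor schemes to test (default D1-D9)
#' @param analyses validation analyses (default D1, D2, SCA)
#' @param steps protocol steps (default seed and refill)
#' @param randomSeeds RNG seeds of the three random starts
#' @param seedN,refillN,minSize protocol sizes (defaults 500 / 5000 / 5)
#' @param threshold,kCommon Jarvis-Patrick parameters for selection and
#'   analysis clusterings
#' @param strict abort on the first cell failure
#' @param verbose print progress
#' @return list with \code{manifest} (one row per experiment),
#'   \code{selections} (named list of \linkS4class{SelectionResult}s),
#'   \code{consistency} (scaffold-consistency histograms of the optimal
#'   seed selections), \code{overlap} (per-step overlap histograms across
#'   methods incl. the random baselines) and \code{sca} (the full-library
#'   SCA clustering)
#' @export
runBenchmark <- function(lib, schemes = paste0("D", 1:9),
                         analyses = c("D1", "D2", "SCA"),
                         steps = c("seed", "refill"),
                         randomSeeds = c(1L, 2L, 3L),
                         seedN = 500L, refillN = 5000L, minSize = 5L,
                         threshold = 0.85, kCommon = 4L,
                         strict = FALSE, verbose = interactive()) {
  if (length(schemes) == 0L) stop("empty scheme list")
  stopifnot(length(analyses) >= 1L, length(steps) >= 1L)
  runs <- c("opt", if (length(randomSeeds))
    paste0("R", seq_along(randomSeeds), "_S"))
  sca <- scaCluster(lib)
  say <- function(...) if (verbose) message(...)

  ## random starts are scheme-independent
  randStarts <- stats::setNames(
    lapply(randomSeeds, function(s) randomSelect(lib, seedN, s)),
    runs[-1L])

  selections <- list()
  for (sc in schemes) {
    say("scheme ", sc)
    spec <- metricSpec(sc)
    selections[[paste(sc, "opt", "seed", sep = ".")]] <-
      selectSeed(lib, spec, n = seedN, membersPerCluster = minSize,
                 threshold = threshold, kCommon = kCommon)
    for (r in names(randStarts))
      selections[[paste(sc, r, "seed", sep = ".")]] <- randStarts[[r]]
    if ("refill" %in% steps) {
      for (r in runs) {
        seedSel <- selections[[paste(sc, r, "seed", sep = ".")]]
        selections[[paste(sc, r, "refill", sep = ".")]] <-
          refillSelection(lib, seedSel, spec, nAdd = refillN,
                          minSize = minSize, threshold = threshold,
                          kCommon = kCommon)
      }
    }
  }

  rows <- list()
  for (sc in schemes) for (an in analyses) for (st in steps) for (r in runs) {
    sel <- selections[[paste(sc, r, st, sep = ".")]]
    cell <- tryCatch({
      vc <- countValidClusters(sel, lib, an, minSize = minSize,
                               threshold = threshold, kCommon = kCommon)
      amis <- NA_real_
      if (an != "SCA") {
        cl <- analysisClustering(sel, lib, an, threshold, kCommon)
        if (nClusters(cl) >= 2L)
          amis <- avgMaxInterclusterSimilarity(cl, lib, an)
      }
      data.frame(scheme = sc, analysis = an, step = st, run = r,
                 n_selected = length(sel),
                 valid_clusters = vc, amis = amis,
                 largest_sca_fraction = largestClusterFraction(sel, sca),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      if (strict) stop(e)
      data.frame(scheme = sc, analysis = an, step = st, run = r,
                 n_selected = length(sel),
                 valid_clusters = NA_integer_, amis = NA_real_,
                 largest_sca_fraction = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- cell
  }
  manifest <- do.call(rbind, rows)

  consistency <- lapply(stats::setNames(schemes, schemes), function(sc) {
    sel <- selections[[paste(sc, "opt", if ("seed" %in% steps) "seed"
                             else steps[1L], sep = ".")]]
    cl <- analysisClustering(sel, lib, sc, threshold, kCommon)
    scaConsistency(cl, scaCluster(lib[match(sel@ids, lib@ids)]))
  })

  overlap <- lapply(stats::setNames(steps, steps), function(st) {
    sels <- c(lapply(schemes, function(sc)
                selections[[paste(sc, "opt", st, sep = ".")]]),
              if (st == "seed") randStarts
              else lapply(names(randStarts), function(r)
                selections[[paste(schemes[1L], r, st, sep = ".")]]))
    if (length(sels) >= 2L) overlapDistribution(sels) else NULL
  })

  list(manifest = manifest, selections = selections,
       consistency = consistency, overlap = overlap, sca = sca)
}

#' Dense ranks of the schemes under each analysis
#'
#' Ranks the optimal selections of one protocol step by valid-cluster
#' count within each analysis (dense ranking, rank 1 best, ties share the
#' better rank), and reports each scheme's mean rank across analyses.
#'
#' @param manifest a benchmark manifest (see \code{\link{runBenchmark}})
#' @param step protocol step to rank (default "seed")
#' @param run which run to rank (default "opt")
#' @return data.frame of per-analysis ranks and the mean rank per scheme
#' @export
schemeRanks <- function(manifest, step = "seed", run = "opt") {
  m <- manifest[manifest$step == step & manifest$run == run, ]
  if (nrow(m) == 0L) stop("no manifest rows for step ", step)
  analyses <- unique(m$analysis)
  schemes <- unique(m$scheme)
  rk <- vapply(analyses, function(an) {
    sub <- m[m$analysis == an, ]
    v <- sub$valid_clusters[match(schemes, sub$scheme)]
    ## dense rank, higher count = better (rank 1), ties share the better rank
    u <- sort(unique(v[!is.na(v)]), decreasing = TRUE)
    match(v, u)
  }, integer(length(schemes)))
  rk <- matrix(rk, nrow = length(schemes),
               dimnames = list(schemes, analyses))
  data.frame(scheme = schemes, rk,
             meanRank = rowMeans(rk, na.rm = TRUE),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write benchmark results as CSV tables + JSON manifest
#'
#' One file per report: valid_clusters.csv, amis.csv, consistency.csv,
#' largest_cluster_fraction.csv, overlap_<step>.csv, manifest.csv and
#' manifest.json (parameters and any per-cell errors).
#'
#' @param res result of \code{\link{runBenchmark}}
#' @param outDir output directory (created if missing)
#' @export
writeBenchmark <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(outDir, f),
                                        row.names = FALSE, quote = FALSE)
  m <- res$manifest
  w(m, "manifest.csv")
  w(stats::reshape(m[, c("scheme", "analysis", "step", "run",
                         "valid_clusters")],
                   idvar = c("scheme", "step", "run"),
                   timevar = "analysis", direction = "wide"),
    "valid_clusters.csv")
  w(m[!is.na(m$amis), c("scheme", "analysis", "step", "run", "amis")],
    "amis.csv")
  w(unique(m[, c("scheme", "step", "run", "largest_sca_fraction")]),
    "largest_cluster_fraction.csv")
  cons <- do.call(rbind, lapply(names(res$consistency), function(sc)
    data.frame(scheme = sc, t(res$consistency[[sc]]),
               check.names = FALSE)))
  w(cons, "consistency.csv")
  for (st in names(res$overlap))
    if (!is.null(res$overlap[[st]]))
      w(data.frame(n_methods = names(res$overlap[[st]]),
                   compounds = as.integer(res$overlap[[st]])),
        paste0("overlap_", st, ".csv"))
  jsonlite::write_json(
    list(experiments = nrow(m),
         failed = sum(!is.na(m$error)),
         schemes = unique(m$scheme), analyses = unique(m$analysis),
         steps = unique(m$step), runs = unique(m$run)),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  invisible(outDir)
}
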