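## Jarvis-Patrick clustering and the scaffold classification approach (SCA).

## dense cluster ids: descending size, ties by smallest member position
.denseLabels <- function(raw) {
  sizes <- table(raw)
  firstPos <- tapply(seq_along(raw), raw, min)
  o <- order(-as.integer(sizes), as.integer(firstPos))
  ranks <- integer(length(sizes))
  ranks[o] <- seq_along(o)
  as.integer(ranks[match(raw, names(sizes))])
}

#' Jarvis-Patrick clustering
#'
#' Two compounds are linked when (by the default conventions) they are
#' neighbors of each other and share at least \code{kCommon} common
#' neighbors, each compound counting as a member of its own neighbor list.
#' Clusters are the connected components of the link graph ("connects two
#' structures"), so linkage is single-link over the Jarvis-Patrick graph.
#' Both conventions can be toggled.
#'
#' @param nbrs a \linkS4class{NeighborTable}
#' @param kCommon minimum number of shared neighbors (default 4)
#' @param includeSelf count each compound in its own neighbor list
#'   (default TRUE)
#' @param requireMutual require the pair itself to be neighbors before
#'   linking (default TRUE)
#' @return a \linkS4class{ClusterResult}
#' @export
jarvisPatrick <- function(nbrs, kCommon = 4L, includeSelf = TRUE,
                          requireMutual = TRUE) {
  stopifnot(is(nbrs, "NeighborTable"))
  kCommon <- as.integer(kCommon)
  if (kCommon < 1L) stop("kCommon must be >= 1")
  n <- length(nbrs@ids)
  deg <- lengths(nbrs@nbr)
  i <- rep.int(seq_len(n), deg)
  j <- unlist(nbrs@nbr, use.names = FALSE)
  if (is.null(j)) j <- integer(0)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  if (includeSelf) A <- A + Matrix::Diagonal(n)
  Aadj <- if (requireMutual)
    Matrix::sparseMatrix(i = i, j = j, x = TRUE, dims = c(n, n))
  ## Common-neighbor counts C = A %*% A are computed in column blocks and
  ## immediately contracted into component labels, so the link graph of a
  ## dense neighborhood (which can approach n^2 edges) never exists as a
  ## whole. Link edges only merge components, so streaming them through
  ## label contraction is exact.
  comp <- seq_len(n)
  blockCols <- 2048L
  for (start in seq(1L, n, by = blockCols)) {
    cols <- start:min(start + blockCols - 1L, n)
    Cb <- A %*% A[, cols, drop = FALSE]
    Lb <- Cb >= kCommon
    if (requireMutual) Lb <- Lb & Aadj[, cols, drop = FALSE]
    Tb <- methods::as(Lb, "TsparseMatrix")
    keep <- Tb@x
    ei <- Tb@i[keep] + 1L
    ej <- cols[Tb@j[keep] + 1L]
    sel <- ei != ej
    if (!any(sel)) next
    a <- comp[ei[sel]]; b <- comp[ej[sel]]
    ab <- unique(cbind(pmin(a, b), pmax(a, b))[a != b, , drop = FALSE])
    if (nrow(ab) == 0L) next
    verts <- unique(as.vector(ab))
    g <- igraph::graph_from_edgelist(
      matrix(match(ab, verts), ncol = 2L), directed = FALSE)
    mem <- igraph::components(g)$membership
    rep <- vapply(split(verts, mem), min, 1L)
    map <- seq_len(n)
    map[verts] <- rep[mem]
    comp <- map[comp]
  }
  new("ClusterResult", ids = nbrs@ids, labels = .denseLabels(comp),
      method = nbrs@scheme,
      parameters = list(threshold = nbrs@threshold, strict = nbrs@strict,
                        kCommon = kCommon, includeSelf = includeSelf,
                        requireMutual = requireMutual))
}

## ---- SCA -------------------------------------------------------------------

.gcd <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }

## exact reduced ring-bond fraction as a string key ("0/1" for bond-less)
.cyclicityKey <- function(mol) {
  b <- bondCount(mol)
  if (b == 0L) return("0/1")
  r <- ringBondCount(mol)
  g <- .gcd(if (r > 0L) r else b, b)
  paste0(r %/% g, "/", b %/% g)
}

#' SCA profile of a molecule
#'
#' The scaffold classification approach characterizes a compound by two
#' descriptor-free numbers: \emph{cyclicity}, the percentage of ring bonds
#' among all bonds (0 for bond-less molecules), and \emph{complexity}, a
#' size measure. The exact complexity formula of the original approach is
#' not public; this package uses the documented surrogate
#' \code{heavyAtomCount + bondCount}, which is reported but never used for
#' cluster membership.
#'
#' @param mol a \linkS4class{Molecule}
#' @return list with \code{complexity}, \code{cyclicity} (percent) and the
#'   exact rational \code{cyclicityKey} used for clustering
#' @examples
#' scaProfile(parseSmiles("Cc1ccccc1", "toluene"))$cyclicity  # 600/7
#' @export
scaProfile <- function(mol) {
  b <- bondCount(mol)
  list(complexity = heavyAtomCount(mol) + b,
       cyclicity = if (b == 0L) 0 else 100 * ringBondCount(mol) / b,
       cyclicityKey = .cyclicityKey(mol))
}

#' SCA profiles of a whole library
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @return data.frame with id, complexity, cyclicity, cyclicityKey
#' @export
scaProfiles <- function(lib) {
  stopifnot(is(lib, "CompoundLibrary"))
  data.frame(
    id = lib@ids,
    complexity = vapply(lib@molecules, function(m)
      heavyAtomCount(m) + bondCount(m), 1L),
    cyclicity = vapply(lib@molecules, function(m) {
      b <- bondCount(m); if (b == 0L) 0 else 100 * ringBondCount(m) / b
    }, 1),
    cyclicityKey = vapply(lib@molecules, .cyclicityKey, ""),
    stringsAsFactors = FALSE)
}

#' SCA clustering by exact cyclicity
#'
#' Groups compounds with identical cyclicity, computed as the exact reduced
#' rational ring_bonds/bonds so floating-point ties cannot split a scaffold
#' class. An optional binning width (percentage points) merges nearby
#' classes for noisy real-world collections; it is off by default.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param binWidth optional bin width in cyclicity percentage points
#' @return a \linkS4class{ClusterResult} with method "SCA"
#' @export
scaCluster <- function(lib, binWidth = NULL) {
  stopifnot(is(lib, "CompoundLibrary"), length(lib) >= 1L)
  key <- if (is.null(binWidth)) {
    vapply(lib@molecules, .cyclicityKey, "")
  } else {
    prof <- scaProfiles(lib)
    as.character(floor(prof$cyclicity / binWidth))
  }
  new("ClusterResult", ids = lib@ids, labels = .denseLabels(key),
      method = "SCA",
      parameters = list(binWidth = binWidth))
}

## ---- ClusterResult accessors ----------------------------------------------

#' Number of clusters in a clustering
#' @param cr a \linkS4class{ClusterResult}
#' @export
nClusters <- function(cr) max(cr@labels, 0L)

#' Members of each cluster
#' @param cr a \linkS4class{ClusterResult}
#' @return list of character vectors of compound ids, by cluster id
#' @export
clusterMembers <- function(cr)
  split(cr@ids, factor(cr@labels, levels = seq_len(nClusters(cr))))

#' Cluster sizes (indexed by cluster id)
#' @param cr a \linkS4class{ClusterResult}
#' @export
clusterSizes <- function(cr) tabulate(cr@labels, nClusters(cr))

#' Cluster labels, named by compound id
#' @param cr a \linkS4class{ClusterResult}
#' @export
clusterLabels <- function(cr) stats::setNames(cr@labels, cr@ids)

setMethod("length", "ClusterResult", function(x) length(x@ids))

setMethod("show", "ClusterResult", function(object) {
  sz <- clusterSizes(object)
  cat("ClusterResult (", object@method, "): ", length(object@ids),
      " compounds in ", nClusters(object), " clusters (",
      sum(sz == 1L), " singletons, largest ", if (length(sz)) max(sz) else 0,
      ")\n", sep = "")
})

#' Serialize a clustering to CSV (+ JSON parameter sidecar)
#'
#' Writes "id,cluster_id,cluster_size" rows; parameters and method go to
#' \code{<path>.json}.
#'
#' @param cr a \linkS4class{ClusterResult}
#' @param path output CSV file
#' @export
writeClusters <- function(cr, path) {
  sz <- clusterSizes(cr)
  utils::write.csv(data.frame(id = cr@ids, cluster_id = cr@labels,
                              cluster_size = sz[cr@labels]),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(method = cr@method), cr@parameters),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
}
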