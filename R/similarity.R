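## Tanimoto similarity, the nine similarity schemes D1-D9, similarity
## matrices and thresholded neighbor tables.
##
## D1  Tanimoto on 2,048-bit path fingerprints
## D2  Tanimoto on the 166-bit structural keys
## D3  Max of the two pure Tanimoto values
## D4  Min of the two pure Tanimoto values
## D5  Avg of the two pure Tanimoto values
## D6  Tanimoto on 2048+166 = 2,214 concatenated bits
## D7  Tanimoto on 1024+166 = 1,190 concatenated bits (one fold)
## D8  Tanimoto on  512+166 =   678 concatenated bits (two folds)
## D9  Tanimoto on  256+166 =   422 concatenated bits (three folds)

.SCHEMES <- data.frame(
  scheme = paste0("D", 1:9),
  mode = c("pure_path", "pure_keys", "max", "min", "avg",
           "concat", "concat", "concat", "concat"),
  pathBits = c(2048L, NA, 2048L, 2048L, 2048L, 2048L, 1024L, 512L, 256L),
  usesKeys = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Construct a similarity-scheme specification
#'
#' @param scheme one of "D1" .. "D9"
#' @return a \linkS4class{MetricSpec}
#' @examples
#' metricSpec("D4")  # Min consensus of path and key Tanimoto
#' @export
metricSpec <- function(scheme) {
  i <- match(scheme, .SCHEMES$scheme)
  if (is.na(i)) stop("unknown scheme: ", scheme,
                     " (expected one of D1..D9)")
  new("MetricSpec", scheme = .SCHEMES$scheme[i], mode = .SCHEMES$mode[i],
      pathBits = .SCHEMES$pathBits[i], usesKeys = .SCHEMES$usesKeys[i])
}

setMethod("show", "MetricSpec", function(object) {
  cat("MetricSpec ", object@scheme, " (", object@mode,
      if (!is.na(object@pathBits)) paste0(", pathBits=", object@pathBits),
      ")\n", sep = "")
})

## ---- Tanimoto --------------------------------------------------------------

#' Tanimoto similarity of two fingerprints
#'
#' |A and B| / |A or B| over the set bits. Two all-zero fingerprints are
#' indistinguishable to the descriptor and score 1 by default
#' (\code{allZero = "one"}); pass \code{allZero = "zero"} to score them 0.
#'
#' @param a,b logical bit vectors or single-compound
#'   \linkS4class{FingerprintSet}s of equal length
#' @param allZero value of the 0/0 case: "one" (default) or "zero"
#' @return similarity in [0, 1]
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))  # 1/3
#' @export
tanimoto <- function(a, b, allZero = c("one", "zero")) {
  allZero <- match.arg(allZero)
  if (is(a, "FingerprintSet")) a <- as.logical(a@bits[1L, ])
  if (is(b, "FingerprintSet")) b <- as.logical(b@bits[1L, ])
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0L) return(if (allZero == "one") 1 else 0)
  sum(a & b) / u
}

#' Consensus of a path-based and a key-based similarity
#'
#' @param sPath,sKeys similarities in [0, 1]
#' @param mode "max", "min" or "avg"
#' @return the consensus similarity
#' @export
consensusSimilarity <- function(sPath, sKeys, mode = c("max", "min", "avg")) {
  mode <- match.arg(mode)
  stopifnot(all(sPath >= 0 & sPath <= 1), all(sKeys >= 0 & sKeys <= 1))
  switch(mode,
         max = pmax(sPath, sKeys),
         min = pmin(sPath, sKeys),
         avg = (sPath + sKeys) / 2)
}

## blockwise Tanimoto between rows of logical matrices A and B
.tanimotoBlock <- function(A, B, allZero = "one") {
  ints <- tcrossprod(A, B)
  uni <- outer(rowSums(A), rowSums(B), "+") - ints
  s <- ints / uni
  s[uni == 0] <- if (allZero == "one") 1 else 0
  s
}

## ---- scheme-level descriptor access ---------------------------------------

## Numeric (0/1) descriptor matrices for a scheme, cached on the library.
.schemeMatrices <- function(lib, spec, allZero = "one") {
  key <- paste0("schemeM_", spec@scheme)
  if (!is.null(lib@cache[[key]])) return(lib@cache[[key]])
  pathM <- NULL; keysM <- NULL
  if (spec@mode != "pure_keys") {
    folds <- as.integer(log2(2048L / spec@pathBits))
    fp <- pathFingerprint(lib)
    if (folds > 0L) fp <- foldFingerprint(fp, folds)
    pathM <- fp@bits + 0
  }
  if (spec@usesKeys) keysM <- structuralKeys(lib)@bits + 0
  res <- switch(spec@mode,
    pure_path = list(single = pathM),
    pure_keys = list(single = keysM),
    concat = list(single = cbind(pathM, keysM)),
    list(path = pathM, keys = keysM))
  assign(key, res, envir = lib@cache)
  res
}

## Similarity closure for a library under a scheme: sim(i, j) returns the
## |i| x |j| block of pairwise similarities (library positions).
makeSimFun <- function(lib, spec, allZero = "one") {
  mats <- .schemeMatrices(lib, spec)
  if (!is.null(mats$single)) {
    M <- mats$single
    function(i, j)
      .tanimotoBlock(M[i, , drop = FALSE], M[j, , drop = FALSE], allZero)
  } else {
    P <- mats$path; K <- mats$keys
    mode <- spec@mode
    function(i, j) {
      sp <- .tanimotoBlock(P[i, , drop = FALSE], P[j, , drop = FALSE], allZero)
      sk <- .tanimotoBlock(K[i, , drop = FALSE], K[j, , drop = FALSE], allZero)
      consensusSimilarity(sp, sk, mode)
    }
  }
}

#' Similarity of two molecules under a scheme
#'
#' @param molA,molB \linkS4class{Molecule}s
#' @param spec a \linkS4class{MetricSpec} or scheme name
#' @param allZero see \code{\link{tanimoto}}
#' @return similarity in [0, 1]
#' @export
metricSimilarity <- function(molA, molB, spec, allZero = "one") {
  if (is.character(spec)) spec <- metricSpec(spec)
  lib <- new("CompoundLibrary",
             molecules = list(molA, molB),
             ids = c("a@1", "b@2"), duplicated = c(FALSE, FALSE),
             cache = new.env(parent = emptyenv()))
  makeSimFun(lib, spec, allZero)(1L, 2L)[1L, 1L]
}

#' Pairwise similarity matrix of a library
#'
#' Descriptors are computed once per compound (cached on the library); the
#' matrix is symmetric with unit diagonal. Materializing the full matrix is
#' refused above \code{maxCompounds} compounds -- use
#' \code{\link{neighborTable}} for large libraries.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param spec a \linkS4class{MetricSpec} or scheme name
#' @param allZero see \code{\link{tanimoto}}
#' @param maxCompounds refuse to materialize above this size (default 5000)
#' @return numeric matrix with compound ids as dimnames
#' @export
similarityMatrix <- function(lib, spec, allZero = "one",
                             maxCompounds = 5000L) {
  if (is.character(spec)) spec <- metricSpec(spec)
  n <- length(lib)
  stopifnot(n >= 1L)
  if (n > maxCompounds)
    stop("library too large to materialize a full matrix (", n, " > ",
         maxCompounds, "); use neighborTable()")
  s <- makeSimFun(lib, spec, allZero)(seq_len(n), seq_len(n))
  dimnames(s) <- list(lib@ids, lib@ids)
  s
}

## ---- neighbor tables -------------------------------------------------------

#' Thresholded neighbor table
#'
#' Two compounds are neighbors when their similarity exceeds the threshold
#' (strictly by default, matching the protocol's definition; set
#' \code{strict = FALSE} for ">=", useful for duplicate-heavy sets).
#' Computed blockwise from the descriptors without materializing the full
#' similarity matrix.
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param spec a \linkS4class{MetricSpec} or scheme name
#' @param threshold similarity threshold in (0, 1]; default 0.85
#' @param strict TRUE for "> threshold", FALSE for ">="
#' @param allZero see \code{\link{tanimoto}}
#' @param blockSize rows per block (default 1024)
#' @return a \linkS4class{NeighborTable}
#' @export
neighborTable <- function(lib, spec, threshold = 0.85, strict = TRUE,
                          allZero = "one", blockSize = 1024L) {
  if (is.character(spec)) spec <- metricSpec(spec)
  stopifnot(threshold > 0, threshold <= 1)
  ## memoized on the library: Seed, Refill and pool-context analyses all
  ## consult the same table
  cacheKey <- paste("nt", spec@scheme, threshold, strict, allZero,
                    sep = "_")
  if (!is.null(lib@cache[[cacheKey]])) return(lib@cache[[cacheKey]])
  n <- length(lib)
  simFun <- makeSimFun(lib, spec, allZero)
  nbr <- vector("list", n)
  sim <- vector("list", n)
  all <- seq_len(n)
  for (start in seq(1L, n, by = blockSize)) {
    rows <- start:min(start + blockSize - 1L, n)
    s <- simFun(rows, all)
    for (r in seq_along(rows)) {
      i <- rows[r]
      v <- s[r, ]
      hit <- if (strict) which(v > threshold) else which(v >= threshold)
      hit <- hit[hit != i]
      o <- order(-v[hit], hit)
      nbr[[i]] <- hit[o]
      sim[[i]] <- unname(v[hit[o]])
    }
  }
  res <- new("NeighborTable", ids = lib@ids, nbr = nbr, sim = sim,
             threshold = threshold, scheme = spec@scheme, strict = strict)
  assign(cacheKey, res, envir = lib@cache)
  res
}

## Jarvis-Patrick clustering of the whole pool, memoized on the library.
.poolJP <- function(lib, spec, threshold, kCommon, strict = TRUE,
                    allZero = "one") {
  key <- paste("jp", spec@scheme, threshold, kCommon, strict, allZero,
               sep = "_")
  if (!is.null(lib@cache[[key]])) return(lib@cache[[key]])
  nt <- neighborTable(lib, spec, threshold, strict = strict,
                      allZero = allZero)
  res <- jarvisPatrick(nt, kCommon)
  assign(key, res, envir = lib@cache)
  res
}

setMethod("length", "NeighborTable", function(x) length(x@ids))

setMethod("show", "NeighborTable", function(object) {
  cat("NeighborTable: ", length(object@ids), " compounds, scheme=",
      object@scheme, ", threshold ",
      if (object@strict) "> " else ">= ", object@threshold,
      ", mean neighbors ", round(mean(lengths(object@nbr)), 2), "\n",
      sep = "")
})

#' Serialize a neighbor table to TSV
#'
#' Columns id, neighbor_id, similarity; a header comment records the scheme
#' and threshold.
#'
#' @param nt a \linkS4class{NeighborTable}
#' @param path output file
#' @export
writeNeighborTable <- function(nt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scheme=", nt@scheme, " threshold=", nt@threshold,
                    " strict=", nt@strict), con)
  writeLines("id\tneighbor_id\tsimilarity", con)
  for (i in seq_along(nt@ids)) {
    if (length(nt@nbr[[i]]))
      writeLines(paste(nt@ids[i], nt@ids[nt@nbr[[i]]],
                       format(nt@sim[[i]], digits = 6L), sep = "\t"), con)
  }
}
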