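## Hashed path fingerprints and fingerprint algebra (folding, concatenation,
## bit statistics, text serialization). The structural-key half of the
## descriptor system lives in keys.R.

.newFPSet <- function(bits, ids, kind, foldLevel = 0L, version = "") {
  rownames(bits) <- ids
  new("FingerprintSet", bits = bits, ids = ids, kind = kind,
      foldLevel = as.integer(foldLevel), version = version)
}

.pathBitsFromStrings <- function(pathSets, nBits, bitsPerPath) {
  n <- length(pathSets)
  bits <- matrix(FALSE, n, nBits)
  if (n == 0L) return(bits)
  all <- unlist(pathSets, use.names = FALSE)
  if (length(all)) {
    uniq <- unique(all)
    pos <- matrix(hashBitPositions(hash32(uniq), nBits, bitsPerPath),
                  nrow = length(uniq))
    idx <- match(all, uniq)
    row <- rep.int(seq_len(n), lengths(pathSets))
    for (j in seq_len(ncol(pos)))
      bits[cbind(row, pos[idx, j] + 1L)] <- TRUE
  }
  bits
}

#' Hashed linear-path fingerprint
#'
#' Every simple path of \code{minPath} to \code{maxPath} bonds is encoded
#' as a canonical path string (see \code{\link{molPathStrings}}), hashed,
#' and the hash seeds a deterministic generator that sets
#' \code{bitsPerPath} bits of an \code{nBits}-long vector. Identical
#' molecules yield identical fingerprints regardless of input atom order;
#' a molecule with no bonds yields the all-zero fingerprint.
#'
#' @param x a \linkS4class{Molecule} or \linkS4class{CompoundLibrary}
#' @param nBits fingerprint length; a power of two >= 64 (default 2048)
#' @param minPath,maxPath path length range in bonds (defaults 1 and 7)
#' @param bitsPerPath bits set per path (default 2)
#' @return a \linkS4class{FingerprintSet} (one row per molecule)
#' @examples
#' fp <- pathFingerprint(parseSmiles("Cc1ccccc1", "toluene"))
#' sum(fpBits(fp))
#' @export
setGeneric("pathFingerprint", function(x, nBits = 2048L, minPath = 1L,
                                       maxPath = 7L, bitsPerPath = 2L)
  standardGeneric("pathFingerprint"))

.checkNBits <- function(nBits) {
  if (nBits < 64L || bitwAnd(nBits, nBits - 1L) != 0L)
    stop("nBits must be a power of two >= 64")
}

.filterMinPath <- function(pathSets, minPath) {
  if (minPath <= 1L) return(pathSets)
  ## a path of k bonds has k+1 atom tokens; count bond tokens instead of
  ## characters since element symbols vary in width
  lapply(pathSets, function(p)
    p[lengths(regmatches(p, gregexpr("[-=#:]", p))) >= minPath])
}

#' @rdname pathFingerprint
setMethod("pathFingerprint", "Molecule",
  function(x, nBits = 2048L, minPath = 1L, maxPath = 7L, bitsPerPath = 2L) {
    .checkNBits(nBits)
    ps <- .filterMinPath(list(molPathStrings(x, maxPath)), minPath)
    .newFPSet(.pathBitsFromStrings(ps, nBits, bitsPerPath), x@id, "path")
  })

#' @rdname pathFingerprint
setMethod("pathFingerprint", "CompoundLibrary",
  function(x, nBits = 2048L, minPath = 1L, maxPath = 7L, bitsPerPath = 2L) {
    .checkNBits(nBits)
    key <- paste0("pathfp", nBits, "_", minPath, "_", maxPath, "_", bitsPerPath)
    if (!is.null(x@cache[[key]])) return(x@cache[[key]])
    ps <- .filterMinPath(libraryPathSets(x, maxPath), minPath)
    res <- .newFPSet(.pathBitsFromStrings(ps, nBits, bitsPerPath),
                     x@ids, "path")
    assign(key, res, envir = x@cache)
    res
  })

#' Fold a path fingerprint
#'
#' One fold halves the length by OR-ing the two halves (output bit i is the
#' OR of input bits i and i + length/2). Only path fingerprints fold; this
#' is how the shorter path parts of the concatenated schemes D7-D9 are
#' produced. Folding never increases the popcount, and folding twice is the
#' same as a single two-fold.
#'
#' @param fp a \linkS4class{FingerprintSet} of kind "path"
#' @param times number of halvings (default 1)
#' @return the folded \linkS4class{FingerprintSet}
#' @export
foldFingerprint <- function(fp, times = 1L) {
  stopifnot(is(fp, "FingerprintSet"))
  if (fp@kind != "path")
    stop("only path fingerprints can be folded")
  times <- as.integer(times)
  stopifnot(times >= 0L)
  bits <- fp@bits
  for (i in seq_len(times)) {
    len <- ncol(bits)
    if (len %% 2L != 0L) stop("fingerprint length not divisible by two")
    half <- len %/% 2L
    bits <- bits[, seq_len(half), drop = FALSE] |
            bits[, half + seq_len(half), drop = FALSE]
  }
  .newFPSet(bits, fp@ids, "path", fp@foldLevel + times)
}

#' Concatenate a path fingerprint with structural keys
#'
#' Produces the combined descriptors of schemes D6-D9: the (possibly
#' folded) path bits followed by the 166 key bits, e.g. 2048 + 166 = 2214
#' bits for D6 or 256 + 166 = 422 bits for D9.
#'
#' @param pathFp a \linkS4class{FingerprintSet} of kind "path"
#' @param keyFp a \linkS4class{FingerprintSet} of kind "keys" over the same
#'   compounds
#' @return a \linkS4class{FingerprintSet} of kind "combined"
#' @export
concatFingerprints <- function(pathFp, keyFp) {
  stopifnot(is(pathFp, "FingerprintSet"), is(keyFp, "FingerprintSet"))
  if (pathFp@kind != "path" || keyFp@kind != "keys")
    stop("concatenation requires one path and one keys fingerprint set")
  if (!identical(pathFp@ids, keyFp@ids))
    stop("fingerprint sets cover different compounds")
  .newFPSet(cbind(pathFp@bits, keyFp@bits), pathFp@ids, "combined",
            pathFp@foldLevel, keyFp@version)
}

#' Bit-setting statistics of a fingerprint collection
#'
#' Per-bit set probabilities, their mean, and the mean per-bit entropy
#' (-p log2 p - (1-p) log2 (1-p), with 0 log 0 = 0). The mean bit-setting
#' probability measures descriptor density; shorter foldings of the same
#' fingerprints are denser.
#'
#' @param fp a \linkS4class{FingerprintSet}
#' @return list with elements \code{setProbability} (per bit),
#'   \code{meanSetProbability} and \code{meanBitEntropy}
#' @export
bitStats <- function(fp) {
  stopifnot(is(fp, "FingerprintSet"))
  if (nrow(fp@bits) == 0L) stop("empty fingerprint collection")
  p <- colMeans(fp@bits)
  ent <- numeric(length(p))
  in01 <- p > 0 & p < 1
  q <- p[in01]
  ent[in01] <- -q * log2(q) - (1 - q) * log2(1 - q)
  list(setProbability = p,
       meanSetProbability = mean(p),
       meanBitEntropy = mean(ent))
}

## ---- accessors & serialization --------------------------------------------

#' Bit matrix of a fingerprint set
#' @param fp a \linkS4class{FingerprintSet}
#' @export
fpBits <- function(fp) fp@bits

#' Number of bits in a fingerprint set
#' @param fp a \linkS4class{FingerprintSet}
#' @export
fpLength <- function(fp) ncol(fp@bits)

setMethod("length", "FingerprintSet", function(x) nrow(x@bits))

setMethod("show", "FingerprintSet", function(object) {
  cat("FingerprintSet: ", nrow(object@bits), " x ", ncol(object@bits),
      " bits, kind=", object@kind,
      if (object@kind == "path" || object@kind == "combined")
        paste0(", foldLevel=", object@foldLevel),
      if (nzchar(object@version)) paste0(", keys=", object@version),
      "\n", sep = "")
})

#' Write fingerprints as hex-encoded text
#'
#' One line per compound: "<id> <length> <hex bits>". Bits are packed
#' most-significant-first in groups of four. \code{readFingerprints}
#' round-trips the format losslessly.
#'
#' @param fp a \linkS4class{FingerprintSet}
#' @param path output file
#' @export
writeFingerprints <- function(fp, path) {
  stopifnot(is(fp, "FingerprintSet"))
  nb <- ncol(fp@bits)
  pad <- (4L - nb %% 4L) %% 4L
  nib <- function(b) {
    b <- c(b, rep(FALSE, pad))
    m <- matrix(as.integer(b), nrow = 4L)
    v <- 8L * m[1L, ] + 4L * m[2L, ] + 2L * m[3L, ] + m[4L, ]
    paste(substring("0123456789abcdef", v + 1L, v + 1L), collapse = "")
  }
  hex <- apply(fp@bits, 1L, nib)
  meta <- paste0("# kind=", fp@kind, " foldLevel=", fp@foldLevel,
                 if (nzchar(fp@version)) paste0(" version=", fp@version))
  writeLines(c(meta, paste(fp@ids, nb, hex)), path)
}

#' @rdname writeFingerprints
#' @export
readFingerprints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  nb <- as.integer(vapply(parts, `[[`, "", 2L))
  stopifnot(length(unique(nb)) == 1L)
  nb <- nb[1L]
  hexmap <- strtoi(c(0:9, letters[1:6]), 16L)
  names(hexmap) <- c(0:9, letters[1:6])
  bits <- t(vapply(parts, function(p) {
    v <- hexmap[strsplit(p[[3L]], "")[[1L]]]
    b <- as.logical(c(bitwAnd(v, 8L), bitwAnd(v, 4L),
                      bitwAnd(v, 2L), bitwAnd(v, 1L)))
    dim(b) <- c(length(v), 4L)
    as.vector(t(b))[seq_len(nb)]
  }, logical(nb)))
  kind <- "path"; fold <- 0L; version <- ""
  if (length(meta)) {
    kv <- regmatches(meta[1L], gregexpr("[a-zA-Z]+=[^ ]+", meta[1L]))[[1L]]
    for (x in kv) {
      p <- strsplit(x, "=", fixed = TRUE)[[1L]]
      if (p[1L] == "kind") kind <- p[2L]
      if (p[1L] == "foldLevel") fold <- as.integer(p[2L])
      if (p[1L] == "version") version <- p[2L]
    }
  }
  .newFPSet(bits, ids, kind, fold, version)
}

#' Write a fingerprint set as a dense 0/1 CSV (one bit per column)
#' @param fp a \linkS4class{FingerprintSet}
#' @param path output file
#' @export
writeFingerprintsCSV <- function(fp, path) {
  df <- as.data.frame(fp@bits + 0L)
  names(df) <- paste0("bit", seq_len(ncol(df)))
  utils::write.csv(cbind(id = fp@ids, df), path, row.names = FALSE,
                   quote = FALSE)
}
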