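## Deterministic 32-bit hashing for path strings, in portable double
## arithmetic (all intermediates stay below 2^53). Hash values seed a small
## linear-congruential generator that draws the bit positions a path sets,
## so a fingerprint is fully determined by the path-string set.

## multiply a 32-bit value (held in a double) by a constant, mod 2^32
.mul32 <- function(h, mHi, mLo) {
  hLo <- h %% 65536
  hHi <- (h - hLo) / 65536
  t <- hLo * mLo
  u <- (hLo * mHi + hHi * mLo) %% 65536
  (t + u * 65536) %% 4294967296
}

## character -> byte lookup used by the hash (covers the path-string
## alphabet; anything else maps to 255)
.HASH_CHARS <- c(LETTERS, letters, 0:9, "-", "=", "#", ":", "+", "[", "]",
                 "(", ")", "*", "@", "/", "\\", ".", "%")

## FNV-1a-style 32-bit hash, vectorized over a character vector.
hash32 <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  nc <- nchar(x)
  h <- rep(2166136261, n)
  for (pos in seq_len(max(nc, 1L))) {
    act <- nc >= pos
    if (!any(act)) break
    b <- match(substring(x[act], pos, pos), .HASH_CHARS)
    b[is.na(b)] <- 255
    ## xor on the low 16 bits (byte values are < 256)
    lo <- h[act] %% 65536
    h[act] <- h[act] - lo + bitwXor(as.integer(lo), as.integer(b))
    ## FNV prime 16777619 = 256 * 65536 + 403
    h[act] <- .mul32(h[act], 256, 403)
  }
  h
}

## one step of the 32-bit LCG (Numerical Recipes constants)
lcg32 <- function(x) {
  ## 1664525 = 25 * 65536 + 26125
  (.mul32(x, 25, 26125) + 1013904223) %% 4294967296
}

## For each hashed path, draw `k` bit positions in [0, nBits). Returns an
## integer vector of 0-based positions (length k * length(h)).
hashBitPositions <- function(h, nBits, k = 2L) {
  out <- vector("list", k)
  x <- h
  for (j in seq_len(k)) {
    x <- lcg32(x)
    out[[j]] <- x %% nBits
  }
  as.integer(unlist(out))
}
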