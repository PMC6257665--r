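## Linear-path enumeration. A path of k bonds (1 <= k <= maxPath) is a
## simple walk in the heavy-atom graph; it is encoded as a string of atom
## tokens (element symbol, lowercased when aromatic) joined by bond tokens
## ("-", "=", "#", ":"). Each path is kept
## in the lexicographically smaller of its two directions (byte order), so
## the path-string set of a molecule is independent of atom numbering.

## Atom tokens encode element and aromaticity only (lowercase = aromatic).
## Formal charge is deliberately not part of the path alphabet: it keeps
## path strings unambiguous to tokenize, and charged variants are covered
## by the charge-type structural keys instead.
.atomTokens <- function(mol) {
  tok <- mol@element
  tok[mol@aromatic] <- tolower(tok[mol@aromatic])
  tok
}

.bondTokens <- function(mol) {
  tok <- c("-", "=", "#")[mol@bondOrder]
  tok[mol@bondAromatic] <- ":"
  tok
}

## evaluate expr under C collation so string comparison is byte order
withCLocale <- function(expr) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  force(expr)
}

## Unique canonical path strings of one molecule. Assumes C collation is
## already in effect (see withCLocale); molPathStrings() sets it itself.
.pathStringsRaw <- function(mol, maxPath = 7L) {
  n <- heavyAtomCount(mol)
  b <- bondCount(mol)
  if (b == 0L) return(character(0))
  adj <- molAdjacency(mol)
  atok <- .atomTokens(mol)
  btok <- .bondTokens(mol)
  from <- mol@bondFrom; to <- mol@bondTo
  acc <- new.env(parent = emptyenv())
  acc$out <- character(512L); acc$k <- 0L
  visited <- logical(n)
  rec <- function(s) {
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$out)) acc$out <- c(acc$out, character(length(acc$out)))
    acc$out[acc$k] <- s
  }
  dfs <- function(v, depth, fwd, rev) {
    for (e in adj[[v]]) {
      w <- if (from[e] == v) to[e] else from[e]
      if (visited[w]) next
      f2 <- paste0(fwd, btok[e], atok[w])
      r2 <- paste0(atok[w], btok[e], rev)
      rec(if (f2 <= r2) f2 else r2)
      if (depth < maxPath) {
        visited[w] <<- TRUE
        dfs(w, depth + 1L, f2, r2)
        visited[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited[s] <- TRUE
    dfs(s, 1L, atok[s], atok[s])
    visited[s] <- FALSE
  }
  unique(acc$out[seq_len(acc$k)])
}

#' Canonical linear-path strings of a molecule
#'
#' Enumerates all simple paths of 1 to \code{maxPath} bonds and returns the
#' unique canonical path strings. These strings are the raw material of
#' \code{\link{pathFingerprint}} and of the path-type structural keys.
#'
#' @param mol a \linkS4class{Molecule}
#' @param maxPath maximum path length in bonds (default 7)
#' @return character vector of canonical path strings
#' @examples
#' molPathStrings(parseSmiles("CCO", "x"))
#' @export
molPathStrings <- function(mol, maxPath = 7L) {
  withCLocale(.pathStringsRaw(mol, maxPath))
}

## Path-string sets for a whole library, cached on the library.
libraryPathSets <- function(lib, maxPath = 7L) {
  key <- paste0("paths", maxPath)
  if (!is.null(lib@cache[[key]])) return(lib@cache[[key]])
  res <- withCLocale(lapply(lib@molecules, .pathStringsRaw, maxPath = maxPath))
  names(res) <- lib@ids
  assign(key, res, envir = lib@cache)
  res
}
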