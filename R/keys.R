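## The 166-bit structural key set.
##
## The key definition is the package's own fixed, versioned dictionary
## (inst/extdata/structural_keys_166.csv): 166 named substructure and
## count-threshold predicates in the spirit of the classic 166-key search
## keys, expressed over features of the heavy-atom graph -- element counts,
## ring statistics, degrees, charges, and canonical path patterns. The
## original vendor key definitions are proprietary; shipping a frozen
## surrogate keeps the descriptor reproducible. Bit i of the key
## fingerprint is set iff the molecule satisfies predicate i.

KEYS_VERSION <- "divpick-SK166/1.0"

.keysCache <- new.env(parent = emptyenv())

## tokenize a path pattern written in the path-string alphabet
.tokenizePattern <- function(p) {
  toks <- regmatches(p, gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]|[-=#:]", p))[[1L]]
  if (sum(nchar(toks)) != nchar(p))
    stop("malformed path pattern: ", p)
  toks
}

## canonical direction of a path pattern (byte order, as in paths.R)
.canonicalPattern <- function(p) {
  toks <- .tokenizePattern(p)
  rev <- paste(base::rev(toks), collapse = "")
  withCLocale(if (p <= rev) p else rev)
}

#' The structural key definition table
#'
#' Returns the shipped 166-key definition (version
#' \code{"divpick-SK166/1.0"}) with path patterns canonicalized to the
#' package's path-string convention.
#'
#' @return data.frame with columns bit, type, param, threshold, name
#' @export
structuralKeyTable <- function() {
  if (!is.null(.keysCache$table)) return(.keysCache$table)
  path <- system.file("extdata", "structural_keys_166.csv",
                      package = "divpick")
  if (!nzchar(path))  # package sourced, not installed
    path <- file.path("inst", "extdata", "structural_keys_166.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 166L, identical(tab$bit, 1:166))
  isPath <- tab$type == "path"
  tab$param[isPath] <- vapply(tab$param[isPath], .canonicalPattern, "")
  .keysCache$table <- tab
  tab
}

## ---- per-molecule graph features ------------------------------------------

.componentsCount <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

## smallest-ring sizes present in the molecule (one BFS per ring bond)
molRingSizes <- function(mol) {
  rb <- which(mol@ringBond)
  if (length(rb) == 0L) return(integer(0))
  n <- heavyAtomCount(mol)
  from <- mol@bondFrom; to <- mol@bondTo
  nbrs <- vector("list", n)
  for (e in seq_along(from)) {
    nbrs[[from[e]]] <- c(nbrs[[from[e]]], list(c(to[e], e)))
    nbrs[[to[e]]] <- c(nbrs[[to[e]]], list(c(from[e], e)))
  }
  sizes <- integer(0)
  for (e in rb) {
    src <- from[e]; dst <- to[e]
    dist <- rep(NA_integer_, n)
    dist[src] <- 0L
    queue <- src
    while (length(queue) && is.na(dist[dst])) {
      v <- queue[1L]; queue <- queue[-1L]
      for (x in nbrs[[v]]) {
        if (x[2L] == e) next
        w <- x[1L]
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
      }
    }
    if (!is.na(dist[dst])) sizes <- c(sizes, dist[dst] + 1L)
  }
  sort(unique(sizes))
}

## ---- key evaluation --------------------------------------------------------

.HALOGENS <- c("F", "Cl", "Br", "I")

#' Structural key fingerprint
#'
#' Evaluates the shipped 166-key definition (see
#' \code{\link{structuralKeyTable}}) on a molecule or library.
#'
#' @param x a \linkS4class{Molecule} or \linkS4class{CompoundLibrary}
#' @return a \linkS4class{FingerprintSet} of kind "keys" with 166 bits
#' @examples
#' k <- structuralKeys(parseSmiles("c1ccccc1", "benzene"))
#' sum(fpBits(k))
#' @export
setGeneric("structuralKeys", function(x) standardGeneric("structuralKeys"))

.evalKeys <- function(mols, ids, pathSets) {
  tab <- structuralKeyTable()
  n <- length(mols)
  bits <- matrix(FALSE, n, 166L)

  elemCount <- function(el)
    vapply(mols, function(m) sum(m@element == el), 1L)
  ringElemCount <- function(el)
    vapply(mols, function(m) {
      ra <- unique(c(m@bondFrom[m@ringBond], m@bondTo[m@ringBond]))
      sum(m@element[ra] == el)
    }, 1L)
  aroElemCount <- function(el)
    vapply(mols, function(m) sum(m@aromatic & m@element == el), 1L)
  degCount <- function(d)
    vapply(mols, function(m)
      sum(tabulate(c(m@bondFrom, m@bondTo), heavyAtomCount(m)) >= d), 1L)

  nAtoms <- vapply(mols, heavyAtomCount, 1L)
  nBonds <- vapply(mols, bondCount, 1L)
  nRings <- vapply(mols, function(m)
    bondCount(m) - heavyAtomCount(m) +
      .componentsCount(heavyAtomCount(m), m@bondFrom, m@bondTo), 1L)
  nAroRings <- vapply(mols, function(m) {
    ab <- m@bondAromatic
    if (!any(ab)) return(0L)
    av <- unique(c(m@bondFrom[ab], m@bondTo[ab]))
    as.integer(sum(ab) - length(av) +
      .componentsCount(length(av), match(m@bondFrom[ab], av),
                       match(m@bondTo[ab], av)))
  }, 1L)
  ringSizes <- lapply(mols, molRingSizes)
  nHalogen <- vapply(mols, function(m) sum(m@element %in% .HALOGENS), 1L)
  nHetero <- vapply(mols, function(m) sum(m@element != "C"), 1L)
  nPos <- vapply(mols, function(m) sum(m@charge > 0L), 1L)
  nNeg <- vapply(mols, function(m) sum(m@charge < 0L), 1L)
  nDouble <- vapply(mols, function(m)
    sum(m@bondOrder == 2L & !m@bondAromatic), 1L)
  nTriple <- vapply(mols, function(m) sum(m@bondOrder == 3L), 1L)

  isPath <- tab$type == "path"
  pats <- tab$param[isPath]
  pathHits <- t(vapply(pathSets, function(s) pats %in% s,
                       logical(length(pats))))
  if (n == 1L) pathHits <- matrix(pathHits, nrow = 1L)
  bits[, which(isPath)] <- pathHits

  for (i in which(!isPath)) {
    ty <- tab$type[i]; pa <- tab$param[i]; th <- tab$threshold[i]
    bits[, i] <- switch(ty,
      elem = elemCount(pa) >= th,
      halogen = nHalogen >= th,
      hetero = nHetero >= th,
      atoms = nAtoms >= th,
      bonds = nBonds >= th,
      rings = nRings >= th,
      aroRings = nAroRings >= th,
      ringSize = vapply(ringSizes, function(s) as.integer(pa) %in% s, TRUE),
      elemRing = ringElemCount(pa) >= th,
      aroElem = aroElemCount(pa) >= th,
      degree = degCount(as.integer(pa)) >= th,
      charge = switch(pa, "+" = nPos, "-" = nNeg, any = nPos + nNeg) >= th,
      multiBond = (if (pa == "=") nDouble else nTriple) >= th,
      stop("unknown key type: ", ty))
  }
  .newFPSet(bits, ids, "keys", 0L, KEYS_VERSION)
}

#' @rdname structuralKeys
setMethod("structuralKeys", "Molecule", function(x) {
  .evalKeys(list(x), x@id, list(molPathStrings(x, 7L)))
})

#' @rdname structuralKeys
setMethod("structuralKeys", "CompoundLibrary", function(x) {
  if (!is.null(x@cache$keys)) return(x@cache$keys)
  res <- .evalKeys(x@molecules, x@ids, libraryPathSets(x, 7L))
  assign("keys", res, envir = x@cache)
  ## the path-string sets are sizable on large libraries; keep them only
  ## if a path fingerprint is also cached (they are cheap to rebuild)
  if (!any(startsWith(ls(x@cache), "pathfp")) &&
      !is.null(x@cache$paths7))
    rm("paths7", envir = x@cache)
  res
})
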