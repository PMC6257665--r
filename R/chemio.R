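## Molecule and library input/output.
##
## SMILES validation, aromaticity perception and canonicalization are
## delegated to OpenBabel (via ChemmineOB::convertFormat, batched). The
## heavy-atom graph is then built by reading the canonical aromatic SMILES
## with the internal reader below, so every molecule -- however its input
## was spelled -- is represented by one and the same graph.

## ---- OpenBabel canonicalization -------------------------------------------

## Batch-canonicalize SMILES strings. Returns a character vector parallel
## to `smiles` with NA for strings OpenBabel rejected. A hard parse error
## makes OpenBabel abort the remainder of a batch, so conversion restarts
## after the first record that produced no output until every record has
## been decided.
obCanonical <- function(smiles, ids = NULL) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  qid <- paste0("q", seq_len(n))
  res <- rep(NA_character_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    inp <- paste0(smiles[todo], "\t", qid[todo], "\n", collapse = "")
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", inp))
    got <- rep(NA_character_, length(todo))
    if (nzchar(out)) {
      lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      can <- vapply(parts, `[[`, "", 1L)
      outIds <- vapply(parts, function(p)
        if (length(p) > 1L) p[[2L]] else "", "")
      hit <- match(qid[todo], outIds)
      got[!is.na(hit)] <- can[hit[!is.na(hit)]]
    }
    ## an empty-graph record canonicalizes to an empty string: treat as NA
    got[!is.na(got) & !nzchar(got)] <- NA_character_
    res[todo] <- got
    miss <- which(is.na(got))
    if (length(miss) == 0L) break
    ## records up to and including the first failure are decided; retry
    ## everything after it
    todo <- todo[seq_along(todo) > miss[1L]]
  }
  res
}

## ---- canonical SMILES reader ----------------------------------------------

.SMI_TOKEN_RE <- paste0(
  "\\[[^]]*\\]|Br|Cl|%[0-9]{2}|[BCNOPSFI]|[bcnops]|",
  "[-=#:/\\\\.()]|[0-9]"
)

.BRACKET_RE <- "^\\[([0-9]*)([A-Za-z][a-z]?|\\*)(@+)?(H[0-9]*)?([+-][0-9]*|\\++|-+)?\\]$"

.parseBracket <- function(tok) {
  m <- regmatches(tok, regexec(.BRACKET_RE, tok))[[1L]]
  if (length(m) == 0L)
    return(NULL)
  sym <- m[3L]
  chg <- m[6L]
  charge <- 0L
  if (nzchar(chg)) {
    sgn <- if (substr(chg, 1L, 1L) == "-") -1L else 1L
    digits <- gsub("[+-]", "", chg)
    charge <- if (nzchar(digits)) sgn * as.integer(digits)
              else sgn * nchar(chg)
  }
  aromatic <- sym == tolower(sym) && sym != "*"
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
  } else sym
  list(element = element, aromatic = aromatic, charge = charge)
}

## Read one canonical SMILES string into graph components. Stereo markers
## (/ \ @) are accepted and ignored; '.' separates disconnected fragments.
readSmilesGraph <- function(s) {
  toks <- regmatches(s, gregexpr(.SMI_TOKEN_RE, s))[[1L]]
  if (sum(nchar(toks)) != nchar(s))
    stop("unsupported SMILES syntax in '", s, "'")
  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  bFrom <- integer(0); bTo <- integer(0); bOrd <- integer(0); bAro <- logical(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_character_
  rings <- list()

  addBond <- function(a, b, sym) {
    if (is.na(sym)) {
      aro <- aromatic[a] && aromatic[b]
      ord <- 1L
    } else {
      aro <- sym == ":"
      ord <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                    "/" = 1L, "\\" = 1L)
    }
    bFrom <<- c(bFrom, a); bTo <<- c(bTo, b)
    bOrd <<- c(bOrd, ord); bAro <<- c(bAro, aro)
  }

  for (tok in toks) {
    if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- tok
    } else if (tok == "(") {
      if (is.na(prev)) stop("branch before any atom in '", s, "'")
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in '", s, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending <- NA_character_
    } else if (grepl("^[0-9]$", tok) || grepl("^%", tok)) {
      num <- sub("^%", "", tok)
      if (is.na(prev)) stop("ring closure before any atom in '", s, "'")
      open <- rings[[num]]
      if (is.null(open)) {
        rings[[num]] <- list(atom = prev, sym = pending)
      } else {
        sym <- if (!is.na(pending)) pending else open$sym
        addBond(open$atom, prev, sym)
        rings[[num]] <- NULL
      }
      pending <- NA_character_
    } else {
      info <- if (startsWith(tok, "[")) .parseBracket(tok)
              else {
                aro <- tok %in% c("b", "c", "n", "o", "p", "s")
                list(element = if (aro) toupper(tok) else tok,
                     aromatic = aro, charge = 0L)
              }
      if (is.null(info)) stop("unsupported atom token '", tok, "' in '", s, "'")
      element <- c(element, info$element)
      aromatic <- c(aromatic, info$aromatic)
      charge <- c(charge, info$charge)
      idx <- length(element)
      if (!is.na(prev)) addBond(prev, idx, pending)
      pending <- NA_character_
      prev <- idx
    }
  }
  if (length(stack)) stop("unbalanced '(' in '", s, "'")
  openRings <- vapply(rings, Negate(is.null), TRUE)
  if (length(openRings) && any(openRings))
    stop("unclosed ring bond in '", s, "'")
  if (length(element) == 0L) stop("no atoms in '", s, "'")
  list(element = element, aromatic = aromatic, charge = charge,
       bondFrom = bFrom, bondTo = bTo, bondOrder = bOrd, bondAromatic = bAro)
}

## Bridge detection (iterative DFS): a bond is a ring bond iff it is not a
## bridge of the molecular graph.
.ringBonds <- function(nAtom, bFrom, bTo) {
  nb <- length(bFrom)
  if (nb == 0L) return(logical(0))
  adj <- vector("list", nAtom)
  for (e in seq_len(nb)) {
    adj[[bFrom[e]]] <- c(adj[[bFrom[e]]], e)
    adj[[bTo[e]]] <- c(adj[[bTo[e]]], e)
  }
  other <- function(e, v) if (bFrom[e] == v) bTo[e] else bFrom[e]
  disc <- integer(nAtom); low <- integer(nAtom)
  isBridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(nAtom)) {
    if (disc[root] > 0L) next
    ## stack frames: vertex, incoming edge, next adj position
    vs <- root; es <- 0L; ps <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(vs)) {
      top <- length(vs)
      v <- vs[top]
      if (ps[top] <= length(adj[[v]])) {
        e <- adj[[v]][ps[top]]
        ps[top] <- ps[top] + 1L
        if (e == es[top]) next
        w <- other(e, v)
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          vs <- c(vs, w); es <- c(es, e); ps <- c(ps, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        vs <- vs[-top]
        pe <- es[top]; es <- es[-top]; ps <- ps[-top]
        if (length(vs)) {
          u <- vs[length(vs)]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) isBridge[pe] <- TRUE
        }
      }
    }
  }
  !isBridge
}

.moleculeFromCanonical <- function(can, id) {
  g <- readSmilesGraph(can)
  rb <- .ringBonds(length(g$element), g$bondFrom, g$bondTo)
  ## an implicit bond between two aromatic atoms is only aromatic inside a
  ## ring; acyclic aryl-aryl bonds (e.g. biphenyl's linker) are single
  g$bondAromatic <- g$bondAromatic & rb
  new("Molecule", id = id, smiles = can,
      element = g$element, aromatic = g$aromatic, charge = g$charge,
      bondFrom = g$bondFrom, bondTo = g$bondTo,
      bondOrder = g$bondOrder, bondAromatic = g$bondAromatic,
      ringBond = rb)
}

## ---- public parsing API ----------------------------------------------------

#' Parse a SMILES string into a Molecule
#'
#' The string is validated and canonicalized by OpenBabel (which also
#' perceives aromaticity); the heavy-atom graph is then built from the
#' canonical form, so any SMILES spelling of the same molecule yields an
#' identical \linkS4class{Molecule}.
#'
#' @param smiles a single SMILES string
#' @param id compound identifier (used in error messages and downstream)
#' @return a \linkS4class{Molecule}
#' @examples
#' m <- parseSmiles("c1ccccc1", "benzene")
#' heavyAtomCount(m)  # 6
#' ringBondCount(m)   # 6
#' @export
parseSmiles <- function(smiles, id = "mol1") {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  can <- obCanonical(smiles, "x")
  if (is.na(can))
    stop("cannot parse SMILES for compound '", id, "': ", smiles)
  .moleculeFromCanonical(can, id)
}

## Build a CompoundLibrary from parallel smiles/id vectors, batching the
## canonicalization. Invalid records are dropped with a warning (lenient)
## or abort (strict).
.makeLibrary <- function(smiles, ids, strict = FALSE, dedup = FALSE) {
  if (length(smiles) == 0L) stop("empty library")
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  can <- obCanonical(smiles, ids)
  bad <- is.na(can)
  if (any(bad)) {
    msg <- paste0("failed to parse ", sum(bad), " record(s): ",
                  paste(utils::head(ids[bad], 5L), collapse = ", "),
                  if (sum(bad) > 5L) ", ...")
    if (strict) stop(msg)
    warning(msg)
    can <- can[!bad]; ids <- ids[!bad]
  }
  if (length(can) == 0L) stop("empty library: no parseable records")
  dup <- duplicated(can)
  if (any(dup)) {
    if (dedup) {
      message("removing ", sum(dup), " duplicate canonical structure(s)")
      can <- can[!dup]; ids <- ids[!dup]; dup <- rep(FALSE, length(can))
    } else {
      warning(sum(dup), " duplicate canonical structure(s) flagged ",
              "(pass dedup = TRUE to drop them)")
    }
  }
  mols <- mapply(.moleculeFromCanonical, can, ids, SIMPLIFY = FALSE,
                 USE.NAMES = FALSE)
  new("CompoundLibrary", molecules = mols, ids = ids, duplicated = dup,
      cache = new.env(parent = emptyenv()))
}

#' Build a library from SMILES strings
#'
#' @param smiles character vector of SMILES
#' @param ids compound identifiers; defaults to the names of \code{smiles}
#'   or "M000001"-style ids
#' @param strict abort on the first unparseable record instead of dropping
#'   it with a warning
#' @param dedup drop records whose canonical SMILES already occurred
#'   (duplicates are only flagged otherwise)
#' @return a \linkS4class{CompoundLibrary}
#' @export
makeLibrary <- function(smiles, ids = NULL, strict = FALSE, dedup = FALSE) {
  if (is.null(ids)) {
    ids <- names(smiles)
    if (is.null(ids))
      ids <- sprintf("M%06d", seq_along(smiles))
  }
  .makeLibrary(unname(smiles), ids, strict = strict, dedup = dedup)
}

#' Read a compound library from a .smi or SDF file
#'
#' The .smi dialect is one molecule per line, "SMILES<whitespace>ID", with
#' '#' comment lines ignored; missing ids are filled in positionally. SDF
#' files are V2000 connection tables; the molecule id is taken from the
#' title line, or from a named data field when \code{idField} is given.
#'
#' @param path input file
#' @param format "smi" or "sdf"; guessed from the file extension by default
#' @param idField for SDF input, name of the data field holding the
#'   compound id (default: the title line)
#' @param strict abort on the first unparseable record
#' @param dedup drop duplicate canonical structures
#' @return a \linkS4class{CompoundLibrary}
#' @export
readLibrary <- function(path, format = c("auto", "smi", "sdf"),
                        idField = NULL, strict = FALSE, dedup = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("sdf", "sd", "mol")) "sdf" else "smi"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) stop("empty library")
    parts <- strsplit(lines, "[ \t]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
    noId <- !nzchar(ids)
    ids[noId] <- sprintf("M%06d", which(noId))
    .makeLibrary(smiles, ids, strict = strict, dedup = dedup)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    n <- length(sdf)
    if (n == 0L) stop("empty library")
    ids <- if (!is.null(idField)) {
      vapply(seq_len(n), function(i) {
        db <- ChemmineR::datablock(sdf[[i]])
        if (idField %in% names(db)) db[[idField]] else ""
      }, "")
    } else {
      vapply(seq_len(n), function(i)
        ChemmineR::sdfid(sdf[i]), "")
    }
    noId <- !nzchar(ids) | is.na(ids)
    ids[noId] <- sprintf("M%06d", which(noId))
    raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
    out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", raw))
    lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(lines)]
    smiles <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    if (length(smiles) != n)
      stop("OpenBabel parsed ", length(smiles), " of ", n, " SDF records; ",
           "cannot align ids reliably")
    .makeLibrary(smiles, ids, strict = strict, dedup = dedup)
  }
}

#' Write a library to a .smi file
#'
#' @param lib a \linkS4class{CompoundLibrary}
#' @param path output file
#' @export
writeLibrary <- function(lib, path) {
  stopifnot(is(lib, "CompoundLibrary"))
  writeLines(paste0(vapply(lib@molecules, slot, "", "smiles"), "\t", lib@ids),
             path)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn parseSmiles number of heavy atoms
#' @param mol a \linkS4class{Molecule}
#' @export
heavyAtomCount <- function(mol) length(mol@element)

#' @describeIn parseSmiles number of bonds between heavy atoms
#' @export
bondCount <- function(mol) length(mol@bondFrom)

#' @describeIn parseSmiles number of bonds lying on a cycle
#' @export
ringBondCount <- function(mol) sum(mol@ringBond)

#' @describeIn parseSmiles canonical SMILES of a molecule
#' @export
canonicalSmiles <- function(mol) mol@smiles

#' Compound identifiers of a library
#' @param lib a \linkS4class{CompoundLibrary}
#' @export
compoundIds <- function(lib) lib@ids

setMethod("length", "CompoundLibrary", function(x) length(x@molecules))

setMethod("[[", "CompoundLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  x@molecules[[i]]
})

#' @export
setMethod("[", "CompoundLibrary", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  if (is.logical(i)) i <- which(i)
  new("CompoundLibrary", molecules = x@molecules[i], ids = x@ids[i],
      duplicated = x@duplicated[i], cache = new.env(parent = emptyenv()))
})

setMethod("show", "Molecule", function(object) {
  cat("Molecule ", object@id, ": ", object@smiles,
      " (", heavyAtomCount(object), " atoms, ", bondCount(object),
      " bonds, ", ringBondCount(object), " ring bonds)\n", sep = "")
})

setMethod("show", "CompoundLibrary", function(object) {
  cat("CompoundLibrary with ", length(object), " molecules",
      if (any(object@duplicated))
        paste0(" (", sum(object@duplicated), " duplicate structures flagged)"),
      "\n", sep = "")
})

## adjacency list (list of integer neighbor vectors), used by descriptors
molAdjacency <- function(mol) {
  n <- heavyAtomCount(mol)
  adj <- vector("list", n)
  b <- bondCount(mol)
  if (b) {
    for (e in seq_len(b)) {
      adj[[mol@bondFrom[e]]] <- c(adj[[mol@bondFrom[e]]], e)
      adj[[mol@bondTo[e]]] <- c(adj[[mol@bondTo[e]]], e)
    }
  }
  adj
}
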