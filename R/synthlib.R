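## Deterministic synthetic compound libraries with planted scaffold-family
## structure. The generator emulates a vendor catalogue at reduced scale:
## scaffold families of highly unequal (power-law) size, dominated by one
## large family of mono-substituted benzenes, with every structure unique
## after canonicalization. Ground-truth family labels are returned
## alongside, so clustering and selection behavior can be validated
## against construction.

## ---- scaffold catalogue ----------------------------------------------------

## Each core is a SMILES template; "{1}"/"{2}" mark substitution sites.
## Mono-substituted benzene is the dominant family and is kept first.
.CORES <- list(
  list(name = "benzene_mono",      mono = "c1ccccc1{1}"),
  list(name = "benzene_di",        di = "c1cc({1})ccc1{2}"),
  list(name = "pyridine",          mono = "c1ccncc1{1}",
       di = "c1cc({1})cnc1{2}"),
  list(name = "pyrimidine",        mono = "c1cncnc1{1}"),
  list(name = "pyrazine",          mono = "c1nccnc1{1}"),
  list(name = "pyridazine",        mono = "c1ccnnc1{1}"),
  list(name = "furan",             mono = "c1ccoc1{1}",
       di = "c1cc({1})oc1{2}"),
  list(name = "thiophene",         mono = "c1ccsc1{1}",
       di = "c1cc({1})sc1{2}"),
  list(name = "pyrrole",           mono = "c1cc[nH]c1{1}"),
  list(name = "thiazole",          mono = "s1ccnc1{1}"),
  list(name = "oxazole",           mono = "o1ccnc1{1}"),
  list(name = "naphthalene",       mono = "c1ccc2ccccc2c1{1}",
       di = "c1cc2cc({1})ccc2cc1{2}"),
  list(name = "quinoline",         mono = "c1ccc2ncccc2c1{1}"),
  list(name = "isoquinoline",      mono = "c1ccc2cnccc2c1{1}"),
  list(name = "indole_n",          mono = "c1ccc2c(c1)ccn2{1}"),
  list(name = "benzothiophene",    mono = "c1ccc2sccc2c1{1}"),
  list(name = "benzimidazole",     mono = "c1ccc2nc[nH]c2c1{1}"),
  list(name = "cyclopropane",      mono = "C1CC1{1}"),
  list(name = "cyclobutane",       mono = "C1CCC1{1}"),
  list(name = "cyclopentane",      mono = "C1CCCC1{1}",
       di = "C1CC({1})CC1{2}"),
  list(name = "cyclohexane",       mono = "C1CCCCC1{1}",
       di = "C1CC({1})CCC1{2}"),
  list(name = "cycloheptane",      mono = "C1CCCCCC1{1}"),
  list(name = "cyclohexene",       mono = "C1CCC=CC1{1}"),
  list(name = "piperidine_n",      mono = "C1CCN({1})CC1",
       di = "C1CC({2})CCN1{1}"),
  list(name = "pyrrolidine_n",     mono = "C1CCN({1})C1"),
  list(name = "piperazine",        mono = "C1CN({1})CCN1C",
       di = "C1CN({1})CCN1{2}"),
  list(name = "morpholine_n",      mono = "C1COCCN1{1}"),
  list(name = "tetrahydrofuran",   mono = "C1CCOC1{1}"),
  list(name = "tetrahydropyran",   mono = "C1CCOCC1{1}"),
  list(name = "biphenyl",          mono = "c1ccc(-c2ccc({1})cc2)cc1",
       di = "c1cc({2})ccc1-c1ccc({1})cc1"),
  list(name = "diphenylmethane",   mono = "C(c1ccccc1)c1ccc({1})cc1"),
  list(name = "diphenylether",     mono = "O(c1ccccc1)c1ccc({1})cc1"),
  list(name = "benzanilide",       mono = "O=C(Nc1ccccc1)c1ccc({1})cc1"),
  list(name = "benzenesulfonamide", mono = "O=S(=O)(N{1})c1ccccc1",
       di = "O=S(=O)(N{1})c1ccc({2})cc1"),
  list(name = "styrene",           mono = "C=Cc1ccc({1})cc1"),
  list(name = "butane",            mono = "CCCC{1}", di = "CC({1})CC{2}"),
  list(name = "pentane",           mono = "CCCCC{1}"),
  list(name = "hexane",            mono = "CCCCCC{1}"),
  list(name = "isobutane",         mono = "CC(C)C{1}"),
  list(name = "neopentyl",         mono = "CC(C)(C)C{1}"),
  list(name = "glycolether",       mono = "CCOCC{1}")
)

## substituent fragments; "linker" fragments may be extended by a further
## fragment at their last atom, "terminal" fragments end a chain
.LINKERS <- c("C", "CC", "O", "OC", "N", "NC", "S", "CO", "C(C)C",
              "C(=O)O", "C(=O)N", "C=C", "CN")
.TERMINALS <- c("F", "Cl", "Br", "I", "C#N", "[N+](=O)[O-]", "C(F)(F)F",
                "C", "CC", "O", "OC", "N", "N(C)C", "S", "C(C)C")

#' Default substituent alphabet of the library generator
#'
#' Small neutral fragments (halogens, short alkyl/alkoxy/amino/nitro/acid
#' chains) written as appendable SMILES pieces. Substituent chains are
#' built by concatenating up to three fragments.
#'
#' @return list with components \code{linkers} and \code{terminals}
#' @export
defaultSubstituents <- function() {
  list(linkers = .LINKERS, terminals = .TERMINALS)
}

## deterministic substituent chain for a draw of (length, fragment indices)
.buildChain <- function(linkIdx, termIdx, subs) {
  paste0(paste(subs$linkers[linkIdx], collapse = ""),
         subs$terminals[termIdx])
}

## power-law family sizes summing exactly to `total` (largest remainder)
.familySizes <- function(total, m, alpha, distribution) {
  if (m == 0L) return(integer(0))
  ## ranks start at 2: the dominant (benzene) family is rank 1 of the same
  ## power law and is sized separately, so it stays the largest family
  w <- if (distribution == "uniform") rep(1, m) else (seq_len(m) + 1L) ^ (-alpha)
  raw <- total * w / sum(w)
  sz <- floor(raw)
  rem <- total - sum(sz)
  if (rem > 0) {
    o <- order(raw - sz, decreasing = TRUE)
    sz[o[seq_len(rem)]] <- sz[o[seq_len(rem)]] + 1
  }
  sz <- pmax(sz, 1L)
  while (sum(sz) > total) {  # min-1 flooring may overshoot
    i <- which.max(sz); sz[i] <- sz[i] - 1L
  }
  as.integer(sz)
}

## Candidate decorated SMILES for one family (deterministic given the RNG
## state). A family is organized as combinatorial *series*, the way vendor
## catalogues are: each series shares a family core plus a fixed stem
## chain, and members of a series vary only in the small terminal
## fragment. Series membership gives families descriptor-space cohesion
## (members of a series are close analogues) while different series keep
## the family internally diverse.
.familyCandidates <- function(core, k, subs, seriesSize = 12L) {
  tmpl <- if (!is.null(core$di)) core$di else core$mono
  twoSites <- grepl("{2}", tmpl, fixed = TRUE)
  nTerm <- length(subs$terminals)
  stemFor <- function() {
    L <- sample.int(4L, 1L, prob = c(0.3, 0.35, 0.25, 0.1)) - 1L
    if (L == 0L) "" else
      paste(subs$linkers[sample.int(length(subs$linkers), L,
                                    replace = TRUE)], collapse = "")
  }
  out <- character(0)
  guard <- 0L
  guardMax <- max(200L, ceiling(k / 3L))
  while (length(out) < k && guard < guardMax) {
    guard <- guard + 1L
    stem <- stemFor()
    second <- if (twoSites) paste0(stemFor(),
                                   subs$terminals[sample.int(nTerm, 1L)])
    nMem <- min(seriesSize, nTerm)
    term <- subs$terminals[sample.int(nTerm, nMem)]
    cand <- vapply(term, function(tm) {
      x <- sub("{1}", paste0(stem, tm), tmpl, fixed = TRUE)
      if (twoSites) x <- sub("{2}", second, x, fixed = TRUE)
      x
    }, "", USE.NAMES = FALSE)
    out <- unique(c(out, cand))
  }
  out[seq_len(min(k, length(out)))]
}

#' Generate a synthetic compound library with planted scaffold families
#'
#' Families are scaffold cores decorated combinatorially with substituent
#' chains. Family sizes follow a power law (few large, many small
#' families) except for the dominant mono-substituted benzene family,
#' whose share of the library is fixed by \code{benzeneFraction}. All
#' structures are canonicalized and globally unique; generation is fully
#' reproducible from \code{rngSeed}.
#'
#' @param n total library size
#' @param nFamilies number of scaffold families (including the benzene
#'   family); at most the size of the scaffold catalogue
#' @param benzeneFraction share of the library in the dominant
#'   mono-substituted benzene family (default 0.15)
#' @param alpha power-law exponent for the remaining family sizes
#'   (default 1.6)
#' @param distribution "power" (default) or "uniform" family sizes
#' @param substituents substituent alphabet, see
#'   \code{\link{defaultSubstituents}}
#' @param rngSeed integer seed; same seed, same library, byte for byte
#' @param idPrefix prefix for generated compound ids
#' @return list with \code{library} (a \linkS4class{CompoundLibrary}) and
#'   \code{labels} (data.frame id, family, scaffold)
#' @examples
#' gen <- generateLibrary(n = 60, nFamilies = 5, rngSeed = 1)
#' table(gen$labels$family)
#' @export
generateLibrary <- function(n = 10000L, nFamilies = 40L,
                            benzeneFraction = 0.15, alpha = 1.6,
                            distribution = c("power", "uniform"),
                            substituents = defaultSubstituents(),
                            rngSeed = 1L, idPrefix = "SYN") {
  distribution <- match.arg(distribution)
  n <- as.integer(n); nFamilies <- as.integer(nFamilies)
  stopifnot(n >= nFamilies, nFamilies >= 1L,
            benzeneFraction >= 0, benzeneFraction < 1)
  if (nFamilies > length(.CORES))
    stop("at most ", length(.CORES), " scaffold families are available")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(rngSeed))

  cores <- .CORES[seq_len(nFamilies)]
  if (benzeneFraction == 0) {
    ## no dominant family: all families follow the size distribution
    sizes <- .familySizes(n, nFamilies, alpha, distribution)
    return(.assembleLibrary(cores, sizes, substituents, idPrefix))
  }
  nBen <- max(1L, round(benzeneFraction * n))
  rest <- .familySizes(n - nBen, nFamilies - 1L, alpha, distribution)
  ## the benzene family is by construction the largest: cap every other
  ## family at 90% of its size and push the excess down the tail
  if (nBen > 0L && length(rest)) {
    cap <- max(1L, floor(0.9 * nBen))
    for (it in seq_len(10L)) {
      over <- sum(pmax(rest - cap, 0L))
      if (over == 0L) break
      rest <- pmin(rest, cap)
      open <- which(rest < cap)
      if (length(open) == 0L) break
      add <- .familySizes(over, length(open), alpha, distribution)
      rest[open] <- rest[open] + add
    }
    ## the exact library size outranks the dominance cap: if every family
    ## saturated the cap, spread the leftover regardless
    leftover <- (n - nBen) - sum(rest)
    if (leftover > 0L)
      rest <- rest + .familySizes(leftover, length(rest), alpha,
                                  distribution)
  }
  sizes <- c(nBen, rest)
  keep <- sizes > 0L
  .assembleLibrary(cores[keep], sizes[keep], substituents, idPrefix)
}

## draw candidates per family, canonicalize, dedupe globally and assemble
## the library plus its ground-truth labels
.assembleLibrary <- function(cores, sizes, substituents, idPrefix) {
  ## draw ~35% extra candidates per family to absorb canonicalization
  ## losses and cross-family duplicates
  cand <- vector("list", length(cores))
  for (f in seq_along(cores))
    cand[[f]] <- .familyCandidates(cores[[f]],
                                   ceiling(sizes[f] * 1.35) + 8L,
                                   substituents)
  allSmi <- unlist(cand, use.names = FALSE)
  fam <- rep.int(seq_along(cores), lengths(cand))
  can <- obCanonical(allSmi)
  ok <- !is.na(can)
  can <- can[ok]; fam <- fam[ok]
  dup <- duplicated(can)
  can <- can[!dup]; fam <- fam[!dup]

  selSmi <- character(0); selFam <- integer(0)
  for (f in seq_along(cores)) {
    pool <- which(fam == f)
    if (length(pool) < sizes[f])
      stop("cannot realize ", sizes[f], " unique structures for family '",
           cores[[f]]$name, "' (only ", length(pool),
           " available); enlarge the substituent alphabet or shrink the ",
           "family")
    take <- pool[seq_len(sizes[f])]
    selSmi <- c(selSmi, can[take])
    selFam <- c(selFam, rep.int(f, sizes[f]))
  }
  ids <- sprintf("%s%06d", idPrefix, seq_along(selSmi))
  mols <- mapply(.moleculeFromCanonical, selSmi, ids, SIMPLIFY = FALSE,
                 USE.NAMES = FALSE)
  lib <- new("CompoundLibrary", molecules = mols, ids = ids,
             duplicated = rep(FALSE, length(ids)),
             cache = new.env(parent = emptyenv()))
  famNames <- vapply(cores, `[[`, "", "name")
  scaffolds <- vapply(cores, function(co)
    if (!is.null(co$di)) co$di else co$mono, "")
  list(library = lib,
       labels = data.frame(id = ids, family = famNames[selFam],
                           scaffold = scaffolds[selFam],
                           stringsAsFactors = FALSE))
}

#' Named small fixture libraries
#'
#' \code{tiny} is a fixed, hand-verifiable set of 24 molecules;
#' \code{skewed1k} and \code{skewed10k} are generator outputs at 1,000 and
#' 10,000 compounds with the default scaffold skew and fixed seeds. A
#' checksum over the canonical SMILES is attached to each library for
#' reproducibility checks.
#'
#' @param which one of "tiny", "skewed1k", "skewed10k"
#' @return list with \code{library}, \code{labels} and \code{checksum}
#' @export
fixtureSuite <- function(which = c("tiny", "skewed1k", "skewed10k")) {
  which <- match.arg(which)
  res <- switch(which,
    tiny = {
      smi <- c(
        benzene = "c1ccccc1",        toluene = "Cc1ccccc1",
        chlorobenzene = "Clc1ccccc1", phenol = "Oc1ccccc1",
        aniline = "Nc1ccccc1",       ethylbenzene = "CCc1ccccc1",
        pyridine = "c1ccncc1",       picoline = "Cc1ccncc1",
        furan = "c1ccoc1",           methylfuran = "Cc1ccoc1",
        thiophene = "c1ccsc1",       naphthalene = "c1ccc2ccccc2c1",
        cyclohexane = "C1CCCCC1",    methylcyclohexane = "CC1CCCCC1",
        cyclopentane = "C1CCCC1",    ethane = "CC",
        butane = "CCCC",             isobutane = "CC(C)C",
        ethanol = "CCO",             acetic = "CC(=O)O",
        acetamide = "CC(=O)N",       acetonitrile = "CC#N",
        nitromethane = "C[N+](=O)[O-]", ether = "CCOCC")
      lib <- makeLibrary(smi, ids = names(smi))
      list(library = lib,
           labels = data.frame(id = names(smi), family = NA_character_,
                               scaffold = NA_character_))
    },
    skewed1k = generateLibrary(n = 1000L, rngSeed = 101L, idPrefix = "S1K"),
    skewed10k = generateLibrary(n = 10000L, rngSeed = 102L,
                                idPrefix = "S10K"))
  smiFile <- tempfile()
  writeLines(vapply(res$library@molecules, slot, "", "smiles"), smiFile)
  res$checksum <- unname(tools::md5sum(smiFile))
  unlink(smiFile)
  res
}
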