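## shared test helpers: small in-code libraries and independent oracles

## a hand-picked mixed library used across tests
tinySmiles <- function() c(
  benzene = "c1ccccc1", toluene = "Cc1ccccc1",
  chlorobenzene = "Clc1ccccc1", phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1", pyridine = "c1ccncc1",
  furan = "c1ccoc1", cyclohexane = "C1CCCCC1",
  ethane = "CC", butane = "CCCC", ethanol = "CCO",
  acetamide = "CC(=O)N")

tinyLibrary <- function() makeLibrary(tinySmiles())

## quiet generator wrapper (drops OpenBabel chatter routed through warnings)
genLib <- function(...) suppressWarnings(generateLibrary(...))

## Independent O(n^3) Jarvis-Patrick oracle: explicit neighbor sets,
## pairwise intersection counting, union-find components.
jpOracle <- function(simMat, threshold, k, strict = TRUE,
                     includeSelf = TRUE, requireMutual = TRUE) {
  n <- nrow(simMat)
  nbr <- lapply(seq_len(n), function(i) {
    v <- simMat[i, ]
    h <- if (strict) which(v > threshold) else which(v >= threshold)
    setdiff(h, i)
  })
  nset <- lapply(seq_len(n), function(i)
    if (includeSelf) c(i, nbr[[i]]) else nbr[[i]])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (requireMutual && !(j %in% nbr[[i]])) next
      if (length(intersect(nset[[i]], nset[[j]])) >= k) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

## canonical form of a partition labelling (first-appearance relabelling),
## so two labelings can be compared as partitions
partitionKey <- function(labels) match(labels, unique(labels))

expect_same_partition <- function(a, b) {
  expect_identical(partitionKey(a), partitionKey(b))
}

## does partition `fine` refine partition `coarse`? (every fine cluster
## inside one coarse cluster)
refines <- function(fine, coarse) {
  all(vapply(split(coarse, fine), function(x) length(unique(x)) == 1L, TRUE))
}
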