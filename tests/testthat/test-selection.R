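## a library of close analogues that forms one big cluster at a low
## threshold: hexyl chain with varied terminal atoms
oneClusterLibrary <- function() {
  makeLibrary(c(a = "CCCCCCO", b = "CCCCCCN", c = "CCCCCCC",
                d = "CCCCCCF", e = "CCCCCCCl", f = "CCCCCCBr",
                g = "CCCCCC(C)C", h = "CCCCCCOC", i = "CCCCCCS",
                j = "CCCCCCCC", k = "CCCCCCC#N", l = "CCCCCCN(C)C"))
}

test_that("a single-cluster pool degenerates to nearest-to-medoid picks", {
  lib <- oneClusterLibrary()
  sel <- selectSeed(lib, "D1", n = 6L, membersPerCluster = 5L,
                    threshold = 0.3, kCommon = 1L)
  cl <- jarvisPatrick(neighborTable(lib, "D1", 0.3), 1L)
  expect_equal(nClusters(cl), 1L)
  expect_equal(length(sel), 6L)
  ## picks are the medoid plus the members most similar to it
  simFun <- divpick:::makeSimFun(lib, metricSpec("D1"))
  med <- divpick:::clusterMedoidPositions(cl@labels, simFun)
  s <- drop(simFun(seq_len(length(lib)), med))
  rest <- setdiff(seq_len(length(lib)), med)
  want <- c(med, rest[order(-s[rest], rest)])[1:6]
  expect_equal(match(sel@ids, compoundIds(lib)), want)
})

test_that("the fill rule takes members_per_cluster from each cluster", {
  lib <- genLib(n = 80L, nFamilies = 8L, rngSeed = 21L)$library
  sel <- selectSeed(lib, "D2", n = 10L, membersPerCluster = 5L,
                    threshold = 0.6, kCommon = 2L)
  expect_equal(length(sel), 10L)
  src <- table(sel@cluster)
  cl <- sel@parameters$clustering
  ## exactly two source clusters with 5 picks each when both have >= 5
  if (all(clusterSizes(cl)[as.integer(names(src))] >= 5L))
    expect_equal(unname(sort(as.integer(src))), c(5L, 5L))
  expect_false(anyDuplicated(sel@ids) > 0L)
})

test_that("max-min medoid ordering matches an exhaustive recomputation", {
  gen <- genLib(n = 60L, nFamilies = 6L, rngSeed = 22L)
  lib <- gen$library
  spec <- metricSpec("D2")
  nt <- neighborTable(lib, spec, 0.6)
  cl <- jarvisPatrick(nt, 2L)
  simFun <- divpick:::makeSimFun(lib, spec)
  med <- divpick:::clusterMedoidPositions(cl@labels, simFun)
  ord <- divpick:::maxMinClusterOrder(med, simFun, seq_len(nClusters(cl)))
  ## independent greedy recomputation from the full medoid matrix
  S <- simFun(med, med)
  nC <- length(med)
  expect_gte(nC, 3L)
  rowMax <- vapply(seq_len(nC), function(i) max(S[i, -i]), 1)
  want <- which.min(rowMax)
  remaining <- setdiff(seq_len(nC), want)
  d <- S[remaining, want]
  while (length(remaining)) {
    nxt <- remaining[which.min(d)]
    want <- c(want, nxt)
    keep <- remaining != nxt
    d <- pmax(d[keep], S[remaining[keep], nxt])
    remaining <- remaining[keep]
  }
  expect_equal(ord, want)
})

test_that("medoids maximize mean within-cluster similarity", {
  lib <- genLib(n = 50L, nFamilies = 6L, rngSeed = 23L)$library
  spec <- metricSpec("D2")
  cl <- jarvisPatrick(neighborTable(lib, spec, 0.6), 2L)
  simFun <- divpick:::makeSimFun(lib, spec)
  med <- divpick:::clusterMedoidPositions(cl@labels, simFun)
  S <- similarityMatrix(lib, spec)
  for (c in seq_len(nClusters(cl))) {
    mem <- which(cl@labels == c)
    means <- rowMeans(S[mem, mem, drop = FALSE])
    expect_equal(med[c], mem[which.max(means)])
  }
})

test_that("refill tops up undersized clusters before adding new ones", {
  lib <- oneClusterLibrary()
  ## hand-build a seed holding 3 members of the single 12-member cluster
  seed <- new("SelectionResult", ids = compoundIds(lib)[1:3],
              phase = rep("seed", 3L), cluster = rep(1L, 3L),
              rank = 1:3, targetN = 3L, scheme = "D1",
              rngSeed = NA_integer_, shortfall = FALSE,
              parameters = list())
  rf <- suppressWarnings(
    refillSelection(lib, seed, "D1", nAdd = 2L, minSize = 5L,
                    threshold = 0.3, kCommon = 1L))
  aud <- rf@parameters$audit
  expect_equal(nrow(aud), 1L)
  expect_equal(aud$type, "fill")
  expect_equal(aud$added, 2L)
  expect_equal(length(rf), 5L)

  ## nAdd below 1 is rejected
  expect_error(refillSelection(lib, seed, "D1", nAdd = 0L), "nAdd")
})

test_that("refill additions only go to undersized or untouched clusters", {
  gen <- genLib(n = 120L, nFamilies = 10L, rngSeed = 24L)
  lib <- gen$library
  sel <- selectSeed(lib, "D2", n = 20L, membersPerCluster = 5L,
                    threshold = 0.7, kCommon = 2L)
  rf <- suppressWarnings(
    refillSelection(lib, sel, "D2", nAdd = 40L, minSize = 5L,
                    threshold = 0.7, kCommon = 2L))
  expect_false(anyDuplicated(rf@ids) > 0L)
  expect_identical(selectedIds(rf, "seed"), sel@ids)
  aud <- rf@parameters$audit
  expect_gt(nrow(aud), 0L)
  cl <- rf@parameters$clustering
  seedCount <- tabulate(cl@labels[match(sel@ids, compoundIds(lib))],
                        nClusters(cl))
  for (r in seq_len(nrow(aud))) {
    cid <- aud$cluster[r]
    if (aud$type[r] == "fill") {
      expect_gt(seedCount[cid], 0L)
      expect_lt(seedCount[cid], 5L)
    } else {
      expect_equal(seedCount[cid], 0L)
    }
  }
})

test_that("seed + refill never duplicates and hits the combined target", {
  gen <- genLib(n = 200L, nFamilies = 12L, rngSeed = 25L)
  lib <- gen$library
  sel <- selectSeed(lib, "D2", n = 25L, membersPerCluster = 5L,
                    threshold = 0.7)
  rf <- refillSelection(lib, sel, "D2", nAdd = 50L, minSize = 5L,
                        threshold = 0.7)
  expect_equal(length(rf), 75L)
  expect_equal(length(unique(rf@ids)), 75L)
  expect_false(rf@shortfall)
})

test_that("selection is deterministic given identical inputs", {
  gen <- genLib(n = 100L, nFamilies = 8L, rngSeed = 26L)
  lib <- gen$library
  s1 <- selectSeed(lib, "D4", n = 15L, threshold = 0.7)
  s2 <- selectSeed(lib, "D4", n = 15L, threshold = 0.7)
  ## byte-identical apart from the descriptor cache environment
  expect_identical(s1@ids, s2@ids)
  expect_identical(s1@cluster, s2@cluster)
  r1 <- refillSelection(lib, s1, "D4", nAdd = 20L, threshold = 0.7)
  r2 <- refillSelection(lib, s2, "D4", nAdd = 20L, threshold = 0.7)
  expect_identical(r1@ids, r2@ids)
})

test_that("random selection is seeded, exact and leaves the RNG alone", {
  lib <- genLib(n = 100L, nFamilies = 8L, rngSeed = 27L)$library
  all <- randomSelect(lib, length(lib), 1L)
  expect_setequal(all@ids, compoundIds(lib))
  expect_error(randomSelect(lib, length(lib) + 1L, 1L), "sample")
  a <- randomSelect(lib, 30L, 7L)
  b <- randomSelect(lib, 30L, 7L)
  expect_identical(a@ids, b@ids)
  set.seed(123L); before <- runif(1L)
  set.seed(123L); invisible(randomSelect(lib, 10L, 5L))
  expect_equal(runif(1L), before)
})

test_that("two random selections overlap near the hypergeometric mean", {
  lib <- genLib(n = 500L, nFamilies = 15L, rngSeed = 28L)$library
  n <- 100L
  ## E[overlap] = n^2 / N = 20; sd ~ 3.6 -- accept a generous band
  ov <- vapply(1:5, function(s) {
    a <- randomSelect(lib, n, s)
    b <- randomSelect(lib, n, s + 100L)
    length(intersect(a@ids, b@ids))
  }, 1L)
  expect_gt(mean(ov), 20 - 3 * 3.6 / sqrt(5))
  expect_lt(mean(ov), 20 + 3 * 3.6 / sqrt(5))
})

test_that("selections serialize to CSV with a JSON sidecar", {
  lib <- oneClusterLibrary()
  sel <- selectSeed(lib, "D1", n = 5L, threshold = 0.3, kCommon = 1L)
  f <- tempfile(fileext = ".csv")
  writeSelection(sel, f)
  got <- utils::read.csv(f)
  expect_equal(got$id, sel@ids)
  expect_equal(got$rank, seq_along(sel@ids))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$scheme, "D1")
  expect_equal(side$threshold, 0.3)
})
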