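## five planted scaffold families of five members each, with distinct
## exact cyclicities by construction
fiveByFive <- function() {
  makeLibrary(c(
    ## cyclicity 0: plain chains
    a1 = "CC", a2 = "CCC", a3 = "CCCC", a4 = "CCO", a5 = "CCN",
    ## cyclicity 6/6: bare six-rings
    b1 = "c1ccccc1", b2 = "c1ccncc1", b3 = "c1cncnc1", b4 = "C1CCCCC1",
    b5 = "C1CCNCC1",
    ## cyclicity 6/7: six-ring plus one exocyclic bond
    c1 = "Cc1ccccc1", c2 = "Clc1ccccc1", c3 = "Oc1ccccc1",
    c4 = "CC1CCCCC1", c5 = "Nc1ccccc1",
    ## cyclicity 6/8
    d1 = "CCc1ccccc1", d2 = "COc1ccccc1", d3 = "CNc1ccccc1",
    d4 = "CCC1CCCCC1", d5 = "ClCc1ccccc1",
    ## cyclicity 11/12: mono-substituted fused bicyclics (11/11 itself
    ## would reduce to 1/1 and merge with the bare six-rings)
    e1 = "Cc1ccc2ccccc2c1", e2 = "Cc1ccc2ncccc2c1", e3 = "Clc1ccc2ccccc2c1",
    e4 = "CC1CCC2CCCCC2C1", e5 = "Oc1ccc2ccccc2c1"))
}

test_that("valid-cluster counting follows the analysis clustering", {
  lib <- fiveByFive()
  ## the 25-compound selection with 5 planted families: SCA finds all 5
  expect_equal(countValidClusters(compoundIds(lib), lib, "SCA"), 5L)
  ## four compounds can never form a valid cluster of five
  expect_equal(countValidClusters(compoundIds(lib)[6:9], lib, "SCA",
                                  minSize = 5L), 0L)
  ## five mutually similar compounds form exactly one valid cluster
  ana <- makeLibrary(c(x1 = "CCCCCCO", x2 = "CCCCCCN", x3 = "CCCCCCC",
                       x4 = "CCCCCCF", x5 = "CCCCCCCl"))
  expect_equal(countValidClusters(compoundIds(ana), ana, "D1",
                                  threshold = 0.3, kCommon = 1L), 1L)
  ## empty selection
  expect_equal(countValidClusters(character(0), lib, "SCA"), 0L)
})

test_that("AMIS equals the exhaustive medoid-pair computation", {
  lib <- fiveByFive()
  sca <- scaCluster(lib)
  expect_equal(nClusters(sca), 5L)
  amis <- avgMaxInterclusterSimilarity(sca, lib, "D1")
  ## brute force over all medoid pairs
  spec <- metricSpec("D1")
  simFun <- divpick:::makeSimFun(lib, spec)
  med <- divpick:::clusterMedoidPositions(
    sca@labels[match(compoundIds(lib), sca@ids)], simFun)
  S <- simFun(med, med)
  brute <- mean(vapply(seq_along(med), function(i) max(S[i, -i]), 1))
  expect_equal(amis, brute)

  ## two clusters: AMIS is their single medoid similarity
  two <- makeLibrary(c(p = "c1ccccc1", q = "Cc1ccccc1"))
  sca2 <- scaCluster(two)
  expect_equal(avgMaxInterclusterSimilarity(sca2, two, "D1"),
               metricSimilarity(two[[1L]], two[[2L]], "D1"))
  ## identical medoid fingerprints across clusters give AMIS 1
  expect_warning(dup <- makeLibrary(c(p = "CCO", q = "OCC")), "duplicate")
  manual <- new("ClusterResult", ids = compoundIds(dup), labels = 1:2,
                method = "manual", parameters = list())
  expect_equal(avgMaxInterclusterSimilarity(manual, dup, "D2"), 1)
  one <- scaCluster(makeLibrary(c(a = "CC", b = "CCC")))
  expect_error(avgMaxInterclusterSimilarity(one, lib, "D1"), "undefined")
})

test_that("scaffold-consistency histograms count spanned SCA classes", {
  lib <- fiveByFive()
  sca <- scaCluster(lib)
  ## identical clusterings: all clusters overlap exactly one class
  h <- scaConsistency(sca, sca)
  expect_equal(unname(h), c(5L, 0L, 0L, 0L, 0L))
  expect_equal(sum(h), nClusters(sca))
  ## a clustering whose single cluster spans two SCA classes
  merged <- new("ClusterResult", ids = compoundIds(lib)[1:10],
                labels = rep(1L, 10L), method = "manual",
                parameters = list())
  scaSub <- scaCluster(lib[1:10])
  expect_equal(unname(scaConsistency(merged, scaSub)),
               c(0L, 1L, 0L, 0L, 0L))
  ## randomized small fixture vs direct set counting
  set.seed(31L)
  lab <- sample.int(3L, 25L, replace = TRUE)
  cl <- new("ClusterResult", ids = compoundIds(lib),
            labels = divpick:::.denseLabels(lab), method = "manual",
            parameters = list())
  h2 <- scaConsistency(cl, sca)
  direct <- table(factor(pmin(vapply(
    split(sca@labels[match(cl@ids, sca@ids)], cl@labels),
    function(x) length(unique(x)), 1L), 5L), levels = 1:5))
  expect_equal(unname(h2), as.integer(direct))
  expect_error(scaConsistency(merged, sca), "different compound sets")
})

test_that("overlap distributions are exact set arithmetic", {
  ids <- sprintf("m%02d", 1:30)
  s1 <- ids[1:10]; s2 <- ids[6:15]; s3 <- ids[c(1:3, 16:20)]
  h <- overlapDistribution(list(s1, s2, s3))
  ## by hand: m01-03 in s1+s3 (2), m04,05 in s1 (1), m06-10 in s1+s2 (2),
  ## m11-15 in s2 (1), m16-20 in s3 (1)
  expect_equal(unname(h), c(12L, 8L, 0L))
  expect_equal(sum(h), length(unique(c(s1, s2, s3))))
  expect_equal(unname(overlapDistribution(list(s1, s1))), c(0L, 10L))
  expect_equal(unname(overlapDistribution(list(s1, ids[21:30]))),
               c(20L, 0L))
  expect_error(overlapDistribution(list(s1)), "at least 2")
})

test_that("largest-cluster fraction is measured against the pool SCA", {
  lib <- fiveByFive()
  sca <- scaCluster(lib)
  largest <- clusterMembers(sca)[[1L]]
  expect_equal(largestClusterFraction(largest, sca), 1)
  expect_equal(largestClusterFraction(setdiff(compoundIds(lib), largest),
                                      sca), 0)
  mix <- c(largest[1:2], setdiff(compoundIds(lib), largest)[1:8])
  expect_equal(largestClusterFraction(mix, sca), 0.2)
})

test_that("the benchmark grid has the prescribed cardinality", {
  lib <- genLib(n = 120L, nFamilies = 10L, rngSeed = 41L)$library
  res <- suppressWarnings(
    runBenchmark(lib, schemes = c("D1", "D2"), randomSeeds = integer(0),
                 seedN = 15L, refillN = 30L, threshold = 0.7,
                 verbose = FALSE))
  expect_equal(nrow(res$manifest), 2L * 3L * 2L * 1L)
  expect_true(all(is.na(res$manifest$error)))
  expect_error(runBenchmark(lib, schemes = character(0)), "empty scheme")
  ## ranks are dense with ties sharing the better rank
  rk <- schemeRanks(res$manifest, step = "seed")
  expect_true(all(rk$meanRank >= 1))
  expect_setequal(rk$scheme, c("D1", "D2"))
})

test_that("benchmark results serialize to the CSV report set", {
  lib <- genLib(n = 120L, nFamilies = 10L, rngSeed = 41L)$library
  res <- suppressWarnings(
    runBenchmark(lib, schemes = c("D1", "D2"), randomSeeds = 1L,
                 seedN = 15L, refillN = 30L, threshold = 0.7,
                 verbose = FALSE))
  expect_equal(nrow(res$manifest), 2L * 3L * 2L * 2L)
  d <- tempfile()
  writeBenchmark(res, d)
  expect_true(all(file.exists(file.path(d,
    c("manifest.csv", "valid_clusters.csv", "amis.csv", "consistency.csv",
      "largest_cluster_fraction.csv", "manifest.json")))))
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), nrow(res$manifest))
})
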