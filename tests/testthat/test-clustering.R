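test_that("Jarvis-Patrick handles the degenerate cases", {
  lib <- tinyLibrary()
  ## threshold 1: nothing is a neighbor, everything a singleton
  nt <- neighborTable(lib, "D1", threshold = 1)
  cl <- jarvisPatrick(nt, 1L)
  expect_equal(nClusters(cl), length(lib))
  expect_true(all(clusterSizes(cl) == 1L))
  expect_error(jarvisPatrick(nt, 0L), "kCommon")
})

test_that("two mutual neighbors with a shared third cluster together", {
  ## hand-built 3-node neighbor graph: 1-2 neighbors, both neighbor 3
  s <- matrix(c(1, .9, .9,
                .9, 1, .9,
                .9, .9, 1), 3L, 3L)
  oracle <- jpOracle(s, 0.5, 1L)
  expect_equal(length(unique(oracle)), 1L)
  ## same through the package on molecules engineered to be similar
  lib <- makeLibrary(c(a = "CCCCCCO", b = "CCCCCCN", c = "CCCCCCC"))
  s2 <- similarityMatrix(lib, "D1")
  th <- min(s2[upper.tri(s2)]) - 0.01
  cl <- jarvisPatrick(neighborTable(lib, "D1", th), 1L)
  expect_equal(nClusters(cl), 1L)
})

test_that("Jarvis-Patrick equals the brute-force oracle on random libraries", {
  for (seed in c(2L, 4L)) {
    lib <- genLib(n = 60L, nFamilies = 10L, rngSeed = seed)$library
    for (sc in c("D1", "D2")) {
      s <- similarityMatrix(lib, sc)
      for (params in list(c(0.5, 1L), c(0.6, 2L), c(0.7, 4L))) {
        th <- params[1L]; k <- as.integer(params[2L])
        cl <- jarvisPatrick(neighborTable(lib, sc, th), k)
        expect_same_partition(cl@labels,
                              jpOracle(s, th, k))
      }
    }
  }
})

test_that("JP conventions are honored by the oracle too", {
  lib <- genLib(n = 50L, nFamilies = 8L, rngSeed = 6L)$library
  s <- similarityMatrix(lib, "D2")
  nt <- neighborTable(lib, "D2", 0.6)
  for (self in c(TRUE, FALSE)) {
    cl <- jarvisPatrick(nt, 2L, includeSelf = self)
    expect_same_partition(cl@labels,
                          jpOracle(s, 0.6, 2L, includeSelf = self))
  }
  cl2 <- jarvisPatrick(nt, 2L, requireMutual = FALSE)
  expect_same_partition(cl2@labels,
                        jpOracle(s, 0.6, 2L, requireMutual = FALSE))
})

test_that("raising kCommon or the threshold only refines the partition", {
  lib <- genLib(n = 80L, nFamilies = 10L, rngSeed = 8L)$library
  nt6 <- neighborTable(lib, "D2", 0.6)
  prev <- NULL
  for (k in 1:5) {
    cl <- jarvisPatrick(nt6, k)
    if (!is.null(prev)) expect_true(refines(cl@labels, prev))
    prev <- cl@labels
  }
  prev <- NULL
  for (th in c(0.5, 0.6, 0.7, 0.8)) {
    cl <- jarvisPatrick(neighborTable(lib, "D2", th), 2L)
    if (!is.null(prev)) expect_true(refines(cl@labels, prev))
    prev <- cl@labels
  }
})

test_that("cluster ids are dense, size-ordered and deterministic", {
  lib <- genLib(n = 60L, nFamilies = 8L, rngSeed = 9L)$library
  cl <- jarvisPatrick(neighborTable(lib, "D2", 0.6), 2L)
  sz <- clusterSizes(cl)
  expect_equal(sort(unique(cl@labels)), seq_len(nClusters(cl)))
  expect_true(all(diff(sz) <= 0))
  expect_equal(sum(sz), length(lib))
  cl2 <- jarvisPatrick(neighborTable(lib, "D2", 0.6), 2L)
  expect_identical(cl@labels, cl2@labels)
})

test_that("SCA profiles follow the ring-bond fraction", {
  expect_equal(scaProfile(parseSmiles("c1ccccc1", "b"))$cyclicity, 100)
  expect_equal(scaProfile(parseSmiles("Cc1ccccc1", "t"))$cyclicity,
               100 * 6 / 7)
  expect_equal(scaProfile(parseSmiles("CC", "e"))$cyclicity, 0)
  expect_equal(scaProfile(parseSmiles("C", "c"))$cyclicity, 0)
  ## complexity grows when bonds are added
  expect_lt(scaProfile(parseSmiles("CCC", "p"))$complexity,
            scaProfile(parseSmiles("CCCC", "b"))$complexity)
})

test_that("SCA clusters group by exact reduced cyclicity", {
  lib <- makeLibrary(c(ben = "c1ccccc1", pyr = "c1ccncc1",
                       tol = "Cc1ccccc1", chx = "C1CCCCC1",
                       eth = "CC", but = "CCCC",
                       dimedecalin = "CC1CCC2CCCCC2C1C"))
  cl <- scaCluster(lib)
  lab <- clusterLabels(cl)
  ## benzene, pyridine, cyclohexane: all 6/6
  expect_equal(lab[["ben"]], lab[["pyr"]])
  expect_equal(lab[["ben"]], lab[["chx"]])
  ## toluene (6/7) differs from benzene (6/6)
  expect_false(lab[["tol"]] == lab[["ben"]])
  ## acyclics cluster together at cyclicity 0
  expect_equal(lab[["eth"]], lab[["but"]])
  ## 11/13 does not reduce to anything shared above
  expect_equal(sum(lab == lab[["dimedecalin"]]), 1L)
})

test_that("SCA clustering is invariant to order and spelling", {
  smis <- c(a = "Cc1ccccc1", b = "CCO", c = "c1ccncc1", d = "CCCC")
  l1 <- makeLibrary(smis)
  l2 <- makeLibrary(rev(smis))
  k1 <- clusterLabels(scaCluster(l1))
  k2 <- clusterLabels(scaCluster(l2))
  for (id in names(smis))
    expect_equal(sum(k1 == k1[[id]]),
                 sum(k2 == k2[[id]]))
  l3 <- makeLibrary(c(a = "c1ccccc1C", b = "OCC", c = "n1ccccc1",
                      d = "CCCC"))
  expect_identical(unname(clusterLabels(scaCluster(l3))), unname(k1))
})

test_that("an all-acyclic library is one single SCA cluster", {
  lib <- makeLibrary(c(a = "CC", b = "CCC", c = "CCO", d = "CC(C)C"))
  expect_equal(nClusters(scaCluster(lib)), 1L)
})

test_that("clusterings serialize to CSV with a JSON sidecar", {
  lib <- tinyLibrary()
  cl <- scaCluster(lib)
  f <- tempfile(fileext = ".csv")
  writeClusters(cl, f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), length(lib))
  expect_equal(got$cluster_size,
               clusterSizes(cl)[got$cluster_id])
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$method, "SCA")
})
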