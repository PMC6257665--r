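test_that("path fingerprints reflect the path structure", {
  ## no bonds, no paths: all-zero fingerprint
  lone <- pathFingerprint(parseSmiles("C", "lone"))
  expect_equal(sum(fpBits(lone)), 0L)

  ## single vs double bond paths differ, so fingerprints must differ
  fc <- pathFingerprint(parseSmiles("CC", "a"))
  fd <- pathFingerprint(parseSmiles("C=C", "b"))
  expect_false(identical(unname(fpBits(fc)), unname(fpBits(fd))))

  ## two spellings of toluene give identical fingerprints
  f1 <- pathFingerprint(parseSmiles("Cc1ccccc1", "t1"))
  f2 <- pathFingerprint(parseSmiles("c1ccccc1C", "t2"))
  expect_identical(unname(fpBits(f1)), unname(fpBits(f2)))
})

test_that("path enumeration is exact on hand-checkable molecules", {
  expect_setequal(molPathStrings(parseSmiles("CCO", "x")),
                  c("C-C", "C-O", "C-C-O"))
  ## benzene: one path string per length 1..5 bonds
  expect_setequal(molPathStrings(parseSmiles("c1ccccc1", "b")),
                  c("c:c", "c:c:c", "c:c:c:c", "c:c:c:c:c", "c:c:c:c:c:c"))
})

test_that("folding halves the length, ORs halves, and composes", {
  lib <- tinyLibrary()
  fp <- pathFingerprint(lib)
  expect_equal(fpLength(fp), 2048L)
  f1 <- foldFingerprint(fp, 1L)
  f2 <- foldFingerprint(fp, 2L)
  f3 <- foldFingerprint(fp, 3L)
  expect_equal(fpLength(f1), 1024L)
  expect_equal(fpLength(f2), 512L)
  expect_equal(fpLength(f3), 256L)
  ## popcount never grows under folding
  expect_true(all(rowSums(fpBits(f1)) <= rowSums(fpBits(fp))))
  ## fold twice = two single folds
  expect_identical(fpBits(foldFingerprint(f1, 1L)), fpBits(f2))
  ## OR semantics on an explicit vector
  v <- matrix(FALSE, 1L, 2048L); v[1L, c(1L, 1025L)] <- TRUE
  fpv <- new("FingerprintSet", bits = v, ids = "x", kind = "path",
             foldLevel = 0L, version = "")
  expect_equal(which(fpBits(foldFingerprint(fpv, 1L))[1L, ]), 1L)
  ## all-zero stays all-zero
  z <- pathFingerprint(parseSmiles("C", "z"))
  expect_equal(sum(fpBits(foldFingerprint(z, 2L))), 0L)
  ## only path fingerprints fold
  expect_error(foldFingerprint(structuralKeys(lib)), "path")
})

test_that("hashing directly at a shorter width equals folding to it", {
  lib <- tinyLibrary()
  direct <- pathFingerprint(lib, nBits = 512L)
  folded <- foldFingerprint(pathFingerprint(lib), 2L)
  expect_identical(unname(fpBits(direct)), unname(fpBits(folded)))
})

test_that("concatenation produces the combined descriptor lengths", {
  lib <- tinyLibrary()
  fp <- pathFingerprint(lib)
  keys <- structuralKeys(lib)
  expect_equal(fpLength(concatFingerprints(fp, keys)), 2214L)
  expect_equal(fpLength(concatFingerprints(foldFingerprint(fp, 1L), keys)),
               1190L)
  expect_equal(fpLength(concatFingerprints(foldFingerprint(fp, 2L), keys)),
               678L)
  expect_equal(fpLength(concatFingerprints(foldFingerprint(fp, 3L), keys)),
               422L)
  expect_error(concatFingerprints(fp, fp), "keys")
  expect_error(concatFingerprints(keys, keys), "path")
})

test_that("bit statistics match hand counts", {
  bits <- rbind(c(TRUE, FALSE), c(TRUE, FALSE),
                c(FALSE, TRUE), c(TRUE, TRUE))
  fp <- new("FingerprintSet", bits = bits, ids = paste0("m", 1:4),
            kind = "keys", foldLevel = 0L, version = "t")
  st <- bitStats(fp)
  expect_equal(unname(st$setProbability), c(0.75, 0.5))
  expect_equal(st$meanSetProbability, 0.625)
  ## the bit set in exactly half the fingerprints has entropy 1
  expect_equal(st$meanBitEntropy,
               mean(c(-0.75 * log2(0.75) - 0.25 * log2(0.25), 1)))

  same <- new("FingerprintSet", bits = bits[c(1L, 1L, 1L), ],
              ids = paste0("m", 1:3), kind = "keys", foldLevel = 0L,
              version = "t")
  expect_equal(bitStats(same)$meanBitEntropy, 0)
})

test_that("shorter foldings are denser on generated molecules", {
  lib <- genLib(n = 60L, nFamilies = 8L, rngSeed = 5L)$library
  fp <- pathFingerprint(lib)
  p2048 <- bitStats(fp)$meanSetProbability
  p512 <- bitStats(foldFingerprint(fp, 2L))$meanSetProbability
  p256 <- bitStats(foldFingerprint(fp, 3L))$meanSetProbability
  expect_true(p512 >= p2048)
  expect_true(p256 >= p512)
})

test_that("structural keys respond to the expected substructures", {
  tab <- structuralKeyTable()
  expect_equal(nrow(tab), 166L)
  ben <- structuralKeys(parseSmiles("c1ccccc1", "ben"))
  on <- tab$name[fpBits(ben)[1L, ]]
  ## regression fixture: benzene's key profile under divpick-SK166/1.0
  expect_setequal(on, c("carbon", "carbon_ge4", "ring", "aromatic_ring",
                        "ring6", "aromatic_C_ge6", "aro_CC", "aro_path2",
                        "aro_path3"))
  ## acyclic alkane: every ring key off
  but <- structuralKeys(parseSmiles("CCCC", "but"))
  ringKeys <- tab$type %in% c("rings", "aroRings", "ringSize", "elemRing",
                              "aroElem")
  expect_false(any(fpBits(but)[1L, ringKeys]))
  ## lone carbon matches exactly the carbon-presence key
  loneC <- structuralKeys(parseSmiles("C", "c1"))
  expect_equal(tab$name[fpBits(loneC)[1L, ]], "carbon")
  ## count-threshold key: nitro group
  nit <- structuralKeys(parseSmiles("[O-][N+](=O)c1ccccc1", "nb"))
  expect_true(fpBits(nit)[1L, tab$name == "nitro"])
  expect_true(fpBits(nit)[1L, tab$name == "cation"])
})

test_that("fingerprint text formats round-trip losslessly", {
  lib <- tinyLibrary()
  cf <- concatFingerprints(foldFingerprint(pathFingerprint(lib), 3L),
                           structuralKeys(lib))
  f <- tempfile()
  writeFingerprints(cf, f)
  rf <- readFingerprints(f)
  expect_identical(fpBits(rf), fpBits(cf))
  expect_identical(rf@kind, "combined")
  expect_identical(rf@foldLevel, 3L)

  csv <- tempfile(fileext = ".csv")
  writeFingerprintsCSV(structuralKeys(lib), csv)
  back <- utils::read.csv(csv)
  expect_identical(unname(as.matrix(back[, -1L]) == 1L),
                   unname(fpBits(structuralKeys(lib))))
})
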