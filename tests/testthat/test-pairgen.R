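# Pair generation: POC labeling, ERCPs, random negatives, retraining schemes.

test_that("POC labeling follows the 20/80 thresholds", {
  # measured assay values: a strong binder, a non-binder, a weak binder
  expect_identical(labelFromPoc(c(3.6, 100, 43)),
                   c("active", "inactive", "ambiguous"))
  # thresholds are exclusive: exactly 20 or 80 stays ambiguous
  expect_identical(labelFromPoc(c(20, 80)), c("ambiguous", "ambiguous"))
  expect_error(labelFromPoc(-1), "non-negative")
  expect_error(labelFromPoc(50, activeMax = 80, inactiveMin = 20), "below")
})

test_that("target-scope ERCPs pair compounds binding the focus target", {
  inter <- data.frame(compound_id = c("C1", "C2", "C3", "C4"),
                      target_id = c("T1", "T1", "T2", "T2"),
                      stringsAsFactors = FALSE)
  p <- pairTable(buildErcps(inter, NULL, "T1", "target"))
  expect_identical(nrow(p), 1L)
  expect_identical(p$compound_a, "C1")
  expect_identical(p$compound_b, "C2")
  expect_identical(p$label, "positive")
  expect_identical(p$scheme, "ERCP_TARGET")
  # a single compound on the focus target yields no pairs
  expect_identical(nPairs(buildErcps(inter[1, ], NULL, "T1", "target")), 0L)
  expect_error(buildErcps(inter, NULL, "T9", "target"), "unknown focus target")
})

test_that("family scope expands ERCPs across family-related targets", {
  inter <- data.frame(compound_id = c("C1", "C2", "C3", "C4", "C5"),
                      target_id = c("T1", "T1", "T2", "T2", "T3"),
                      stringsAsFactors = FALSE)
  fams <- data.frame(target_id = c("T1", "T2", "T3"),
                     family_db = "PFAM",
                     family_id = c("F1", "F1", "F2"),
                     stringsAsFactors = FALSE)
  p <- pairTable(buildErcps(inter, fams, "T1", "family:PFAM"))
  # T1 and T2 share F1: all pairs among C1..C4, but nothing with C5 (T3)
  expect_identical(nrow(p), 6L)
  expect_true(all(p$scheme == "ERCP_FAMILY"))
  expect_false(any(p$compound_a == "C5" | p$compound_b == "C5"))
  key <- paste(p$compound_a, p$compound_b)
  expect_true("C1 C3" %in% key)  # cross-target pair via the shared family
  expect_error(buildErcps(inter, fams, "T1", "family:SMART"), "unknown family database")
})

test_that("affinity thresholds restrict the ERCP compound pool", {
  inter <- data.frame(compound_id = c("C1", "C2", "C3"),
                      target_id = "T1",
                      affinity_nM = c(50, 900, 5000),
                      stringsAsFactors = FALSE)
  expect_identical(nPairs(buildErcps(inter, NULL, "T1", "target")), 3L)
  expect_identical(nPairs(buildErcps(inter, NULL, "T1", "target",
                                     affinityMaxNM = 1000)), 1L)
})

test_that("random negative pairs follow the count formula and the seed", {
  actives <- sprintf("A%02d", 1:10)
  pool <- sprintf("D%02d", 1:30)
  neg <- sampleNegativePairs(actives, pool, nPositives = 10, negPerPos = 6, seed = 3)
  expect_identical(nPairs(neg), 60L)
  expect_true(all(pairTable(neg)$label == "negative"))
  expect_true(all(pairTable(neg)$scheme == "RAND_NEG"))
  again <- sampleNegativePairs(actives, pool, nPositives = 10, negPerPos = 6, seed = 3)
  expect_identical(pairTable(neg), pairTable(again))
  other <- sampleNegativePairs(actives, pool, nPositives = 10, negPerPos = 6, seed = 4)
  expect_false(identical(pairTable(neg), pairTable(other)))
  # cap: a 2x2 universe cannot give more than 4 pairs
  expect_warning(capped <- sampleNegativePairs(c("a1", "a2"), c("d1", "d2"),
                                               nPositives = 10, negPerPos = 6,
                                               seed = 1), "available")
  expect_identical(nPairs(capped), 4L)
  expect_error(sampleNegativePairs(character(), pool, 5, seed = 1), "non-empty")
  expect_error(sampleNegativePairs(actives, c("A01", "x"), 5, seed = 1), "disjoint")
})

test_that("pairing schemes are exact Cartesian products with scheme-tied labels", {
  inp <- pairingInput(pNew = c("a1", "a2"), nNew = c("i1", "i2", "i3"),
                      pPrv = c("k1", "k2", "k3", "k4", "k5"), nPrv = c("r1", "r2"))
  pp <- pairTable(makePairingData(inp, "PP"))
  expect_identical(nrow(pp), 2L * 5L)
  expect_true(all(pp$label == "positive" & pp$scheme == "PP"))
  np <- pairTable(makePairingData(inp, "NP"))
  expect_identical(nrow(np), 3L * 5L)
  expect_true(all(np$label == "negative" & np$scheme == "NP"))
  nn <- pairTable(makePairingData(inp, "NN"))
  expect_identical(nrow(nn), 3L * 2L)
  pn <- pairTable(makePairingData(inp, "PN"))
  expect_identical(nrow(pn), 2L * 3L)
  all4 <- pairTable(makePairingData(inp))
  expect_identical(nrow(all4), 10L + 15L + 6L + 6L)
  expect_true(all(all4$compound_a < all4$compound_b))
  expect_false(anyDuplicated(paste(all4$compound_a, all4$compound_b)) > 0)
})

test_that("an empty N_new empties every scheme that uses it", {
  inp <- pairingInput(pNew = c("a1", "a2"), pPrv = c("k1", "k2"))
  expect_identical(nPairs(makePairingData(inp, c("NP", "NN", "PN"))), 0L)
})

test_that("internal P_new pairs are excluded unless requested", {
  inp <- pairingInput(pNew = c("a1", "a2", "a3"), pPrv = "k1")
  expect_identical(nPairs(makePairingData(inp, "PP")), 3L)
  expect_identical(nPairs(makePairingData(inp, "PP", includeInternalPP = TRUE)),
                   3L + 3L)
})

test_that("overlapping pairing-input sets are rejected with the offending ids", {
  expect_error(pairingInput(pNew = c("x", "y"), nNew = c("y", "z")), "y")
})

test_that("scheme counts hold exactly across random set sizes", {
  set.seed(11)
  for (rep in 1:20) {
    sizes <- sample(0:12, 4, replace = TRUE)
    mk <- function(prefix, n) if (n) sprintf("%s%02d", prefix, seq_len(n)) else character()
    inp <- pairingInput(mk("p", sizes[1]), mk("n", sizes[2]),
                        mk("k", sizes[3]), mk("r", sizes[4]))
    expect_identical(nPairs(makePairingData(inp, "PP")), sizes[1] * sizes[3])
    expect_identical(nPairs(makePairingData(inp, "NP")), sizes[2] * sizes[3])
    expect_identical(nPairs(makePairingData(inp, "NN")), sizes[2] * sizes[4])
    expect_identical(nPairs(makePairingData(inp, "PN")), sizes[1] * sizes[2])
  }
})

test_that("pair construction canonicalizes order and rejects self-pairs", {
  p <- pairTable(chemicalPairs(c("z", "b"), c("a", "c"), "NP"))
  expect_identical(p$compound_a, c("a", "b"))
  expect_identical(p$compound_b, c("z", "c"))
  expect_error(chemicalPairs("x", "x", "PP"), "self-pairs")
})

test_that("PairingInput derives from POC results with ambiguous compounds dropped", {
  res <- data.frame(compound_id = c("c1", "c2", "c3"),
                    poc_percent = c(5, 95, 50), stringsAsFactors = FALSE)
  inp <- pairingInputFromPoc(res, pPrv = "k1", nPrv = "r1")
  expect_identical(inp@pNew, "c1")
  expect_identical(inp@nNew, "c2")
})

test_that("pair lists round-trip through CSV", {
  inp <- pairingInput(pNew = "a1", nNew = c("i1", "i2"), pPrv = c("k1", "k2"))
  pairs <- makePairingData(inp, c("PP", "NP"))
  path <- withr::local_tempfile(fileext = ".csv")
  writePairs(pairs, path)
  expect_identical(pairTable(readPairs(path)), pairTable(pairs))
})
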