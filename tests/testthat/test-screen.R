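# Library screening, novelty filters, hooks, clustering, substructure search.

test_that("screening keeps compounds at or above the cutoff, sorted", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  lib <- generateScreeningLibrary(fix$universe, nBackground = 30,
                                  nPlantedHits = 4, seed = 71)
  refs <- cpds[setdiff(fix$actives, lib$planted)]
  hits <- screenLibrary(fix$model, lib$library, refs, scoreCutoff = 0.8)
  expect_true(all(hits$ecbs_score >= 0.8))
  expect_true(all(diff(hits$ecbs_score) <= 0))
  expect_true(all(!nzchar(hits$excluded_by)) && all(!hits$pains_flag))
  # empty library is fine; empty reference set is not
  expect_identical(nrow(screenLibrary(fix$model, cpds[character()], refs)), 0L)
  expect_error(screenLibrary(fix$model, lib$library, cpds[character()]), "non-empty")
})

test_that("the score cutoff boundary is inclusive", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  lib <- generateScreeningLibrary(fix$universe, nBackground = 20,
                                  nPlantedHits = 3, seed = 72)
  refs <- cpds[setdiff(fix$actives, lib$planted)]
  sc <- compoundScore(fix$model, lib$library, refs)
  cutoff <- max(sc$score)  # an achieved score: the top compound must survive
  hits <- screenLibrary(fix$model, lib$library, refs, scoreCutoff = cutoff)
  expect_identical(nrow(hits), sum(sc$score >= cutoff))
  expect_gte(nrow(hits), 1L)
})

test_that("similarity filtering excludes strictly above the cutoff", {
  # constructed fingerprints: sim(h_same, act) = 1, sim(h_edge, act) = 0.5
  # exactly, sim(h_far, act) = 0
  cpds <- bitCompounds(list(act = 1:10,
                            h_same = 1:10,
                            h_edge = 1:5,      # 5/10 bits shared: TC = 0.5 exactly
                            h_far = 101:110))
  hits <- data.frame(compound_id = c("h_same", "h_edge", "h_far"),
                     ecbs_score = c(0.9, 0.85, 0.81), best_active_id = "act",
                     excluded_by = "", pains_flag = FALSE,
                     cluster_id = NA_character_, is_center = FALSE,
                     stringsAsFactors = FALSE)
  out <- similarityFilter(hits, cpds, cpds["act"], fpKind = "MACCS166",
                          cutoff = 0.5)
  expect_identical(out$excluded_by, c("similarity", "", ""))
  expect_equal(out$max_known_similarity, c(1, 0.5, 0))
  # monotone: a lower cutoff can only add exclusions
  lower <- similarityFilter(hits, cpds, cpds["act"], fpKind = "MACCS166",
                            cutoff = 0.3)
  expect_true(all(!nzchar(out$excluded_by) | nzchar(lower$excluded_by)))
  expect_identical(lower$excluded_by, c("similarity", "similarity", ""))
})

test_that("exclusion hooks flag or exclude per contract", {
  cpds <- bitCompounds(list(h1 = 1:5, h2 = 6:10))
  hits <- data.frame(compound_id = c("h1", "h2"), ecbs_score = c(0.9, 0.8),
                     best_active_id = "a", excluded_by = "", pains_flag = FALSE,
                     cluster_id = NA_character_, is_center = FALSE,
                     stringsAsFactors = FALSE)
  none <- applyExclusionHook(hits, cpds, function(c) FALSE, "pharmacophore")
  expect_true(all(!nzchar(none$excluded_by)))
  all_ <- applyExclusionHook(hits, cpds, function(c) TRUE, "pharmacophore")
  expect_true(all(all_$excluded_by == "pharmacophore"))
  pains <- applyExclusionHook(hits, cpds, function(c) TRUE, "PAINS")
  expect_true(all(pains$pains_flag))
  expect_true(all(!nzchar(pains$excluded_by)))  # flag-only, no exclusion
  expect_error(applyExclusionHook(hits, cpds, function(c) stop("boom"), "hk"),
               "h1")
})

test_that("the bundled PAINS patterns flag a quinone but not benzene", {
  pred <- painsPredicate()
  q <- parseCompounds("q", "O=C1C=CC(=O)C=C1")
  b <- parseCompounds("b", "c1ccccc1")
  expect_true(pred(q))
  expect_false(pred(b))
})

test_that("Butina clustering handles degenerate geometries", {
  same <- parseCompounds(sprintf("m%d", 1:5), rep("Cc1ccccc1O", 5))
  cl <- butinaCluster(same, "PATH5_2048", 0.6)
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_identical(sum(cl$is_center), 1L)
  # pairwise-dissimilar compounds become singletons
  far <- bitCompounds(list(a = 1:5, b = 21:25, c = 41:45, d = 61:65))
  cl2 <- butinaCluster(far, "MACCS166", 0.5)
  expect_identical(length(unique(cl2$cluster_id)), 4L)
  expect_true(all(cl2$is_center))
  expect_error(butinaCluster(far, "MACCS166", 0), "simCutoff")
})

test_that("Butina clustering agrees with the brute-force leader simulation", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    fp <- randomFingerprintSet(n, "MACCS166", p = 0.15)
    sim <- tanimotoMatrix(fp)
    cutoff <- runif(1, 0.2, 0.8)
    got <- butinaClusterFromSimilarity(sim, cutoff)
    want <- bruteButina(sim, cutoff)
    # same number of clusters, same memberships, same centers
    expect_identical(length(unique(got$cluster_id)), length(want))
    expect_identical(sum(got$is_center), length(want))
    gotClusters <- split(got$compound_id, got$cluster_id)
    for (w in want) {
      matchIdx <- which(vapply(gotClusters, function(g) setequal(g, w$members), TRUE))
      expect_length(matchIdx, 1L)
      expect_true(got$is_center[got$compound_id == w$center])
    }
    # partition: sizes sum to n
    expect_identical(length(got$compound_id), n)
  }
})

test_that("cluster centers join the hit table one per cluster", {
  cpds <- bitCompounds(list(h1 = 1:10, h2 = c(1:9, 30), h3 = 50:60, h4 = 80:90))
  hits <- data.frame(compound_id = c("h1", "h2", "h3", "h4"),
                     ecbs_score = c(0.9, 0.88, 0.85, 0.82),
                     best_active_id = "a", excluded_by = "", pains_flag = FALSE,
                     cluster_id = NA_character_, is_center = FALSE,
                     stringsAsFactors = FALSE)
  cl <- butinaCluster(cpds, "MACCS166", 0.6)
  out <- selectClusterCenters(cl, hits)
  expect_identical(sum(out$is_center), length(unique(cl$cluster_id)))
  expect_true(all(!is.na(out$cluster_id)))
  # singletons are their own centers
  expect_true(out$is_center[out$compound_id == "h3"])
  # clusters referencing unknown hits fail
  expect_error(selectClusterCenters(cl, hits[1:2, ]), "unknown hit")
  # excluded hits can never be centers
  hits$excluded_by[1] <- "similarity"
  cl1 <- cl[cl$compound_id == "h1", ]
  if (cl1$is_center) expect_error(selectClusterCenters(cl, hits), "excluded")
})

test_that("novelty reports rank references per fingerprint kind", {
  cpds <- parseCompounds(c("query", "same", "close", "far"),
                         c("Nc1ccc(I)cc1", "Nc1ccc(I)cc1", "Nc1ccc(Br)cc1",
                           "C1CCOC1"))
  rep <- noveltyReport(cpds["query"], cpds[c("same", "close", "far")],
                       fpKinds = c("MORGAN_R2_1024", "MACCS166"),
                       activities = c(same = "POC 3.6", close = "POC 15",
                                      far = "POC 100"))
  expect_identical(nrow(rep), 6L)
  for (k in unique(rep$kind)) {
    sub <- rep[rep$kind == k, ]
    expect_identical(sub$reference_id[1], "same")
    expect_equal(sub$similarity[1], 1.0)
    expect_true(all(diff(sub$similarity) <= 0))
  }
  expect_identical(rep$activity[rep$reference_id == "same"][1], "POC 3.6")
})

test_that("substructure search honors ignored atoms", {
  cands <- parseCompounds(c("tol", "cyc", "pyr"),
                          c("Cc1ccccc1", "C1CCCCC1", "c1ccncc1"))
  expect_identical(substructureMatch("c1ccccc1", cands), "tol")
  # a core bigger than the candidate cannot match
  expect_length(substructureMatch("c1ccc2ccccc2c1", cands), 0)
  # a compound always contains itself
  expect_identical(substructureMatch("Cc1ccccc1", cands), "tol")
  # deleting the amino and iodo decorations leaves a plain phenyl core
  core <- parseCompounds("core", "Nc1ccc(I)cc1")
  expect_length(substructureMatch(core, cands), 0)
  g <- ecbscreen:::.molGraph(unname(smiles(core)))
  ign <- which(g$elem %in% c("N", "I"))
  expect_identical(substructureMatch(core, cands, ignoreAtomIndices = ign), "tol")
  expect_error(substructureMatch(core, cands, ignoreAtomIndices = 99L), "out of range")
  expect_error(substructureMatch("c1cc(", cands), "invalid substructure pattern")
})

test_that("hit tables write to CSV with empty flags preserved", {
  hits <- data.frame(compound_id = "h1", ecbs_score = 0.9, best_active_id = "a",
                     excluded_by = "", pains_flag = FALSE,
                     cluster_id = "C1", is_center = TRUE,
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeHits(hits, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$compound_id, "h1")
  expect_true(back$is_center)
})
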