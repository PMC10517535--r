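# Pair featurization, forest training, ensembles, scoring, persistence.

test_that("pair featurization is symmetric with AND/XOR segments", {
  set.seed(5)
  a <- list(MACCS166 = randomFingerprintSet(4, prefix = "a"))
  b <- list(MACCS166 = randomFingerprintSet(4, prefix = "b"))
  X <- featurizePair(a, b)
  Y <- featurizePair(b, a)
  expect_identical(unname(X), unname(Y))
  expect_identical(ncol(X), 2L * 166L)
  # identical fingerprints: XOR segment all-zero, AND segment equals the bits
  Z <- featurizePair(a, a)
  expect_true(all(Z[, grepl("xor", colnames(Z))] == 0))
  expect_identical(unname(Z[, grepl("and", colnames(Z))]),
                   unname(fingerprintBits(a$MACCS166)))
  expect_error(featurizePair(a, b, kinds = "PATH5_2048"), "missing fingerprint kind")
})

test_that("training rejects degenerate inputs", {
  fix <- tinyTrainedModel()
  tab <- pairTable(fix$pairs)
  posOnly <- chemicalPairs(tab$compound_a[tab$label == "positive"],
                           tab$compound_b[tab$label == "positive"], "ERCP_TARGET")
  expect_error(trainEcbsModel(posOnly, universeCompounds(fix$universe),
                              kinds = "MACCS166"), "both positive and negative")
  ghost <- chemicalPairs(c("nope1", tab$compound_a[1]),
                         c("nope2", tab$compound_b[nrow(tab)]),
                         c("ERCP_TARGET", "RAND_NEG"))
  expect_error(trainEcbsModel(ghost, universeCompounds(fix$universe),
                              kinds = "MACCS166"), "unresolvable")
})

test_that("training is deterministic for a fixed seed and data", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  m2 <- trainEcbsModel(fix$pairs, cpds, kinds = "MACCS166", numTrees = 200L,
                       seed = 9L)
  m3 <- trainEcbsModel(fix$pairs, cpds, kinds = "MACCS166", numTrees = 200L,
                       seed = 9L)
  probe <- pairTable(fix$pairs)[1:20, ]
  expect_identical(scorePairs(m2, cpds, probe$compound_a, probe$compound_b),
                   scorePairs(m3, cpds, probe$compound_a, probe$compound_b))
})

test_that("pair scores are symmetric probabilities separating the classes", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  tab <- pairTable(fix$pairs)
  sAB <- scorePairs(fix$model, cpds, tab$compound_a, tab$compound_b)
  sBA <- scorePairs(fix$model, cpds, tab$compound_b, tab$compound_a)
  expect_identical(sAB, sBA)
  expect_true(all(sAB >= 0 & sAB <= 1))
  expect_gt(mean(sAB[tab$label == "positive"]), mean(sAB[tab$label == "negative"]))
  # training-set AUCPR on the separable synthetic universe is near-perfect
  expect_gte(aucpr(sAB, tab$label == "positive")$area, 0.95)
})

test_that("ensembles average their members", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  uni <- fix$universe
  perScope <- list(
    target = fix$pairs,
    "family:FAMA" = {
      inter <- universeInteractions(uni)
      pos <- buildErcps(inter, universeFamilies(uni), "T1", "family:FAMA")
      neg <- sampleNegativePairs(unique(inter$compound_id),
                                 universeTruth(uni)$compound_id[
                                   universeTruth(uni)$role == "decoy"],
                                 nPairs(pos), negPerPos = 3, seed = 31L)
      combinePairs(pos, neg, warnDuplicates = FALSE)
    })
  ens <- trainEcbsEnsemble(perScope, cpds, kinds = "MACCS166",
                           numTrees = 150L, seed = 5L)
  expect_length(ens@members, 2L)
  expect_identical(vapply(ens@members, function(m) m@scope, ""),
                   c("target", "family:FAMA"))
  tab <- pairTable(fix$pairs)[1:10, ]
  memberScores <- vapply(ens@members, function(m)
    scorePairs(m, cpds, tab$compound_a, tab$compound_b), numeric(10))
  ensScore <- scorePairs(ens, cpds, tab$compound_a, tab$compound_b)
  expect_equal(ensScore, rowMeans(memberScores))
  expect_true(all(ensScore >= apply(memberScores, 1, min) - 1e-12))
  expect_true(all(ensScore <= apply(memberScores, 1, max) + 1e-12))
  # a single-member ensemble scores exactly like its member
  solo <- trainEcbsEnsemble(perScope["target"], cpds, kinds = "MACCS166",
                            numTrees = 150L, seed = 5L)
  expect_equal(scorePairs(solo, cpds, tab$compound_a, tab$compound_b),
               scorePairs(solo@members[[1]], cpds, tab$compound_a, tab$compound_b))
})

test_that("compound scoring takes the max over references and names the argmax", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  refs <- cpds[fix$actives[1:5]]
  queries <- cpds[c(fix$actives[6], "D_001")]
  sc <- compoundScore(fix$model, queries, refs)
  pairScores <- vapply(fix$actives[1:5], function(r)
    scorePairs(fix$model, cpds, rep(ids(queries)[1], 1), r), 0)
  expect_equal(sc$score[1], max(pairScores))
  expect_identical(sc$best_active_id[1], names(which.max(pairScores)))
  # single reference: the compound score is that pair's score
  solo <- compoundScore(fix$model, queries, cpds[fix$actives[1]])
  expect_equal(solo$score[1], unname(pairScores[1]))
  expect_error(compoundScore(fix$model, queries, cpds[character()]), "non-empty")
})

test_that("a query identical to a reference usually maxes out at that reference", {
  # forests see identical pairs (XOR all-zero) only rarely during training,
  # so the argmax property is probabilistic: it must hold in a majority of
  # replicate universes
  wins <- 0L
  for (i in 1:10) {
    uni <- generateUniverse(synthConfig(nTargets = 2, activesPerTarget = 6,
                                        nDecoys = 20, nNearMiss = 8,
                                        seed = 200L + i))
    tr <- universeTruth(uni)
    cpds <- universeCompounds(uni)
    acts <- tr$compound_id[tr$role == "active"]
    base <- baseTrainingPairs(uni, acts, seed = 300L + i)
    mod <- trainEcbsModel(base, cpds, kinds = "MACCS166", numTrees = 200L,
                          seed = 400L + i)
    refFp <- fingerprintBits(computeFingerprint(cpds, "MACCS166"))[acts[1], , drop = FALSE]
    twin <- abstractCompounds("Z_twin", list(MACCS166 = refFp))
    sc <- compoundScore(mod, twin, cpds[acts[1:5]])
    if (sc$best_active_id == acts[1]) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("retraining unions the pair sets and records the composition", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  truth <- universeTruth(fix$universe)
  inp <- pairingInput(pNew = fix$actives[1:2],
                      nNew = truth$compound_id[truth$role == "near_miss"][1:4],
                      pPrv = fix$actives[-(1:2)],
                      nPrv = truth$compound_id[truth$role == "decoy"])
  basePairs <- baseTrainingPairs(fix$universe, inp@pPrv, seed = 41L)
  newPairs <- makePairingData(inp, c("PP", "NP"))
  model <- retrainEcbsModel(basePairs, newPairs, cpds, kinds = "MACCS166",
                            numTrees = 150L, seed = 6L)
  expect_identical(model@trainingMeta$composition, "PP-NP")
  expect_identical(model@trainingMeta$nPositive + model@trainingMeta$nNegative,
                   nPairs(basePairs) + nPairs(newPairs))
  # an empty addition reproduces base training exactly
  none <- retrainEcbsModel(basePairs, makePairingData(pairingInput(), "PP"),
                           cpds, kinds = "MACCS166", numTrees = 150L, seed = 6L)
  plain <- trainEcbsModel(basePairs, cpds, kinds = "MACCS166",
                          numTrees = 150L, seed = 6L)
  probe <- pairTable(basePairs)[1:15, ]
  expect_identical(scorePairs(none, cpds, probe$compound_a, probe$compound_b),
                   scorePairs(plain, cpds, probe$compound_a, probe$compound_b))
  # duplicated pairs are dropped with a warning
  expect_warning(retrainEcbsModel(basePairs, basePairs, cpds, kinds = "MACCS166",
                                  numTrees = 50L, seed = 6L), "duplicate")
})

test_that("the single-compound baseline separates disjoint-bit toys perfectly", {
  acts <- bitCompounds(list(a1 = 1:20, a2 = 2:21, a3 = 3:22,
                            i1 = 100:120, i2 = 101:121, i3 = 102:122))
  bl <- trainSingleCompoundBaseline(acts, c("a1", "a2", "a3"),
                                    c("i1", "i2", "i3"), kinds = "MACCS166",
                                    numTrees = 100L, seed = 2L, minNodeSize = 1L)
  sc <- scoreCompounds(bl, acts, ids(acts))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(sc[1:3] > 0.5) && all(sc[4:6] < 0.5))
  expect_error(scorePairs(bl, acts, "a1", "a2"), "single")
  expect_error(trainSingleCompoundBaseline(acts, c("a1", "a2"), character()),
               "both active and inactive")
})

test_that("the pair model with NP pairs keeps up with the single-compound baseline", {
  # compound-level task: rank held-out actives above held-out near-misses
  # and decoys; the pair model retrained with NP pairs should match or beat
  # the standard model in a majority of replicates
  wins <- 0L
  nRep <- 10L
  for (i in seq_len(nRep)) {
    s <- 100L + i
    uni <- generateUniverse(synthConfig(nTargets = 2, activesPerTarget = 8,
                                        nDecoys = 40, nNearMiss = 16, seed = s))
    tr <- universeTruth(uni); cpds <- universeCompounds(uni)
    exp <- generateNewExperimentalData(uni, 3, 8, seed = s + 1L)
    inp <- exp$input
    acts <- tr$compound_id[tr$role == "active"]
    testActs <- c(setdiff(acts[grepl("T1", acts)], inp@pNew)[1:2],
                  setdiff(acts[grepl("T2", acts)], inp@pNew)[1:2])
    pPrv <- setdiff(inp@pPrv, testActs)
    decoys <- tr$compound_id[tr$role == "decoy"]
    testDec <- decoys[1:10]
    nPrv <- setdiff(decoys, testDec)
    testNm <- setdiff(tr$compound_id[tr$role == "near_miss"], inp@nNew)
    inp2 <- pairingInput(inp@pNew, inp@nNew, pPrv, nPrv)
    pairModel <- retrainEcbsModel(baseTrainingPairs(uni, pPrv, seed = s + 2L),
                                  makePairingData(inp2, "NP"), cpds,
                                  kinds = "MACCS166", numTrees = 300L, seed = s + 3L)
    testIds <- c(testActs, testNm, testDec)
    y <- as.integer(testIds %in% testActs)
    aPair <- aucpr(compoundScore(pairModel, cpds[testIds], cpds[pPrv])$score, y)$area
    bl <- trainSingleCompoundBaseline(cpds, c(pPrv, inp2@pNew), c(inp2@nNew, nPrv),
                                      kinds = "MACCS166", numTrees = 300L,
                                      seed = s + 3L)
    aBl <- aucpr(scoreCompounds(bl, cpds, testIds), y)$area
    if (aPair >= aBl) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("models round-trip through the persistence container", {
  fix <- tinyTrainedModel()
  cpds <- universeCompounds(fix$universe)
  path <- withr::local_tempfile(fileext = ".rds")
  saveEcbsModel(fix$model, path)
  back <- loadEcbsModel(path)
  probe <- pairTable(fix$pairs)[1:10, ]
  expect_identical(scorePairs(back, cpds, probe$compound_a, probe$compound_b),
                   scorePairs(fix$model, cpds, probe$compound_a, probe$compound_b))
  expect_identical(back@trainingMeta, fix$model@trainingMeta)
  # corrupted and foreign files are refused
  writeLines("not a model", path)
  expect_error(loadEcbsModel(path), "corrupted|not an ecbscreen model")
  saveRDS(list(format = "something-else"), path)
  expect_error(loadEcbsModel(path), "not an ecbscreen model")
})
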