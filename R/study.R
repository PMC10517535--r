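# study: reproducible simulation harnesses over the synthetic universe --
# the package's in-silico analogue of the iterative screening experiment.

#' Base training pairs for a universe
#'
#' The first-round training set: target-scope ERCP positives over the given
#' known actives (all unordered pairs of actives sharing a target) plus
#' randomly sampled active x decoy negative pairs at the standard 1:6
#' positive:negative ratio.
#'
#' @param universe a [SyntheticUniverse-class].
#' @param activeIds the actives available for training (e.g. everything but
#'   a held-out set).
#' @param negPerPos negatives per positive (default 6).
#' @param seed integer seed for the negative draw.
#' @return a [ChemicalPairs-class].
#' @export
baseTrainingPairs <- function(universe, activeIds, negPerPos = 6, seed = 1L) {
  stopifnot(is(universe, "SyntheticUniverse"))
  inter <- universe@interactions
  inter <- inter[inter$compound_id %in% activeIds, , drop = FALSE]
  truth <- universe@truth
  posSets <- lapply(unique(inter$target_id), function(t)
    buildErcps(inter, universe@families, t, scope = "target"))
  pos <- do.call(combinePairs, c(posSets, list(warnDuplicates = FALSE)))
  if (!nPairs(pos)) stop("no positive pairs; need at least two actives on one target")
  neg <- sampleNegativePairs(unique(inter$compound_id),
                             truth$compound_id[truth$role == "decoy"],
                             nPairs(pos), negPerPos = negPerPos, seed = seed)
  combinePairs(pos, neg, warnDuplicates = FALSE)
}

#' Retraining-improvement study over replicate universes
#'
#' For each replicate: generate a universe, simulate one round of
#' experimental validation ([generateNewExperimentalData()]), build the base
#' training data, and cross-validate the requested pairing-scheme
#' combinations with a common test set. Near-miss inactives make the base
#' model produce false positives, so combinations containing NP pairs are
#' expected to recover held-out AUCPR.
#'
#' @param nSeeds number of replicate universes.
#' @param seed master seed; every replicate derives its own seeds from it.
#' @param schemeCombos combinations passed to [crossValidateSchemes()].
#' @param config universe configuration template (its seed is replaced per
#'   replicate).
#' @param nTruePos,nFalsePos sizes of the simulated experimental round.
#' @param k,kinds,numTrees forwarded to [crossValidateSchemes()].
#' @return data.frame `replicate`, `scheme_combo`, `mean_aucpr`.
#' @export
simulateRetrainingStudy <- function(nSeeds = 10L, seed = 1L,
                                    schemeCombos = c("None", "NP", "PP-NP"),
                                    config = synthConfig(),
                                    nTruePos = 4L, nFalsePos = 19L,
                                    k = 7L, kinds = "MACCS166",
                                    numTrees = 500L) {
  rows <- list()
  for (i in seq_len(nSeeds)) {
    s <- deriveSeed(seed, i)
    cfg <- config
    cfg$seed <- s
    uni <- generateUniverse(cfg)
    exp <- generateNewExperimentalData(uni, nTruePos = nTruePos,
                                       nFalsePos = nFalsePos,
                                       seed = deriveSeed(s, 1L))
    base <- baseTrainingPairs(uni, exp$input@pPrv, seed = deriveSeed(s, 2L))
    cv <- crossValidateSchemes(base, exp$input, universeCompounds(uni),
                               schemeCombos = schemeCombos, k = k,
                               seed = deriveSeed(s, 3L), kinds = kinds,
                               numTrees = numTrees)
    rows[[i]] <- cbind(replicate = i, cv$summary[, c("scheme_combo", "mean_aucpr")])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screening-enrichment study over replicate universes
#'
#' For each replicate: hold a sample of actives out of training, plant them
#' in a fresh decoy library, train the base model on the remaining actives,
#' and compare the mean max-aggregated compound score of planted actives
#' against the background.
#'
#' @param nSeeds number of replicates.
#' @param seed master seed.
#' @param config universe configuration template.
#' @param nBackground,nPlanted library composition (default a
#'   2,000-compound library with 10 planted actives).
#' @param scoreCutoff the selection cutoff whose hit count is reported.
#' @param kinds,numTrees forwarded to [trainEcbsModel()].
#' @return data.frame `replicate`, `mean_planted`, `mean_background`,
#'   `n_hits`, `n_planted_hits`.
#' @export
simulateScreeningStudy <- function(nSeeds = 10L, seed = 1L,
                                   config = synthConfig(),
                                   nBackground = 1990L, nPlanted = 10L,
                                   scoreCutoff = 0.8, kinds = "MACCS166",
                                   numTrees = 500L) {
  rows <- list()
  for (i in seq_len(nSeeds)) {
    s <- deriveSeed(seed, 1000L + i)
    cfg <- config
    cfg$seed <- s
    uni <- generateUniverse(cfg)
    lib <- generateScreeningLibrary(uni, nBackground = nBackground,
                                    nPlantedHits = nPlanted,
                                    seed = deriveSeed(s, 1L))
    truth <- universeTruth(uni)
    trainActives <- setdiff(truth$compound_id[truth$role == "active"], lib$planted)
    base <- baseTrainingPairs(uni, trainActives, seed = deriveSeed(s, 2L))
    model <- trainEcbsModel(base, universeCompounds(uni), kinds = kinds,
                            numTrees = numTrees, seed = deriveSeed(s, 3L))
    sc <- compoundScore(model, lib$library, universeCompounds(uni)[trainActives])
    planted <- sc$compound_id %in% lib$planted
    rows[[i]] <- data.frame(
      replicate = i,
      mean_planted = mean(sc$score[planted]),
      mean_background = mean(sc$score[!planted]),
      n_hits = sum(sc$score >= scoreCutoff),
      n_planted_hits = sum(sc$score[planted] >= scoreCutoff))
  }
  do.call(rbind, rows)
}
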