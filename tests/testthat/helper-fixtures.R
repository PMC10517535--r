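# Shared fixtures built in code. The "tiny universe" keeps model-level tests
# fast; heavier study-scale runs live only in the acceptance tests.

tinyConfig <- function(seed = 1L) {
  synthConfig(nTargets = 2L, activesPerTarget = 6L, nDecoys = 20L,
              nNearMiss = 8L, seed = seed)
}

# Abstract compound set with hand-chosen MACCS bit rows, for tests that need
# exact Tanimoto values.
bitCompounds <- function(rows) {
  len <- fingerprintLength("MACCS166")
  m <- matrix(0L, nrow = length(rows), ncol = len)
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  abstractCompounds(names(rows), list(MACCS166 = m))
}

# A small trained pair model over a tiny universe, cached per test run.
.tinyModelCache <- new.env(parent = emptyenv())
tinyTrainedModel <- function(seed = 7L) {
  key <- as.character(seed)
  if (!is.null(.tinyModelCache[[key]])) return(.tinyModelCache[[key]])
  uni <- generateUniverse(tinyConfig(seed))
  truth <- universeTruth(uni)
  actives <- truth$compound_id[truth$role == "active"]
  base <- baseTrainingPairs(uni, actives, seed = seed + 1L)
  model <- trainEcbsModel(base, universeCompounds(uni), kinds = "MACCS166",
                          numTrees = 200L, seed = seed + 2L)
  res <- list(universe = uni, pairs = base, model = model, actives = actives)
  .tinyModelCache[[key]] <- res
  res
}
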