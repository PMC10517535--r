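# evaluate: compound-level k-fold cross-validation with a common pair test
# set, precision-recall curves and AUCPR per pairing-scheme combination.

#' Split compounds into k balanced folds
#'
#' Random partition at the *compound* level (not the pair level), so that no
#' chemical information about a test compound can leak into training through
#' pairs. Fold sizes differ by at most one; the assignment is reproducible
#' from the seed.
#'
#' @param compoundIds character vector of compound ids.
#' @param k number of folds (default 7).
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @export
splitCompoundsKfold <- function(compoundIds, k = 7L, seed = 1L) {
  compoundIds <- unique(as.character(compoundIds))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  if (k > length(compoundIds)) {
    stop("k = ", k, " exceeds the number of compounds (", length(compoundIds), ")")
  }
  shuffled <- withSeed(seed, sample(compoundIds))
  assignments <- setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  new("FoldPlan", k = k, assignments = assignments, seed = as.integer(seed))
}

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d compounds in %d folds (seed %d)\n",
              length(object@assignments), object@k, object@seed))
})

#' Fold membership accessor
#'
#' @param plan a [FoldPlan-class].
#' @param fold fold index in `1..k`.
#' @return character ids assigned to that fold.
#' @export
foldMembers <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"))
  names(plan@assignments)[plan@assignments == fold]
}

#' Split a pair list into a common test set and the remaining training pairs
#'
#' Every pair containing at least one test compound goes to the test side;
#' the rest stay available for training. Reusing one such test set across
#' all pairing-scheme combinations keeps their AUCPR values comparable (the
#' positive/negative balance of the test set is identical for every model).
#'
#' @param pairs a [ChemicalPairs-class].
#' @param testCompounds character vector of test compound ids (may be
#'   empty, giving an empty test side).
#' @return list with [ChemicalPairs-class] elements `test` and `train`.
#' @export
buildCommonTestSet <- function(pairs, testCompounds) {
  stopifnot(is(pairs, "ChemicalPairs"))
  p <- pairTable(pairs)
  inTest <- p$compound_a %in% testCompounds | p$compound_b %in% testCompounds
  list(test = new("ChemicalPairs", pairs = p[inTest, , drop = FALSE]),
       train = new("ChemicalPairs", pairs = p[!inTest, , drop = FALSE]))
}

#' Area under the precision-recall curve (step-wise average precision)
#'
#' The curve is traversed in descending score order with tied scores grouped
#' at a single threshold (forest probabilities produce ties); the area is
#' the non-interpolated sum of precision times recall increment at each
#' threshold. This estimator never credits the optimistic linear
#' interpolation between PR points.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) true labels; both classes must be present.
#' @return list with `area` (numeric in `[0, 1]`) and `curve` (data.frame
#'   `threshold`, `precision`, `recall`).
#' @examples
#' aucpr(c(0.9, 0.8, 0.3), c(1, 0, 1))$area  # 0.8333...
#' @export
aucpr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels must align")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  P <- sum(labels == 1L)
  if (P == 0L || P == length(labels)) {
    stop("labels must contain at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: last index of each distinct threshold
  lastOfGroup <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[lastOfGroup]
  n <- lastOfGroup
  precision <- tp / n
  recall <- tp / P
  area <- sum(diff(c(0, recall)) * precision)
  list(area = area,
       curve = data.frame(threshold = s[lastOfGroup],
                          precision = precision, recall = recall))
}

#' Cross-validate pairing-scheme combinations with a common test set
#'
#' For each fold of a compound-level [FoldPlan-class]:
#' the common test set is every pair (base or scheme-derived) touching a
#' test compound; then, for each requested combination, a model is retrained
#' on the base training pairs plus that combination's scheme pairs --
#' excluding any pair that touches a test compound -- and scored on the
#' common test set. A leakage guard asserts that no training pair ever
#' contains a test compound.
#'
#' @param basePairs base training data ([ChemicalPairs-class]; ERCP
#'   positives plus random negatives).
#' @param input a [PairingInput-class] supplying the retraining sets.
#' @param compounds a [CompoundSet-class].
#' @param schemeCombos character vector of combinations: `"None"` or
#'   `"-"`-joined subsets of PP/NP/NN/PN, e.g.
#'   `c("None", "PP", "NP", "NN", "PP-NP", "NP-NN", "PP-NN", "PP-NP-NN")`.
#' @param k,seed fold count and seed for [splitCompoundsKfold()]; the model
#'   seed for a fold is shared across combinations so they stay comparable.
#' @param kinds,numTrees forwarded to [trainEcbsModel()].
#' @return list of class `ecbs_cv` with `summary` (data.frame
#'   `scheme_combo`, `mean_aucpr`, `n_folds`) and `perFold` (data.frame
#'   `scheme_combo`, `fold`, `aucpr`, `pos_count`, `neg_count`).
#' @export
crossValidateSchemes <- function(basePairs, input, compounds,
                                 schemeCombos = c("None", "PP", "NP", "NN",
                                                  "PP-NP", "NP-NN", "PP-NN",
                                                  "PP-NP-NN"),
                                 k = 7L, seed = 1L,
                                 kinds = c("MACCS166", "SUBSTRUCT_FP4"),
                                 numTrees = 500L) {
  stopifnot(is(basePairs, "ChemicalPairs"), is(input, "PairingInput"))
  comboSchemes <- lapply(schemeCombos, function(cmb) {
    if (identical(cmb, "None")) return(character())
    parts <- strsplit(cmb, "-", fixed = TRUE)[[1]]
    bad <- setdiff(parts, c("PP", "NP", "NN", "PN"))
    if (length(bad)) stop("unknown scheme(s) in combo '", cmb, "': ",
                          paste(bad, collapse = ", "))
    parts
  })
  names(comboSchemes) <- schemeCombos
  usedSchemes <- unique(unlist(comboSchemes))
  schemePairs <- if (length(usedSchemes)) makePairingData(input, usedSchemes) else .emptyPairs()
  pool <- combinePairs(basePairs, schemePairs, warnDuplicates = FALSE)
  poolTab <- pairTable(pool)
  baseSchemes <- c("ERCP_TARGET", "ERCP_FAMILY", "RAND_NEG")
  cpdIds <- sort(unique(c(poolTab$compound_a, poolTab$compound_b)))
  plan <- splitCompoundsKfold(cpdIds, k = k, seed = seed)
  perFold <- list()
  for (f in seq_len(plan@k)) {
    testIds <- foldMembers(plan, f)
    split <- buildCommonTestSet(pool, testIds)
    testTab <- pairTable(split$test)
    if (length(unique(testTab$label)) < 2L) {
      warning("fold ", f, " has a single-class common test set; skipped")
      next
    }
    trainTab <- pairTable(split$train)
    # leakage guard: the training side must never touch a test compound
    stopifnot(!any(trainTab$compound_a %in% testIds),
              !any(trainTab$compound_b %in% testIds))
    foldSeed <- deriveSeed(seed, f)
    for (cmb in schemeCombos) {
      keep <- trainTab$scheme %in% c(baseSchemes, comboSchemes[[cmb]])
      trainPairs <- new("ChemicalPairs", pairs = trainTab[keep, , drop = FALSE])
      model <- trainEcbsModel(trainPairs, compounds, kinds = kinds,
                              numTrees = numTrees, seed = foldSeed)
      sc <- scorePairs(model, compounds, testTab$compound_a, testTab$compound_b)
      res <- aucpr(sc, testTab$label == "positive")
      perFold[[length(perFold) + 1L]] <- data.frame(
        scheme_combo = cmb, fold = f, aucpr = res$area,
        pos_count = sum(testTab$label == "positive"),
        neg_count = sum(testTab$label == "negative"),
        stringsAsFactors = FALSE)
    }
  }
  perFold <- do.call(rbind, perFold)
  summary <- do.call(rbind, lapply(schemeCombos, function(cmb) {
    sub <- perFold[perFold$scheme_combo == cmb, , drop = FALSE]
    data.frame(scheme_combo = cmb, mean_aucpr = mean(sub$aucpr),
               n_folds = nrow(sub), stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, perFold = perFold, k = plan@k,
                 seed = as.integer(seed)),
            class = "ecbs_cv")
}

#' @export
print.ecbs_cv <- function(x, ...) {
  cat(sprintf("Pairing-scheme cross-validation (%d folds, seed %d)\n", x$k, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report
#'
#' @param cv result of [crossValidateSchemes()].
#' @param path base path: `<path>.csv` receives the summary,
#'   `<path>.json` the per-fold detail.
#' @return invisibly, the two paths.
#' @export
writeEvaluationReport <- function(cv, path) {
  stopifnot(inherits(cv, "ecbs_cv"))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(cv$summary, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(k = cv$k, seed = cv$seed, summary = cv$summary,
                            per_fold = cv$perFold),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
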