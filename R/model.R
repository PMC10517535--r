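# model: symmetric pair featurization, random-forest pair classifiers, the
# per-scope ensemble, compound-level max-score aggregation, and retraining.

#' Featurize compound pairs symmetrically
#'
#' For every fingerprint kind, the feature vector concatenates the bitwise
#' AND of the two fingerprints (shared substructure) followed by their
#' bitwise XOR (differences). Both operators are symmetric, so
#' `featurizePair(a, b)` and `featurizePair(b, a)` are identical element-wise
#' and the learned pair score cannot depend on argument order. Kinds are
#' concatenated in the order given; the total length is twice the summed
#' fingerprint lengths.
#'
#' @param fpA,fpB named lists mapping fingerprint kind to a
#'   [FingerprintSet-class]; row `i` of every member is compound `i` of the
#'   pair list (single-row sets are recycled).
#' @param kinds the kinds to use, in feature order; defaults to the kinds
#'   present in `fpA`.
#' @return numeric feature matrix, one row per pair, with named columns
#'   `<kind>_and_<i>` / `<kind>_xor_<i>`.
#' @export
featurizePair <- function(fpA, fpB, kinds = names(fpA)) {
  if (is.null(kinds) || !length(kinds)) stop("no fingerprint kinds given")
  segs <- lapply(kinds, function(kind) {
    if (is.null(fpA[[kind]]) || is.null(fpB[[kind]])) {
      stop("missing fingerprint kind '", kind, "' for pair featurization")
    }
    A <- fingerprintBits(fpA[[kind]])
    B <- fingerprintBits(fpB[[kind]])
    if (nrow(A) != nrow(B)) {
      if (nrow(A) == 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
      else if (nrow(B) == 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
      else stop("fingerprint sets must align")
    }
    andSeg <- A * B
    xorSeg <- (A + B == 1L) * 1L
    colnames(andSeg) <- sprintf("%s_and_%d", kind, seq_len(ncol(A)))
    colnames(xorSeg) <- sprintf("%s_xor_%d", kind, seq_len(ncol(A)))
    cbind(andSeg, xorSeg)
  })
  do.call(cbind, segs)
}

# Feature matrix for id-addressed pairs drawn from one or two compound sets.
.pairFeaturesByIds <- function(cpdsA, aIds, cpdsB, bIds, kinds) {
  fpA <- fpB <- list()
  for (kind in kinds) {
    FA <- computeFingerprint(cpdsA, kind)
    FB <- if (identical(cpdsA, cpdsB)) FA else computeFingerprint(cpdsB, kind)
    ia <- match(aIds, ids(FA)); ib <- match(bIds, ids(FB))
    if (anyNA(ia)) stop("unresolvable compound id(s): ",
                        paste(head(aIds[is.na(ia)], 5), collapse = ", "))
    if (anyNA(ib)) stop("unresolvable compound id(s): ",
                        paste(head(bIds[is.na(ib)], 5), collapse = ", "))
    fpA[[kind]] <- fingerprintSet(kind, fingerprintBits(FA)[ia, , drop = FALSE])
    fpB[[kind]] <- fingerprintSet(kind, fingerprintBits(FB)[ib, , drop = FALSE])
  }
  featurizePair(fpA, fpB, kinds)
}

.schemeCounts <- function(pairs) {
  tab <- table(pairTable(pairs)$scheme)
  setNames(as.integer(tab), names(tab))
}

#' Train a pair-classification model for one evolutionary scope
#'
#' Fits a `ranger` probability forest with its default parameters (500 trees,
#' sqrt-of-features variables per split) on symmetric pair features; the seed
#' fixes both the forest and therefore all downstream predictions. Training
#' metadata records per-scheme pair counts, class balance and forest
#' parameters.
#'
#' @param pairs a [ChemicalPairs-class] containing both labels.
#' @param compounds a [CompoundSet-class] resolving every paired id.
#' @param scope scope label stored on the model (`"target"` or
#'   `"family:<db>"`).
#' @param kinds fingerprint kinds used for featurization; the default
#'   MACCS + FP4 combination matches the screening configuration.
#' @param numTrees,mtry forest size and variables per split (`NULL` mtry =
#'   ranger's sqrt default).
#' @param minNodeSize minimal node size (`NULL` = ranger's default; set to 1
#'   for very small training sets).
#' @param seed integer seed.
#' @return an [EcbsModel-class].
#' @export
trainEcbsModel <- function(pairs, compounds, scope = "target",
                           kinds = c("MACCS166", "SUBSTRUCT_FP4"),
                           numTrees = 500L, mtry = NULL, seed = 1L,
                           minNodeSize = NULL) {
  stopifnot(is(pairs, "ChemicalPairs"), is(compounds, "CompoundSet"))
  p <- pairTable(pairs)
  if (!nrow(p)) stop("cannot train on an empty pair set")
  if (length(unique(p$label)) < 2L) {
    stop("training pairs must contain both positive and negative labels")
  }
  X <- .pairFeaturesByIds(compounds, p$compound_a, compounds, p$compound_b, kinds)
  y <- factor(p$label, levels = c("negative", "positive"))
  dat <- data.frame(.label = y, X, check.names = FALSE)
  forest <- ranger::ranger(dependent.variable.name = ".label", data = dat,
                           num.trees = numTrees, mtry = mtry,
                           min.node.size = minNodeSize,
                           probability = TRUE, seed = as.integer(seed),
                           num.threads = 1)
  new("EcbsModel", scope = scope, forest = forest,
      featureSpec = list(kinds = kinds,
                         lengths = vapply(kinds, fingerprintLength, 1L),
                         pairwise = TRUE, featureNames = colnames(X)),
      trainingMeta = list(schemeCounts = .schemeCounts(pairs),
                          nPositive = sum(p$label == "positive"),
                          nNegative = sum(p$label == "negative"),
                          numTrees = as.integer(numTrees),
                          mtry = if (is.null(mtry)) NA_integer_ else as.integer(mtry),
                          seed = as.integer(seed),
                          composition = "base"))
}

setMethod("show", "EcbsModel", function(object) {
  m <- object@trainingMeta
  cat(sprintf("EcbsModel [%s] %s: %d trees on %d pairs (%d+/%d-), kinds: %s\n",
              object@scope, m$composition %||% "base", m$numTrees,
              m$nPositive + m$nNegative, m$nPositive, m$nNegative,
              paste(object@featureSpec$kinds, collapse = "+")))
})

setMethod("show", "EcbsEnsemble", function(object) {
  cat(sprintf("EcbsEnsemble of %d member(s), combine = %s\n",
              length(object@members), object@combine))
  for (m in object@members) show(m)
})

#' Train an ensemble of per-scope models
#'
#' One [EcbsModel-class] per evolutionary scope (e.g. the target scope plus
#' one family scope per protein-family database); ensemble predictions are
#' the unweighted mean of member predictions.
#'
#' @param perScopePairs named list mapping scope label to its
#'   [ChemicalPairs-class] training set.
#' @param compounds a [CompoundSet-class].
#' @param kinds,numTrees,mtry,seed passed to [trainEcbsModel()].
#' @return an [EcbsEnsemble-class].
#' @export
trainEcbsEnsemble <- function(perScopePairs, compounds,
                              kinds = c("MACCS166", "SUBSTRUCT_FP4"),
                              numTrees = 500L, mtry = NULL, seed = 1L) {
  if (!length(perScopePairs) || is.null(names(perScopePairs))) {
    stop("`perScopePairs` must be a non-empty named list (scope -> pairs)")
  }
  members <- lapply(names(perScopePairs), function(scope) {
    tryCatch(
      trainEcbsModel(perScopePairs[[scope]], compounds, scope = scope,
                     kinds = kinds, numTrees = numTrees, mtry = mtry, seed = seed),
      error = function(e) stop("scope '", scope, "': ", conditionMessage(e),
                               call. = FALSE))
  })
  new("EcbsEnsemble", members = members, combine = "mean")
}

.predictFeatures <- function(model, X) {
  if (is(model, "EcbsEnsemble")) {
    preds <- vapply(model@members, function(m) .predictFeatures(m, X),
                    numeric(nrow(X)))
    if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
    return(rowMeans(preds))
  }
  if (!is(model, "EcbsModel") || is.null(model@forest)) stop("model is not trained")
  pr <- stats::predict(model@forest, data = as.data.frame(X, check.names = FALSE),
                       num.threads = 1)$predictions
  unname(pr[, "positive"])
}

.modelKinds <- function(model) {
  if (is(model, "EcbsEnsemble")) model@members[[1]]@featureSpec$kinds
  else model@featureSpec$kinds
}

.assertPairwise <- function(model) {
  spec <- if (is(model, "EcbsEnsemble")) model@members[[1]]@featureSpec else model@featureSpec
  if (!isTRUE(spec$pairwise)) {
    stop("model was trained on single compounds; use scoreCompounds()")
  }
}

#' Score compound pairs
#'
#' Positive-class probability of the pair classifier (mean over members for
#' an ensemble). Symmetric in the two compounds by construction of the
#' features.
#'
#' @param model an [EcbsModel-class] or [EcbsEnsemble-class].
#' @param compounds a [CompoundSet-class] resolving the paired ids.
#' @param a,b compound id vectors (element-wise pairs).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
scorePairs <- function(model, compounds, a, b) {
  .assertPairwise(model)
  X <- .pairFeaturesByIds(compounds, as.character(a), compounds,
                          as.character(b), .modelKinds(model))
  .predictFeatures(model, X)
}

#' Score library compounds against reference actives (max aggregation)
#'
#' Each query is paired with every reference active; the compound score is
#' the highest pair score, and the reference achieving it is reported (ties
#' broken by lexicographic reference id).
#'
#' @param model an [EcbsModel-class] or [EcbsEnsemble-class].
#' @param queries [CompoundSet-class] of library compounds.
#' @param references non-empty [CompoundSet-class] of reference actives.
#' @return data.frame with columns `compound_id`, `score`,
#'   `best_active_id`, in query order.
#' @export
compoundScore <- function(model, queries, references) {
  .assertPairwise(model)
  stopifnot(is(queries, "CompoundSet"), is(references, "CompoundSet"))
  if (!length(references)) stop("`references` must be non-empty")
  if (!length(queries)) {
    return(data.frame(compound_id = character(), score = numeric(),
                      best_active_id = character(), stringsAsFactors = FALSE))
  }
  qIds <- ids(queries); rIds <- ids(references)
  # order references lexicographically so that which.max's first-hit rule
  # implements the documented tie-break
  rOrd <- order(rIds)
  rIds <- rIds[rOrd]
  grid <- expand.grid(q = seq_along(qIds), r = seq_along(rIds))
  X <- .pairFeaturesByIds(queries, qIds[grid$q], references, rIds[grid$r],
                          .modelKinds(model))
  sc <- matrix(.predictFeatures(model, X), nrow = length(qIds))
  best <- apply(sc, 1, which.max)
  data.frame(compound_id = qIds, score = apply(sc, 1, max),
             best_active_id = rIds[best], stringsAsFactors = FALSE)
}

#' Retrain a model with new pair data
#'
#' Full refit on the union of the base and new pairs (forests are cheap at
#' this scale and refitting keeps the model a pure function of its training
#' set). Duplicate pairs after canonicalization are dropped with a warning.
#' The metadata records the scheme composition of the added data, e.g.
#' `"PP-NP"`.
#'
#' @param basePairs,newPairs [ChemicalPairs-class] objects.
#' @param compounds a [CompoundSet-class].
#' @param scope,kinds,numTrees,mtry,seed as in [trainEcbsModel()].
#' @return an [EcbsModel-class].
#' @export
retrainEcbsModel <- function(basePairs, newPairs, compounds, scope = "target",
                             kinds = c("MACCS166", "SUBSTRUCT_FP4"),
                             numTrees = 500L, mtry = NULL, seed = 1L) {
  combined <- combinePairs(basePairs, newPairs, warnDuplicates = TRUE)
  model <- trainEcbsModel(combined, compounds, scope = scope, kinds = kinds,
                          numTrees = numTrees, mtry = mtry, seed = seed)
  newSchemes <- unique(pairTable(newPairs)$scheme)
  ordered <- intersect(c("PP", "NP", "NN", "PN"), newSchemes)
  model@trainingMeta$composition <-
    if (length(ordered)) paste(ordered, collapse = "-") else "base"
  model
}

#' Single-compound baseline classifier
#'
#' The standard (non-pair) model used only for benchmarking: a probability
#' forest on individual compound fingerprints, actives vs inactives.
#'
#' @param compounds a [CompoundSet-class].
#' @param activeIds,inactiveIds compound id vectors (both non-empty).
#' @param kinds,numTrees,mtry,seed as in [trainEcbsModel()].
#' @return an [EcbsModel-class] with scope `"single"`.
#' @export
trainSingleCompoundBaseline <- function(compounds, activeIds, inactiveIds,
                                        kinds = c("MACCS166", "SUBSTRUCT_FP4"),
                                        numTrees = 500L, mtry = NULL, seed = 1L,
                                        minNodeSize = NULL) {
  if (!length(activeIds) || !length(inactiveIds)) {
    stop("baseline needs both active and inactive compounds")
  }
  allIds <- c(as.character(activeIds), as.character(inactiveIds))
  segs <- lapply(kinds, function(kind) {
    F <- computeFingerprint(compounds, kind)
    idx <- match(allIds, ids(F))
    if (anyNA(idx)) stop("unresolvable compound id(s): ",
                         paste(head(allIds[is.na(idx)], 5), collapse = ", "))
    m <- fingerprintBits(F)[idx, , drop = FALSE]
    colnames(m) <- sprintf("%s_%d", kind, seq_len(ncol(m)))
    m
  })
  X <- do.call(cbind, segs)
  y <- factor(rep(c("positive", "negative"), c(length(activeIds), length(inactiveIds))),
              levels = c("negative", "positive"))
  dat <- data.frame(.label = y, X, check.names = FALSE)
  forest <- ranger::ranger(dependent.variable.name = ".label", data = dat,
                           num.trees = numTrees, mtry = mtry,
                           min.node.size = minNodeSize, probability = TRUE,
                           seed = as.integer(seed), num.threads = 1)
  new("EcbsModel", scope = "single", forest = forest,
      featureSpec = list(kinds = kinds,
                         lengths = vapply(kinds, fingerprintLength, 1L),
                         pairwise = FALSE, featureNames = colnames(X)),
      trainingMeta = list(schemeCounts = integer(),
                          nPositive = length(activeIds),
                          nNegative = length(inactiveIds),
                          numTrees = as.integer(numTrees),
                          mtry = if (is.null(mtry)) NA_integer_ else as.integer(mtry),
                          seed = as.integer(seed),
                          composition = "single"))
}

#' Score individual compounds with the single-compound baseline
#'
#' @param model baseline [EcbsModel-class] from
#'   [trainSingleCompoundBaseline()].
#' @param compounds a [CompoundSet-class].
#' @param queryIds ids to score.
#' @return numeric probabilities in `[0, 1]`.
#' @export
scoreCompounds <- function(model, compounds, queryIds) {
  stopifnot(is(model, "EcbsModel"))
  if (isTRUE(model@featureSpec$pairwise)) {
    stop("model is a pair model; use scorePairs() or compoundScore()")
  }
  queryIds <- as.character(queryIds)
  segs <- lapply(model@featureSpec$kinds, function(kind) {
    F <- computeFingerprint(compounds, kind)
    idx <- match(queryIds, ids(F))
    if (anyNA(idx)) stop("unresolvable compound id(s): ",
                         paste(head(queryIds[is.na(idx)], 5), collapse = ", "))
    m <- fingerprintBits(F)[idx, , drop = FALSE]
    colnames(m) <- sprintf("%s_%d", kind, seq_len(ncol(m)))
    m
  })
  .predictFeatures(model, do.call(cbind, segs))
}

.MODEL_FORMAT_VERSION <- 1L

#' Persist / load a trained model
#'
#' The container records a format version, the feature specification and all
#' training metadata; a round-trip preserves predictions bit-identically.
#' Corrupted or incompatible files raise a structured error.
#'
#' @param model an [EcbsModel-class] or [EcbsEnsemble-class].
#' @param path file path.
#' @return `saveEcbsModel` the path, invisibly; `loadEcbsModel` the model.
#' @export
saveEcbsModel <- function(model, path) {
  stopifnot(is(model, "EcbsModel") || is(model, "EcbsEnsemble"))
  saveRDS(list(format = "ecbscreen-model", version = .MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname saveEcbsModel
#' @export
loadEcbsModel <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted model file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "ecbscreen-model")) {
    stop("not an ecbscreen model file: ", path)
  }
  if (!identical(obj$version, .MODEL_FORMAT_VERSION)) {
    stop("model format version ", obj$version, " is not supported (expected ",
         .MODEL_FORMAT_VERSION, ")")
  }
  validObject(obj$model)
  obj$model
}
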