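#' @import methods
NULL

.PAIR_SCHEMES <- c("ERCP_TARGET", "ERCP_FAMILY", "RAND_NEG", "PP", "NP", "NN", "PN")
.POSITIVE_SCHEMES <- c("ERCP_TARGET", "ERCP_FAMILY", "PP")

#' CompoundSet: identified chemical structures with cached fingerprints
#'
#' A `CompoundSet` holds compound identifiers, canonical SMILES (which may be
#' `NA` for abstract, fingerprint-only compounds produced by the synthetic
#' generator's bit-vector mode), and a lazy cache of binary fingerprints.
#' Fingerprints are computed on demand by [computeFingerprint()] and reused
#' afterwards; a cached fingerprint matrix is never recomputed or mutated.
#'
#' @slot ids character vector of unique, non-empty compound identifiers.
#' @slot smiles character vector of canonical SMILES, `NA` for abstract
#'   compounds that carry pre-computed fingerprints instead of a structure.
#' @slot fpCache environment mapping fingerprint kind to a 0/1 integer matrix
#'   with one row per compound.
#' @aliases CompoundSet
#' @seealso [parseCompounds()], [readCompoundTable()], [computeFingerprint()]
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(ids = "character", smiles = "character", fpCache = "environment"))

# Each instance needs its own cache environment; the S4 prototype environment
# would otherwise be shared by every CompoundSet ever created.
setMethod("initialize", "CompoundSet", function(.Object, ..., fpCache) {
  if (missing(fpCache)) fpCache <- new.env(parent = emptyenv())
  callNextMethod(.Object, ..., fpCache = fpCache)
})

setValidity("CompoundSet", function(object) {
  msgs <- character()
  if (length(object@ids) != length(object@smiles)) {
    msgs <- c(msgs, "ids and smiles must have equal length")
  }
  if (anyNA(object@ids) || any(!nzchar(object@ids))) {
    msgs <- c(msgs, "compound ids must be non-empty")
  }
  if (anyDuplicated(object@ids)) {
    dup <- unique(object@ids[duplicated(object@ids)])
    msgs <- c(msgs, paste0("duplicate compound ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(grepl("[[:space:]]", object@ids))) {
    msgs <- c(msgs, "compound ids must not contain whitespace")
  }
  for (kind in ls(object@fpCache)) {
    m <- get(kind, envir = object@fpCache)
    if (!is.matrix(m) || nrow(m) != length(object@ids)) {
      msgs <- c(msgs, sprintf("cached fingerprint '%s' does not match compound count", kind))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FingerprintSet: fixed-length binary fingerprints of one kind
#'
#' @slot kind one of the kinds listed by [fingerprintKinds()].
#' @slot bits 0/1 integer matrix, one row per compound (rownames are compound
#'   ids), with exactly [fingerprintLength()] columns. Immutable by
#'   convention: accessors copy, nothing writes back.
#' @aliases FingerprintSet
#' @exportClass FingerprintSet
setClass("FingerprintSet", representation(kind = "character", bits = "matrix"))

setValidity("FingerprintSet", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !(object@kind %in% fingerprintKinds())) {
    msgs <- c(msgs, paste0("kind must be one of: ", paste(fingerprintKinds(), collapse = ", ")))
  } else if (ncol(object@bits) != fingerprintLength(object@kind)) {
    msgs <- c(msgs, sprintf("bit matrix has %d columns; kind %s requires %d",
                            ncol(object@bits), object@kind, fingerprintLength(object@kind)))
  }
  if (is.null(rownames(object@bits))) msgs <- c(msgs, "bit matrix must have compound-id rownames")
  if (!all(object@bits %in% c(0L, 1L))) msgs <- c(msgs, "bits must be 0/1")
  if (length(msgs)) msgs else TRUE
})

#' ChemicalPairs: labeled, canonically ordered compound pairs
#'
#' Each row is an unordered pair of distinct compounds stored with
#' `compound_a < compound_b` (lexicographic), a binary label, and the
#' provenance scheme that generated the pair. The label is tied to the scheme:
#' pairs from `ERCP_TARGET`, `ERCP_FAMILY` or `PP` are positive, all other
#' schemes (`RAND_NEG`, `NP`, `NN`, `PN`) are negative.
#'
#' @slot pairs data.frame with columns `compound_a`, `compound_b`, `label`,
#'   `scheme`.
#' @aliases ChemicalPairs
#' @seealso [chemicalPairs()], [buildErcps()], [makePairingData()]
#' @exportClass ChemicalPairs
setClass("ChemicalPairs", representation(pairs = "data.frame"))

setValidity("ChemicalPairs", function(object) {
  p <- object@pairs
  msgs <- character()
  need <- c("compound_a", "compound_b", "label", "scheme")
  if (!all(need %in% names(p))) {
    return(paste0("pair table must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(p)) {
    if (any(p$compound_a >= p$compound_b)) {
      msgs <- c(msgs, "pairs must satisfy compound_a < compound_b (no self-pairs)")
    }
    if (anyDuplicated(paste(p$compound_a, p$compound_b))) {
      msgs <- c(msgs, "duplicate pairs are not allowed within one pair set")
    }
    if (!all(p$scheme %in% .PAIR_SCHEMES)) {
      msgs <- c(msgs, paste0("scheme must be one of: ", paste(.PAIR_SCHEMES, collapse = ", ")))
    }
    okLabel <- ifelse(p$scheme %in% .POSITIVE_SCHEMES, "positive", "negative")
    if (!all(p$label == okLabel)) {
      msgs <- c(msgs, "label must be positive iff scheme is ERCP_TARGET, ERCP_FAMILY or PP")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PairingInput: the four compound sets that drive retraining
#'
#' Holds the newly measured active compounds (`pNew`), newly measured inactive
#' compounds (`nNew`, typically false positives of the previous screening
#' round), previously known actives (`pPrv`) and previous random negatives
#' (`nPrv`). The four sets must be pairwise disjoint.
#'
#' @slot pNew,nNew,pPrv,nPrv character vectors of compound ids.
#' @aliases PairingInput
#' @seealso [pairingInput()], [makePairingData()]
#' @exportClass PairingInput
setClass("PairingInput",
  representation(pNew = "character", nNew = "character",
                 pPrv = "character", nPrv = "character"))

setValidity("PairingInput", function(object) {
  sets <- list(P_new = object@pNew, N_new = object@nNew,
               P_prv = object@pPrv, N_prv = object@nPrv)
  msgs <- character()
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) msgs <- c(msgs, sprintf("%s contains duplicate ids", nm))
  }
  nms <- names(sets)
  for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov)) {
      msgs <- c(msgs, sprintf("%s and %s overlap: %s", nms[j], nms[i],
                              paste(head(ov, 5), collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EcbsModel: a trained chemical-pair random-forest classifier
#'
#' One evolutionary scope (`"target"`, `"family:<db>"`, or `"single"` for the
#' single-compound baseline). The forest is a `ranger` probability forest over
#' symmetric pair features (per fingerprint kind, the AND segment followed by
#' the XOR segment of the two bit vectors).
#'
#' @slot scope character scalar scope label.
#' @slot forest fitted `ranger` object.
#' @slot featureSpec list: `kinds`, `lengths`, `pairwise`, `featureNames`.
#' @slot trainingMeta list: per-scheme pair counts, class counts, seed,
#'   forest parameters, scheme composition.
#' @aliases EcbsModel
#' @seealso [trainEcbsModel()], [scorePairs()], [compoundScore()]
#' @exportClass EcbsModel
setClass("EcbsModel",
  representation(scope = "character", forest = "ANY",
                 featureSpec = "list", trainingMeta = "list"))

#' EcbsEnsemble: ensemble of per-scope pair models
#'
#' Combines one [EcbsModel-class] per evolutionary scope (e.g. a target-level
#' model plus one model per protein-family database); the ensemble score of a
#' pair is the unweighted arithmetic mean of the member scores.
#'
#' @slot members list of [EcbsModel-class] objects.
#' @slot combine character, only `"mean"` is supported.
#' @aliases EcbsEnsemble
#' @seealso [trainEcbsEnsemble()]
#' @exportClass EcbsEnsemble
setClass("EcbsEnsemble", representation(members = "list", combine = "character"))

setValidity("EcbsEnsemble", function(object) {
  msgs <- character()
  if (!length(object@members)) msgs <- c(msgs, "ensemble needs at least one member")
  if (!all(vapply(object@members, is, TRUE, class2 = "EcbsModel"))) {
    msgs <- c(msgs, "all ensemble members must be EcbsModel objects")
  }
  if (!identical(object@combine, "mean")) msgs <- c(msgs, "only combine = 'mean' is supported")
  if (length(msgs)) msgs else TRUE
})

#' FoldPlan: compound-level cross-validation assignment
#'
#' @slot k integer fold count.
#' @slot assignments named integer vector mapping compound id to fold index
#'   in `1..k`; fold sizes differ by at most one.
#' @slot seed integer seed the plan was drawn with.
#' @aliases FoldPlan
#' @seealso [splitCompoundsKfold()]
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(k = "integer", assignments = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  msgs <- character()
  if (is.null(names(object@assignments))) msgs <- c(msgs, "assignments must be named by compound id")
  if (length(object@assignments)) {
    if (!all(object@assignments %in% seq_len(object@k))) {
      msgs <- c(msgs, "fold indices must lie in 1..k")
    }
    sizes <- tabulate(object@assignments, nbins = object@k)
    if (diff(range(sizes)) > 1L) msgs <- c(msgs, "fold sizes must differ by at most 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticUniverse: a generated compound/target world with known truth
#'
#' @slot compounds [CompoundSet-class] of all generated compounds.
#' @slot targets data.frame with column `target_id`.
#' @slot families data.frame `target_id`, `family_db`, `family_id`.
#' @slot interactions data.frame `compound_id`, `target_id`, `affinity_nM`
#'   (actives only; near-misses and decoys have no interaction records).
#' @slot truth data.frame `compound_id`, `role` in
#'   `{active, near_miss, decoy}`, `target_id` (`NA` for decoys).
#' @slot config the [synthConfig()] list the universe was generated from,
#'   plus the realized bit layout in `config$layout` (bit mode).
#' @aliases SyntheticUniverse
#' @seealso [generateUniverse()]
#' @exportClass SyntheticUniverse
setClass("SyntheticUniverse",
  representation(compounds = "CompoundSet", targets = "data.frame",
                 families = "data.frame", interactions = "data.frame",
                 truth = "data.frame", config = "list"))

setValidity("SyntheticUniverse", function(object) {
  msgs <- character()
  tr <- object@truth
  if (!setequal(tr$compound_id, ids(object@compounds)) ||
      nrow(tr) != length(ids(object@compounds))) {
    msgs <- c(msgs, "truth must cover every compound exactly once")
  }
  if (!all(tr$role %in% c("active", "near_miss", "decoy"))) {
    msgs <- c(msgs, "truth roles must be active/near_miss/decoy")
  }
  act <- tr$compound_id[tr$role == "active"]
  if (!all(act %in% object@interactions$compound_id)) {
    msgs <- c(msgs, "every active must have an interaction record")
  }
  non <- tr$compound_id[tr$role != "active"]
  if (any(non %in% object@interactions$compound_id)) {
    msgs <- c(msgs, "near-misses and decoys must not have interaction records")
  }
  if (length(msgs)) msgs else TRUE
})
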