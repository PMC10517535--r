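# pairgen: labeled chemical-pair construction. Positives are evolutionarily
# related chemical pairs (ERCPs: compounds binding a common target, or targets
# sharing a protein family); negatives come from random pairing or from the
# experimentally derived retraining schemes NP/NN/PN.

#' Construct a ChemicalPairs object
#'
#' Pairs are canonicalized to `compound_a < compound_b` (lexicographic) so
#' pair sets have set semantics across runs; self-pairs are rejected and
#' duplicates (after canonicalization) are dropped.
#'
#' @param a,b character vectors of compound ids (element-wise pairs).
#' @param scheme provenance scheme per pair (or scalar): one of
#'   `ERCP_TARGET`, `ERCP_FAMILY`, `RAND_NEG`, `PP`, `NP`, `NN`, `PN`.
#'   The label is implied: positive iff the scheme is `ERCP_TARGET`,
#'   `ERCP_FAMILY` or `PP`.
#' @return a [ChemicalPairs-class].
#' @export
chemicalPairs <- function(a, b, scheme) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  scheme <- rep(as.character(scheme), length.out = length(a))
  if (any(a == b)) {
    stop("self-pairs are not allowed: ", paste(head(a[a == b], 5), collapse = ", "))
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b)
  keep <- !duplicated(key)
  df <- data.frame(compound_a = a[keep], compound_b = b[keep],
                   label = ifelse(scheme[keep] %in% .POSITIVE_SCHEMES,
                                  "positive", "negative"),
                   scheme = scheme[keep], stringsAsFactors = FALSE)
  new("ChemicalPairs", pairs = df)
}

.emptyPairs <- function() {
  new("ChemicalPairs", pairs = data.frame(
    compound_a = character(), compound_b = character(),
    label = character(), scheme = character(), stringsAsFactors = FALSE))
}

#' @describeIn pairTable pair table of a ChemicalPairs object
#' @export
setMethod("pairTable", "ChemicalPairs", function(x) x@pairs)

#' @describeIn nPairs pair count
#' @export
setMethod("nPairs", "ChemicalPairs", function(x) nrow(x@pairs))

setMethod("show", "ChemicalPairs", function(object) {
  p <- object@pairs
  cat(sprintf("ChemicalPairs: %d pair%s (%d positive, %d negative)\n",
              nrow(p), if (nrow(p) == 1) "" else "s",
              sum(p$label == "positive"), sum(p$label == "negative")))
  if (nrow(p)) {
    tab <- table(p$scheme)
    cat("  schemes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' Combine pair sets
#'
#' @param ... [ChemicalPairs-class] objects.
#' @param warnDuplicates warn when a pair occurs in more than one input
#'   (the first occurrence wins).
#' @return a deduplicated [ChemicalPairs-class].
#' @export
combinePairs <- function(..., warnDuplicates = TRUE) {
  sets <- list(...)
  stopifnot(all(vapply(sets, is, TRUE, class2 = "ChemicalPairs")))
  df <- do.call(rbind, lapply(sets, pairTable))
  if (is.null(df) || !nrow(df)) return(.emptyPairs())
  key <- paste(df$compound_a, df$compound_b)
  dup <- duplicated(key)
  if (any(dup) && warnDuplicates) {
    warning(sum(dup), " duplicate pair(s) dropped when combining pair sets")
  }
  rownames(df) <- NULL
  new("ChemicalPairs", pairs = df[!dup, , drop = FALSE])
}

#' Classify a POC measurement as active / inactive / ambiguous
#'
#' Percent-of-control (POC) from a competitive binding assay at fixed
#' concentration: lower means stronger binding. Compounds below `activeMax`
#' are active, above `inactiveMin` inactive, anything between is ambiguous
#' and excluded from retraining input.
#'
#' @param pocPercent numeric vector of POC values (percent, >= 0).
#' @param activeMax active threshold (default 20: POC below 20% is active).
#' @param inactiveMin inactive threshold (default 80: POC above 80% is
#'   inactive).
#' @return character vector in `{"active", "inactive", "ambiguous"}`.
#' @examples
#' labelFromPoc(c(3.6, 100, 43))
#' @export
labelFromPoc <- function(pocPercent, activeMax = 20, inactiveMin = 80) {
  assertScalarNumber(activeMax, "activeMax")
  assertScalarNumber(inactiveMin, "inactiveMin")
  if (activeMax >= inactiveMin) stop("`activeMax` must be below `inactiveMin`")
  if (anyNA(pocPercent) || any(pocPercent < 0)) {
    stop("POC values must be non-negative numbers")
  }
  ifelse(pocPercent < activeMax, "active",
         ifelse(pocPercent > inactiveMin, "inactive", "ambiguous"))
}

#' Build evolutionarily related chemical pairs (ERCPs) for a focus target
#'
#' With `scope = "target"` the positives are all unordered pairs of distinct
#' compounds binding the focus target itself. With `scope = "family:<db>"`
#' the related-target set is the focus target plus every target sharing at
#' least one family id with it in that family database, and positives are all
#' unordered pairs of distinct compounds each binding some related target
#' (the target-specific confinement of the family-level model).
#'
#' @param interactions data.frame with columns `compound_id`, `target_id`
#'   and optionally `affinity_nM`.
#' @param families data.frame with columns `target_id`, `family_db`,
#'   `family_id` (required for family scope).
#' @param focusTarget target id present in `interactions` or `families`.
#' @param scope `"target"` or `"family:<db>"` (e.g. `"family:PFAM"`).
#' @param affinityMaxNM optional affinity cutoff; interactions with
#'   `affinity_nM` above it are ignored when forming pairs.
#' @return a [ChemicalPairs-class] of positive pairs (scheme `ERCP_TARGET`
#'   or `ERCP_FAMILY`).
#' @export
buildErcps <- function(interactions, families = NULL, focusTarget,
                       scope = "target", affinityMaxNM = NULL) {
  stopifnot(all(c("compound_id", "target_id") %in% names(interactions)))
  knownTargets <- unique(c(interactions$target_id,
                           if (!is.null(families)) families$target_id))
  if (!focusTarget %in% knownTargets) stop("unknown focus target: ", focusTarget)
  if (!is.null(affinityMaxNM) && "affinity_nM" %in% names(interactions)) {
    keep <- is.na(interactions$affinity_nM) | interactions$affinity_nM <= affinityMaxNM
    interactions <- interactions[keep, , drop = FALSE]
  }
  if (identical(scope, "target")) {
    related <- focusTarget
    schemeTag <- "ERCP_TARGET"
  } else if (grepl("^family:", scope)) {
    db <- sub("^family:", "", scope)
    if (is.null(families) || !db %in% families$family_db) {
      stop("unknown family database '", db, "'")
    }
    fam <- families[families$family_db == db, , drop = FALSE]
    focusFams <- fam$family_id[fam$target_id == focusTarget]
    related <- unique(c(focusTarget, fam$target_id[fam$family_id %in% focusFams]))
    schemeTag <- "ERCP_FAMILY"
  } else {
    stop("scope must be 'target' or 'family:<db>'")
  }
  cpds <- sort(unique(interactions$compound_id[interactions$target_id %in% related]))
  if (length(cpds) < 2L) return(.emptyPairs())
  idx <- utils::combn(length(cpds), 2L)
  chemicalPairs(cpds[idx[1, ]], cpds[idx[2, ]], schemeTag)
}

#' Sample random negative pairs
#'
#' Pairs active compounds with randomly selected (most likely inactive)
#' compounds from a disjoint pool. Draws
#' `round(negPerPos * nPositives)` distinct pairs uniformly without
#' replacement, capped at `|actives| * |pool|` (with a warning when the cap
#' binds). The default ratio of 6 negatives per positive mirrors the
#' roughly 1:6 positive:negative balance the method trains with.
#'
#' @param actives character vector of active compound ids.
#' @param randomPool character vector of candidate random negatives,
#'   disjoint from `actives`.
#' @param nPositives number of positive pairs the negatives accompany.
#' @param negPerPos negatives drawn per positive (default 6).
#' @param seed integer RNG seed; the draw is reproducible.
#' @return a [ChemicalPairs-class] with scheme `RAND_NEG`.
#' @export
sampleNegativePairs <- function(actives, randomPool, nPositives,
                                negPerPos = 6, seed = 1L) {
  actives <- unique(as.character(actives))
  randomPool <- unique(as.character(randomPool))
  if (!length(actives)) stop("`actives` must be non-empty")
  if (!length(randomPool)) stop("`randomPool` must be non-empty")
  ov <- intersect(actives, randomPool)
  if (length(ov)) {
    stop("`randomPool` must be disjoint from `actives`; overlap: ",
         paste(head(ov, 5), collapse = ", "))
  }
  if (negPerPos <= 0) stop("`negPerPos` must be positive")
  want <- round(negPerPos * nPositives)
  total <- length(actives) * length(randomPool)
  if (want > total) {
    warning("requested ", want, " negative pairs but only ", total,
            " are available; returning all of them")
    want <- total
  }
  pick <- withSeed(seed, sample.int(total, want))
  ai <- ((pick - 1L) %% length(actives)) + 1L
  pi <- ((pick - 1L) %/% length(actives)) + 1L
  chemicalPairs(actives[ai], randomPool[pi], "RAND_NEG")
}

#' Construct a PairingInput
#'
#' @param pNew newly measured active compound ids.
#' @param nNew newly measured inactive compound ids (false positives of the
#'   previous screening round).
#' @param pPrv previously known active compound ids.
#' @param nPrv previous random-negative compound ids.
#' @return a [PairingInput-class]; overlapping sets raise an error naming
#'   the offending ids.
#' @export
pairingInput <- function(pNew = character(), nNew = character(),
                         pPrv = character(), nPrv = character()) {
  new("PairingInput", pNew = as.character(pNew), nNew = as.character(nNew),
      pPrv = as.character(pPrv), nPrv = as.character(nPrv))
}

setMethod("show", "PairingInput", function(object) {
  cat(sprintf("PairingInput: |P_new|=%d, |N_new|=%d, |P_prv|=%d, |N_prv|=%d\n",
              length(object@pNew), length(object@nNew),
              length(object@pPrv), length(object@nPrv)))
})

#' Derive a PairingInput from POC assay results
#'
#' Applies [labelFromPoc()] to new experimental results; ambiguous compounds
#' (POC between the thresholds) are excluded.
#'
#' @param results data.frame with columns `compound_id`, `poc_percent`.
#' @param pPrv,nPrv previously known actives / previous random negatives.
#' @param activeMax,inactiveMin POC thresholds, see [labelFromPoc()].
#' @return a [PairingInput-class].
#' @export
pairingInputFromPoc <- function(results, pPrv, nPrv,
                                activeMax = 20, inactiveMin = 80) {
  stopifnot(all(c("compound_id", "poc_percent") %in% names(results)))
  lab <- labelFromPoc(results$poc_percent, activeMax, inactiveMin)
  pairingInput(pNew = results$compound_id[lab == "active"],
               nNew = results$compound_id[lab == "inactive"],
               pPrv = pPrv, nPrv = nPrv)
}

.crossPairs <- function(xs, ys, scheme) {
  if (!length(xs) || !length(ys)) return(.emptyPairs())
  grid <- expand.grid(a = xs, b = ys, stringsAsFactors = FALSE)
  chemicalPairs(grid$a, grid$b, scheme)
}

#' Build retraining pair data from the four experimental compound sets
#'
#' The four schemes are Cartesian products of the [PairingInput-class]
#' sets: `PP = P_new x P_prv` (positive), `NP = N_new x P_prv`,
#' `NN = N_new x N_prv` and `PN = P_new x N_new` (all negative). New actives
#' are paired with *known* active compounds, so PP contains no
#' `P_new x P_new` internal pairs unless `includeInternalPP = TRUE`.
#'
#' @param input a [PairingInput-class].
#' @param schemes subset of `c("PP", "NP", "NN", "PN")`.
#' @param includeInternalPP also pair new actives among themselves.
#' @return a [ChemicalPairs-class], deduplicated, canonical order.
#' @examples
#' inp <- pairingInput(pNew = c("a1", "a2"), nNew = c("i1", "i2", "i3"),
#'                     pPrv = c("k1", "k2", "k3"), nPrv = c("r1", "r2"))
#' nPairs(makePairingData(inp, "PP"))  # 2 x 3 = 6 positive pairs
#' @export
makePairingData <- function(input, schemes = c("PP", "NP", "NN", "PN"),
                            includeInternalPP = FALSE) {
  stopifnot(is(input, "PairingInput"))
  schemes <- match.arg(schemes, c("PP", "NP", "NN", "PN"), several.ok = TRUE)
  out <- list()
  if ("PP" %in% schemes) {
    pp <- .crossPairs(input@pNew, input@pPrv, "PP")
    if (includeInternalPP && length(input@pNew) >= 2L) {
      idx <- utils::combn(sort(input@pNew), 2L)
      pp <- combinePairs(pp, chemicalPairs(idx[1, ], idx[2, ], "PP"),
                         warnDuplicates = FALSE)
    }
    out <- c(out, list(pp))
  }
  if ("NP" %in% schemes) out <- c(out, list(.crossPairs(input@nNew, input@pPrv, "NP")))
  if ("NN" %in% schemes) out <- c(out, list(.crossPairs(input@nNew, input@nPrv, "NN")))
  if ("PN" %in% schemes) out <- c(out, list(.crossPairs(input@pNew, input@nNew, "PN")))
  do.call(combinePairs, c(out, list(warnDuplicates = FALSE)))
}

#' Write / read pair lists as CSV
#'
#' @param pairs a [ChemicalPairs-class].
#' @param path CSV path with columns
#'   `compound_a,compound_b,label,scheme`.
#' @return `writePairs` returns the path invisibly; `readPairs` a
#'   [ChemicalPairs-class].
#' @export
writePairs <- function(pairs, path) {
  stopifnot(is(pairs, "ChemicalPairs"))
  write.csv(pairTable(pairs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePairs
#' @export
readPairs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(.emptyPairs())
  chemicalPairs(df$compound_a, df$compound_b, df$scheme)
}
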