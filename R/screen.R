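# screen: library scoring, novelty filtering, Butina clustering,
# cluster-center selection, novelty reports and substructure search.

#' Screen a chemical library with a trained pair model
#'
#' Scores every library compound against the reference actives with
#' [compoundScore()] (max-score aggregation) and keeps compounds with score
#' at or above the cutoff, sorted by descending score then id.
#'
#' @param model an [EcbsModel-class] or [EcbsEnsemble-class].
#' @param library a [CompoundSet-class] (may be empty).
#' @param referenceActives non-empty [CompoundSet-class].
#' @param scoreCutoff selection threshold (default 0.8).
#' @return hit table: data.frame `compound_id`, `ecbs_score`,
#'   `best_active_id`, `excluded_by` (";"-joined flags, empty = kept),
#'   `pains_flag`, `cluster_id`, `is_center`.
#' @export
screenLibrary <- function(model, library, referenceActives, scoreCutoff = 0.8) {
  stopifnot(is(library, "CompoundSet"), is(referenceActives, "CompoundSet"))
  if (!length(referenceActives)) stop("`referenceActives` must be non-empty")
  if (!length(library)) return(.emptyHits())
  sc <- compoundScore(model, library, referenceActives)
  sc <- sc[sc$score >= scoreCutoff, , drop = FALSE]
  sc <- sc[order(-sc$score, sc$compound_id), , drop = FALSE]
  rownames(sc) <- NULL
  data.frame(compound_id = sc$compound_id, ecbs_score = sc$score,
             best_active_id = sc$best_active_id, excluded_by = "",
             pains_flag = FALSE, cluster_id = NA_character_,
             is_center = FALSE, stringsAsFactors = FALSE)
}

.emptyHits <- function() {
  data.frame(compound_id = character(), ecbs_score = numeric(),
             best_active_id = character(), excluded_by = character(),
             pains_flag = logical(), cluster_id = character(),
             is_center = logical(), stringsAsFactors = FALSE)
}

.addExclusion <- function(flags, add) {
  ifelse(add, ifelse(nzchar(flags), paste(flags, "similarity", sep = ";"), "similarity"), flags)
}

#' Flag hits that are structurally similar to known actives
#'
#' For each hit the highest Tanimoto similarity to any known active is taken
#' as representative; hits strictly above the cutoff are flagged
#' `excluded_by = "similarity"`. The inequality is strict -- a hit exactly at
#' the cutoff is kept -- and lowering the cutoff can only exclude more hits,
#' never fewer.
#'
#' @param hits hit table from [screenLibrary()].
#' @param libraryCompounds [CompoundSet-class] containing the hit compounds.
#' @param knownActives non-empty [CompoundSet-class].
#' @param fpKind fingerprint kind used for the similarity (default
#'   `FCFP6_LIKE`, the functional-class fingerprint recorded in model
#'   metadata).
#' @param cutoff exclusion threshold (default 0.47).
#' @return the hit table with `excluded_by` updated and a
#'   `max_known_similarity` column appended.
#' @export
similarityFilter <- function(hits, libraryCompounds, knownActives,
                             fpKind = "FCFP6_LIKE", cutoff = 0.47) {
  stopifnot(is(knownActives, "CompoundSet"))
  if (!length(knownActives)) stop("`knownActives` must be non-empty")
  if (!nrow(hits)) { hits$max_known_similarity <- numeric(); return(hits) }
  fpHits <- computeFingerprint(libraryCompounds[hits$compound_id], fpKind)
  fpAct <- computeFingerprint(knownActives, fpKind)
  sim <- tanimotoMatrix(fpHits, fpAct)
  maxSim <- apply(sim, 1, max)
  excl <- maxSim > cutoff
  hits$excluded_by <- .addExclusion(hits$excluded_by, excl)
  hits$max_known_similarity <- unname(maxSim)
  hits
}

#' Apply a pluggable exclusion hook
#'
#' External filters that are not part of this package (e.g. pharmacophore
#' matching in a proprietary tool) plug in as a predicate over single
#' compounds. Hits for which the predicate is true get
#' `excluded_by = <hookName>`; the special PAINS hook only raises
#' `pains_flag` and does not exclude (nonspecific-binder candidates are
#' reported, not dropped). A predicate error aborts with the offending hit
#' id.
#'
#' @param hits hit table.
#' @param libraryCompounds [CompoundSet-class] containing the hit compounds.
#' @param predicate function taking a length-one [CompoundSet-class] and
#'   returning `TRUE`/`FALSE`.
#' @param hookName label recorded in `excluded_by`.
#' @param flagOnly if `TRUE`, set `pains_flag` instead of excluding;
#'   defaults to `TRUE` exactly for `hookName = "PAINS"`.
#' @return the updated hit table.
#' @export
applyExclusionHook <- function(hits, libraryCompounds, predicate, hookName,
                               flagOnly = identical(hookName, "PAINS")) {
  if (!nrow(hits)) return(hits)
  verdict <- vapply(hits$compound_id, function(id) {
    res <- tryCatch(predicate(libraryCompounds[id]),
                    error = function(e) stop("exclusion hook '", hookName,
                                             "' failed on hit '", id, "': ",
                                             conditionMessage(e), call. = FALSE))
    isTRUE(res)
  }, logical(1))
  if (flagOnly) {
    hits$pains_flag <- hits$pains_flag | verdict
  } else {
    hits$excluded_by <- ifelse(verdict,
                               ifelse(nzchar(hits$excluded_by),
                                      paste(hits$excluded_by, hookName, sep = ";"),
                                      hookName),
                               hits$excluded_by)
  }
  hits
}

#' Bundled pan-assay interference (PAINS) substructure patterns
#'
#' A small curated subset of widely known PAINS alert substructures
#' (quinones, catechols, rhodanines and relatives) expressed as SMARTS; used
#' by [painsPredicate()] to flag likely nonspecific binders. Flagging is
#' advisory: PAINS hits are reported, not excluded.
#'
#' @return named character vector of SMARTS patterns.
#' @export
painsPatterns <- function() {
  c(quinone_A       = "O=C1C=CC(=O)C=C1",
    catechol        = "c1ccc(O)c(O)c1",
    rhodanine       = "S=C1NC(=O)CS1",
    ene_rhodanine   = "S=C1N=C(S1)C=C",
    hydroxyphenyl_hydrazone = "c1cc(O)ccc1C=NN",
    azo             = "cN=Nc",
    isothiazolinone = "S1C=CC(=O)N1",
    mannich_phenol  = "c1(O)c(CN)cccc1",
    beta_keto_enol  = "C(=O)C=C(O)",
    nitroso         = "[#6]N=O",
    anhydride       = "C(=O)OC(=O)",
    thiourea_enone  = "NC(=S)NC=C")
}

#' PAINS predicate over single compounds
#'
#' @param patterns SMARTS vector, defaults to [painsPatterns()].
#' @return a predicate suitable for [applyExclusionHook()] with
#'   `hookName = "PAINS"`; `TRUE` when any pattern matches.
#' @export
painsPredicate <- function(patterns = painsPatterns()) {
  function(cpd) {
    stopifnot(is(cpd, "CompoundSet"), length(cpd) == 1L)
    smi <- unname(smiles(cpd))
    if (is.na(smi)) stop("PAINS matching requires a SMILES structure")
    any(.smartsCounts(smi, patterns) > 0L)
  }
}

.smartsCounts <- function(smilesVec, patterns) {
  txt <- paste(smilesVec, sprintf("m%d", seq_along(smilesVec)), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", txt, identity)
  out <- matrix(0L, nrow = length(smilesVec), ncol = length(patterns))
  for (j in seq_along(patterns)) {
    out[, j] <- ChemmineOB::smartsSearch_OB(mols, patterns[[j]])
  }
  rowSums(out > 0L)
}

#' Butina leader clustering on fingerprint similarity
#'
#' Neighbors are compound pairs with Tanimoto similarity at or above the
#' cutoff. Iteratively, the unassigned compound with the most unassigned
#' neighbors (ties by lexicographic id) becomes a cluster leader and claims
#' itself plus its unassigned neighbors; compounds without neighbors end up
#' as singleton clusters. The leader is the cluster center -- the minimal,
#' most conserved core structure of its cluster.
#'
#' @param compounds non-empty [CompoundSet-class].
#' @param fpKind fingerprint kind (default the path-based `PATH5_2048` used
#'   for clustering tested molecules).
#' @param simCutoff Tanimoto neighbor cutoff in `(0, 1]` (default 0.6).
#' @return data.frame `compound_id`, `cluster_id` (`"C1"`, `"C2"`, ... in
#'   creation order), `is_center`.
#' @export
butinaCluster <- function(compounds, fpKind = "PATH5_2048", simCutoff = 0.6) {
  stopifnot(is(compounds, "CompoundSet"))
  if (!length(compounds)) stop("cannot cluster an empty compound set")
  if (!(simCutoff > 0 && simCutoff <= 1)) stop("`simCutoff` must be in (0, 1]")
  fp <- computeFingerprint(compounds, fpKind)
  sim <- tanimotoMatrix(fp)
  butinaClusterFromSimilarity(sim, simCutoff)
}

#' Butina clustering from a precomputed similarity matrix
#'
#' @param sim symmetric similarity matrix with compound-id dimnames.
#' @param simCutoff neighbor cutoff.
#' @return as [butinaCluster()].
#' @export
butinaClusterFromSimilarity <- function(sim, simCutoff = 0.6) {
  cpdIds <- rownames(sim)
  n <- length(cpdIds)
  nbr <- sim >= simCutoff
  diag(nbr) <- FALSE
  unassigned <- rep(TRUE, n)
  cluster <- character(n)
  center <- logical(n)
  nextCluster <- 0L
  ord <- order(cpdIds)  # lexicographic tie-break
  while (any(unassigned)) {
    counts <- colSums(nbr[unassigned, , drop = FALSE]) * unassigned
    candidates <- ord[unassigned[ord]]
    leader <- candidates[which.max(counts[candidates])]
    members <- c(leader, which(nbr[leader, ] & unassigned))
    members <- unique(members)
    nextCluster <- nextCluster + 1L
    cluster[members] <- sprintf("C%d", nextCluster)
    center[leader] <- TRUE
    unassigned[members] <- FALSE
  }
  data.frame(compound_id = cpdIds, cluster_id = cluster, is_center = center,
             stringsAsFactors = FALSE)
}

#' Attach cluster assignments and centers to a hit table
#'
#' Exactly one center (the Butina leader) per cluster; excluded hits must
#' not be part of the clustering, so they can never become centers.
#'
#' @param clusters output of [butinaCluster()] over the *unexcluded* hits.
#' @param hits hit table.
#' @return the hit table with `cluster_id` and `is_center` filled in.
#' @export
selectClusterCenters <- function(clusters, hits) {
  unknown <- setdiff(clusters$compound_id, hits$compound_id)
  if (length(unknown)) {
    stop("cluster references unknown hit(s): ", paste(head(unknown, 5), collapse = ", "))
  }
  idx <- match(clusters$compound_id, hits$compound_id)
  excluded <- nzchar(hits$excluded_by[idx])
  if (any(excluded & clusters$is_center)) {
    stop("excluded hits cannot be cluster centers: ",
         paste(head(clusters$compound_id[excluded & clusters$is_center], 5), collapse = ", "))
  }
  hits$cluster_id[idx] <- clusters$cluster_id
  hits$is_center[idx] <- clusters$is_center
  hits
}

#' Structural-novelty report for a query compound
#'
#' Ranks every reference by Tanimoto similarity to the query under each
#' requested fingerprint kind, annotated with known activities when
#' supplied. Low similarity across several fingerprint systems plus a failed
#' substructure search is the evidence used to call a hit structurally
#' novel.
#'
#' @param query length-one [CompoundSet-class].
#' @param references non-empty [CompoundSet-class].
#' @param fpKinds fingerprint kinds (default Morgan + MACCS).
#' @param activities optional named vector (reference id -> annotation,
#'   e.g. `"POC 3.6"`).
#' @return data.frame `kind`, `reference_id`, `similarity`, `activity`,
#'   sorted by descending similarity within kind.
#' @export
noveltyReport <- function(query, references,
                          fpKinds = c("MORGAN_R2_1024", "MACCS166"),
                          activities = NULL) {
  stopifnot(is(query, "CompoundSet"), length(query) == 1L,
            is(references, "CompoundSet"))
  if (!length(references)) stop("`references` must be non-empty")
  out <- lapply(fpKinds, function(kind) {
    fq <- computeFingerprint(query, kind)
    fr <- computeFingerprint(references, kind)
    sim <- as.numeric(tanimotoMatrix(fq, fr))
    df <- data.frame(kind = kind, reference_id = ids(references),
                     similarity = sim, stringsAsFactors = FALSE)
    df$activity <- if (is.null(activities)) NA_character_ else
      unname(activities[df$reference_id])
    df[order(-df$similarity, df$reference_id), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Delete atoms (1-based indices into the heavy-atom block of the canonical
# structure) and return the SMILES of the remaining fragment(s).
.reducedCoreSmiles <- function(smi, ignoreAtomIndices) {
  g <- .molGraph(smi)
  if (any(ignoreAtomIndices < 1L | ignoreAtomIndices > g$n)) {
    stop("ignore indices out of range 1..", g$n)
  }
  keep <- setdiff(seq_len(g$n), ignoreAtomIndices)
  if (!length(keep)) stop("cannot ignore every atom of the core")
  remap <- match(seq_len(g$n), keep)
  edges <- g$edges[g$edges[, 1] %in% keep & g$edges[, 2] %in% keep, , drop = FALSE]
  lines <- c("reduced core", " ecbscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(keep), nrow(edges)))
  for (i in keep) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, g$elem[i]))
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", remap[edges[r, 1]],
                                remap[edges[r, 2]], edges[r, 3]))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(lines, collapse = "\n"), "\n"))
  smiOut <- strsplit(trimws(strsplit(out, "\n")[[1]][1]), "\t")[[1]][1]
  if (is.na(smiOut) || !nzchar(smiOut)) stop("failed to rebuild reduced core")
  smiOut
}

#' Substructure search of a core against candidate compounds
#'
#' Subgraph-isomorphism matching via SMARTS: candidates containing the core
#' (with the ignored atoms deleted first, e.g. to drop variable amino/halo
#' decorations) are returned. A multi-fragment reduced core requires every
#' fragment to match.
#'
#' @param core a SMILES/SMARTS string or a length-one [CompoundSet-class].
#' @param candidates a [CompoundSet-class].
#' @param ignoreAtomIndices optional integer indices (1-based, heavy atoms
#'   in canonical order) deleted from the core before matching. Only valid
#'   when `core` is a structure, not a raw SMARTS pattern.
#' @return character vector of matching candidate ids.
#' @export
substructureMatch <- function(core, candidates, ignoreAtomIndices = NULL) {
  stopifnot(is(candidates, "CompoundSet"))
  if (is(core, "CompoundSet")) {
    stopifnot(length(core) == 1L)
    core <- unname(smiles(core))
  }
  if (!is.character(core) || length(core) != 1L || !nzchar(core)) {
    stop("`core` must be a single SMILES/SMARTS string or a length-one CompoundSet")
  }
  if (!is.null(ignoreAtomIndices) && length(ignoreAtomIndices)) {
    core <- .reducedCoreSmiles(core, as.integer(ignoreAtomIndices))
  }
  if (!length(candidates)) return(character())
  patterns <- strsplit(core, ".", fixed = TRUE)[[1]]
  txt <- paste(smiles(candidates), ids(candidates), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", txt, identity)
  ok <- rep(TRUE, length(candidates))
  for (pat in patterns) {
    counts <- tryCatch(ChemmineOB::smartsSearch_OB(mols, pat),
                       error = function(e) stop("invalid substructure pattern '",
                                                pat, "': ", conditionMessage(e),
                                                call. = FALSE))
    ok <- ok & (counts > 0L)
  }
  ids(candidates)[ok]
}

#' Write a screening hit table
#'
#' @param hits hit table.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeHits <- function(hits, path) {
  write.csv(hits, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
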