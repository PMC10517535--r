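# synthdata: synthetic compound universes with scaffold-structured actives,
# random decoys and near-miss inactives. Two generation modes: "bits" samples
# fingerprint bit vectors directly (fast, chemistry-free, fully deterministic
# across toolkit versions) and "smiles" assembles real structures from
# scaffold and decoration fragments so the chemistry readers and filters are
# exercised end to end.

.defaultScaffolds <- function() c(
  "O=C(Nc1ccc(%s)cc1)%s",
  "O=S(=O)(c1ccc(%s)cc1)N%s",
  "O=C(COc1ccc(%s)cc1)%s",
  "O=C(OCc1ccc(%s)cc1)%s",
  "N#Cc1ccc(%s)cc1%s")

.defaultDecorations <- function() c("C", "CC", "CCC", "CC(C)C", "CCO", "CO",
                                    "CN", "C(C)=O", "COC", "CCN")

.defaultDecoyCores <- function() c("C1CCCCC1", "c1ccccc1", "C1CCNCC1",
                                   "c1ccncc1", "C1CCOC1", "CC(C)CC",
                                   "C1CCCC1", "c1ccc2ccccc2c1")

#' Synthetic-universe configuration
#'
#' Defaults define the study conditions every simulation in this package
#' runs under: three targets with ten actives each, sixty random decoys, and
#' twenty near-miss inactives attached to the first (focus) target -- the
#' false-positive regime that motivates NP retraining pairs. In bit mode
#' each target owns disjoint scaffold, activity and "poison" bit blocks;
#' actives carry scaffold + activity bits, near-misses carry scaffold +
#' activity + poison bits (structurally close to actives yet inactive), and
#' decoys carry background noise only. In SMILES mode actives are a scaffold
#' core decorated with an iodo activity group, near-misses the same core
#' without it, and decoys random fragment assemblies.
#'
#' @param mode `"bits"` or `"smiles"`.
#' @param nTargets number of protein targets.
#' @param activesPerTarget actives generated per target.
#' @param nDecoys random decoy compounds.
#' @param nNearMiss near-miss inactives (all on the focus/first target).
#' @param kinds fingerprint kinds realized in bit mode.
#' @param familyLayout named list: family database -> list of integer
#'   vectors of target indices sharing a family. `NULL` gives two databases,
#'   one grouping consecutive target pairs, one offset by a single target,
#'   so family-level ERCPs always exist.
#' @param scaffoldLibrary character vector of `sprintf` templates with two
#'   `%s` slots (activity group, decoration), SMILES mode.
#' @param decorationLibrary substituent fragments, SMILES mode.
#' @param noiseRate background bit probability, bit mode (default 0.05).
#' @param seed integer seed; every generated artifact is a pure function of
#'   the configuration and this seed.
#' @return a list of class `synth_config`.
#' @export
synthConfig <- function(mode = c("bits", "smiles"), nTargets = 3L,
                        activesPerTarget = 10L, nDecoys = 60L, nNearMiss = 20L,
                        kinds = c("MACCS166", "SUBSTRUCT_FP4"),
                        familyLayout = NULL,
                        scaffoldLibrary = .defaultScaffolds(),
                        decorationLibrary = .defaultDecorations(),
                        noiseRate = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nTargets >= 1L, activesPerTarget >= 0L, nDecoys >= 0L,
            nNearMiss >= 0L, noiseRate >= 0, noiseRate <= 1)
  if (mode == "smiles") {
    if (!length(scaffoldLibrary) || !length(decorationLibrary)) {
      stop("SMILES mode requires non-empty scaffold and decoration libraries")
    }
    if (nTargets > length(scaffoldLibrary)) {
      stop("nTargets exceeds the scaffold library size (", length(scaffoldLibrary), ")")
    }
  }
  if (is.null(familyLayout)) {
    pairup <- function(offset) {
      idx <- seq_len(nTargets)
      split(idx, (idx - 1L + offset) %/% 2L)
    }
    familyLayout <- list(FAMA = unname(pairup(0L)), FAMB = unname(pairup(1L)))
  }
  structure(list(mode = mode, nTargets = as.integer(nTargets),
                 activesPerTarget = as.integer(activesPerTarget),
                 nDecoys = as.integer(nDecoys), nNearMiss = as.integer(nNearMiss),
                 kinds = kinds, familyLayout = familyLayout,
                 scaffoldLibrary = scaffoldLibrary,
                 decorationLibrary = decorationLibrary,
                 noiseRate = noiseRate, seed = as.integer(seed)),
            class = "synth_config")
}

.familyTable <- function(config, targetIds) {
  rows <- list()
  for (db in names(config$familyLayout)) {
    fams <- config$familyLayout[[db]]
    for (i in seq_along(fams)) {
      idx <- fams[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = targetIds[idx],
        family_db = db, family_id = sprintf("%s_%d", db, i),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Disjoint per-target bit blocks for one fingerprint kind; falls back to
# independent sampling when the kind is too short to give every target its
# own blocks.
.bitLayout <- function(len, nTargets) {
  nScaffold <- max(4L, round(0.18 * len))
  nActivity <- max(2L, round(0.06 * len))
  nPoison <- max(2L, round(0.06 * len))
  per <- nScaffold + nActivity + nPoison
  layout <- vector("list", nTargets)
  if (per * nTargets <= len) {
    pool <- sample.int(len, per * nTargets)
    for (t in seq_len(nTargets)) {
      blk <- pool[(t - 1L) * per + seq_len(per)]
      layout[[t]] <- list(scaffold = blk[seq_len(nScaffold)],
                          activity = blk[nScaffold + seq_len(nActivity)],
                          poison = blk[nScaffold + nActivity + seq_len(nPoison)])
    }
  } else {
    for (t in seq_len(nTargets)) {
      blk <- sample.int(len, per)
      layout[[t]] <- list(scaffold = blk[seq_len(nScaffold)],
                          activity = blk[nScaffold + seq_len(nActivity)],
                          poison = blk[nScaffold + nActivity + seq_len(nPoison)])
    }
  }
  layout
}

.sampleBitRow <- function(len, onBits, pOn, noiseRate) {
  row <- as.integer(runif(len) < noiseRate)
  for (blk in onBits) row[blk] <- as.integer(runif(length(blk)) < pOn)
  row
}

#' Generate a synthetic universe
#'
#' Deterministic per configuration seed. Bit mode realizes per-target
#' scaffold/activity/poison bit blocks (stored in `config$layout` of the
#' result for reproducibility); SMILES mode assembles structures from the
#' fragment libraries. Actives get one interaction record each with an
#' affinity below 100 nM; near-misses and decoys get none.
#'
#' @param config a [synthConfig()] list.
#' @return a [SyntheticUniverse-class].
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withSeed(config$seed, {
    targetIds <- sprintf("T%d", seq_len(config$nTargets))
    activeIds <- character(); activeTarget <- character()
    for (t in seq_len(config$nTargets)) {
      if (config$activesPerTarget > 0L) {
        activeIds <- c(activeIds, sprintf("A_%s_%02d", targetIds[t],
                                          seq_len(config$activesPerTarget)))
        activeTarget <- c(activeTarget, rep(targetIds[t], config$activesPerTarget))
      }
    }
    nearIds <- if (config$nNearMiss > 0L)
      sprintf("M_%s_%02d", targetIds[1], seq_len(config$nNearMiss)) else character()
    decoyIds <- if (config$nDecoys > 0L)
      sprintf("D_%03d", seq_len(config$nDecoys)) else character()
    allIds <- c(activeIds, nearIds, decoyIds)

    if (config$mode == "bits") {
      layout <- list()
      fps <- list()
      for (kind in config$kinds) {
        len <- fingerprintLength(kind)
        lay <- .bitLayout(len, config$nTargets)
        layout[[kind]] <- lay
        m <- matrix(0L, nrow = length(allIds), ncol = len)
        r <- 0L
        for (i in seq_along(activeIds)) {
          t <- match(activeTarget[i], targetIds)
          r <- r + 1L
          m[r, ] <- .sampleBitRow(len, lay[[t]][c("scaffold", "activity")],
                                  0.9, config$noiseRate)
        }
        for (i in seq_along(nearIds)) {
          r <- r + 1L
          m[r, ] <- .sampleBitRow(len, layout[[kind]][[1]], 0.9, config$noiseRate)
        }
        for (i in seq_along(decoyIds)) {
          r <- r + 1L
          m[r, ] <- .sampleBitRow(len, list(), 0, config$noiseRate)
        }
        fps[[kind]] <- m
      }
      compounds <- abstractCompounds(allIds, fps)
      config$layout <- layout
    } else {
      act <- "I"    # halogen activity group on the scaffold
      inact <- "[H]"
      mkSmiles <- function(role, tIdx) {
        template <- config$scaffoldLibrary[tIdx]
        deco <- sample(config$decorationLibrary, 1L)
        sprintf(template, if (role == "active") act else inact, deco)
      }
      smi <- character(length(allIds))
      r <- 0L
      for (i in seq_along(activeIds)) {
        r <- r + 1L
        smi[r] <- mkSmiles("active", match(activeTarget[i], targetIds))
      }
      for (i in seq_along(nearIds)) {
        r <- r + 1L
        smi[r] <- mkSmiles("near", 1L)
      }
      for (i in seq_along(decoyIds)) {
        r <- r + 1L
        smi[r] <- paste0(sample(config$decorationLibrary, 1L),
                         sample(.defaultDecoyCores(), 1L))
      }
      compounds <- parseCompounds(allIds, smi)
    }

    interactions <- data.frame(
      compound_id = activeIds, target_id = activeTarget,
      affinity_nM = round(runif(length(activeIds), 1, 100), 1),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      compound_id = allIds,
      role = c(rep("active", length(activeIds)),
               rep("near_miss", length(nearIds)),
               rep("decoy", length(decoyIds))),
      target_id = c(activeTarget, rep(targetIds[1], length(nearIds)),
                    rep(NA_character_, length(decoyIds))),
      stringsAsFactors = FALSE)
    new("SyntheticUniverse", compounds = compounds,
        targets = data.frame(target_id = targetIds, stringsAsFactors = FALSE),
        families = .familyTable(config, targetIds),
        interactions = interactions, truth = truth, config = unclass(config))
  })
}

setMethod("show", "SyntheticUniverse", function(object) {
  tab <- table(object@truth$role)
  cat(sprintf("SyntheticUniverse (%s mode): %d targets; %s\n",
              object@config$mode, nrow(object@targets),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

#' @describeIn ids compound ids of a SyntheticUniverse
#' @export
setMethod("ids", "SyntheticUniverse", function(x) ids(x@compounds))

#' Universe accessors
#'
#' @param universe a [SyntheticUniverse-class].
#' @return `universeCompounds` the [CompoundSet-class]; `universeTruth`,
#'   `universeInteractions`, `universeFamilies` the respective data.frames.
#' @export
universeCompounds <- function(universe) universe@compounds

#' @rdname universeCompounds
#' @export
universeTruth <- function(universe) universe@truth

#' @rdname universeCompounds
#' @export
universeInteractions <- function(universe) universe@interactions

#' @rdname universeCompounds
#' @export
universeFamilies <- function(universe) universe@families

#' Simulate a round of experimental validation
#'
#' Emulates feeding first-round screening picks into a binding assay: some
#' true actives come back active (POC drawn uniformly below 15%) and some
#' near-misses come back inactive (POC above 85%), both consistent with
#' [labelFromPoc()] at the 20/80 thresholds. The defaults (4 actives, 19
#' inactives) match the motivating single-target experiment the retraining schemes were
#' designed around. `P_prv` becomes every remaining active, `N_prv` the
#' decoy pool.
#'
#' @param universe a [SyntheticUniverse-class].
#' @param nTruePos newly confirmed actives drawn from the focus target's
#'   actives.
#' @param nFalsePos newly refuted near-misses (0 gives an empty `N_new`).
#' @param seed integer seed.
#' @param focusTarget target id (default: the universe's first target).
#' @return list with `input` (a [PairingInput-class]) and `results`
#'   (data.frame `compound_id`, `target_id`, `poc_percent`, `kd_nM`).
#' @export
generateNewExperimentalData <- function(universe, nTruePos = 4L, nFalsePos = 19L,
                                        seed = 1L, focusTarget = NULL) {
  stopifnot(is(universe, "SyntheticUniverse"))
  truth <- universe@truth
  focusTarget <- focusTarget %||% universe@targets$target_id[1]
  actives <- truth$compound_id[truth$role == "active" & truth$target_id == focusTarget]
  nears <- truth$compound_id[truth$role == "near_miss" & truth$target_id == focusTarget]
  decoys <- truth$compound_id[truth$role == "decoy"]
  if (nTruePos > length(actives)) {
    stop("not enough actives on ", focusTarget, ": have ", length(actives),
         ", requested ", nTruePos)
  }
  if (nFalsePos > length(nears)) {
    stop("not enough near-misses on ", focusTarget, ": have ", length(nears),
         ", requested ", nFalsePos)
  }
  withSeed(seed, {
    pNew <- sort(sample(actives, nTruePos))
    nNew <- sort(sample(nears, nFalsePos))
    pPrv <- setdiff(truth$compound_id[truth$role == "active"], pNew)
    results <- data.frame(
      compound_id = c(pNew, nNew), target_id = focusTarget,
      poc_percent = round(c(runif(length(pNew), 0, 15),
                            runif(length(nNew), 85, 100)), 1),
      kd_nM = round(c(runif(length(pNew), 100, 5000),
                      rep(NA_real_, length(nNew))), 0),
      stringsAsFactors = FALSE)
    list(input = pairingInput(pNew = pNew, nNew = nNew, pPrv = pPrv, nPrv = decoys),
         results = results)
  })
}

#' Generate a screening library with planted actives
#'
#' Background compounds are fresh random decoys from the universe's
#' generative model; planted hits are actives drawn from the universe (train
#' the screening model without them to measure enrichment). The library
#' order is shuffled deterministically.
#'
#' @param universe a [SyntheticUniverse-class].
#' @param nBackground number of fresh background decoys.
#' @param nPlantedHits number of planted actives (must not exceed the
#'   universe's actives).
#' @param seed integer seed.
#' @return list with `library` (a [CompoundSet-class]) and `planted`
#'   (character ids of the planted actives).
#' @export
generateScreeningLibrary <- function(universe, nBackground = 1990L,
                                     nPlantedHits = 10L, seed = 1L) {
  stopifnot(is(universe, "SyntheticUniverse"))
  truth <- universe@truth
  actives <- truth$compound_id[truth$role == "active"]
  if (nPlantedHits > length(actives)) {
    stop("cannot plant ", nPlantedHits, " actives; universe has ", length(actives))
  }
  config <- universe@config
  withSeed(seed, {
    planted <- sort(sample(actives, nPlantedHits))
    bgIds <- sprintf("L%05d", seq_len(nBackground))
    if (config$mode == "bits") {
      fps <- list()
      for (kind in config$kinds) {
        len <- fingerprintLength(kind)
        m <- matrix(as.integer(runif(nBackground * len) < config$noiseRate),
                    nrow = nBackground)
        fps[[kind]] <- m
      }
      background <- if (nBackground > 0L) abstractCompounds(bgIds, fps) else
        universe@compounds[character()]
    } else {
      smi <- paste0(sample(config$decorationLibrary, nBackground, replace = TRUE),
                    sample(.defaultDecoyCores(), nBackground, replace = TRUE))
      background <- parseCompounds(bgIds, smi)
    }
    lib <- if (nPlantedHits > 0L)
      combineCompounds(background, universe@compounds[planted]) else background
    lib <- lib[sample(length(lib))]
    list(library = lib, planted = planted)
  })
}

#' Write the synthetic universe as the pipeline's CSV formats
#'
#' Emits the exact file formats the readers consume (`compounds.csv`,
#' `interactions.csv`, `families.csv`, `truth.csv`, plus one
#' `fingerprints_<kind>.csv` per realized kind in bit mode), so a synthetic
#' run exercises every reader.
#'
#' @param universe a [SyntheticUniverse-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeUniverse <- function(universe, dir) {
  stopifnot(is(universe, "SyntheticUniverse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  cp <- file.path(dir, "compounds.csv")
  write.csv(data.frame(id = ids(universe@compounds),
                       smiles = unname(smiles(universe@compounds)),
                       stringsAsFactors = FALSE), cp, row.names = FALSE, quote = FALSE)
  paths <- c(paths, cp)
  for (nm in c("interactions", "families", "truth")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(slot(universe, nm), p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (universe@config$mode == "bits") {
    for (kind in universe@config$kinds) {
      p <- file.path(dir, sprintf("fingerprints_%s.csv", kind))
      writeFingerprints(computeFingerprint(universe@compounds, kind), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
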