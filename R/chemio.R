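# chemio: compound parsing, canonicalization and tabular I/O.
# Chemistry is delegated to Open Babel through ChemmineOB; this module owns
# id bookkeeping, the largest-fragment rule for salts, and error reporting.

.canonicalizeBatch <- function(smiles, ids) {
  txt <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", txt))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[2] %||% NA_character_, "")
  can <- vapply(parts, `[`, "", 1)
  setNames(can, got)[ids]
}

# Heavy-atom count heuristic used only to pick the largest fragment of a
# multi-fragment (salt) SMILES; exact counts are not needed, only ordering.
.heavyAtomCount <- function(smi) {
  toks <- gregexpr("Cl|Br|Si|Se|\\[[^]]*\\]|[BCNOPSFI]|[bcnops]", smi)[[1]]
  if (toks[1] == -1L) 0L else length(toks)
}

.largestFragment <- function(can) {
  vapply(can, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags[which.max(vapply(frags, .heavyAtomCount, 0L))]
  }, "", USE.NAMES = FALSE)
}

#' Construct a CompoundSet from ids and SMILES
#'
#' SMILES are canonicalized with Open Babel; multi-fragment inputs (salt
#' forms) are reduced to their largest organic fragment before any
#' fingerprinting, so that screening libraries containing salts behave like
#' their parent compounds. Two different spellings of the same molecule yield
#' the same canonical SMILES and therefore identical fingerprints.
#'
#' @param ids character vector of unique, non-empty compound ids.
#' @param smiles character vector of SMILES strings (same length as `ids`).
#' @param onError `"stop"` (default) raises an error naming every id whose
#'   SMILES fails to parse; `"skip"` drops the offending compounds with a
#'   warning.
#' @return a [CompoundSet-class].
#' @examples
#' cpds <- parseCompounds(c("b1", "b2"), c("c1ccccc1", "C1=CC=CC=C1"))
#' smiles(cpds)  # both rows carry the same canonical benzene SMILES
#' @export
parseCompounds <- function(ids, smiles, onError = c("stop", "skip")) {
  onError <- match.arg(onError)
  ids <- as.character(ids)
  smiles <- as.character(smiles)
  if (length(ids) != length(smiles)) stop("`ids` and `smiles` must have equal length")
  if (length(ids) == 0L) return(new("CompoundSet", ids = character(), smiles = character()))
  if (anyNA(smiles) || any(!nzchar(smiles))) {
    bad <- ids[is.na(smiles) | !nzchar(smiles)]
    stop("empty SMILES for compound(s): ", paste(head(bad, 10), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate compound id(s): ", paste(head(dup, 10), collapse = ", "))
  }
  can <- .canonicalizeBatch(smiles, ids)
  if (anyNA(can)) {
    # Open Babel stops a batch at the first bad record; reconvert the
    # unresolved tail one compound at a time to classify each record.
    miss <- which(is.na(can))
    for (i in miss) can[i] <- .canonicalizeBatch(smiles[i], ids[i])
  }
  bad <- ids[is.na(can) | !nzchar(can)]
  if (length(bad)) {
    msg <- paste0("unparsable SMILES for compound(s): ", paste(head(bad, 10), collapse = ", "))
    if (onError == "stop") stop(msg)
    warning(msg, "; skipped")
    keep <- !(ids %in% bad)
    ids <- ids[keep]; can <- can[keep]
  }
  frag <- .largestFragment(unname(can))
  resplit <- frag != unname(can)
  if (any(resplit)) {
    # re-canonicalize the kept fragment so downstream SDF round-trips agree
    frag[resplit] <- unname(.canonicalizeBatch(frag[resplit], ids[resplit]))
  }
  new("CompoundSet", ids = unname(ids), smiles = unname(frag))
}

#' Parse a single compound
#'
#' Convenience wrapper around [parseCompounds()] for one id/SMILES pair.
#'
#' @param id compound id.
#' @param smiles SMILES string.
#' @return a length-one [CompoundSet-class].
#' @export
parseCompound <- function(id, smiles) parseCompounds(id, smiles)

#' Read a compound table from .smi, SDF or CSV
#'
#' `.smi` files are whitespace-separated `SMILES id` lines (a missing id
#' column yields `cpd_<line>` ids); CSV needs header columns `id` and
#' `smiles`; SDF (V2000) records are converted through Open Babel and take
#' their ids from the molecule name field. Record order is preserved and
#' duplicate ids are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"smi"`, `"sdf"` or `"csv"`.
#' @param onError passed to [parseCompounds()]; `"skip"` drops unparsable
#'   records with a warning naming their position.
#' @return a [CompoundSet-class].
#' @export
readCompoundTable <- function(path, format = c("auto", "smi", "sdf", "csv"),
                              onError = c("stop", "skip")) {
  format <- match.arg(format)
  onError <- match.arg(onError)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", csv = "csv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass `format` explicitly"))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(new("CompoundSet", ids = character(), smiles = character()))
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    smi <- vapply(toks, `[`, "", 1)
    id <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2L) toks[[i]][2] else sprintf("cpd_%d", i)
    }, "")
    parseCompounds(id, smi, onError = onError)
  } else if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df))) {
      stop("CSV must have columns `id` and `smiles`")
    }
    if (anyDuplicated(df$id)) {
      dup <- unique(df$id[duplicated(df$id)])
      stop("duplicate compound id(s) in ", path, ": ", paste(head(dup, 10), collapse = ", "))
    }
    parseCompounds(df$id, df$smiles, onError = onError)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    nm <- ChemmineR::sdfid(sdf)
    nm[is.na(nm) | !nzchar(nm)] <- sprintf("cpd_%d", which(is.na(nm) | !nzchar(nm)))
    smi <- vapply(seq_along(sdf), function(i) {
      as.character(ChemmineR::sdf2smiles(sdf[i]))
    }, "")
    parseCompounds(nm, smi, onError = onError)
  }
}

#' Write a canonical SMILES table
#'
#' @param cpds a [CompoundSet-class].
#' @param path output CSV path (columns `id`, `smiles`).
#' @return invisibly, the path.
#' @export
writeCompoundTable <- function(cpds, path) {
  stopifnot(is(cpds, "CompoundSet"))
  write.csv(data.frame(id = ids(cpds), smiles = smiles(cpds),
                       stringsAsFactors = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn ids ids of a CompoundSet
#' @export
setMethod("ids", "CompoundSet", function(x) x@ids)

#' @describeIn smiles canonical SMILES of a CompoundSet
#' @export
setMethod("smiles", "CompoundSet", function(x) setNames(x@smiles, x@ids))

setMethod("length", "CompoundSet", function(x) length(x@ids))

setMethod("show", "CompoundSet", function(object) {
  n <- length(object)
  cached <- ls(object@fpCache)
  cat(sprintf("CompoundSet with %d compound%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    shown <- head(seq_len(n), 5)
    for (i in shown) {
      cat(sprintf("  %s  %s\n", object@ids[i],
                  if (is.na(object@smiles[i])) "<abstract>" else object@smiles[i]))
    }
    if (n > 5) cat(sprintf("  ... and %d more\n", n - 5))
  }
  if (length(cached)) cat("cached fingerprints:", paste(cached, collapse = ", "), "\n")
})

#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@ids)
    if (anyNA(idx)) stop("unknown compound id(s): ", paste(head(i[is.na(idx)], 5), collapse = ", "))
  } else {
    idx <- seq_along(x@ids)[i]
  }
  cache <- new.env(parent = emptyenv())
  for (kind in ls(x@fpCache)) {
    assign(kind, get(kind, envir = x@fpCache)[idx, , drop = FALSE], envir = cache)
  }
  new("CompoundSet", ids = x@ids[idx], smiles = x@smiles[idx], fpCache = cache)
})

#' Combine compound sets
#'
#' @param ... [CompoundSet-class] objects with pairwise distinct ids.
#' @return a single [CompoundSet-class]; fingerprint kinds cached in every
#'   input are carried over.
#' @export
combineCompounds <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, is, TRUE, class2 = "CompoundSet")))
  allIds <- unlist(lapply(sets, ids))
  if (anyDuplicated(allIds)) {
    dup <- unique(allIds[duplicated(allIds)])
    stop("cannot combine: duplicate compound id(s): ", paste(head(dup, 5), collapse = ", "))
  }
  kinds <- Reduce(intersect, lapply(sets, function(s) ls(s@fpCache)))
  cache <- new.env(parent = emptyenv())
  for (kind in kinds) {
    assign(kind, do.call(rbind, lapply(sets, function(s) get(kind, envir = s@fpCache))),
           envir = cache)
  }
  new("CompoundSet", ids = allIds,
      smiles = unlist(lapply(sets, function(s) s@smiles)), fpCache = cache)
}

#' Construct an abstract CompoundSet from pre-computed fingerprints
#'
#' Used by the synthetic generator's bit-vector mode: compounds carry no
#' structure, only fingerprint bit matrices, so model and evaluation code can
#' be exercised without any chemistry toolkit in the loop.
#'
#' @param ids compound ids.
#' @param fingerprints named list mapping fingerprint kind to a 0/1 matrix
#'   with `length(ids)` rows.
#' @return a [CompoundSet-class] with `NA` SMILES and a pre-seeded cache.
#' @export
abstractCompounds <- function(ids, fingerprints) {
  stopifnot(is.list(fingerprints), length(fingerprints) > 0L,
            !is.null(names(fingerprints)))
  cache <- new.env(parent = emptyenv())
  for (kind in names(fingerprints)) {
    m <- fingerprints[[kind]]
    if (!kind %in% fingerprintKinds()) stop("unknown fingerprint kind: ", kind)
    if (nrow(m) != length(ids)) stop("fingerprint matrix rows must match ids")
    if (ncol(m) != fingerprintLength(kind)) {
      stop(sprintf("kind %s requires %d bits, got %d", kind, fingerprintLength(kind), ncol(m)))
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    assign(kind, m, envir = cache)
  }
  new("CompoundSet", ids = as.character(ids),
      smiles = rep(NA_character_, length(ids)), fpCache = cache)
}
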