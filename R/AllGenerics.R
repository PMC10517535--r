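#' Compound identifiers
#'
#' @param x a [CompoundSet-class], [FingerprintSet-class] or
#'   [SyntheticUniverse-class].
#' @return character vector of compound ids.
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' Canonical SMILES of a compound collection
#'
#' @param x a [CompoundSet-class].
#' @return named character vector of canonical SMILES (`NA` for abstract
#'   fingerprint-only compounds).
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' Tanimoto similarity between fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both bit vectors are all-zero
#' (degenerate molecules must not poison screening with NaN). Both arguments
#' must hold fingerprints of the same kind.
#'
#' @param a,b [FingerprintSet-class] objects of equal kind; lengths must match
#'   or either may have a single row (recycled).
#' @return numeric vector of similarities in `[0, 1]`.
#' @seealso [tanimotoMatrix()] for the full cross matrix.
#' @export
setGeneric("tanimoto", function(a, b) standardGeneric("tanimoto"))

#' Pair table of a ChemicalPairs object
#'
#' @param x a [ChemicalPairs-class].
#' @return data.frame with columns `compound_a`, `compound_b`, `label`,
#'   `scheme`.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' Number of pairs
#'
#' @param x a [ChemicalPairs-class].
#' @return integer pair count.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
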