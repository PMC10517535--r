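# Binary fingerprints. MACCS166, SUBSTRUCT_FP4 and the folded Morgan kind are
# produced by Open Babel; PATH5_2048 (linear subgraph paths up to 5 bonds) and
# FCFP6_LIKE (functional-class circular fingerprint, radius 3) are implemented
# here on the heavy-atom molecular graph.

.FP_LENGTHS <- c(MACCS166 = 166L, SUBSTRUCT_FP4 = 512L, MORGAN_R2_1024 = 1024L,
                 PATH5_2048 = 2048L, FCFP6_LIKE = 1024L)

#' Supported fingerprint kinds
#'
#' * `MACCS166` - the 166 MACCS structural keys (Open Babel).
#' * `SUBSTRUCT_FP4` - Open Babel's FP4 SMARTS-pattern substructure
#'   fingerprint, 512 bits.
#' * `MORGAN_R2_1024` - radius-2 circular (Morgan/ECFP4-style) fingerprint
#'   folded to 1024 bits.
#' * `PATH5_2048` - linear subgraph paths of 1-5 bonds hashed to 2048 bits
#'   (an RDKit-path-style fingerprint used for clustering tested molecules).
#' * `FCFP6_LIKE` - functional-class circular fingerprint, radius 3, 1024
#'   bits, with atoms typed by pharmacophoric class rather than element.
#'   FCFP-style bit definitions vary across toolkits, so the kind used by a
#'   model or filter is always recorded in its metadata.
#'
#' @return character vector of kind names.
#' @export
fingerprintKinds <- function() names(.FP_LENGTHS)

#' Bit length of a fingerprint kind
#'
#' @param kind one of [fingerprintKinds()].
#' @return integer number of bits.
#' @export
fingerprintLength <- function(kind) {
  if (!kind %in% names(.FP_LENGTHS)) {
    stop("unsupported fingerprint kind '", kind, "'; supported kinds: ",
         paste(fingerprintKinds(), collapse = ", "))
  }
  .FP_LENGTHS[[kind]]
}

# ---- Open Babel backed kinds -------------------------------------------------

.obFingerprints <- function(smiles, ids, obName) {
  txt <- paste(smiles, ids, collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", txt, identity)
  m <- ChemmineOB::fingerprint_OB(mols, obName)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)  # single molecule
  if (nrow(m) != length(ids)) stop("fingerprint computation dropped molecules")
  storage.mode(m) <- "integer"
  m
}

# ---- Molecular graph for the hand-rolled kinds ------------------------------

# Heavy-atom graph from a canonical SMILES: element symbols plus an edge list
# with (kekulized) bond orders.
.molGraph <- function(smi) {
  sdf <- ChemmineR::smiles2sdf(setNames(smi, "m"))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    edges <- matrix(integer(), ncol = 3)
  } else {
    edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  ord <- vector("list", n)
  for (i in seq_len(n)) ord[[i]] <- integer()
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]; o <- edges[r, 3]
      adj[[a]] <- c(adj[[a]], b); ord[[a]] <- c(ord[[a]], o)
      adj[[b]] <- c(adj[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  list(elem = elem, edges = edges, adj = adj, ord = ord, n = n)
}

# Atoms sitting on at least one cycle: an edge lies on a cycle iff removing it
# leaves its endpoints connected. Molecules are tiny, so a per-edge BFS is fine.
.ringAtoms <- function(g) {
  inRing <- rep(FALSE, g$n)
  if (!nrow(g$edges)) return(inRing)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1]; b <- g$edges[r, 2]
    seen <- rep(FALSE, g$n); seen[a] <- TRUE
    queue <- a
    while (length(queue) && !seen[b]) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_along(g$adj[[v]])) {
        w <- g$adj[[v]][k]
        if ((v == a && w == b) || (v == b && w == a)) next  # skip the edge itself
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    if (seen[b]) { inRing[a] <- TRUE; inRing[b] <- TRUE }
  }
  inRing
}

.ELEMENT_CODES <- c(C = 1, N = 2, O = 3, S = 4, P = 5, F = 6, Cl = 7, Br = 8,
                    I = 9, B = 10, Si = 11, Se = 12, H = 13)

.elemCode <- function(elem) {
  code <- .ELEMENT_CODES[elem]
  code[is.na(code)] <- 99
  unname(code)
}

# Linear path fingerprint: all simple paths of 1..maxBonds bonds, each path
# canonicalized as the lexicographically smaller of its two directions over
# the (element, bond-order) token sequence, hashed onto nbits bits.
.pathBits <- function(g, maxBonds = 5L, nbits = 2048L) {
  bits <- integer(nbits)
  if (!g$n) return(bits)
  codes <- .elemCode(g$elem)
  emit <- function(tokens) {
    rev_tokens <- rev(tokens)
    canon <- if (paste(tokens, collapse = ",") <= paste(rev_tokens, collapse = ","))
      tokens else rev_tokens
    bits[(hashTokens(canon) %% nbits) + 1L] <<- 1L
  }
  walk <- function(path, tokens, visited) {
    if ((length(path) - 1L) >= 1L) emit(tokens)
    if ((length(path) - 1L) >= maxBonds) return()
    v <- path[length(path)]
    for (k in seq_along(g$adj[[v]])) {
      w <- g$adj[[v]][k]
      if (visited[w]) next
      visited[w] <- TRUE
      walk(c(path, w), c(tokens, 100 + g$ord[[v]][k], codes[w]), visited)
      visited[w] <- FALSE
    }
  }
  for (a in seq_len(g$n)) {
    visited <- rep(FALSE, g$n); visited[a] <- TRUE
    walk(a, codes[a], visited)
  }
  bits
}

# Pharmacophoric atom-class flags used as the initial invariants of the
# functional-class circular fingerprint. Heuristic on the heavy-atom graph:
# donor-like N/O (low heavy degree, so likely protonated), acceptor N/O/S,
# halogen, carbon, high degree (>=3), ring membership.
.atomClasses <- function(g) {
  inRing <- .ringAtoms(g)
  deg <- lengths(g$adj)
  t(vapply(seq_len(g$n), function(i) {
    e <- g$elem[i]
    c(donor = as.integer((e == "N" && deg[i] <= 2) || (e == "O" && deg[i] <= 1)),
      acceptor = as.integer(e %in% c("N", "O", "S")),
      halogen = as.integer(e %in% c("F", "Cl", "Br", "I")),
      carbon = as.integer(e == "C"),
      branched = as.integer(deg[i] >= 3),
      ring = as.integer(inRing[i]))
  }, numeric(6)))
}

# Morgan-style iteration: the invariant of an atom at radius r hashes its
# previous invariant with the sorted (bond order, neighbour invariant) list;
# every invariant reached at radii 0..radius sets one folded bit.
.circularBits <- function(g, initInv, radius = 3L, nbits = 1024L) {
  bits <- integer(nbits)
  if (!g$n) return(bits)
  inv <- initInv
  bits[(inv %% nbits) + 1L] <- 1L
  for (r in seq_len(radius)) {
    newInv <- numeric(g$n)
    for (i in seq_len(g$n)) {
      nb <- g$adj[[i]]
      if (!length(nb)) { newInv[i] <- inv[i]; next }
      env <- sort(g$ord[[i]] * 2200000000 + inv[nb])
      newInv[i] <- hashTokens(c(r, inv[i], env %% 2147483647))
    }
    inv <- newInv
    bits[(inv %% nbits) + 1L] <- 1L
  }
  bits
}

.fcfpBits <- function(g, nbits = 1024L) {
  cls <- .atomClasses(g)
  initInv <- apply(cls, 1, function(f) hashTokens(f))
  .circularBits(g, initInv, radius = 3L, nbits = nbits)
}

.graphFingerprints <- function(smiles, ids, kind) {
  n <- length(smiles)
  nb <- fingerprintLength(kind)
  out <- matrix(0L, nrow = n, ncol = nb)
  for (i in seq_len(n)) {
    g <- .molGraph(smiles[i])
    out[i, ] <- if (kind == "PATH5_2048") .pathBits(g, 5L, nb) else .fcfpBits(g, nb)
  }
  out
}

# ---- Public surface ----------------------------------------------------------

#' Compute (and cache) fingerprints of one kind for a compound set
#'
#' Deterministic: the same canonical SMILES always yields the same bit vector.
#' Results are cached inside the [CompoundSet-class]; repeated calls return
#' the cached matrix. Abstract compounds (no SMILES) must already carry a
#' cached matrix for the requested kind.
#'
#' @param cpds a [CompoundSet-class].
#' @param kind one of [fingerprintKinds()].
#' @return a [FingerprintSet-class].
#' @examples
#' cpds <- parseCompounds("bz", "c1ccccc1")
#' fp <- computeFingerprint(cpds, "MACCS166")
#' sum(fp@bits)  # aromatic-ring keys are set
#' @export
computeFingerprint <- function(cpds, kind) {
  stopifnot(is(cpds, "CompoundSet"))
  nb <- fingerprintLength(kind)  # also validates the kind
  if (exists(kind, envir = cpds@fpCache, inherits = FALSE)) {
    return(new("FingerprintSet", kind = kind,
               bits = get(kind, envir = cpds@fpCache)))
  }
  if (anyNA(cpds@smiles)) {
    bad <- cpds@ids[is.na(cpds@smiles)]
    stop("no SMILES and no cached ", kind, " fingerprint for compound(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (length(cpds) == 0L) {
    m <- matrix(integer(), nrow = 0L, ncol = nb)
  } else if (kind == "MACCS166") {
    m <- .obFingerprints(cpds@smiles, cpds@ids, "MACCS")[, seq_len(166L), drop = FALSE]
  } else if (kind == "SUBSTRUCT_FP4") {
    m <- .obFingerprints(cpds@smiles, cpds@ids, "FP4")
  } else if (kind == "MORGAN_R2_1024") {
    wide <- .obFingerprints(cpds@smiles, cpds@ids, "ECFP4")
    m <- matrix(0L, nrow = nrow(wide), ncol = 1024L)
    for (blk in seq_len(ncol(wide) / 1024L)) {
      m <- m | wide[, (blk - 1L) * 1024L + seq_len(1024L), drop = FALSE]
    }
    storage.mode(m) <- "integer"
  } else {
    m <- .graphFingerprints(cpds@smiles, cpds@ids, kind)
  }
  rownames(m) <- cpds@ids
  assign(kind, m, envir = cpds@fpCache)
  new("FingerprintSet", kind = kind, bits = m)
}

#' @describeIn ids ids of a FingerprintSet
#' @export
setMethod("ids", "FingerprintSet", function(x) rownames(x@bits))

setMethod("length", "FingerprintSet", function(x) nrow(x@bits))

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d x %s (%d bits), mean popcount %.1f\n",
              nrow(object@bits), object@kind, ncol(object@bits),
              if (nrow(object@bits)) mean(rowSums(object@bits)) else 0))
})

#' Bit matrix of a FingerprintSet
#'
#' @param fp a [FingerprintSet-class].
#' @return 0/1 integer matrix, rownames are compound ids.
#' @export
fingerprintBits <- function(fp) {
  stopifnot(is(fp, "FingerprintSet"))
  fp@bits
}

#' Build a FingerprintSet from a raw bit matrix
#'
#' @param kind fingerprint kind.
#' @param bits 0/1 matrix with compound-id rownames and
#'   [fingerprintLength()] columns.
#' @return a [FingerprintSet-class].
#' @export
fingerprintSet <- function(kind, bits) {
  storage.mode(bits) <- "integer"
  new("FingerprintSet", kind = kind, bits = bits)
}

#' @describeIn tanimoto element-wise Tanimoto between two FingerprintSets
#' @export
setMethod("tanimoto", signature("FingerprintSet", "FingerprintSet"), function(a, b) {
  if (a@kind != b@kind) {
    stop("fingerprint kind mismatch: ", a@kind, " vs ", b@kind)
  }
  A <- a@bits; B <- b@bits
  if (nrow(A) != nrow(B)) {
    if (nrow(A) == 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
    else if (nrow(B) == 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
    else stop("fingerprint sets must have equal length (or either length 1)")
  }
  inter <- rowSums(A & B)
  uni <- rowSums(A | B)
  unname(ifelse(uni == 0, 0, inter / uni))
})

#' Full Tanimoto cross-similarity matrix
#'
#' @param a,b [FingerprintSet-class] objects of the same kind (`b` defaults
#'   to `a` for a self-similarity matrix).
#' @return numeric matrix `length(a) x length(b)`; all-zero vs all-zero
#'   pairs get similarity 0.
#' @export
tanimotoMatrix <- function(a, b = a) {
  stopifnot(is(a, "FingerprintSet"), is(b, "FingerprintSet"))
  if (a@kind != b@kind) stop("fingerprint kind mismatch: ", a@kind, " vs ", b@kind)
  A <- a@bits; B <- b@bits
  inter <- tcrossprod(A, B)
  uni <- outer(rowSums(A), rowSums(B), `+`) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(rownames(A), rownames(B))
  sim
}

#' Write / read a fingerprint cache as CSV of bit strings
#'
#' Plain-text cache format: columns `id` and `bits` (a string of 0/1
#' characters of the kind's fixed length).
#'
#' @param fp a [FingerprintSet-class].
#' @param path CSV path.
#' @return `writeFingerprints` returns the path invisibly;
#'   `readFingerprints` returns a [FingerprintSet-class].
#' @export
writeFingerprints <- function(fp, path) {
  stopifnot(is(fp, "FingerprintSet"))
  df <- data.frame(id = rownames(fp@bits),
                   bits = apply(fp@bits, 1, paste, collapse = ""),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFingerprints
#' @param kind fingerprint kind the file holds.
#' @export
readFingerprints <- function(path, kind) {
  nb <- fingerprintLength(kind)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  m <- t(vapply(df$bits, function(s) as.integer(strsplit(s, "")[[1]]), integer(nb)))
  rownames(m) <- df$id
  fingerprintSet(kind, m)
}
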