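# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops over bits, thresholds and compounds.

bruteTanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- 0L; uni <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1L && b[i] == 1L) inter <- inter + 1L
    if (a[i] == 1L || b[i] == 1L) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

# Enumerates every distinct score threshold and recomputes precision/recall
# from scratch at each one.
bruteAucpr <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  area <- 0
  prevRecall <- 0
  for (th in thresholds) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / P
    area <- area + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  area
}

# Plain re-simulation of leader clustering: neighbors at >= cutoff, leader =
# unassigned compound with most unassigned neighbors, ties by smallest id.
bruteButina <- function(sim, cutoff) {
  cpdIds <- rownames(sim)
  unassigned <- cpdIds
  out <- list()
  while (length(unassigned)) {
    best <- NULL; bestCount <- -1
    for (id in sort(unassigned)) {
      count <- 0
      for (other in unassigned) {
        if (other != id && sim[id, other] >= cutoff) count <- count + 1
      }
      if (count > bestCount) { best <- id; bestCount <- count }
    }
    members <- best
    for (other in unassigned) {
      if (other != best && sim[best, other] >= cutoff) members <- c(members, other)
    }
    out[[length(out) + 1L]] <- list(center = best, members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  out
}

randomFingerprintSet <- function(n, kind = "MACCS166", p = 0.2, prefix = "r") {
  len <- fingerprintLength(kind)
  m <- matrix(as.integer(runif(n * len) < p), nrow = n)
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(n))
  fingerprintSet(kind, m)
}
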