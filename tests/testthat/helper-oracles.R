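# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the most naive route available, without touching
# the implementation paths they check.

# naive per-position re-lookup of a structural profile
oracle_profile <- function(sequence, table) {
  k <- table$order
  L <- nchar(sequence)
  out <- numeric(L - k + 1)
  for (i in seq_along(out)) {
    out[i] <- table$values[[substr(sequence, i, i + k - 1)]]
  }
  out
}

# direct-formula metrics from a 2x2 confusion matrix (actual x predicted)
oracle_f <- function(cm, cls) {
  tp <- cm[cls, cls]
  p <- tp / sum(cm[, cls])
  r <- tp / sum(cm[cls, ])
  if (!is.finite(p)) p <- 0
  if (!is.finite(r)) r <- 0
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}
oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) 0 else (po - pe) / (1 - pe)
}

random_cm <- function() {
  matrix(sample.int(120, 4, replace = TRUE) - 1L, 2, 2,
         dimnames = list(c("promoter", "non-promoter"),
                         c("promoter", "non-promoter")))
}

# exhaustive within-block permutation enumeration of the Friedman rank-sum
# statistic T = sum_j (R_j - N(k+1)/2)^2 (tiny N only)
oracle_friedman_exact_p <- function(scores) {
  N <- nrow(scores); k <- ncol(scores)
  r <- t(apply(scores, 1, rank))
  Tobs <- sum((colSums(r) - N * (k + 1) / 2)^2)
  perms <- promstruct:::permutations(k)
  np <- nrow(perms)
  idx <- rep(1L, N)
  total <- 0; extreme <- 0
  repeat {
    s <- colSums(perms[idx, , drop = FALSE])
    total <- total + 1
    if (sum((s - N * (k + 1) / 2)^2) >= Tobs - 1e-9) extreme <- extreme + 1
    j <- N
    while (j >= 1) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L; j <- j - 1
    }
    if (j < 1) break
  }
  extreme / total
}

# brute-force exclusion-distance check: every base of every window at least
# min_dist from every excluded point
oracle_min_exclusion_distance <- function(coords, L, tss, genes) {
  pts <- c(tss$position, genes$start, genes$end - 1L)
  mins <- vapply(seq_len(nrow(coords)), function(i) {
    bases <- coords$start[i]:(coords$start[i] + L - 1L)
    min(abs(outer(bases, pts, "-")))
  }, numeric(1))
  min(mins)
}

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

zero_table <- function(order = 2, name = "flat") {
  property_table(name, order,
                 setNames(rep(0, 4^order), promstruct:::all_kmers(order)))
}

toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}
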