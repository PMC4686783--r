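#' Matched score matrix (blocks x treatments)
#'
#' Container for matched comparison: rows are blocks (cross-validation
#' folds), columns are treatments (datasets or classifiers). Every cell must
#' be present.
#'
#' @param scores Numeric matrix, N blocks x k treatments, k >= 2, N >= 2.
#' @return Object of class `matched_scores`.
#' @export
matched_scores <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need at least 2 treatments (columns)")
  if (nrow(scores) < 2) stop("need at least 2 blocks (rows)")
  if (anyNA(scores)) stop("matched scores must have no missing cells")
  storage.mode(scores) <- "double"
  structure(scores, class = c("matched_scores", "matrix"))
}

block_ranks <- function(scores) {
  t(apply(scores, 1, rank))  # average ranks on ties
}

#' Friedman rank test over matched blocks
#'
#' Ranks treatments within each block (average ranks on ties) and tests the
#' null of exchangeable treatments with the tie-corrected chi-square
#' statistic (Conover form), `df = k - 1`. With `method = "exact"` (or
#' `"auto"` for small problems) the p-value is computed by exact enumeration
#' of all `k!^N` equally likely within-block rank orderings via dynamic
#' programming over rank-sum vectors; the enumeration assumes tie-free
#' blocks. The Iman-Davenport F refinement is available via
#' `method = "iman_davenport"`.
#'
#' @param scores A [matched_scores()] matrix (or coercible).
#' @param method `"chisq"` (default), `"exact"`, `"auto"`, or
#'   `"iman_davenport"`.
#' @return List of class `friedman_result`: `statistic`, `p_value`,
#'   `mean_ranks`, `method`, `N`, `k`.
#' @export
friedman_test_ranks <- function(scores,
                                method = c("chisq", "exact", "auto",
                                           "iman_davenport")) {
  method <- match.arg(method)
  scores <- matched_scores(unclass(scores))
  N <- nrow(scores); k <- ncol(scores)
  r <- block_ranks(scores)
  Rj <- colSums(r)
  Tstat <- sum((Rj - N * (k + 1) / 2)^2)
  A <- sum(r^2)
  Cc <- N * k * (k + 1)^2 / 4
  if (A - Cc <= 0) {
    chisq <- 0
  } else {
    chisq <- (k - 1) * Tstat / (A - Cc)
  }
  if (method == "auto") {
    method <- if (N * factorial(k) <= 1e5) "exact" else "chisq"
  }
  p <- switch(method,
    chisq = if (chisq == 0) 1 else pchisq(chisq, df = k - 1, lower.tail = FALSE),
    iman_davenport = {
      if (chisq == 0) 1
      else if (N * (k - 1) - chisq <= 0) 0
      else {
        fstat <- (N - 1) * chisq / (N * (k - 1) - chisq)
        stats::pf(fstat, k - 1, (N - 1) * (k - 1), lower.tail = FALSE)
      }
    },
    exact = friedman_exact_p(Tstat, N, k)
  )
  structure(list(statistic = chisq, p_value = p,
                 mean_ranks = Rj / N, method = method, N = N, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test (%s): chi-squared = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$k - 1, x$p_value))
  cat("mean ranks:", paste(sprintf("%.2f", x$mean_ranks), collapse = " "), "\n")
  invisible(x)
}

permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(k)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(k)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Exact null distribution of T = sum_j (R_j - N(k+1)/2)^2 by convolving the
# per-block rank-vector distribution over N blocks (tie-free orderings).
# Rank-sum vectors of the first k-1 treatments are integer-encoded in base
# (N*k + 1); adding one block's permutation is then a uniform index shift,
# so each convolution step is a handful of vectorized adds.
friedman_exact_p <- function(T_obs, N, k) {
  perms <- permutations(k)
  base <- N * k + 1L
  shift <- as.integer(perms[, -k, drop = FALSE] %*% base^(seq_len(k - 1L) - 1L))
  size <- base^(k - 1L)
  if (size > 5e7) {
    stop(sprintf(
      "exact enumeration infeasible for N = %d, k = %d; use method = 'chisq'",
      N, k))
  }
  dist <- numeric(size)
  dist[1] <- 1  # code 0: all rank sums zero
  for (b in seq_len(N)) {
    nxt <- numeric(size)
    nz <- which(dist > 0)
    for (s in shift) {
      idx <- nz + s
      nxt[idx] <- nxt[idx] + dist[nz]
    }
    dist <- nxt
  }
  nz <- which(dist > 0)
  codes <- nz - 1L
  sums <- matrix(0, length(nz), k)
  rest <- codes
  for (j in seq_len(k - 1L)) {
    sums[, j] <- rest %% base
    rest <- rest %/% base
  }
  sums[, k] <- N * k * (k + 1) / 2 - rowSums(sums[, -k, drop = FALSE])
  centre <- N * (k + 1) / 2
  Tvals <- rowSums((sums - centre)^2)
  sum(dist[nz][Tvals >= T_obs - 1e-9]) / sum(dist[nz])
}

.q_cache <- new.env(parent = emptyenv())

nemenyi_q <- function(k, alpha) {
  if (is.null(.q_cache$tab)) {
    path <- system.file("extdata", "nemenyi_q.tsv", package = "promstruct")
    if (!nzchar(path)) stop("bundled Nemenyi critical-value table not found")
    .q_cache$tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#")
  }
  tab <- .q_cache$tab
  col <- switch(as.character(alpha), "0.05" = "q_0.05", "0.1" = "q_0.10",
                "0.10" = "q_0.10",
                stop("alpha must be 0.05 or 0.10 (bundled table)"))
  row <- tab[tab$k == k, ]
  if (nrow(row) != 1) {
    stop(sprintf("k = %d outside the bundled critical-value table (2..20)", k))
  }
  row[[col]]
}

#' Nemenyi post-hoc test
#'
#' Declares treatments i and j significantly different when their mean-rank
#' gap reaches the critical difference `CD = q_alpha * sqrt(k(k+1)/(6N))`,
#' with `q_alpha` the infinite-df studentized-range quantile divided by
#' sqrt(2) (bundled for k = 2..20, alpha in \{0.05, 0.10\}). Usually run
#' after a Friedman rejection; the test itself runs unconditionally.
#'
#' @param scores A [matched_scores()] matrix.
#' @param alpha Significance level, 0.05 (default) or 0.10.
#' @return Object of class `significance_matrix`: list with `significant`
#'   (symmetric logical k x k, `FALSE` diagonal), `mean_ranks`, `cd`,
#'   `alpha`, `q`.
#' @export
nemenyi_test <- function(scores, alpha = 0.05) {
  scores <- matched_scores(unclass(scores))
  N <- nrow(scores); k <- ncol(scores)
  mean_ranks <- colMeans(block_ranks(scores))
  q <- nemenyi_q(k, alpha)
  cd <- q * sqrt(k * (k + 1) / (6 * N))
  diffs <- abs(outer(mean_ranks, mean_ranks, "-"))
  sig <- diffs >= cd
  diag(sig) <- FALSE
  nm <- colnames(scores)
  if (is.null(nm)) nm <- paste0("T", seq_len(k))
  dimnames(sig) <- list(nm, nm)
  names(mean_ranks) <- nm
  structure(list(significant = sig, mean_ranks = mean_ranks, cd = cd,
                 alpha = alpha, q = q),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  k <- ncol(x$significant)
  cat(sprintf("Nemenyi post-hoc (alpha = %.2f): CD = %.4f\n", x$alpha, x$cd))
  m <- matrix("-", k, k, dimnames = dimnames(x$significant))
  m[lower.tri(m, diag = TRUE)] <-
    ifelse(x$significant[lower.tri(x$significant, diag = TRUE)], "T", "F")
  print(as.data.frame(m), right = TRUE)
  invisible(x)
}

#' Friedman + Nemenyi comparison over a sweep results table
#'
#' Reshapes the long-format table from [sweep_datasets()] into one matched
#' block design per group: with `group_by = "datasets"` each classifier
#' yields a folds x datasets score matrix (blocks = shared CV folds,
#' treatments = datasets) tested with [friedman_test_ranks()] and
#' [nemenyi_test()]; with `group_by = "classifiers"` the roles of dataset
#' and classifier are swapped.
#'
#' @param results Long-format data frame with columns `dataset`,
#'   `classifier`, `fold` and the score column.
#' @param group_by Treatments: `"datasets"` or `"classifiers"`.
#' @param metric Score column name (default `"f_macro"`).
#' @param alpha Significance level for the Nemenyi matrices.
#' @param method Friedman p-value method (see [friedman_test_ranks()]).
#' @return Named list (one element per classifier or per dataset), each with
#'   `friedman` and `nemenyi` components.
#' @export
compare_report <- function(results, group_by = c("datasets", "classifiers"),
                           metric = "f_macro", alpha = 0.05,
                           method = "chisq") {
  group_by <- match.arg(group_by)
  stopifnot(all(c("dataset", "classifier", "fold", metric) %in% names(results)))
  if (group_by == "datasets") {
    outer_col <- "classifier"; treat_col <- "dataset"
  } else {
    outer_col <- "dataset"; treat_col <- "classifier"
  }
  treatments <- unique(results[[treat_col]])
  if (length(treatments) < 2) {
    stop(sprintf("need at least 2 %s to compare, got %d",
                 group_by, length(treatments)))
  }
  out <- list()
  for (g in unique(results[[outer_col]])) {
    sub <- results[results[[outer_col]] == g, , drop = FALSE]
    folds <- sort(unique(sub$fold))
    m <- matrix(NA_real_, length(folds), length(treatments),
                dimnames = list(folds, treatments))
    for (i in seq_len(nrow(sub))) {
      m[as.character(sub$fold[i]), sub[[treat_col]][i]] <- sub[[metric]][i]
    }
    if (anyNA(m)) {
      gaps <- which(is.na(m), arr.ind = TRUE)
      stop(sprintf("incomplete results for %s '%s': missing %s",
                   outer_col, g,
                   paste(sprintf("(fold %s, %s)", rownames(m)[gaps[, 1]],
                                 colnames(m)[gaps[, 2]]),
                         collapse = ", ")))
    }
    out[[g]] <- list(friedman = friedman_test_ranks(m, method = method),
                     nemenyi = nemenyi_test(m, alpha = alpha))
  }
  out
}
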