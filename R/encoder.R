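check_acgt <- function(sequence) {
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(sequence, bad, bad), bad),
         call. = FALSE)
  }
  invisible(sequence)
}

#' Encode one sequence into a single-property structural profile
#'
#' Slides a window of width `table$order` along the sequence and looks each
#' k-mer up in the property table, yielding a vector of `L - order + 1`
#' values for a sequence of length L (the "structural profile" of the
#' property along the sequence).
#'
#' @param sequence Nucleotide string over \{A, C, G, T\} (uppercased first).
#' @param table A [property_table()].
#' @return Numeric vector of length `nchar(sequence) - table$order + 1`,
#'   with attributes `property` (the table name) and `offsets` (0-based
#'   start offset of each k-mer).
#' @examples
#' bse <- builtin_registry()$tables$base_stack_energy
#' encode_profile("AAC", bse)  # c(-5.37, -10.51)
#' @export
encode_profile <- function(sequence, table) {
  stopifnot(inherits(table, "property_table"))
  sequence <- toupper(sequence)
  check_acgt(sequence)
  L <- nchar(sequence)
  k <- table$order
  if (L < k) {
    stop(sprintf("sequence length %d is shorter than table order %d", L, k))
  }
  starts <- seq_len(L - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  out <- unname(table$values[kmers])
  attr(out, "property") <- table$name
  attr(out, "offsets") <- starts - 1L
  out
}

#' Encode one sequence into a concatenated feature vector
#'
#' Computes the structural profile of every property in the registry and
#' concatenates them in registry order (property-major, position-minor), the
#' fixed feature layout of this package. For the canonical registry (11
#' dinucleotide + 2 trinucleotide properties) a window of L nucleotides
#' yields `11 * (L - 1) + 2 * (L - 2)` features; e.g. 3898 for L = 301.
#'
#' @param sequence Nucleotide string over \{A, C, G, T\}.
#' @param registry A [property_registry()].
#' @return Named numeric vector; names are `<property>_<i>` with `i` the
#'   1-based profile position.
#' @export
encode_features <- function(sequence, registry) {
  stopifnot(inherits(registry, "property_registry"))
  parts <- lapply(registry$tables, function(t) encode_profile(sequence, t))
  out <- unlist(lapply(parts, as.numeric), use.names = FALSE)
  names(out) <- feature_names(nchar(sequence), registry)
  out
}

feature_names <- function(L, registry) {
  unlist(lapply(registry$tables, function(t) {
    sprintf("%s_%d", t$name, seq_len(L - t$order + 1L))
  }), use.names = FALSE)
}

#' Number of predictor attributes for a window length
#'
#' @param length_or_spec Either a window length L (integer) or a
#'   [window_spec()], whose length is `upstream + downstream + 1`.
#' @param registry A [property_registry()] (canonical registry by default).
#' @return Integer: `sum(L - order_p + 1)` over the registry's properties.
#' @examples
#' feature_count(window_spec(250, 50))  # 3898
#' @export
feature_count <- function(length_or_spec, registry = builtin_registry()) {
  L <- if (inherits(length_or_spec, "window_spec")) {
    window_length(length_or_spec)
  } else {
    as.integer(length_or_spec)
  }
  sum(L - registry_orders(registry) + 1L)
}

#' Encode a labelled sequence set into a feature matrix
#'
#' Applies [encode_features()] to every sequence (all of one length) and
#' stacks the vectors into a numeric matrix with one row per sequence, the
#' dataset representation consumed by [run_cv()]. Row order follows input
#' order; labels are carried through unchanged.
#'
#' @param sequences A `labeled_sequences` data frame (see
#'   [assemble_dataset()], [synth_labeled_set()]) or any data frame with
#'   columns `id`, `bases`, `label`.
#' @param registry A [property_registry()].
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, named columns), `labels` (factor with levels `promoter`,
#'   `non-promoter`) and `ids`.
#' @export
encode_dataset <- function(sequences, registry = builtin_registry()) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "bases", "label") %in% names(sequences)))
  n <- nrow(sequences)
  labels <- factor(sequences$label, levels = c("promoter", "non-promoter"))
  if (n == 0) {
    # degenerate: typed empty matrix with defined column layout for L = 0
    x <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(structure(list(x = x, labels = labels, ids = character(0)),
                     class = "feature_matrix"))
  }
  if (anyNA(labels)) stop("labels must be 'promoter' or 'non-promoter'")
  seqs <- toupper(sequences$bases)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop(sprintf("all sequences must have the same length (found %s)",
                 paste(sort(unique(lens)), collapse = ", ")))
  }
  L <- lens[1]
  for (s in seqs) check_acgt(s)
  # property-wise vectorized lookup: one n x (L - k + 1) block per property
  blocks <- lapply(registry$tables, function(t) {
    k <- t$order
    starts <- seq_len(L - k + 1L)
    block <- vapply(starts, function(s) {
      unname(t$values[substring(seqs, s, s + k - 1L)])
    }, numeric(n))
    if (n == 1) block <- matrix(block, nrow = 1)
    block
  })
  x <- do.call(cbind, blocks)
  colnames(x) <- feature_names(L, registry)
  rownames(x) <- NULL
  structure(list(x = x, labels = labels, ids = as.character(sequences$id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' One header row, one row per sequence, and a final `class` column — the
#' flat-file interchange format for downstream tools.
#'
#' @param fm A `feature_matrix` from [encode_dataset()].
#' @param file Output path.
#' @param sep Field separator (tab by default).
#' @return `file`, invisibly.
#' @export
write_feature_matrix <- function(fm, file, sep = "\t") {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$x)
  df$class <- as.character(fm$labels)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Class-average structural profile
#'
#' Position-wise arithmetic mean of one property's profile over all
#' sequences of a class — the summary plotted to compare the average
#' promoter and non-promoter structural landscape around the TSS. Positions
#' are reported relative to the TSS (TSS base at 0) when the sequences carry
#' a `tss_offset`; otherwise as 0-based window offsets.
#'
#' @param sequences A `labeled_sequences` data frame.
#' @param property Property name (must exist in `registry`).
#' @param class_label `"promoter"` or `"non-promoter"`.
#' @param registry A [property_registry()].
#' @return Named numeric vector of position means; names are k-mer start
#'   positions relative to the TSS.
#' @export
average_profile <- function(sequences, property,
                            class_label = c("promoter", "non-promoter"),
                            registry = builtin_registry()) {
  class_label <- match.arg(class_label)
  if (!property %in% names(registry$tables)) {
    stop(sprintf("unknown property '%s'", property))
  }
  sel <- sequences[sequences$label == class_label, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop(sprintf("no sequences with label '%s'", class_label))
  }
  table <- registry$tables[[property]]
  profs <- vapply(toupper(sel$bases), function(s) encode_profile(s, table),
                  numeric(nchar(sel$bases[1]) - table$order + 1L),
                  USE.NAMES = FALSE)
  means <- if (is.matrix(profs)) rowMeans(profs) else mean(profs)
  off <- if ("tss_offset" %in% names(sel) && !anyNA(sel$tss_offset)) {
    sel$tss_offset[1]
  } else {
    0L
  }
  names(means) <- seq_along(means) - 1L - off
  means
}
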