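#' Window specification around a TSS
#'
#' A window named `"U-D"` spans `U` nucleotides upstream of the TSS, the TSS
#' base itself, and `D` nucleotides downstream, for a total length of
#' `U + D + 1`; e.g. the 250-50 window is 301 nucleotides long.
#'
#' @param upstream Non-negative integer U.
#' @param downstream Non-negative integer D.
#' @return Object of class `window_spec` with fields `upstream`,
#'   `downstream`, `name`.
#' @examples
#' window_length(window_spec(10, 30))  # 41
#' @export
window_spec <- function(upstream, downstream) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (is.na(upstream) || upstream < 0 || is.na(downstream) || downstream < 0) {
    stop("'upstream' and 'downstream' must be non-negative integers")
  }
  structure(list(upstream = upstream, downstream = downstream,
                 name = sprintf("%d-%d", upstream, downstream)),
            class = "window_spec")
}

#' @rdname window_spec
#' @param spec A `window_spec`.
#' @export
window_length <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  spec$upstream + spec$downstream + 1L
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s (length %d)\n", x$name, window_length(x)))
  invisible(x)
}

new_labeled_sequences <- function(id, bases, label, tss_offset = NA_integer_) {
  id <- as.character(id)
  structure(
    data.frame(id = id, bases = as.character(bases),
               label = as.character(label),
               tss_offset = rep_len(as.integer(tss_offset), length(id)),
               stringsAsFactors = FALSE),
    class = c("labeled_sequences", "data.frame")
  )
}

boundary_error <- function(msg) {
  stop(errorCondition(msg, class = c("promstruct_boundary_error", "error")))
}
noisy_error <- function(msg) {
  stop(errorCondition(msg, class = c("promstruct_noisy_error", "error")))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Extract a promoter window around one TSS
#'
#' Slices `upstream` bases before and `downstream` bases after the TSS (the
#' TSS base included) from the genome. On the minus strand the slice is
#' taken from the mirrored coordinates and reverse-complemented, so that
#' "upstream" always means transcriptional upstream and the TSS base sits at
#' offset `upstream` in the returned window.
#'
#' @param genome A `DNAStringSet` (or FASTA path) with named chromosomes.
#' @param chrom Chromosome name.
#' @param position 0-based genome coordinate of the TSS base.
#' @param strand `"+"` or `"-"`.
#' @param spec A [window_spec()].
#' @param id Sequence identifier for the output record.
#' @return A one-row `labeled_sequences` data frame with `label =
#'   "promoter"` and `tss_offset = spec$upstream`.
#' @export
extract_promoter_window <- function(genome, chrom, position, strand, spec,
                                    id = sprintf("%s:%d%s", chrom, position, strand)) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "window_spec"), strand %in% c("+", "-"))
  if (!chrom %in% names(genome)) stop(sprintf("unknown chromosome '%s'", chrom))
  position <- as.integer(position)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  U <- spec$upstream; D <- spec$downstream
  if (strand == "+") {
    lo <- position - U; hi <- position + D
  } else {
    lo <- position - D; hi <- position + U
  }
  if (lo < 0 || hi > len - 1) {
    boundary_error(sprintf(
      "window [%d, %d] out of bounds for %s (length %d)", lo, hi, chrom, len))
  }
  w <- Biostrings::subseq(genome[[chrom]], start = lo + 1L, end = hi + 1L)
  if (strand == "-") w <- Biostrings::reverseComplement(w)
  bases <- as.character(w)
  if (grepl("[^ACGT]", bases)) {
    noisy_error(sprintf(
      "window at %s:%d%s contains ambiguity codes", chrom, position, strand))
  }
  new_labeled_sequences(id, bases, "promoter", tss_offset = U)
}

#' Extract promoter windows for a TSS table, skipping unusable ones
#'
#' Applies [extract_promoter_window()] to every row of a TSS table. Windows
#' that run off a chromosome end or contain ambiguity codes ("noisy"
#' sequences) are skipped and counted rather than raising, mirroring the
#' usual practice of excluding such records from training sets.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param tss Data frame with columns `chrom`, `position` (0-based),
#'   `strand` (see [read_tss_bed()]).
#' @param spec A [window_spec()].
#' @return A `labeled_sequences` data frame; attribute `skipped` holds the
#'   counts of boundary- and noise-skipped records.
#' @export
extract_promoter_windows <- function(genome, tss, spec) {
  genome <- as_genome(genome)
  out <- vector("list", nrow(tss))
  skipped <- c(boundary = 0L, noisy = 0L)
  for (i in seq_len(nrow(tss))) {
    rec <- tryCatch(
      extract_promoter_window(genome, tss$chrom[i], tss$position[i],
                              tss$strand[i], spec,
                              id = sprintf("prom_%05d", i)),
      promstruct_boundary_error = function(e) "boundary",
      promstruct_noisy_error = function(e) "noisy"
    )
    if (is.character(rec)) {
      skipped[rec] <- skipped[rec] + 1L
    } else {
      out[[i]] <- rec
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- new_labeled_sequences(character(0), character(0),
                                                 character(0))
  attr(res, "skipped") <- skipped
  res
}

# forbidden start positions induced by one excluded point p, for windows of
# length L whose every base must lie >= min_dist from p
forbidden_starts <- function(points, L, min_dist) {
  IRanges::IRanges(start = points - min_dist + 1L - (L - 1L),
                   end = points + min_dist - 1L)
}

eligible_starts_by_chrom <- function(genome, tss, genes, L, min_dist) {
  chroms <- names(genome)
  lens <- stats::setNames(Biostrings::width(genome), chroms)
  lapply(stats::setNames(chroms, chroms), function(ch) {
    if (lens[[ch]] < L) return(IRanges::IRanges())
    valid <- IRanges::IRanges(start = 0L, end = lens[[ch]] - L)
    pts <- integer(0)
    if (!is.null(tss) && nrow(tss)) {
      pts <- c(pts, tss$position[tss$chrom == ch])
    }
    if (!is.null(genes) && nrow(genes)) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      pts <- c(pts, g$start, g$end - 1L)  # first and last gene base
    }
    if (!length(pts)) return(valid)
    IRanges::setdiff(valid, IRanges::reduce(forbidden_starts(pts, L, min_dist)))
  })
}

#' Sample non-promoter windows at a safe distance from annotation
#'
#' Draws `n` windows of length `L` uniformly (without replacement over start
#' positions) from the regions of the genome where every base of the window
#' lies at least `min_dist` nucleotides from every annotated TSS position
#' and from every gene start/end boundary — the construction that keeps
#' likely regulatory or transcribed positions out of the negative class.
#' Windows containing ambiguity codes are rejected and redrawn.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param tss Data frame of TSS records (`chrom`, `position`), or `NULL`.
#' @param genes Data frame of gene intervals (`chrom`, `start`, `end`,
#'   0-based half-open), or `NULL`.
#' @param n Number of windows to sample.
#' @param length Window length L.
#' @param min_dist Minimum distance in nucleotides (default 1000).
#' @param seed Integer seed; the sample is reproducible given the seed.
#' @param no_overlap If `TRUE`, sampled windows are additionally forced to
#'   be pairwise disjoint.
#' @return A `labeled_sequences` data frame with `label = "non-promoter"`;
#'   attribute `coords` records chrom/start of each window.
#' @export
sample_nonpromoters <- function(genome, tss, genes, n, length,
                                min_dist = 1000L, seed = 1L,
                                no_overlap = FALSE) {
  genome <- as_genome(genome)
  if (sum(Biostrings::width(genome)) == 0) stop("empty genome")
  L <- as.integer(length)
  elig <- eligible_starts_by_chrom(genome, tss, genes, L, as.integer(min_dist))
  counts <- vapply(elig, function(r) sum(IRanges::width(r)), numeric(1))
  total <- sum(counts)
  if (total < n) {
    stop(sprintf("insufficient eligible start positions: need %d, found %d",
                 n, total))
  }
  # global index -> (chrom, start) over the concatenated eligible ranges
  index_to_start <- function(idx) {
    ch <- findInterval(idx - 1, cumsum(c(0, counts)),
                       rightmost.closed = FALSE)
    within <- idx - c(0, cumsum(counts))[ch]
    r <- elig[[ch]]
    off <- findInterval(within - 1, cumsum(c(0, IRanges::width(r))))
    start <- IRanges::start(r)[off] + (within - c(0, cumsum(IRanges::width(r)))[off] - 1)
    list(chrom = names(elig)[ch], start = as.integer(start))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  drawn <- sample.int(total, min(total, n))
  pool <- setdiff(seq_len(total), drawn)
  keep <- list(); taken <- list()
  accept <- function(ch, st) {
    if (grepl("[^ACGT]", as.character(
      Biostrings::subseq(genome[[ch]], st + 1L, st + L)))) return(FALSE)
    if (no_overlap) {
      for (t in taken) {
        if (t$chrom == ch && st < t$start + L && t$start < st + L) return(FALSE)
      }
    }
    TRUE
  }
  i <- 1
  while (length(keep) < n) {
    if (i > length(drawn)) {
      if (!length(pool)) {
        stop(sprintf(
          "insufficient eligible windows after rejection: %d accepted of %d needed",
          length(keep), n))
      }
      extra <- pool[sample.int(length(pool), 1)]
      pool <- setdiff(pool, extra)
      drawn <- c(drawn, extra)
    }
    loc <- index_to_start(drawn[i])
    if (accept(loc$chrom, loc$start)) {
      taken[[length(taken) + 1]] <- loc
      keep[[length(keep) + 1]] <- as.character(
        Biostrings::subseq(genome[[loc$chrom]], loc$start + 1L, loc$start + L))
    }
    i <- i + 1
  }
  coords <- data.frame(
    chrom = vapply(taken, `[[`, "", "chrom"),
    start = vapply(taken, `[[`, 1L, "start"))
  res <- new_labeled_sequences(
    sprintf("nonprom_%05d", seq_len(n)), unlist(keep), "non-promoter")
  attr(res, "coords") <- coords
  res
}

#' Assemble a balanced, shuffled labelled dataset
#'
#' Binds equal numbers of promoter and non-promoter records and shuffles
#' them with a fixed seed, preserving the exact multiset of inputs and a
#' 50/50 class balance.
#'
#' @param promoters,nonpromoters `labeled_sequences` data frames with equal
#'   row counts.
#' @param seed Integer shuffle seed.
#' @return A `labeled_sequences` data frame.
#' @export
assemble_dataset <- function(promoters, nonpromoters, seed = 1L) {
  if (nrow(promoters) != nrow(nonpromoters)) {
    stop(sprintf("class imbalance: %d promoters vs %d non-promoters",
                 nrow(promoters), nrow(nonpromoters)))
  }
  all <- rbind(as.data.frame(promoters), as.data.frame(nonpromoters))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  out <- all[sample.int(nrow(all)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("labeled_sequences", "data.frame")
  out
}

#' Read TSS records from a BED file
#'
#' Expects single-base BED intervals; returns 0-based TSS coordinates.
#'
#' @param file BED path.
#' @return Data frame with columns `chrom`, `position` (0-based), `strand`
#'   (`*` entries become `+`).
#' @export
read_tss_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr) - 1L,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read gene intervals from a BED file
#'
#' @param file BED path.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @export
read_gene_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write a labelled sequence set as FASTA (plus optional TSV manifest)
#'
#' FASTA headers carry `label=` and, for promoters, `tss_offset=` fields so
#' the set round-trips through [read_labeled_fasta()].
#'
#' @param sequences A `labeled_sequences` data frame.
#' @param file FASTA output path.
#' @param manifest Optional TSV path for the id/label/tss_offset table.
#' @return `file`, invisibly.
#' @export
write_labeled_fasta <- function(sequences, file, manifest = NULL) {
  hdr <- sprintf("%s label=%s%s", sequences$id, sequences$label,
                 ifelse(is.na(sequences$tss_offset), "",
                        sprintf(" tss_offset=%d", sequences$tss_offset)))
  ss <- Biostrings::DNAStringSet(sequences$bases)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, file)
  if (!is.null(manifest)) {
    utils::write.table(as.data.frame(sequences)[c("id", "label", "tss_offset")],
                       manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_labeled_fasta
#' @export
read_labeled_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  label <- sub(".*label=(\\S+).*", "\\1", hdr)
  tss <- rep(NA_integer_, length(hdr))
  has <- grepl("tss_offset=", hdr)
  tss[has] <- as.integer(sub(".*tss_offset=(\\d+).*", "\\1", hdr[has]))
  new_labeled_sequences(id, as.character(ss), label, tss)
}
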