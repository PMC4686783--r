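# Promoter-class generative model at full effect: a first-order (dinucleotide)
# chain applied inside a TSS-proximal band. C<->G transitions dominate, so at
# full effect the band approaches a quasi-periodic CpG-rich consensus (a
# caricature of a CpG island) whose dinucleotide content -- and hence whose
# structural profile -- is far from the i.i.d. background and has low
# within-class variance. Rows = previous base (A, C, G, T).
PROMOTER_TRANSITIONS <- matrix(c(
  0.02, 0.58, 0.38, 0.02,
  0.02, 0.06, 0.90, 0.02,
  0.02, 0.90, 0.06, 0.02,
  0.02, 0.58, 0.38, 0.02
), nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES))
PROMOTER_INITIAL <- c(A = 0.02, C = 0.50, G = 0.46, T = 0.02)

#' Configuration for the synthetic promoter/non-promoter generator
#'
#' The generator emulates the statistical structure this package is built to
#' detect: two balanced classes of fixed-length windows where promoters
#' carry a position-dependent dinucleotide-composition bias concentrated in
#' a band around the TSS, so that class-average structural profiles differ
#' inside the band and nowhere else. `effect` interpolates linearly between
#' the background model (`effect = 0`, classes exchangeable by construction)
#' and a GC/CpG-enriched promoter chain (`effect = 1`).
#'
#' @param n_per_class Sequences per class (>= 1).
#' @param upstream,downstream Window extent around the TSS (defaults 10 and
#'   30: the 41-nt window).
#' @param effect Class-signal strength in \[0, 1\].
#' @param background_gc Background GC fraction in (0, 1); the default 0.4
#'   reflects the AT-rich composition of a mammalian genome.
#' @param seed Integer seed governing all randomness.
#' @param genome_length,n_tss,n_genes Size of the synthetic genome and its
#'   annotation (used by [synth_genome()] for sampler tests).
#' @param signal_band Length-2 integer vector: TSS-relative positions
#'   (TSS = 0) delimiting the band carrying the promoter signal.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_per_class, upstream = 10L, downstream = 30L,
                         effect = 1, background_gc = 0.4, seed = 1L,
                         genome_length = 1000000L, n_tss = 10L, n_genes = 5L,
                         signal_band = c(-30L, 10L)) {
  if (n_per_class < 1) stop("'n_per_class' must be >= 1")
  if (effect < 0 || effect > 1) stop("'effect' must be in [0, 1]")
  if (background_gc <= 0 || background_gc >= 1) {
    stop("'background_gc' must be in (0, 1)")
  }
  if (length(signal_band) != 2 || signal_band[1] > signal_band[2]) {
    stop("'signal_band' must be c(lo, hi) with lo <= hi")
  }
  structure(list(
    n_per_class = as.integer(n_per_class),
    spec = window_spec(upstream, downstream),
    effect = effect, background_gc = background_gc,
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_tss = as.integer(n_tss), n_genes = as.integer(n_genes),
    signal_band = as.integer(signal_band)
  ), class = "synth_config")
}

background_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# vectorized categorical draw: one base per row of a probability matrix
draw_bases <- function(prob) {
  u <- runif(nrow(prob))
  cp <- t(apply(prob, 1, cumsum))
  idx <- rowSums(u > cp) + 1L
  DNA_BASES[idx]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic labelled promoter/non-promoter set
#'
#' Draws `n_per_class` promoter and `n_per_class` non-promoter windows of
#' length `upstream + downstream + 1`. Non-promoters are i.i.d. background
#' bases at the configured GC. Promoters are background outside the signal
#' band; inside the band each base follows the `effect`-interpolated
#' promoter chain (see [synth_config()]). At `effect = 0` the interpolated
#' chain collapses exactly to the background, so the two classes are
#' exchangeable. Output is deterministic per seed.
#'
#' @param config A [synth_config()].
#' @return A `labeled_sequences` data frame (promoters first, then
#'   non-promoters; shuffle with [assemble_dataset()] if needed).
#' @export
synth_labeled_set <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  U <- config$spec$upstream; D <- config$spec$downstream
  L <- window_length(config$spec)
  n <- config$n_per_class
  e <- config$effect
  p_bg <- background_probs(config$background_gc)
  trans <- (1 - e) * matrix(p_bg, 4, 4, byrow = TRUE,
                            dimnames = dimnames(PROMOTER_TRANSITIONS)) +
    e * PROMOTER_TRANSITIONS
  init <- (1 - e) * p_bg + e * PROMOTER_INITIAL
  band <- config$signal_band
  positions <- (-U):D
  with_seed(config$seed, {
    prom <- matrix("", nrow = n, ncol = L)
    prev_in_band <- FALSE
    for (j in seq_len(L)) {
      pos <- positions[j]
      in_band <- pos >= band[1] && pos <= band[2]
      if (!in_band) {
        prom[, j] <- sample(DNA_BASES, n, replace = TRUE, prob = p_bg)
      } else if (!prev_in_band) {
        prom[, j] <- draw_bases(matrix(init, n, 4, byrow = TRUE))
      } else {
        prom[, j] <- draw_bases(trans[match(prom[, j - 1], DNA_BASES), ,
                                      drop = FALSE])
      }
      prev_in_band <- in_band
    }
    nonp <- matrix(sample(DNA_BASES, n * L, replace = TRUE, prob = p_bg),
                   nrow = n)
    rbind(
      new_labeled_sequences(sprintf("prom_%05d", seq_len(n)),
                            apply(prom, 1, paste, collapse = ""),
                            "promoter", tss_offset = U),
      new_labeled_sequences(sprintf("nonprom_%05d", seq_len(n)),
                            apply(nonp, 1, paste, collapse = ""),
                            "non-promoter")
    )
  })
}

#' Generate a synthetic genome with TSS and gene annotation
#'
#' Produces an i.i.d.-background single-chromosome genome at the configured
#' GC, `n_tss` TSS positions and `n_genes` non-overlapping gene intervals
#' placed uniformly — the fixture for exercising the exclusion-distance
#' negative sampler. Deterministic per seed.
#'
#' @param config A [synth_config()].
#' @param gene_length_range Length-2 vector of gene interval lengths.
#' @return List with `genome` (`DNAStringSet`, one chromosome `"chrS"`),
#'   `tss` and `genes` (data frames as in [read_tss_bed()] /
#'   [read_gene_bed()]).
#' @export
synth_genome <- function(config, gene_length_range = c(2000L, 10000L)) {
  stopifnot(inherits(config, "synth_config"))
  len <- config$genome_length
  with_seed(config$seed + 1L, {
    bases <- sample(DNA_BASES, len, replace = TRUE,
                    prob = background_probs(config$background_gc))
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chrS"
    margin <- 2000L
    if (len <= 2L * margin) stop("genome too short for annotation placement")
    tss_pos <- sort(sample(seq.int(margin, len - margin), config$n_tss))
    tss <- data.frame(chrom = "chrS", position = as.integer(tss_pos),
                      strand = sample(c("+", "-"), config$n_tss, replace = TRUE),
                      stringsAsFactors = FALSE)
    genes <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
    placed <- IRanges::IRanges()
    tries <- 0L
    while (nrow(genes) < config$n_genes) {
      tries <- tries + 1L
      if (tries > 200L * config$n_genes) {
        stop("could not place non-overlapping gene intervals (genome too small?)")
      }
      glen <- sample(seq.int(gene_length_range[1], gene_length_range[2]), 1)
      gstart <- sample(seq.int(margin, len - margin - glen), 1)
      cand <- IRanges::IRanges(start = gstart, width = glen)
      if (length(IRanges::findOverlaps(cand, placed)) == 0) {
        placed <- c(placed, cand)
        genes <- rbind(genes, data.frame(
          chrom = "chrS", start = as.integer(gstart),
          end = as.integer(gstart + glen), strand = sample(c("+", "-"), 1),
          stringsAsFactors = FALSE))
      }
    }
    genes <- genes[order(genes$start), ]
    rownames(genes) <- NULL
    list(genome = genome, tss = tss, genes = genes)
  })
}

#' Write the synthetic genome bundle to FASTA/BED files
#'
#' @param bundle Output of [synth_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three written paths.
#' @export
write_synth_genome <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(bundle$genome, fa)
  tss_bed <- file.path(dir, "tss.bed")
  write_bed <- function(df, file, point = FALSE) {
    start <- if (point) df$position else df$start
    end <- if (point) df$position + 1L else df$end
    utils::write.table(
      data.frame(df$chrom, start, end,
                 name = sprintf("rec%04d", seq_len(nrow(df))),
                 score = 0L, strand = df$strand),
      file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_bed(bundle$tss, tss_bed, point = TRUE)
  gene_bed <- file.path(dir, "genes.bed")
  write_bed(bundle$genes, gene_bed)
  c(genome = fa, tss = tss_bed, genes = gene_bed)
}
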