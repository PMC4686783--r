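test_that("window arithmetic: length U + D + 1 across all sixteen window specs", {
  specs <- list(c(10, 1), c(10, 3), c(10, 5), c(10, 10), c(10, 20), c(10, 30),
                c(10, 40), c(10, 50), c(20, 50), c(30, 50), c(40, 50),
                c(50, 50), c(100, 50), c(150, 50), c(200, 50), c(250, 50))
  for (s in specs) {
    ws <- window_spec(s[1], s[2])
    expect_identical(window_length(ws), as.integer(s[1] + s[2] + 1))
    expect_identical(ws$name, sprintf("%d-%d", s[1], s[2]))
  }
  expect_identical(window_length(window_spec(250, 50)), 301L)
  expect_identical(window_length(window_spec(10, 30)), 41L)
  expect_error(window_spec(-1, 5), "non-negative")
})

test_that("plus-strand extraction slices genome[pos-U .. pos+D] with TSS at offset U", {
  g <- toy_genome(c(chr1 = "ACGTACGTACGTACGTACGTACGTACGTAC"))  # 30 nt
  rec <- extract_promoter_window(g, "chr1", 15, "+", window_spec(10, 1))
  expect_identical(nchar(rec$bases), 12L)
  expect_identical(rec$bases, substr("ACGTACGTACGTACGTACGTACGTACGTAC", 6, 17))
  expect_identical(rec$tss_offset, 10L)
  expect_identical(rec$label, "promoter")
})

test_that("minus-strand extraction reverse-complements the mirrored window", {
  withr::local_seed(17)
  seq40 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  g <- toy_genome(c(chrX = seq40))
  U <- 6L; D <- 3L; pos <- 20L
  rec <- extract_promoter_window(g, "chrX", pos, "-", window_spec(U, D))
  # hand-computed: plus-strand slice [pos-D, pos+U] (0-based), then revcomp
  expected <- oracle_revcomp(substr(seq40, pos - D + 1, pos + U + 1))
  expect_identical(rec$bases, expected)
  expect_identical(rec$tss_offset, U)
  # the TSS base itself maps to the complement of the genome base at pos
  expect_identical(substr(rec$bases, U + 1, U + 1),
                   oracle_revcomp(substr(seq40, pos + 1, pos + 1)))
})

test_that("out-of-bounds and ambiguous windows raise typed errors", {
  g <- toy_genome(c(chr1 = "ACGTACGTACNTACGTACGT"))
  expect_error(extract_promoter_window(g, "chr1", 2, "+", window_spec(10, 1)),
               class = "promstruct_boundary_error")
  expect_error(extract_promoter_window(g, "chr1", 12, "+", window_spec(3, 3)),
               class = "promstruct_noisy_error")
  expect_error(extract_promoter_window(g, "chr9", 2, "+", window_spec(1, 1)),
               "unknown chromosome")
})

test_that("bulk extraction skips and counts unusable windows", {
  g <- toy_genome(c(chr1 = "ACGTACGTACNTACGTACGTACGTACGTAC"))
  tss <- data.frame(chrom = "chr1", position = c(1L, 10L, 20L),
                    strand = c("+", "+", "+"))
  out <- extract_promoter_windows(g, tss, window_spec(3, 3))
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "skipped"), c(boundary = 1L, noisy = 1L))
})

test_that("non-promoter sampling honours the exclusion distance (independent oracle)", {
  cfg <- synth_config(n_per_class = 1, seed = 41, genome_length = 300000L,
                      n_tss = 10L, n_genes = 5L)
  b <- synth_genome(cfg)
  np <- sample_nonpromoters(b$genome, b$tss, b$genes, n = 120, length = 41,
                            min_dist = 1000, seed = 8)
  expect_identical(nrow(np), 120L)
  expect_true(all(np$label == "non-promoter"))
  expect_true(all(nchar(np$bases) == 41L))
  co <- attr(np, "coords")
  expect_gte(oracle_min_exclusion_distance(co, 41L, b$tss, b$genes), 1000)
})

test_that("non-promoter sampling is seed-deterministic and seed-sensitive", {
  cfg <- synth_config(n_per_class = 1, seed = 42, genome_length = 120000L,
                      n_tss = 4L, n_genes = 2L)
  b <- synth_genome(cfg)
  a1 <- sample_nonpromoters(b$genome, b$tss, b$genes, 50, 41, seed = 3)
  a2 <- sample_nonpromoters(b$genome, b$tss, b$genes, 50, 41, seed = 3)
  a3 <- sample_nonpromoters(b$genome, b$tss, b$genes, 50, 41, seed = 4)
  expect_identical(a1$bases, a2$bases)
  expect_false(identical(a1$bases, a3$bases))
})

test_that("a fully excluded genome raises a capacity error reporting the count", {
  g <- toy_genome(c(chr1 = paste(rep("ACGT", 500), collapse = "")))  # 2 kb
  tss <- data.frame(chrom = "chr1", position = 1000L, strand = "+")
  expect_error(
    sample_nonpromoters(g, tss, NULL, n = 1, length = 41, min_dist = 1000, seed = 1),
    "insufficient eligible start positions.*found 0")
})

test_that("no-overlap sampling yields pairwise disjoint windows", {
  cfg <- synth_config(n_per_class = 1, seed = 43, genome_length = 60000L,
                      n_tss = 2L, n_genes = 1L)
  b <- synth_genome(cfg)
  np <- sample_nonpromoters(b$genome, b$tss, b$genes, 40, 101, seed = 6,
                            no_overlap = TRUE)
  co <- attr(np, "coords")[order(attr(np, "coords")$start), ]
  expect_true(all(diff(co$start) >= 101))
})

test_that("dataset assembly enforces balance and preserves the input multiset", {
  p <- promstruct:::new_labeled_sequences(paste0("p", 1:7),
                                          strrep("ACGT", 3)[rep(1, 7)],
                                          "promoter", 2L)
  np <- promstruct:::new_labeled_sequences(paste0("n", 1:7),
                                           strrep("TGCA", 3)[rep(1, 7)],
                                           "non-promoter")
  ds <- assemble_dataset(p, np, seed = 99)
  expect_identical(nrow(ds), 14L)
  expect_identical(sort(ds$id), sort(c(p$id, np$id)))
  expect_identical(mean(ds$label == "promoter"), 0.5)
  expect_identical(assemble_dataset(p, np, seed = 99)$id, ds$id)
  # minimal case and the unbalanced error
  expect_identical(nrow(assemble_dataset(p[1, ], np[1, ], seed = 1)), 2L)
  expect_error(assemble_dataset(p[1:3, ], np[1:4, ], seed = 1), "imbalance")
})

test_that("labelled FASTA and BED round-trips preserve records and coordinates", {
  set <- synth_labeled_set(synth_config(n_per_class = 5, seed = 10))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_labeled_fasta(set, fa, manifest = NULL)
  back <- read_labeled_fasta(fa)
  expect_identical(back$bases, set$bases)
  expect_identical(back$label, set$label)
  expect_identical(back$tss_offset, set$tss_offset)

  b <- synth_genome(synth_config(n_per_class = 1, seed = 2,
                                 genome_length = 50000L, n_tss = 3L, n_genes = 2L))
  dir <- withr::local_tempdir()
  paths <- write_synth_genome(b, dir)
  expect_identical(read_tss_bed(paths[["tss"]])$position, b$tss$position)
  genes <- read_gene_bed(paths[["genes"]])
  expect_identical(genes$start, b$genes$start)
  expect_identical(genes$end, b$genes$end)
  g2 <- promstruct:::as_genome(paths[["genome"]])
  expect_identical(as.character(g2[["chrS"]]), as.character(b$genome[["chrS"]]))
})
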