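---
title: "Structural-profile encoding and classifier comparison for promoter prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-profile encoding and classifier comparison for promoter prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Promoters are the regulatory regions surrounding the transcription start
site (TSS). Treating promoter identification as binary classification —
promoter window vs non-promoter window — requires a numerical
representation of DNA. This package uses *structural profiles*: each di-
or trinucleotide step of a sequence is mapped, via a lookup table, to a
physicochemical or conformational quantity (base-stacking energy,
bendability, propeller twist, ...). A window of $L$ nucleotides scanned
with a table of order $k$ yields a profile of $L - k + 1$ values;
concatenating the profiles of all 13 properties in a fixed registry order
yields the feature vector

$$ n_\text{features} \;=\; \sum_{p} (L - k_p + 1) \;=\; 11\,(L-1) + 2\,(L-2), $$

since 11 of the 13 canonical properties are dinucleotide scales and 2
(bendability, nucleosome positioning) are trinucleotide scales. For the
301-nt window spanning 250 nt upstream and 50 nt downstream of the TSS this
gives 3898 predictors; for the 41-nt `10-30` window, 518.

The package's purpose is to study, on data it fully controls, how two
experimental dials — window length and number of training sequences —
affect classifier performance, using the machinery a practitioner would
apply to real promoter data: balanced dataset construction, shared-partition
stratified 10-fold cross-validation of SVM (RBF), Random Forest and k-NN,
per-class F-measure and Cohen's kappa, and Friedman/Nemenyi rank statistics
across matched folds.

## Property tables

A `property_table` maps every k-mer over {A, C, G, T} to a finite value;
completeness ($4^k$ entries) is validated at load time. Only the
base-stacking-energy table ships with published values (kcal/mole,
reverse-complement symmetric). The other 12 bundled tables are **synthetic
stand-ins**: reverse-complement-symmetric values drawn once in realistic
ranges for each property and frozen as text files named `*.synthetic.tsv`.
The exact published variants of those 12 scales (units, sign conventions,
source compilation) cannot be pinned down from publicly printed material,
so the package ships honest placeholders and keeps every exact-value check
confined to the stacking-energy table. Any table can be replaced at run
time by loading a user file with `read_property_table()` and building a
custom `property_registry()`.

## Dataset construction

`extract_promoter_window()` slices `U` bases upstream and `D` downstream of
an annotated TSS (the TSS base included, always at window offset `U`);
minus-strand windows are reverse-complemented so "upstream" is
transcriptional upstream. Windows that leave the chromosome or contain
ambiguity codes are rejected with typed conditions (and skip-counted by the
bulk extractor) rather than imputed.

`sample_nonpromoters()` draws negatives uniformly, without replacement over
start positions, from the regions where **every base** of the window lies at
least 1000 nt (configurable) from every TSS position and from every gene
start/end boundary. The whole-window reading of the distance rule is the
conservative one; coordinates are 0-based half-open internally, matching
BED. An independent brute-force distance check over every sampled window is
part of the test suite.

`assemble_dataset()` enforces the exact 50/50 class balance and shuffles
with a fixed seed.

## The synthetic generator

`synth_labeled_set()` emulates the statistical structure the encoder is
meant to detect: promoters differ from non-promoters by a
position-dependent dinucleotide bias in a TSS-proximal band (default
positions −30 to +10 around the TSS; band edges are configuration). Outside
the band, and everywhere in non-promoters, bases are i.i.d. at the
background GC (default 0.40, the AT-rich composition typical of a mammalian
genome). Inside the band, bases follow a first-order chain dominated by
C↔G transitions, so at full effect the band approaches a quasi-periodic
CpG-rich consensus — a deliberate caricature of a CpG island whose
dinucleotide content, and hence whose structural profile, departs strongly
from background while retaining within-class variability. The `effect`
parameter in $[0, 1]$ linearly interpolates each transition row toward the
background distribution; at `effect = 0` the interpolated chain *is* the
background, so the classes are exchangeable by construction and the whole
downstream pipeline can be audited for type-I behaviour.

A first-order model was chosen because the encoder reads di- and
trinucleotides: any compositional difference the generator creates is
guaranteed to be visible in the structural profiles. What the generator
does **not** imitate: real promoter motif content (TATA box, Inr), CpG
methylation structure, isochore-scale GC variation, repeats, or ambiguity
codes. Passing tests on synthetic data therefore demonstrate that the
machinery is correct and well-calibrated, not that any particular accuracy
carries over to real genomes.

`synth_genome()` produces an i.i.d. background chromosome plus uniformly
placed, non-overlapping TSS and gene annotation for exercising the negative
sampler.

## Evaluation harness

`stratified_folds()` partitions rows so per-class fold sizes differ by at
most one; the assignment is seeded and *shared* across classifiers, so every
algorithm is scored on identical test partitions — the property that later
makes folds usable as matched blocks. `run_cv()` trains on each fold's
complement, with z-score standardization fitted on training rows only
(SVM and k-NN are scale-sensitive; the `scale = FALSE` switch reproduces a
raw-feature run). Metrics: per-class precision/recall/F, macro-averaged F
(mean of the two per-class F values — the natural choice for balanced
classes), Cohen's kappa, per fold and pooled. Degenerate F cases return 0.

Classifiers are the standard implementations (`kernlab::ksvm` with RBF
kernel, `randomForest`, `class::knn`). The published per-window-dataset
parameter values ship verbatim via `table3_defaults()`; fractional `mtry`
entries are rounded to integers with a warning, and no hyperparameter
search is performed. k-NN uses odd `k` (no voting ties with two classes);
exact distance ties are resolved by the underlying routine and have
essentially zero probability on continuous features.

## Friedman and Nemenyi

`friedman_test_ranks()` ranks treatments within blocks (average ranks on
ties) and computes the tie-corrected chi-square statistic with $k-1$
degrees of freedom. Because the chi-square approximation is coarse for
small designs, an exact mode enumerates all $k!^N$ equally likely
within-block orderings by dynamic programming over integer-encoded rank-sum
vectors (the default `auto` rule switches to it when $N \cdot k! \le 10^5$);
the Iman–Davenport F refinement is also available. In our own measurements
at $N = 10$ the chi-square p can differ from the exact p by up to ≈0.23
($k=2$), ≈0.10 ($k=3$) and ≈0.04 ($k=4$) in absolute value, so the exact
mode is the recommended choice at fold-level sample sizes.

`nemenyi_test()` flags a pair when its mean-rank gap reaches
$CD = q_\alpha \sqrt{k(k+1)/(6N)}$, with $q_\alpha$ the infinite-df
studentized-range quantile over $\sqrt 2$, bundled for $k = 2..20$ and
$\alpha \in \{0.05, 0.10\}$. The significance matrix is symmetric with a
false diagonal and is printed in the conventional lower-triangle T/F
layout. `compare_report()` reshapes a long sweep table into one matched
design per classifier (blocks = folds, treatments = datasets) or per
dataset (treatments = classifiers).

## Numerical and design choices

* Feature layout is property-major, position-minor, in canonical registry
  order; column names are `<property>_<position>`.
* Sequences with ambiguity codes are rejected by the encoder; filtering is
  an upstream, counted operation.
* The negative sampler permits overlapping windows by default (a
  `no_overlap` switch enforces disjointness); eligibility is computed by
  interval arithmetic and sampling is uniform without replacement over
  start positions.
* All stochastic steps (generation, shuffling, folds, forest growth) take
  explicit integer seeds, and seed state is restored on exit so library
  calls do not perturb the caller's RNG.
* Exact Friedman enumeration assumes tie-free blocks (ties in observed
  scores are ranked with midranks before the statistic is computed);
  continuous F-measures make within-block ties rare.

## Scale of the shipped experiments

The bundled tests and the acceptance script run the pipeline at desk scale,
chosen to exercise every code path in minutes on one core: signal recovery
at 1000 sequences per class on the band-covering 41-nt `30-10` window
(all three classifiers, Random Forest at 100 trees for these synthetic
runs); the type-I audit at 500 per class on the `10-30` window plus twenty
4-dataset Friedman replicates at 150 per class; an effect-size sweep
(0, 0.3, 0.6, 1.0) at 500 per class; and a 4-window length sweep at 250 per
class. The published full-scale design (14,000–120,000 sequences, 16
windows) is expressible with the same functions.

## Known limitations

* Twelve of the thirteen bundled property tables are synthetic stand-ins;
  analyses of real genomes should load published tables.
* The generator's class signal is purely compositional and first-order;
  no positional motif grammar.
* Only two-class, balanced designs are supported in the metrics layer.
* The Nemenyi critical-value table covers $k \le 20$ treatments.

## A worked example

```{r, eval = FALSE}
library(promstruct)

cfg <- synth_config(n_per_class = 500, upstream = 10, downstream = 30,
                    effect = 1, seed = 1)
set <- synth_labeled_set(cfg)
ds  <- assemble_dataset(set[set$label == "promoter", ],
                        set[set$label == "non-promoter", ], seed = 2)
fm  <- encode_dataset(ds)                      # 1000 x 518 feature matrix
folds <- stratified_folds(fm$labels, 10, seed = 3)
run_cv(fm, classifier_spec("svm_rbf", C = 1, sigma = 1e-3), folds)

# window-length sweep with a shared-partition design and rank statistics
wins <- list(`30-10` = c(30, 10), `50-50` = c(50, 50), `250-50` = c(250, 50))
dsets <- lapply(wins, function(w) {
  s <- synth_labeled_set(synth_config(500, w[1], w[2], effect = 1, seed = w[1]))
  encode_dataset(s)
})
res <- sweep_datasets(dsets, list(knn = classifier_spec("knn", k = 9)),
                      n_folds = 10, fold_seed = 7)
compare_report(res, "datasets", method = "auto")
```
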