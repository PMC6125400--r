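---
title: "Methods: replicate-consistency differential peaks and mark/expression concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-consistency differential peaks and mark/expression concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markconcord)
```

## The problem

Broad repressive histone marks such as H3K27me3 cover kilobase-scale domains
with diffuse boundaries. Count-based differential-binding statistics that work
well for narrow marks (H3K4me3 at promoters) are unreliable there, because a
"peak" is not a well-localised unit with a stable summit. An alternative that
trades power for near-certainty is purely occupancy-based: call a region
differential only when **every** replicate of one condition has a called peak
there and **no** replicate of the other condition does. `markconcord`
implements that rule, the machinery around it (consensus construction,
replicate-support spectra), and the downstream integration: annotating
differential peaks to genes, predicting expression direction from the marks
(more H3K4me3 &rArr; up; H3K27me3 gained in treatment &rArr; down), checking
the prediction against differential expression, and testing gene-list
overlaps with the hypergeometric distribution.

## The procedure

1. **Consensus.** For each condition, pool all replicates' peaks and take
   maximal runs of pooled coverage as candidate regions; keep a candidate when
   every replicate has at least one peak overlapping it by `min_bp` bases
   (default 1). The construction is symmetric in replicate order, idempotent,
   and deterministic.
2. **Support spectrum.** Each consensus region of condition A is scored by the
   number of B replicates (0..n) with an overlapping peak; the tabulation is
   the familiar "present in all four / three / ... / none of the other
   samples" spectrum, with percentages rounded half-up to two decimals.
3. **Exclusive calls.** Consensus regions with other-condition support
   `<= max_other` (default 0) are differential peaks, labelled
   `gain_in_treatment` or `gain_in_control` depending on which condition's
   consensus they come from. `max_other` is exposed purely for sensitivity
   analyses; the headline rule is 0.
4. **Annotation.** Each differential peak is associated with every gene whose
   TSS window, promoter or gene body it overlaps (nearest TSS first, up to
   `max_multi = 3` genes), else with its nearest gene as intergenic.
   Classification precedence is tss > promoter > gene_body > intergenic.
5. **Concordance.** Peak-level directions collapse to one status per gene
   (mixed directions for one mark are conflicts, excluded and reported);
   differential expression is selected by unadjusted p < 0.01 with direction
   from the sign of the log fold-change; the two marks and expression are
   cross-tabulated, and genes with an unambiguous predicted direction and
   observed differential expression are checked for agreement.

## Conventions and parameters

* **Coordinates.** BED input/output is 0-based half-open; internally
  everything is a `GenomicRanges::GRanges` (1-based closed), the standard
  container of this field, and conversion happens only at the file boundary.
  Overlap means "shares at least `min_bp` bases" with half-open arithmetic,
  so book-ended BED intervals do not overlap. `merge_intervals()` likewise
  never fuses book-ended intervals; consensus *candidates*, by contrast, are
  maximal runs of pooled base coverage (a per-base notion, under which
  book-ended peaks from different replicates belong to one run).
* **TSS.** The 5' base in gene orientation: the interval start for `+`
  genes, the final base before the half-open end for `-` genes. The paper-
  style promoter window is 2,000 bp upstream of the TSS to 200 bp into the
  gene, strand-aware and half-open at both ends; "at the TSS" means some
  peak base lies within 100 bp (`tss_radius`) of the TSS base, the most
  permissive defensible anchor. Signed distances are negative upstream in
  gene orientation. Nearest-gene ties break by smaller gene start, then
  lexicographic id.
* **Chromosome names** compare by exact string match; `read_peak_bed()` has
  a `normalize_chr` flag for stripping `chr` prefixes, because silent naming
  mismatches are the most common BED failure mode.
* **Count-based stand-in test.** Where per-region counts are available
  (narrow marks), `score_differential_binding()` offers a deliberately
  transparent alternative to negative-binomial machinery: log2 CPM with a
  0.5 pseudocount, pooled-variance two-sample t per region, Benjamini-
  Hochberg FDR at 0.1. It is labelled a stand-in and makes no equivalence
  claim to dispersion-modelling tools; with small replicate numbers it is
  conservative in power but holds its type-I error (verified in the tests to
  within 3 binomial SEs at alpha = 0.05 on 100,000 null regions). Its
  library-size normalisation assumes differential regions are a negligible
  fraction of the genome; with strong asymmetric signal in many regions,
  CPM normalisation would bias null regions, as any global-scaling method
  does.
* **Hypergeometric overlaps.** `P(X >= k)` including the observed overlap.
  The universe is a required argument with no default: an overlap
  probability quoted without its universe is not reproducible, so the
  package forces that choice into the open.

## The synthetic-data generator

`simulate_dataset()` plants a fully known truth so that every stage is
testable without any external download. The genome is laid out in zones: a
coarse gene grid whose slots leave `promoter_upstream + 2 * wmax` margins,
and a fine peak grid with pitch `3 * wmax` (wmax = maximum peak width). By
construction any two planted regions are separated by at least `2 * wmax`
bases, so condition-exclusive regions can never be contaminated by a
neighbouring region's jittered peaks — exclusivity of the planted truth is a
layout guarantee, not a sampling accident.

* **Shared peaks** appear in each replicate of both conditions independently
  with probability `1 - drop_prob`; their replicate-support is therefore
  Binomial(n, 1 - drop_prob), a property the tests check.
* **Exclusive regions** appear in every replicate of their condition and
  never in the other; they are placed inside the upstream promoter segment
  ([TSS-2000, TSS-101], clear of the 100 bp TSS window) of a randomly chosen
  host gene, which makes annotation recovery checkable.
* **Partial-support regions** appear in all control replicates and in exactly
  `k` treatment replicates, populating the middle of the support spectrum.
* **Jitter** (Gaussian, default sd 20 bp) is applied independently to both
  ends of every replicate-level peak and clamped to width >= 1; exclusive
  and partial regions are jittered but never dropped, keeping the planted
  classes exact.
* **Expression.** Host genes of exclusive regions get per-replicate
  expression shifted by the mark-implied direction; `n_replicates` values
  per condition are compared by a pooled t test, so null p-values are
  exactly uniform and the realised log fold-change is
  Normal(&plusmn;effect_size, null_sd).

Defaults (4+4 replicates, ~1,000 shared regions, 25 treatment-exclusive and
10 control-exclusive regions, partial regions at k = 1..3, broad peak widths
0.5-2 kb, jitter sd 20 bp, drop probability 0.1, effect size 0.3 log2 units
with sd 0.1) describe the replicated two-condition design the package
targets: high inter-condition overlap, a small exclusive fraction skewed
towards the treatment, and modest bulk-tissue expression effects. No
quantitative replicate-concordance parameter exists to fit against, so the
noise defaults were chosen once to echo the qualitative shape of published
support spectra, and the effect size to match the magnitude of reported
bulk fold-changes.

What the generator does **not** emulate: read-level noise, fragment-size and
GC effects, peak-shape differences between marks beyond width, correlated
replicate failures, and boundary ambiguity of broad domains (planted regions
have crisp edges). Passing tests therefore demonstrate the correctness of
the interval logic and integration rules, not robustness to every artefact
of real ChIP-seq.

## Numerical and design choices

* Percentages print with half-up rounding (two decimals for spectra, whole
  numbers for direction tallies), matching how such tables are reported.
* Consensus candidates with zero pooled coverage gaps: see *Conventions* —
  the per-base run definition was chosen so that the construction agrees
  exactly with a per-base brute-force oracle, which is how the tests verify
  it on random instances.
* Degenerate inputs: empty BED files parse to empty peak sets with a
  warning; an empty other-condition replicate list puts every region in
  support bin 0; a zero-variance region in the count test gets p = 1 when
  its effect is 0 (identical columns can never be called).
* The t test uses the pooled-variance form: with 4 replicates per group and
  log-scale counts, equal-variance pooling is the standard small-sample
  choice and is exactly what the uniform-null-p guarantee of the expression
  generator relies on.
* One RNG stream per generator call, seeded from the config (`seed + 1`
  annotation, `+ 2` gene linkage, `+ 11`/`+ 13` per mark, `+ 3` expression),
  so each component is independently reproducible and a dataset is a pure
  function of its config.
* Problem sizes in the tests (1,000 shared regions for recovery checks,
  100 random instances of <= 50 intervals for oracle equivalence, 100
  simulation seeds of 1,000 regions for calibration) were sized to give
  tight Monte-Carlo bands while keeping the suite quick to run locally.
* The pipeline (`run_pipeline()`) is driven by a single config (R list or
  YAML), rejects unknown keys, echoes the effective config next to its
  outputs with an md5 digest, and treats a directory containing a completed
  summary as done unless forced — an audit-trail design borrowed from
  workflow tools.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(jitter_sd = 0, drop_prob = 0, seed = 7)
sim <- simulate_dataset(cfg)
cons <- build_consensus(sim$k27$peaks$ethanol, condition = "ethanol")
calls <- call_exclusive_peaks(cons, sim$k27$peaks$control,
                              direction = "gain_in_treatment")
length(calls)  # 25: exactly the planted treatment-exclusive regions
assoc <- associate_peaks_to_genes(calls, sim$genes)
table(assoc$region_class)  # all "promoter": planted placement recovered
```

## Known limitations

* The exclusive rule is binary occupancy: a region quantitatively reduced
  but still called in one other-condition replicate is invisible to it. The
  `max_other` flag relaxes this, at the cost of the clean "none of the
  other" interpretation.
* The count-based test is a stand-in; for serious narrow-mark analyses a
  dispersion-modelling tool should be used and its calls fed into the
  annotation/concordance stages, which are agnostic to how directions were
  obtained.
* Gene models are one interval per gene id; isoform collapsing is the
  caller's responsibility.
* Multi-peak/multi-gene bookkeeping reports peak-level and gene-level counts
  separately rather than mixing them in one table, because their totals
  answer different questions.
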