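---
title: "Ranking HTE reagents by median top-n z-scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking HTE reagents by median top-n z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hterank)
```

## The model and its assumptions

High-throughput experimentation screens many reagent combinations per
chemical transformation (one electrophile/nucleophile substrate pair). The
outcome proxy is the LC–MS product peak area percent, renormalized so that
only starting-material, product and side-product peaks form the denominator.
This proxy assumes that UV response factors of starting material and product
are comparable and that side products are integrated; both assumptions are
imperfect and both err on the side of within-transformation comparisons,
which is the only scale on which the package compares raw outcomes.

Outcomes are standardized per transformation, $z = (x - \mu_t)/\sigma_t$,
and a reagent is scored by the median of the pooled top-$n$ z-scores of the
reactions that contain it. Two properties motivate this construction:

* **Context sensitivity.** A hit in a transformation full of failures earns
  a large $z$; an equal-area hit among many hits earns a small one. Because
  $\mu_t$ and $\sigma_t$ are computed over *all* of a transformation's
  reactions, the statistic is invariant under per-transformation affine
  rescaling of outcomes — substrate difficulty cancels out.
* **Optimum-seeking robustness.** Only the top-$n$ z-scores per reagent
  enter the statistic: the search is for reaction-space optima, so a
  reagent's failures in conditions where everything failed should not drag
  it down. The median (not mean) of the pooled set caps the influence of
  any single outlier. Top-$n$ scores are *not* required to be positive, so
  consistently poor reagents still rank low.

z-scores here are a normalization device only. HTE outcome distributions
are strongly right-skewed and fail normality tests essentially always, so
no probabilistic interpretation (tail probabilities, p-values) is attached
to them anywhere in the package.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_top` | 5 | z-scores | Balance between robustness (large) and rewarding one-off excellence (small). |
| `min_transformations` | 5 | transformations | Hides reagents supported by too few campaigns; counted within the active slice, after filters, so a display decision never depends on data outside the slice. |
| `topn_scope` | `per_transformation` | — | Take the top `n_top` within each transformation containing the reagent and pool (default), or the global top `n_top` across all its reactions. See "Open choices". |
| `sd_type` | `population` | — | $\sigma$ convention; see "Numerical choices". |
| `plate_threshold` | 10 | area % | A plate with no reaction above this value carries no usable signal; the comparison is strict (`> 10`). |

## Numerical choices

* **Population vs sample $\sigma$.** The transformation's reaction set is
  the entire frame of reference for its z-scores, not a sample from a larger
  population, so the default divides by $N$. A `sd_type = "sample"` switch
  is provided; both conventions satisfy the brute-force oracle tests under
  their own definition. Rankings are usually unaffected because the factor
  $\sqrt{N/(N-1)}$ is shared within a transformation.
* **Degenerate frames.** A transformation with a single reaction, or with
  all outcomes equal ($\sigma_t = 0$), has no discriminating information:
  all its z-scores are set to 0, flagged, and excluded from ranking.
* **Ties.** At the top-$n$ boundary, records sort by (z descending,
  reaction_id ascending) and exactly $n$ are kept — determinism over
  inclusiveness. In the multi-sample collapse, ties at the maximum resolve
  to the earliest sampling point (shorter reaction time preferred). Ranking
  ties break by support (more transformations first), then name.
* **Even-length medians** are the mean of the two central order statistics
  (the `stats::median` convention), computed at full precision; display
  rounds to 2 decimals.
* **Plate filter boundary.** "More than ten area percent" is strict: a plate
  maximum of exactly 10.0 is excluded, 10.1 is included. Excluded
  transformations are flagged and retained, never deleted.
* **Denominator classes.** Product, starting material and side products are
  retained in the renormalization; injection, reagent, solvent,
  internal-standard and unknown peaks are excluded. The retained set is
  configurable (`retain =`), since practice varies on whether unidentified
  peaks should count.
* **Shapiro–Wilk capacity.** The test accepts at most 5000 observations;
  larger reaction types are subsampled to 4999 with a fixed seed (0) so the
  diagnostics report is reproducible. Skewness is the adjusted
  Fisher–Pearson sample estimator (`e1071::skewness(type = 2)`).
* **Name hygiene.** Reagent names are opaque strings compared exactly after
  Unicode NFC normalization, en-dash → hyphen replacement, soft-hyphen
  removal and whitespace collapsing. No fuzzy matching: silently merging
  two distinct reagents would corrupt rankings, whereas a split reagent is
  visible in the output and fixable in the data.

## Open choices and how they were settled

* **Per-transformation vs global top-n.** The formal set definition of the
  statistic takes the $n$ highest z-scores of a reagent overall; published
  boxplot analyses of this kind instead describe "top five hits per
  transformation". Both readings are implemented; the per-transformation
  scope is the default because it matches the figure-level practice and
  gives every supporting transformation a voice, while the global scope is
  retained as `topn_scope = "global"`. Which mode produced any given
  published figure cannot be decided from the description alone, which is
  exactly why both are first-class and oracle-tested.
* **Plate vs transformation for the inclusion filter.** The filter is
  stated per plate, but ranking operates on transformations, and a
  transformation may span plates. `plate_filter()` defaults to grouping by
  transformation and accepts any grouping column (e.g. `plate_id`) when
  plate-level metadata exists.
* **Ligand pooling.** All precatalysts of one ligand can be pooled under
  the ligand's name via an editable two-column catalog; catalysts missing
  from the catalog are ranked under their own name and reported, so pooling
  is auditable rather than silent. `ligand_pooling_comparison()` exposes
  the per-precatalyst vs pooled view; the pooled median always lies between
  the per-precatalyst medians.

## The synthetic campaign generator

`generate_campaign()` emulates the statistical structure the ranking method
must survive: many transformations per reaction type (~113 reactions each,
matching the scale of real campaign collections, sampled at 3
time/temperature points), right-skewed outcomes (lognormal noise; truncated
normal and zero-inflated variants available), per-transformation difficulty
offsets, reagent effects shared across transformations and expressed in
units of the noise SD, and controlled hit sparsity. Each transformation has
a guaranteed hit (one outcome > 10 area %) with probability `hit_sparsity`
and is capped below 10 otherwise, so the realized plate-inclusion rate is a
binomial draw around the spec value. The default `hit_sparsity` of 0.8
reflects that archived collections are hit-enriched: plates with no signal
are filtered before analysis. One RNG substream per transformation, keyed
by a counter, makes campaigns reproducible bit-for-bit and stable under
extension. Outcomes are clamped to [0, 100] before z-scoring so the
area-percent invariant holds literally.

What the generator does **not** emulate: batch effects and project
clustering ("similarity islands"), correlated reagent–substrate
interactions (effects are additive across roles), UV response-factor
mismatch, and chemically meaningful reagent names. Passing recovery tests
therefore show that the statistic recovers planted additive effects under
realistic noise — not that it resolves interaction-dominated chemistry.

## Validation strategy and problem sizes

The test suite checks the implementation against an independently written
brute-force transcription of the ranking definitions (plain loops, own
median) on over 100 random micro-campaigns (≤5 transformations × ≤20
reactions) in both top-n scopes and both σ conventions; property tests
cover the z-score identity (mean 0, SD 1 within 1e-9), affine invariance,
normalization conservation and scale invariance, plate-filter boundary and
monotonicity, and median robustness. A 100-seed recovery study (one ligand
planted at +1.5 noise-SDs, 6 transformations × ~24 reactions, 6 candidate
ligands) requires the planted winner to rank first in ≥90% of seeds.
`scripts/acceptance.R` reruns these checks at full campaign scale
(42 types × 14 transformations × ~113 reactions ≈ 66k reactions), the size
chosen to mirror the scale of real archived collections while keeping a
single-CPU run in minutes.

## Known limitations

* The ranking is descriptive, not inferential: no uncertainty is attached
  to rank scores, and small support differences between reagents are not
  significant in any statistical sense.
* Slicing too finely (many simultaneous filters) leaves thin slices where
  `min_transformations` hides everything; the empty-slice diagnostics name
  the responsible filter, but the remedy is a coarser query.
* CSV outputs of the command-line tools are byte-reproducible; the PDF
  boxplot embeds a device creation timestamp, so plot reproducibility is
  guaranteed at the level of plotted data (order and values), not bytes.
* Replication of published collection-level statistics requires the
  corresponding dataset file locally; `published_dataset_path()` documents
  where it is looked for.
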