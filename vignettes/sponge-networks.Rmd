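---
title: "Methods: sponge-network inference and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sponge-network inference and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `spongenet`, the
reasoning for its defaults, the numerical conventions, and what the
synthetic-data generator does and does not emulate. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The inference chain

The package implements a gated integration chain for a two-group design
(control vs. treated, typically n = 3 replicates each):

1. **Normalization.** Microarray intensities are quantile-normalized
   (`quantile_normalize()`, delegating to `limma::normalizeQuantiles`):
   every sample is mapped onto the mean of the sorted columns, so all
   columns share one empirical distribution. miRNA read counts are scaled
   to a common library depth inside the count test instead; quantile
   normalization is not appropriate for small count panels.
2. **Differential expression.** Intensities: equal-variance Student *t*
   on `log2(x + 1)` per feature (`ttest_de()`). Counts: a
   common-dispersion negative-binomial exact conditional test
   (`nb_exact_de()`, below). Both report signed fold change on *linear*
   group means, raw p, BH-adjusted q, and the feature's raw intensity
   (max of the two linear group means).
3. **Gates.** Significance means |signed FC| ≥ `fc_min` (1.5) and
   p ≤ `p_max` (0.05) on the *raw* p-value — the conventional array
   screen; q is reported alongside and `use_adjusted = TRUE` switches the
   gate to it. Sponge candidates additionally need raw intensity
   strictly > 100 (highly expressed transcripts sponge more effectively)
   and membership in the annotation whitelist. Following the asymmetry of
   the original analysis, the reverse (down-regulated) network applies
   significance only.
4. **Genomic context.** lncRNAs are classified against coding genes by a
   fixed priority order (natural antisense → intronic antisense → sense
   overlap → bidirectional → intergenic), and cis candidate pairs are
   called at interval gap < 300 kb or by opposite-strand overlap.
5. **External evidence.** Candidate lncRNA–mRNA pairs are filtered by
   reference co-expression (|r| within [0.6, 0.8], sign concordant with
   the observed fold-change product) and optionally joined to disease
   annotations. Triads are then assembled from binding and target tables
   into a tripartite network.
6. **Enrichment and validation statistics.** Right-tail hypergeometric
   over-representation with BH FDR; Kruskal–Wallis, Dunn's post hoc and
   control-relative folds for qRT-PCR-style measurements.

## The negative-binomial exact test

The reference workflow for miRNA counts is an edgeR-style NB-GLM with
empirical-Bayes tagwise dispersion. `spongenet` deliberately implements a
simpler, fully specified variant so that its behaviour is checkable
against first-principles oracles:

* library sizes are scaled to the common mean depth;
* one **common dispersion** φ is estimated by the method of moments
  (var = μ + φμ², pooled within-group moments, averaged across features,
  floored at 1e−8);
* each feature is tested by an **exact conditional test** on its rounded
  group sums: the sum of n i.i.d. NB(μ, φ) is NB(nμ, φ/n), and
  conditional on the total every split is assigned its probability; the
  two-sided p is the summed probability of all splits no more likely than
  the observed one (tie tolerance 1 + 1e−7).

In the Poisson limit (φ → 0) this is exactly the classical exact binomial
test of an even split, which the test suite asserts. The fidelity gap
against the full NB-GLM is deliberate and is validated differently: by
type-I calibration on simulated null counts (the observed rejection rate
at α = 0.05 must stay within ±0.01) and by an agreement check of
significance calls against edgeR's `exactTest` on strong signals. Tagwise
(per-feature) dispersion moderation is out of scope; with very few
features or grossly heterogeneous dispersions the common-φ assumption is
the main approximation.

Fold changes for count features with a zero group mean use a 0.5
pseudo-mean on both sides; all-zero features get p = 1 and direction
`flat`.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `fc_min` | 1.5 | ratio | conventional array effect gate |
| `p_max` | 0.05 | probability | conventional screen; raw p, q reported |
| `window` | 300 000 | bp | cis-regulation proximity window; strict `<` |
| `intensity_min` | 100 | linear intensity | sponge-expression gate; strict `>` |
| `r_min`, `r_max` | 0.6, 0.8 | \|correlation\| | reference co-expression band, inclusive |
| `noise_sd` | 0.3 | log2 units | microarray replicate noise (generator) |
| `nb_dispersion` | 0.1 | φ | biological CV² of replicated small-RNA libraries |
| `n_per_group` | 3 | samples | triplicate cell-culture design |

Decisions taken where the underlying conventions were genuinely open:

* **Distance** between features is the gap between closest interval ends
  (0 when they overlap), not TSS-to-TSS; strand is ignored for proximity.
* The proximity boundary is **strict** (`gap < window`), and the intensity
  gate is strict (`> 100`).
* The co-expression band is **inclusive** on |r|, so strong negative
  reference correlations also qualify; concordance then requires
  sign(r) = sign(FC_lnc · FC_mRNA). `mode = "any"` disables the sign check
  (its output provably contains the sign-concordant output).
* **Raw intensity** of a feature is the maximum of its two linear group
  means.
* The *t* test is computed on `log2(x + 1)` (pseudocount for zero
  safety); the scale is recorded in the result's attributes.
* Classification priority puts exonic antisense overlap first, so a lncRNA
  spanning both exon and intron of an opposite-strand gene is *natural*
  antisense; genes without exon records count their whole span as exonic,
  making `intronic_antisense` unreachable for them (single-exon
  fallback). An opposite-strand gene-span overlap that touches no exon
  and is not intron-contained falls through to `intergenic`; the
  generator never produces this configuration and real annotations make
  it rare.
* Slash-joined gene labels (`MAGEA3/MAGEA6`) are opaque single
  identifiers, matching how published tables count them.
* Ward clustering uses `stats::hclust(method = "ward.D2")` on Euclidean
  distances; merge tie-breaking follows `hclust`'s deterministic
  convention.

## What the generator emulates

`simulate_study()` produces a complete synthetic study with recoverable
truth: log-normal intensities (homoscedastic on the log2 scale) with
planted fold-change ratios for a `de_frac` subset of features; NB counts
with mean `lib_size · π_i · ratio^I(treated)`; an annotation that plants
each lncRNA in one of four exact configurations (intergenic far from all
coding genes, intergenic at a recorded gap below the window, exon-
overlapping antisense, intron-contained antisense) on a slot grid whose
2-Mb spacing guarantees that only the planted relations fall inside the
window; and interaction tables that always contain every planted triad
edge plus optional decoy edges among pairs with at least one
non-differential endpoint.

Determinism: every stage reseeds from the master seed with a fixed
offset, so stages are independently reproducible, and a repeated
`simulate_study()`/`run_pipeline()` with the same configuration is
byte-identical on disk.

Two generator choices deserve emphasis:

* **Triad members carry the strongest planted effect** (the top of
  `effect_grid`) and baselines in a fixed well-expressed band
  (log2 intensity in [log2 400, 9.3]). Sponge hypotheses are meant to be
  unambiguous in the truth: recovery tests assert that the DE gates —
  necessary-condition filters — never drop a planted triad, which is a
  statement about the gates, not about detecting marginal effects.
  The band also keeps planted features away from the extreme ranks of
  the panel, where quantile normalization provably compresses fold
  changes (the top-ranked feature of every column is mapped to the same
  value). This rank-compression is a real property of quantile
  normalization that users of small custom panels should be aware of.
* **Panel sizes default to 300 lncRNAs / 300 mRNAs / 200 miRNAs.**
  Quantile normalization assumes a large feature panel with mostly
  unchanged features; far smaller panels put planted features at extreme
  ranks often enough to distort calibration. The defaults are the
  smallest sizes at which the method's assumptions hold comfortably while
  keeping the full test suite fast.

Not emulated: probe-level microarray effects, batch effects, sequencing
reads (counts are drawn directly), tagwise dispersion heterogeneity,
annotation errors, and any correlation structure between features beyond
the planted relations. Passing recovery tests therefore demonstrates the
correctness of the gating logic and statistics under the stated model,
not robustness to those real-data complications.

## Problem sizes used in the checks

The test suite and acceptance script size their simulations as follows:
type-I calibration uses 6000 null features per test (binomial SE ≈ 0.28
percentage points at α = 5%, so the ±1-point acceptance band is ≈ 3.6
SE); triad recovery uses the generator defaults over three seeds, with
background decoy density 0 and 0.01; interval pairing is cross-checked
against an O(n²) scan on three random annotations; the hypergeometric
tail is enumerated exactly for universes up to N = 12; Dunn's
normal-approximation p is compared to a full permutation enumeration at
N = 12 (three groups of four; at N = 9 the normal approximation deviates
from the exact distribution by more than 0.02 for mid-range p-values, so
the smaller case is not a meaningful agreement check).

## Interface notes

The package is an R library first: each analysis stage is an exported
function, `run_pipeline()` orchestrates them into a reproducible run
directory with a machine-readable manifest, and `scripts/acceptance.R` is
the reference command-line entry point for recomputing the headline
numbers. Stage parameters are all reachable through
`pipeline_config()` / `sim_config()` arguments.

## Known limitations

* Sponge triads are correlational hypotheses; the package makes no causal
  or stoichiometric claim (no ceRNA kinetics).
* Binding and target tables are consumed as curated inputs; no sequence-
  based site prediction is performed.
* The common-dispersion exact test is conservative for features whose
  true dispersion is far from the common estimate.
* `n = 3` per group gives the *t* test little power at |FC| near the 1.5
  gate; planted-truth recovery is only guaranteed for strong effects.
* Disease and co-expression joins are only as good as their reference
  tables; database-version-dependent counts are not reproduction targets.
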