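---
title: "Methods: pan-cancer screening of synthetic-lethal gene pairs"
author: "slscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer screening of synthetic-lethal gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slscreen)
```

## The problem

Two genes are synthetic-lethal (SL) when perturbing either alone leaves a
cell viable but perturbing both kills it. In tumors, one member of an SL
pair is often inactivated by mutation; drugging its partner then kills
tumor cells selectively. `slscreen` implements an integrative pan-cancer
screening cascade over candidate SL pairs that combines evidence from
five layers — catalog provenance, somatic mutation recurrence,
expression dysregulation, patient survival, and drug response — and adds
a miRNA regulatory layer built from isomiR-resolved small-RNA data.

Candidate pairs come from two kinds of sources: genetic-interaction
screens in yeast, transferred to human through ortholog maps under the
assumption that strongly negative interactions are conserved, and
curated human SL databases (predicted or experimentally validated). The
cascade then asks which candidates carry coherent cancer-genomic signal.

## The screening cascade

1. **Catalog.** Yeast pairs are retained when their genetic-interaction
   score is at most −0.35 (strongly negative scores mark
   synthetic-lethal or synthetic-sick interactions). Each retained pair
   expands to the Cartesian product of its members' human orthologs;
   pairs with unmapped members are dropped and counted. The transferred
   pairs are unioned with the human-database pairs into a catalog of
   unordered pairs keyed canonically (lexicographic order); the original
   source order is kept as metadata because positional summaries
   downstream refer to "first" and "second" genes as listed in the
   source. Duplicate yeast scores collapse to the most negative
   (strongest) value — the sources do not state a rule, and the
   conservative extreme is the natural choice.

2. **Gene annotation.** Each catalog gene is flagged against seven
   binary characteristics (cancer hallmarks, Cancer Gene Census, core
   essentiality, oncogene, tumor suppressor, actionable, drug target),
   supplied as GMT gene sets. "Core" genes carry at least four
   characteristics. Interaction degrees are binned as
   {1, 2–10, 11–50, >50}; the boundary between the last two bins is a
   documented choice where the source material is ambiguous.

3. **Mutation screen.** Per-gene per-cancer mutation frequency is the
   number of distinct mutated samples over the full cohort size — cohort
   sizes are an explicit input rather than inferred from the mutation
   file, which would silently undercount. A pair passes when **both**
   genes exceed 2% frequency in at least five cancer types (thresholds
   read strictly: "more than 2%" is `> 0.02`, "at least five" is `>= 5`).

4. **Expression screen.** Differential expression per cancer type calls
   a gene dysregulated at `|log2FC| > 1.5` and `padj < 0.05`; genes
   dysregulated in more than ten cancer types (`>= 11`) are kept, and a
   pair passes when both members are kept.

5. **Combined screen.** A pair orientation (mutated gene, partner)
   passes when the mutated gene exceeds 2% frequency in at least five
   cancers and the partner is **up**-regulated in at least eleven. Both
   orientations are tracked separately and can both qualify. The mutated
   gene's own expression is deliberately never filtered. The
   high-mutation subset further requires the mutated gene to exceed 3%
   somewhere.

6. **Survival.** For a pair and cancer, patients split into MM/MW/WW
   (both/one/neither gene mutated) or AA/AN/NN (both/one/neither gene
   abnormally expressed). The two-group analysis compares the extreme
   groups; the three-group analysis uses all three with a 2-df log-rank
   test. The number of pairs significant at p < 0.05 is referred to an
   empirical null built by redrawing equal-size sets of random non-SL
   pairs B = 1000 times: `empirical p = #{null >= observed} / B`,
   without the +1 correction (the reporting convention allows an
   empirical p of exactly 0; a `plus_one` flag provides the conservative
   variant).

7. **Drug response.** For a pair's patient groups, each drug's effect is
   the difference in mean min–max-normalized response, tested with a
   two-sided Mann–Whitney test; significance requires all of
   `|effect| > 0.10`, `p < 0.05`, and BH FDR < 0.10 across the drugs of
   the contrast. Mann–Whitney is used because response distributions are
   unspecified and groups are small; the [0, 1] normalized scale keeps
   the 0.10 effect threshold meaningful regardless of the upstream
   response metric (IC50, AUC, z-score).

8. **miRNA network.** Small-RNA tables are resolved at the isomiR level;
   each miRNA locus is represented by its dominant isomiR — the sequence
   with the largest total count pooled across the cohort, ties broken to
   the lexicographically smallest sequence (pooling is more stable than
   per-sample voting; both the pooling and the tie-break are documented
   determinism choices). Collapsed loci go through the same DE engine;
   miRNAs down-regulated in at least four cancer types enter the
   network. The network is a typed graph: undirected `sl` edges between
   screened mRNAs, directed `targets` edges from selected miRNAs to
   screened mRNAs (target maps are an input — a database lookup, not a
   computation). Exports are GraphML and SIF.

## The differential-expression engine

The screens consume only four summary fields per gene and cancer —
`baseMean`, `log2FC`, `padj`, and a direction call — so the engine is a
deliberately simple, fully self-contained estimator rather than a
negative-binomial GLM:

* **Normalization**: median-of-ratios size factors against a
  geometric-mean pseudo-reference over genes with all-positive counts.
* **Fold change**: `log2((mean normalized tumor + 1) / (mean normalized
  normal + 1))`; the pseudo-count stabilizes zeros and makes the
  all-zero gene exactly null.
* **Test**: two-sided Welch t-test on `log2(normalized + 1)`, vectorized
  over genes; degenerate zero-variance genes get p = 1 when means agree.
* **Adjustment**: Benjamini–Hochberg within each cancer type (the screen
  is per cancer type).

Known limitations, verified in the test suite: the label-swap
antisymmetry and depth invariance hold exactly up to the pseudo-count;
and median-of-ratios assumes dysregulation is not heavily one-sided —
planting 20% of genes all in one direction biases null log2FC estimates
by roughly −0.2 at small n, which is why the FDR-control study uses
direction-balanced effects. Fewer than two samples per condition is a
hard error: no silent single-sample inference.

The per-patient "abnormally expressed" call needed by AA/AN/NN grouping
is not defined by the screening thresholds themselves; the package uses
a z-score rule — abnormal when `|x − μ_normal| > 1.96 σ_normal` on the
log scale, never abnormal when σ_normal = 0 — and flags the cutoff in
its outputs. Under a Gaussian null this calls ~5% of sample–gene pairs
abnormal, which the suite verifies.

## The synthetic-data generator

Every pipeline input can be generated from one `PlantedTruth` object so
the cascade is testable end to end without external cohorts:

* **Mutations**: per cancer, Bernoulli calls at planted rates
  (background 0.005 by default — sparse, like most cohort genes);
  variant classes drawn from a missense-dominant categorical
  distribution (0.6/0.1/0.1/0.1/0.1), the composition typical of tumor
  cohorts. Signal pairs share one planted cancer set per pair, since the
  screen requires both genes recurrent in the *same* cancers.
* **Counts**: negative-binomial with gene-level dispersion (default
  0.1), the overdispersion structure RNA-seq models assume; tumor means
  are the normal means scaled by `2^{planted log2FC}`.
* **Survival**: exponential event times with hazard
  `baseline × HR(group)` and independent exponential censoring — the
  simplest law with a controllable hazard ratio; no particular
  survival-time law is assumed by the method.
* **isomiRs**: locus totals are negative-binomial; isomiR counts are
  multinomial with the planted proportion vector, so counts conserve the
  locus total by construction and the planted dominant index is strictly
  the largest proportion.
* **Drug response**: Gaussian around a base response with a planted
  shift added for the MM group, truncated to [0, 1].

One global seed fans out to per-generator child streams through a fixed
label-hash rule (`child_seed`), so adding a generator never perturbs
another's draws, and identical (config, seed) is byte-identical. A
configuration with no planted signal produces strictly null truth, and
the suite checks that nullness propagates to empty screen outputs.

What the generator does **not** emulate: mutational signatures, copy
number, batch effects, paired designs, correlated genes, or realistic
library-size variation. Passing tests therefore demonstrate the
correctness and operating characteristics of the screening machinery
under its stated model, not performance on real cohorts.

## Operating characteristics (computed by the suite and `scripts/acceptance.R`)

Problem sizes were chosen once as a realistic desk-scale study:

* **End-to-end recovery**: 20 cancers, 500 genes, 10 planted
  combined-screen pairs (mutation rate 0.10 vs 0.005 background in 6
  cancers; log2FC +2.5 in 12 cancers; dispersion 0.1; 60 tumor / 30
  normal expression samples and 150-sample mutation cohorts per cancer),
  20 replicate datasets. The combined screen attains precision and
  recall 1.0 on every replicate.
* **Log-rank calibration**: hazard ratio 1, ~30% censoring, 100 patients
  per arm, 2000 replicates; rejection at α = 0.05 stays within
  [0.04, 0.06] and the p-values pass a KS uniformity check.
* **Randomization self-consistency**: with observed pairs drawn from the
  null universe (200 outer replicates, B = 99), the empirical p is
  approximately uniform. This check runs the continuous mean −log10(p)
  statistic mode: the default count statistic is a small tied integer,
  under which uniformity is not well-posed for any implementation. With
  10 planted pairs at hazard ratio 3 (200 vs 200 patients, B = 1000) the
  empirical p is ≤ 0.05 in every replicate.
* **DE recovery**: planted log2FC of ±2 at 100 + 100 samples is
  recovered within ±0.2 on average, and the mean false-discovery
  proportion over 500 direction-balanced replicates stays within the BH
  bound.
* **Oracle equivalence**: the filter-type operations match brute-force
  reference implementations exactly on 100 randomized instances each.
* **Fixture regression**: `make_fixture()` writes a complete synthetic
  dataset plus a manifest of expected stage counts computed by an
  independent brute-force pass (explicit loops, `stats::t.test`,
  `survival::survdiff`) over the written files; `run_pipeline()` must
  reproduce the manifest exactly, and reruns are byte-identical (stage
  runtimes are kept out of written files for this reason).

## Numerical and design choices

* Thresholds are configuration with the screening defaults above;
  every output file header stamps the active config hash and seed, so
  silent threshold drift is visible as a diff.
* Strict threshold reading throughout ("more than 10" ⇒ ≥ 11).
* The log-rank statistic is computed by direct observed-minus-expected
  summation over distinct event times with the usual hypergeometric
  covariance (and a generalized inverse for degenerate strata); it
  matches `survival::survdiff` to 1e−8 on randomized instances in the
  suite, and is fast enough to sit inside the B = 1000 randomization
  loop. Arms smaller than 5 patients are skipped and logged rather than
  tested.
* Random null pair sets are drawn uniformly without replacement from the
  analysis gene universe, excluding the SL catalog. Uniform sampling is
  the neutral null; no degree or expression matching is attempted, and
  the prognostic statistic is the significant-pair count by default.
* The SynLethDB-style confidence scores of human pairs are carried
  through unused: no stated filter consumes them, and inventing a
  threshold would be a guess.
* miRNA–gene "adverse expression" is implemented as miRNA-down with
  gene-up; mixed-direction regulation is out of scope and noted as such.

## Interface

The exported functions are the primary interface, orchestrated by
`run_pipeline()` over a YAML config (see `make_fixture()` for a complete
worked configuration); `inst/scripts/slscreen.R` is a thin command-line
wrapper over the same two entry points.
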