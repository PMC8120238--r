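---
title: "Methods: from tissue RNA-seq to candidate small-RNA regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tissue RNA-seq to candidate small-RNA regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAcoexp)
```

## The problem

Bulk RNA-seq of several tissues along a differentiation axis — here
modelled on the bovine male reproductive tract: testicular parenchyma
(TP), head epididymis (HE) and tail epididymis (TE), sampled in four
animals (12 libraries) — quantifies mRNAs together with small
non-coding RNAs (miRNAs, snRNAs, snoRNAs). The scientific question is
which of the differentially expressed (DE) small RNAs plausibly
*modulate* the DE genes. No single statistic answers that; the package
chains several lines of circumstantial evidence:

1. **Differential expression** per pairwise tissue comparison
   (moderated t).
2. **Regulatory impact factor (RIF)** scores, ranking DE small RNAs by
   how strongly their co-expression with DE mRNAs differs between the
   two tissues of a comparison.
3. A **PCIT co-expression network** over all DE transcripts, keeping
   only correlations that survive an information-theoretic triple-wise
   test and exceed |r| > 0.95.
4. **Sequence-level confirmation** for miRNA candidates: a seed-site
   scan of negatively correlated mRNA neighbors, then the minimum free
   energy (mfe) of the miRNA:mRNA duplex, with mfe < −20 kcal/mol as
   the call threshold.
5. **Over-representation analysis** of DE lists and network clusters
   against user-supplied gene sets, with Holm (Bonferroni step-down)
   adjustment and kappa-score clustering of redundant terms.

A transcript that is a DE small RNA, RIF-significant, negatively and
extremely correlated with a DE mRNA, and whose duplex with that mRNA has
a seed site and mfe < −20 kcal/mol is reported as a candidate
down-regulator of that target — the package's final deliverable
(`triage_report()`).

## Normalization model

Counts become RPKM, `count / (mapped reads in millions × exon length in
kb)`, then `log2(RPKM + 1)`. The pseudo-count offset of 1 is
configurable; 1 keeps zeros at zero and is the common default.
`mapped_reads_millions` defaults to the column totals of the counts
matrix but can be supplied per sample (the sample sheet's
`mapped_reads` column); whenever the quantified transcripts are a
subset of the transcriptome the explicit totals are strongly preferred,
because column sums make the normalization sensitive to composition —
a handful of strongly induced transcripts deflate every other
transcript in that tissue.

Library (batch) effects are removed with the mixed model

$$y = \mu + L_{\text{library}} + g_{\text{gene}} + gt_{\text{gene:tissue}}
      + ga_{\text{gene:animal}} + e,$$

library fixed, the rest random. Variance components are estimated by
REML (`lme4`); with `varcomp_ratios` supplied, the model is solved
directly through Henderson's mixed-model equations (sparse Cholesky;
`solve_mme()`), which is also how the fit is verified against a dense
solve in the tests. Normalized values subtract only the sum-to-zero
constrained library solutions: gene, tissue and animal structure —
including the tissue contrasts that downstream stages test — is
deliberately retained. A single library passes through unchanged, and
the fit is idempotent. The model description admits two readings of the
random part (with or without gene:animal); the default fits the
superset and `drop_animal = TRUE` gives the smaller model.

## Differential expression

Transcripts with fewer than 3 samples at ≥ 2 RPKM are removed first.
The filter wording in the source protocol is ambiguous (read literally
it removes almost everything); the implemented rule is the standard
keep-if-expressed reading: keep a transcript iff ≥ `min_samples`
samples reach ≥ `min_rpkm`.

Per comparison (HE/TE, HE/TP, TE/TP — first-named tissue enters fold
changes positively), each transcript gets a pooled two-group variance
$s_g^2$ with $d_g = n_1 + n_2 - 2$ df and the empirical-Bayes moderated
statistic

$$\tilde t_g = \frac{\bar y_{1g} - \bar y_{2g}}
  {\tilde s_g \sqrt{1/n_1 + 1/n_2}}, \qquad
  \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

with p-values on $d_0 + d_g$ df. The prior $(d_0, s_0^2)$ is estimated
by the closed-form method of moments on $\log s_g^2$ (trigamma
inversion); on shared data the estimates agree with limma's `eBayes` to
numerical precision, which the test suite asserts. `d0 = 0` recovers
the ordinary t exactly and `d0 = Inf` the fully shrunk statistic. DE
calls require Benjamini–Hochberg adjusted p ≤ 0.05 *and* |log2FC| ≥ 1
(fold change ≥ 2); both thresholds are configurable. Tests are
two-sided and unpaired; animal blocking was left out because the
normalization model already absorbs gene-by-animal structure.

## RIF scoring

For a comparison with conditions 1 and 2, targets $j$ (DE mRNAs) and
regulators $i$ (DE small RNAs):

$$\mathrm{PIF}_j = \tfrac12 (e_{1j} + e_{2j})(e_{1j} - e_{2j}), \qquad
  \mathrm{DW}_{ij} = r_{1ij} - r_{2ij},$$

$$\mathrm{RIF1}_i = \frac1{n}\sum_j \mathrm{PIF}_j\,\mathrm{DW}_{ij}^2,
  \qquad
  \mathrm{RIF2}_i = \frac1{n}\sum_j \left[(e_{1j} r_{1ij})^2 -
  (e_{2j} r_{2ij})^2\right],$$

where $e_{cj}$ are condition means of normalized expression and
$r_{cij}$ within-condition Pearson correlations (set to 0 for constant
vectors). Scores are z-standardized across the regulators of a
comparison; |z| ≥ 1.96 on either score flags significance. Regulators
are paired with the DE genes of the *same* comparison (the protocol
text also contains a cross-comparison example; the surrounding sentence
states the same-comparison rule, which we take as authoritative —
`regulator_ids` lets a user run any pairing).

**Power caveat.** With four samples per condition, a within-condition
correlation is extremely noisy (sd ≈ 0.5 under the null), and every
decoy regulator's chance correlation with the dominant co-expression
factor mimics a true signal. Simulations show that a regulator coupled
to its targets in one tissue and *uncorrelated* in the other rarely
clears |z| ≥ 1.96 more than ~2/3 of the time no matter how many targets
it has. A regulator whose coupling *inverts sign* between tissues —
differential wiring in the strict sense, the construct RIF was designed
to measure — is recovered in ≳90% of runs. The synthetic generator
therefore plants the sign-inverting kind by default
(`regulator_rewire = TRUE`); `regulator_rewire = FALSE` gives the
weaker one-tissue coupling for sensitivity studies.

## PCIT

For every transcript trio $(x, y, z)$ the three first-order partial
correlations, e.g.

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
 {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

yield a local tolerance $\varepsilon_{xyz}$, the mean of the three
absolute partial-to-direct ratios. Edge $(x,y)$ is eliminated if some
$z$ satisfies $|r_{xy}| \le |\varepsilon\, r_{xz}|$ and
$|r_{xy}| \le |\varepsilon\, r_{yz}|$. Numerical guards: a denominator
$1 - r^2 < 10^{-12}$ sets the partial to 0, a zero direct correlation
contributes 0 to the tolerance — so $\varepsilon$ is always finite and
the significance matrix never contains NaN. The scan is $O(n^3)$ in
compiled code, deterministic, and verified flag-for-flag against an
independently coded brute-force R implementation on random matrices.
The network keeps edges that are PCIT-significant *and* |r| > 0.95
(`require_pcit = FALSE` uses the magnitude alone, for users who read
the protocol's threshold as self-sufficient).

Hubs are nodes with degree strictly above mean + 2 sd (sample sd;
ties at the threshold are not hubs); hub-centrality uses exact
unnormalized betweenness the same way. "Clusters" are connected
components, ordered by size then smallest member.

## miRNA target confirmation

Seed conventions follow TargetScan: position 1 is the miRNA 5′
nucleotide, the seed is nt 2–7, and on the target (5′→3′) the 6mer core
is the reverse complement of the seed. 7mer-m8 adds a match to nt 8 on
the core's 5′ side; 7mer-A1 adds an adenine on the 3′ side regardless of
the miRNA's nt 1; 8mer has both. Every core occurrence is reported once
with its most specific class, at 0-based coordinates. cDNA is scanned
by default (any sequence set can be supplied).

Hybridization energy is computed by a dynamic program over
intermolecular duplexes only: nearest-neighbor Watson–Crick stacks
(ten Turner-2004-style parameters completed by strand-flip symmetry),
a flat −1.3 kcal/mol stack for steps containing G:U, affine bulge
(3.3 + 0.5/nt) and internal-loop (1.0 + 0.6/nt) penalties capped at 15
nt per side, and a +4.09 duplex-initiation term. This is a compact
parameterization, not the full Turner table — energies land on the
right scale (a perfect 8-bp G:C helix scores −18.7 kcal/mol; a
22-nt perfect duplex ≈ −40) and all parameters are overridable through
`energy_params()`. If no structure is stabilizing the mfe is reported
as 0 with an empty structure; ties in the traceback resolve toward
stacking, then smaller target positions. The DP is verified against
exhaustive enumeration of all duplex structures for short sequences. A
pair is a confirmed target iff it has ≥ 1 seed site *and*
mfe < −20 kcal/mol.

## Enrichment

Over-representation uses the hypergeometric upper tail
(enrichment-only, matching the protocol tool's default) with Holm's
step-down procedure — the standard reading of "Bonferroni step-down".
The universe defaults to the transcripts passing the expression filter,
not the genome. Redundant significant terms are clustered by Cohen's
kappa between their membership indicators over the *query* genes; edges
at kappa ≥ 0.4, clusters = connected components, identical memberships
give kappa 1 by convention even when degenerate.

## The synthetic generator

`simulate_dataset()` draws negative-binomial counts
(variance $\mu + \phi\mu^2$, $\phi = 0.01$ by default) around
log-normal baselines, with:

* tissue effects of ±`log2fc_de`/2 on each planted DE transcript's pair
  (so the planted pairwise contrast is exactly `log2fc_de`, default 2);
* one hub miRNA regulator (default) up-regulated by `regulator_log2fc`
  (default 7 log2 units, the scale of the motivating study's hub miRNA)
  in its active tissue, its 40 mRNA targets following with alternating
  sign — half repressed, half co-activated;
* a per-sample latent factor of amplitude 0.4 log2 units shared between
  regulator and targets, whose target-side sign inverts outside the
  active tissue (differential wiring), with target-specific noise set so
  the design correlation is `regulator_correlation` (default 0.95);
* multiplicative library offsets ($2^{\pm 0.5}$ by default) on the
  count scale, which the normalization stage must remove;
* the true per-library sequencing depth recorded as `mapped_reads`,
  because the 500 simulated transcripts are a subsample of a
  transcriptome and column sums would misstate depth.

`simulate_sequences()` emits a 22-nt mature sequence per regulator and a
cDNA per mRNA. Planted 8mer targets carry the full-length complement of
the miRNA (which contains the 8mer site at the recorded position), so
both the site scan and the duplex energy behave as they do for genuine
strong targets; the other site classes plant the minimal site with
flanks chosen to block upgrade. All other sequence is rejection-sampled
free of any planted miRNA's seed core, which makes the planted site list
exactly recoverable — the round-trip against the scanner is a test.

What the generator does **not** emulate: animal (paired) effects,
realistic bovine base composition, isoform structure, GC/length bias,
overdispersion heterogeneity, or correlated background modules. Passing
tests therefore demonstrate correctness of the statistics and the
recoverability of planted structure under the stated noise model — not
performance on real tissue data.

## Problem sizes and determinism

Default analyses run at 500 transcripts × 12 samples; calibration
checks use 2,000-transcript null simulations and 20 seeds, sizes chosen
so the whole suite and the acceptance script run in minutes on a single
CPU while keeping Monte-Carlo error well inside the asserted margins.
Every stochastic step is seeded; a fixed seed reproduces every file
byte-for-byte. All tabular output is TSV, networks are GraphML or
SIF + attribute tables, and configuration objects validate their
invariants on construction.

## Known limitations

* The mixed model estimates one set of library effects jointly across
  genes; per-gene library adjustment is not offered.
* RIF significance at n = 4/condition has the power ceiling described
  above; treat |z| ≥ 1.96 as a ranking device, not a hypothesis test.
* The duplex energy model is deliberately compact; for publication-grade
  energies re-run candidate pairs through a full nearest-neighbor tool
  and expect rank agreement rather than identical values.
* Enrichment ignores ontology structure (no term hierarchy or
  parent-child pruning); supply flattened gene sets.
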