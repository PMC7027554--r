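---
title: "Methods: copy-number risk stratification and proteogenomic driver nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number risk stratification and proteogenomic driver nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`adenodrive` re-implements, as a reusable and fully tested pipeline, a
multi-omic analysis of colorectal adenoma progression: stratify adenomas
into high and low risk by arm-level copy-number events, compare the two
groups on RNA and protein level, score the tumor microenvironment, and
nominate progression drivers by concordant DNA/RNA/protein gene-dosage
effects. This vignette documents the statistical model of each stage, the
defaults and why they were chosen, and what the bundled simulator does and
does not emulate.

## The risk classifier

Seven arm-level copy-number changes are treated as colorectal
cancer-associated events (CAEs): gains of 8q, 13q and 20q and losses of
8p, 15q, 17p and 18q (`cae_universe()`). An adenoma with **two or more**
CAEs is a high-risk adenoma (HRA). Low-risk adenomas (LRA) are defined
conservatively: microsatellite-stable (MSS) lesions with **zero** CAEs.
Everything else is excluded with an explicit reason, with precedence
MSI > inconclusive CAE calling > exactly one CAE. This mirrors the
exclusion bookkeeping of the reference cohort this package models: of 30
adenomas, 9 HRAs, 15 LRAs and 6 exclusions (2 MSI, 2 single-CAE, 2
inconclusive) leave 24 unambiguously classifiable lesions — a composition
the test suite and acceptance script reconstruct exactly.

### From bins to arm calls

Input is a per-sample binned log2 read-depth ratio profile (BED-like TSV,
0-based half-open; 1 Mb bins by default, the usual granularity of
low-coverage WGS). `segment_profile()` runs recursive binary
segmentation: each chromosome is recursively split at the bin index
maximising the pooled-variance two-sample t statistic, and a split is kept
only when `n * log(RSS0 / RSS1) > penalty`. The default penalty 15
approximates a BIC charge of `3 * log(n)` for the extra mean and
breakpoint at typical arm sizes (50–150 bins); smaller penalties admit
occasional spurious splits of pure-noise stretches, which do not move true
step boundaries (the first cut always equals the exhaustive single-split
optimum, a tested invariant) but clutter the segment table. Segments tile
the binned territory exactly; the per-chromosome MAD of bin residuals is
attached to the segment set as an attribute.

`call_arms()` reduces segments to one call per arm of an hg19-derived arm
table (22 autosomes; acrocentric p-arms 13p/14p/15p/21p/22p dropped).
The gained (lost) fraction of an arm is the overlap-length-weighted share
of territory in segments with mean ≥ `gain_thr` (≤ `loss_thr`); defaults
±0.15 correspond to roughly a one-copy event at tumor purity ≈ 0.25, the
weakest signal worth calling at this bin size. An arm is called gain or
loss when the altered fraction reaches `min_altered_frac` (default 0.5),
and **inconclusive** when the chromosome's residual bin MAD exceeds
`noise_mad_max` (default 0.25) or gained and lost fractions are both above
threshold, or the arm is uncovered. "Inconclusive" has no standard
operational definition, so this noise/contradiction rule is a recorded
design choice; segments read back from SEG files carry no residual-noise
attribute and are treated as noise-free. All thresholds are exposed as
configuration because the original calling pipeline is described only by
reference.

## Differential expression

RNA counts are normalised to `log2 CPM` with pseudocount 0.5. Group
comparison uses an empirical-Bayes moderated t: per gene the pooled
variance `s_g^2` on `d_g` degrees of freedom is shrunk to
`(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, with the prior `(d0, s0^2)`
estimated by moment matching on `log s_g^2` (digamma/trigamma matching of
the log-F distribution, the same estimator the limma package uses; the
test suite cross-checks both `d0` and the per-gene t against limma). One
deliberate boundary convention: when the spread of `log s_g^2` does not
exceed its pure-sampling expectation, the prior is taken as `d0 = Inf`
with `s0^2` equal to the *geometric mean* of the observed variances, so
that exactly equal gene variances are shrunk to themselves and the
moderated t degenerates to the ordinary pooled t.

Protein log-intensities use the same machinery with pairwise-complete
observations and a per-group observed-fraction gate (default 0.6); missing
values are never imputed, because the missingness mechanism of DIA mass
spectrometry (dropout of low-intensity measurements) would bias any
imputation that ignores it.

Ranked lists for GSEA score genes by `sign(logFC) * -log10(p)` (p floored
at 1e-300), with ties broken by `|logFC|` then gene id so the order is a
deterministic function of the table. The exact fold-change/p-value
combination is a recorded design choice; the constraint it satisfies is
that significantly overexpressed group-A genes sit at the top of the
list.

## Enrichment

`es_preranked()` is the weighted Kolmogorov–Smirnov-like running sum:
hits advance by `|score|^p` (normalised over the set, p = 1 by default),
misses retreat by `1/(N - k)`; the enrichment score is the extreme signed
deviation. Walk extremes occur only adjacent to hits, so the
implementation evaluates just-before/just-after values per hit; exact
± ties (measure-zero for continuous scores) resolve to the earlier
position in the walk. With p = 0 the statistic reduces to the classic KS
statistic, and the test suite checks exact equality against the fgsea
package's statistic.

Significance uses a **gene-tag permutation null** (random member sets of
equal size drawn from the ranked universe): at 9 vs 15 samples a
phenotype-permutation null would be both noisy and inconsistent with
ranking by a DE statistic. Nominal p is the plus-one estimator over
same-sign null scores (so p ≥ 1/(n_perm + 1)); NES divides by the mean
magnitude of same-sign nulls; FDR q follows the GSEA ratio estimator on
the pooled normalised null. Sets are flagged enriched at q ≤ 0.15, a conventional reporting
threshold for hallmark-set enrichment at small group sizes.

`ssgsea_score()` ranks genes per sample (stable tie-break by gene order)
and sums the difference between the rank-weighted in-set ECDF (weights
`rank^alpha`, alpha = 0.25) and the unweighted out-set ECDF; raw scores
are normalised by the max–min range across the run. ESTIMATE-style
scoring is exactly this statistic applied to a stromal and an immune
signature; the microarray-specific tumor-purity transform of the original
ESTIMATE method is out of scope, and the signatures are user-supplied
(the simulator generates matched synthetic ones).

## Gene-dosage analysis and driver nomination

`gene_copy_number()` assigns each gene the overlap-length-weighted mean
log2 of overlapping segments. `dosage_correlations()` computes, per gene
and within an analysis group (all adenomas, or all CRCs), the three
pairwise correlations CN–RNA, CN–protein and RNA–protein, with
t-approximation p-values and BH adjustment *within each pair type*; a
gene passes when all three correlations are positive with q ≤ 0.05.

**Correlation default is Pearson, not a rank method.** In unaltered
samples the gene-level CN estimate is a near-constant plus sub-threshold
segment jitter; midranks promote that jitter to full rank variation and
dilute genuine dosage relations roughly by half in cohorts where only a
minority of samples carry the event. Pearson on log2 values — the common
choice in proteogenomic dosage analyses — is robust to this; Spearman
remains selectable for heavy-tailed data.

`nominate_drivers()` encodes the candidate logic: a driver must
pass the three-way test in **both** adenomas and carcinomas, lie on a CAE
arm, and sit on an arm whose events among HRAs are **gain-only**
(`direction_on_arm()`); arms with mixed gains and losses — 8p behaves this
way — are excluded because opposite dosage directions within the group
make "amplified and overexpressed" uninterpretable. The audit table keeps
per-filter flags.

## Validation statistics

`ihc_score()` is the exact product of epithelial staining intensity
(0–3) and percent positive cells (0–100), range 0–300. `mann_whitney()`,
`fisher_exact()` and `spearman_corr()` fix conventions over the standard
base-R implementations: exact Mann–Whitney enumeration when
`nA + nB <= 12` without ties (normal approximation with tie and
continuity correction otherwise, p = 1 when all values coincide);
two-sided Fisher p as the hypergeometric mass of tables no more likely
than observed (p = 1 on an empty margin); Spearman rho with midranks and
the two-sided t-approximation p on n − 2 degrees of freedom. Each is
tested against brute-force enumeration oracles.

## The simulator: what it emulates

`simulate_cohort()` generates, from one seed and bit-for-bit
reproducibly, the full input bundle for 18 normal / 15 LRA / 9 HRA /
30 CRC samples (the modeled study design):

* **Arm events.** HRAs always carry ≥ 2 CAEs; LRAs and normals none;
  CRCs follow per-CAE frequencies, much lower for the 20% of CRCs planted
  MSI (chromosomally quiet, as observed for MSI tumors). Per-arm CAE
  frequencies have no fixed reference values, so the defaults (20q+ most
  frequent, at 0.8 in both HRA and MSS CRC) are one-time plausible
  choices, exposed as configuration. Gains draw 1–3 extra
  copies (probabilities 0.55/0.3/0.15) — arm gains in chromosomally
  unstable colorectal tumors are frequently multi-copy — anchored so one
  extra copy gives `log2(3/2)`; losses are one-copy. Gains of
  loss-direction CAE arms occur at low rate (an 8p gain riding a
  whole-chromosome-8 gain), which is what makes mixed-direction arms
  possible; gain-direction CAE arms are never lost, matching their
  near-absence in chromosomally unstable colorectal tumors.
* **Bulk dilution.** Observed copy-number signal is
  `log2(purity * 2^planted + 1 - purity)` (purity defaults 0.75 adenoma /
  0.65 CRC with ±0.05 sample jitter), plus Gaussian bin noise (sd 0.1).
  Purity and the planted stroma percentage are drawn separately; stroma
  medians are the modeled study conditions 40.89% (HRA) and 27.20% (LRA).
* **RNA.** Negative-binomial counts (dispersion 0.01, library 1e6) whose
  means multiply by `2^(beta * CN_log2)` for dosage genes (beta = 1),
  by class-dependent factors for planted differential genes, and by
  stroma/immune-fraction-coupled factors for signature genes. Planted DE
  and signature genes live on non-CAE arms so the dosage ground truth
  stays uncontaminated by class-correlated copy number.
* **Protein.** Log-intensity is an offset plus 0.9 times the *realized*
  RNA logCPM deviation plus noise (sd 0.08): protein is synthesised from
  the same transcript pool the RNA assay measures, so biological
  variation is shared between layers and attenuated on protein level.
  Dropout is logistic in the true intensity
  (`plogis((9 - intensity)/1)`, ≈ 5% overall), the standard
  missing-not-at-random behaviour of DIA proteomics. Planted dosage
  genes are always protein-quantified — a three-layer dosage effect is
  only defined for quantified proteins — with the remaining quantified
  fraction (60% of genes) chosen by abundance.

The residual-noise defaults (count dispersion, protein noise, dropout)
were calibrated **once**, before the test suite was frozen, so that the
planted effects are recoverable at the modeled group sizes — recovery of
planted classes ≥ 95%, dosage sensitivity ≥ 0.8 at FDR ≤ 0.1, and
nomination of every planted 20q driver with no null nominations in ≥ 90%
of replicate seeds — which is precisely what the acceptance checks then
verify end-to-end. They represent a clean-measurement regime: the
explicit planted effects are the dominant biological variation, and the
residual captures technical noise only.

What the simulator does **not** emulate: focal and sub-arm events,
GC/mappability bin artifacts, batch effects, inter-gene correlation
beyond the planted structure, tied library-size variation, isoforms, and
peptide-level protein inference. Passing tests therefore demonstrate that
the statistical machinery recovers planted structure under the stated
noise model — not that the pipeline is robust to every artifact of real
sequencing or DIA data.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; SEG files are written
  1-based inclusive and converted on read.
* Numerically constant segments (RSS < 1e-12) are never split; zero-variance
  genes get a variance floor of 1e-12 and p = 1 when the fold change is 0.
* BH adjustment excludes NA p-values from the multiplicity count and
  propagates them.
* `rank_genes`, `ssgsea_score` and `detect_caes` break all ties by stable
  gene/arm order, so outputs are invariant to input permutation.
* Perfect correlations (|r| = 1) are reported with p from the
  t-approximation at the machine-epsilon floor of `1 - r^2`.
* GSEA p-values can never be 0 (plus-one estimator); a degenerate
  one-signed null yields the minimum attainable p.
* `run_pipeline()` aborts naming the failing stage; every artifact
  carries the run seed and a config hash.

## Problem sizes used in the checks

The automated checks run on the default cohort (72 samples, 1000 genes,
2875 bins per sample), 20 replicate seeds for the end-to-end driver
recovery, 50 replicates of 2000-gene null matrices for moderated-t
calibration, and 50 × 20 random sets at 200 permutations for GSEA
calibration. These sizes give stable Monte-Carlo estimates for the
tolerances tested (rates within ±50% of nominal alpha, sensitivities with
20 planted positives).

## Known limitations

* **Library-composition coupling.** Classes with strong planted
  up-effects (stroma, DE, dosage) have higher total expression, so logCPM
  of unaffected genes shifts slightly downward in those classes. This is
  the familiar composition artifact of CPM-type normalisation; it inflates
  the count of nominally "down" genes in cohort-level DE (a TMM-style
  scale factor would mitigate it) but does not contaminate the dosage
  ground truth, which is evaluated per gene against planted flags.
* The arm model fixes boundaries at centromere midpoints of hg19; no
  sub-arm resolution.
* FDR for GSEA uses the ratio estimator, which can be conservative or
  anticonservative for very small collections; with fewer than ~10 sets
  nominal p is the more reliable quantity.
* Where the field's pipelines genuinely differ (exact DE method, GSEA
  null, correlation statistic, significance cut-offs), this package fixes
  reasonable, fully documented conventions rather than guessing any one
  lab's choices; cohort-level counts from real data are therefore
  comparable in kind, not in value, across convention sets.
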