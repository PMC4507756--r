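---
title: "Guide-gene co-expression screening: model, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-gene co-expression screening: model, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

## The screening model

`coexscreen` formalises a transcriptome co-expression screen for pathway
regulators. The biological premise is that a coordinately regulated
biosynthetic pathway — the running example is the flavonoid pathway of
ripening strawberry fruit — expresses its structural genes in concert
across genotypes, so a transcription factor whose transcript tracks many
pathway members is a plausible regulator of the pathway. The statistical
machinery is deliberately simple and transparent:

* **Association measure.** The Pearson product–moment correlation $r$
  between two genes' expression profiles across the $n$ genotypes of a
  segregating population (two parents plus their progeny).
* **Significance.** The exact t transform
  $t = r\sqrt{\nu} / \sqrt{1 - r^2}$ referred to a t distribution with
  $\nu$ degrees of freedom, two-tailed. By default $\nu = n - 2$; a
  `df_override` lets the caller evaluate P-values at a stated df when
  replicating an analysis whose reported df implies a different effective
  sample count than the full population (11 df implies 13 observations per
  comparison; which genotypes were excluded cannot be recovered from a
  report, so the override reproduces the stated statistics without
  guessing).
* **Hard thresholding.** A pair is a *positive edge* iff $r > 0.65$ and
  $P < 0.05$, both strict. No multiplicity adjustment is applied in this
  replication profile (none was applied in the analyses the pipeline
  mirrors); a Benjamini–Hochberg option would be a one-line extension of
  the edge table and is intentionally not a default.
* **Screen rule.** A candidate with at least `min_links = 4` positive
  links to the 15 guide roles is retained. Isoforms (PAL1/PAL2, CHS1/CHS2)
  count as separate roles.

A useful analytic fact, asserted in the test suite: at $\nu = 11$ the
critical $r$ for two-tailed $P = 0.05$ is
$t_{0.975,11} / \sqrt{11 + t_{0.975,11}^2} \approx 0.553 < 0.65$, so under
that df the $r > 0.65$ condition *implies* $P < 0.05$ — the correlation
threshold is the binding rule, and link counts can be reproduced from
printed coefficient tables alone (`count_positive_links()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `rpkm_min` | 0.5 RPKM | strict expressed-gene floor |
| `fold` | 2 | strict DEG ratio threshold |
| `pseudocount` | 0 | added to both profiles before ratios; 0 keeps the convention that $q>0, c=0$ counts as up-regulated |
| `r_min`, `p_max` | 0.65, 0.05 | positive-edge rule, strict inequalities |
| `df_override` | `NULL` | evaluate P at a stated df instead of $n-2$ |
| `transform` | `"none"` | correlate RPKM as loaded; `"log2p1"` correlates $\log_2(\mathrm{RPKM}+1)$ |
| `min_links` | 4 | retention floor of the candidate screen |

Strictness of every inequality follows the screen's published wording
("RPKM > 0.5", "> 2-fold", "r > 0.65"): boundary values are excluded, and
the tests pin that behaviour (a gene at exactly 0.5 RPKM is not expressed;
a ratio of exactly 2 is not differential).

No transform is applied before correlation by default, because the
replication profile makes no claim about one. For simulated data we
routinely use `transform = "log2p1"`: the generator's planted correlations
live on the log scale, and $\log_2(\mathrm{RPKM}+1)$ is an affine function
of the latent Gaussian for well-expressed genes, so the sample correlation
then estimates the planted coefficient directly rather than the attenuated
raw-scale correlation of a log-normal pair. Outputs record the transform
used.

Zero-variance profiles yield an explicitly *undefined* correlation
(`defined = FALSE`), never a silent $r = 0$ — silent zeros would corrupt
degree counts and screen tallies.

## Differential expression and clustering

`count_deg()` tallies genes whose ratio between two genotypes exceeds the
fold threshold, over the universe of genes expressed in at least one of the
two samples (this avoids 0/0 among doubly-silent genes). The definition
forces the antisymmetry $n_\mathrm{up}(A,B) = n_\mathrm{down}(B,A)$ on any
universe, which the implementation enforces and the tests verify —
reported DEG tables occasionally violate it narrowly (upstream rounding or
per-row filtering), which we treat as an inconsistency of the source
table, not behaviour to reproduce. With `pseudocount = 0` the counts are
invariant to common rescaling of both profiles.

`cluster_genotypes()` defaults to correlation distance
($1 - r$ on $\log_2(\mathrm{RPKM}+1)$) with average linkage — the
conventional choice for expression-profile dendrograms; no method was
stated in the analyses being mirrored, so the choice is recorded in the
result object and the Newick export.

## qPCR quantification

`delta_delta_ct()` implements the Livak $2^{-\Delta\Delta C_t}$ estimator
with the standard conventions: arithmetic mean of replicate Cts before
$\Delta C_t$; the control baseline is the *mean* $\Delta C_t$ over all
control samples (matching assays where each treated fruit is compared to
the control pool); replicate SD propagates as
$\sqrt{s^2_\mathrm{target} + s^2_\mathrm{ref}}$. Because $\Delta C_t$ is a
within-sample difference, any per-sample cycle shift common to target and
reference cancels exactly — the normalisation contract, tested directly.
Primer efficiencies from dilution series
($E = 10^{-1/\mathrm{slope}} - 1$) are reported but never used to correct
fold changes by default; a Pfaffl-style correction is deliberately out of
the default path because the readouts being mirrored were pure
$2^{-\Delta\Delta C_t}$. Group significance uses a two-sided Welch t-test
(treatment vs control) or one-way ANOVA across stages; all-constant groups
return the limiting P with a `degenerate` flag instead of an error.

Replicate dispersion is emitted per sample (technical-replicate SD on the
$\Delta C_t$ scale) while the group test operates across biological
samples; both levels are available because reported SDs in this kind of
assay are ambiguous between the two.

## What the generator emulates — and what it does not

`simulate_population()` draws log-normal RPKM with a Gaussian latent layer:

* module guides share a factor $F$ with loading $\sqrt{\rho}$, giving every
  within-module pair latent correlation exactly $\rho$
  (`guide_module_rho`, default 0.8 — calibrated so observed coefficients
  land in the 0.67–0.81 range typical of printed pathway tables);
* each planted TF is $w\,u + \sqrt{1-w^2}\,\varepsilon$ where $u$ is the
  standardised mean of its linked guides' latents and
  $w = \rho_\mathrm{target} / \sqrt{(1+(k-1)\rho)/k}$ for $k$ linked
  guides; $w > 1$ (an unsatisfiable request) fails before sampling;
* background genes are independent; a `dropout_fraction` (default 0.1) is
  silenced at meanlog $\log 0.05$ with sdlog 0.3, far below the 0.5 RPKM
  floor;
* marginals: meanlog 5.7 (≈ 300 RPKM) for guides, matching the
  hundreds-scale expression of pathway structural genes, and meanlog 3
  (≈ 20 RPKM) for TFs and background, matching the tens-scale expression
  of regulator transcripts; sdlog 1;
* defaults mirror the mirrored study design: 16 genotypes (2 parents + 14
  progeny), 15 guides, a 1897-entry candidate list, module membership
  excluding the tannin- (LAR, ANR), flavonol- (FLS) and F3'H roles —
  the branch structure observed in ripe fruit, where only
  anthocyanin-directed genes intercorrelate.

The generator does **not** emulate: count-level sampling noise (RPKM are
smooth log-normals), homoeolog/ploidy structure, linkage between
genotypes, batch effects, or guide–guide correlations that differ by pair
(the module is exchangeable). Passing recovery tests therefore shows the
screen's statistical machinery is correct and well calibrated at the
study's size — not that real octoploid fruit data meet the generator's
assumptions.

`simulate_qpcr()` builds Cts as
$C_t = \mathrm{baseline} - \log_2(\mathrm{abundance}) + N(0, \sigma)$ with
a reference gene at constant abundance, so the noise-free case is recovered
exactly ($\Delta\Delta C_t = -4$ for a 16-fold change) and the noisy case
is unbiased on the $\log_2$ scale.

## Numerical choices and degenerate inputs

* $|r| = 1$ maps to $t = \pm\infty$ and the limiting $P = 0$.
* Ties at thresholds are excluded everywhere (strict inequalities).
* Equal link counts in the screen are ordered lexicographically by gene ID
  for deterministic reports.
* Candidates absent from the matrix are skipped with a logged count, not
  fatal; candidates overlapping the guide set are fatal.
* Missing cells in expression TSVs are rejected by default; a permissive
  mode drops incomplete genes and reports how many, because complete
  vectors are required by every downstream Pearson computation.
* Gene identifiers are opaque strings; no structure is parsed from them.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
brute-force oracle comparisons on matrices up to 6 genes × 8 samples (100
draws), permutation nulls at $10^5$ replicates on 10 fixtures, planted-TF
recovery on 16 genotypes × (15 guides + 3 planted + 500 background) over
20 seeds, and $2^{-\Delta\Delta C_t}$ recovery over 50 seeds. These sizes
give stable Monte-Carlo comparisons (binomial/SE tolerances are computed,
not guessed) while keeping a full run in well under a minute for the unit
suite.

## Known limitations

* Pearson correlation on raw RPKM conflates marginal skew with dependence;
  the `log2p1` transform is available but not forced, to keep the
  replication profile faithful.
* Hard thresholding ignores the multiplicity of the 1897-candidate screen;
  the per-candidate false-positive probability at 4-of-15 links is small
  but nonzero (the suite measures background retention well under 5%).
* The df override applies one df to every pair; datasets with per-pair
  missingness would need per-pair df, which the mirrored analysis did not
  report and this package does not attempt.
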