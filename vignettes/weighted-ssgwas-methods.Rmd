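---
title: "Weighted single-step GWAS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dairy populations are rarely fully genotyped: phenotypes and deep
pedigrees exist for many more animals than SNP panels do. Single-step
genomic BLUP (ssGBLUP) analyses all animals jointly by replacing the
pedigree relationship matrix with a blend of pedigree and genomic
information, and a single-step GWAS then converts the resulting genomic
breeding values into per-SNP allele substitution effects and per-window
shares of the additive variance. This package implements that pipeline —
quality control, relationship matrices, variance-component estimation,
effect back-solving with iterative re-weighting, and window-level
reporting — together with a gene-dropping simulator of the cohort design
it targets: roughly six hundred cows descended from 19 sire families
across 19 farms, with milk protein composition traits.

## Model

The animal model is

$$y = X\beta + Wa + e,\qquad
\operatorname{var}\begin{pmatrix}a\\e\end{pmatrix} =
\begin{pmatrix}H\sigma^2_a & 0\\ 0 & I\sigma^2_e\end{pmatrix},$$

with fixed effects overall mean, farm, lactation and parity
(treatment-coded categorical factors), and one additive genetic effect
per pedigree animal. The single-step relationship inverse is

$$H^{-1} = A^{-1} +
\begin{pmatrix}0 & 0\\ 0 & G_w^{-1} - A_{22}^{-1}\end{pmatrix},$$

where $A$ is the numerator relationship matrix (tabular method, exact
inbreeding), $A_{22}$ its genotyped block, and $G_w$ a tuned, blended
VanRaden genomic matrix: $G = Z D Z' \lambda$ with
$\lambda = 1/\sum_i 2p_i(1-p_i)$, $Z$ the allele-frequency-centered
genotypes and $D$ diagonal SNP weights ($D = I$ on the first pass).

SNP effects are back-solved from the genotyped animals' breeding values
through the equivalence of the SNP and animal models,

$$\hat u = \lambda D Z' G^{*-1}\hat a_g = D Z' (Z D Z')^{-1}\hat a_g,$$

each SNP's variance share is $\hat u_i^2\, 2p_i(1-p_i)$, and one
re-weighting iteration rebuilds $G^*$ with $d_i \propto$ these shares
before re-solving — the single-iteration scheme that maximises GEBV
accuracy in the weighting literature. Windows of five adjacent SNPs
(sliding step 1) are scored by the sample variance of their summed
genetic values across genotyped animals as a percentage of
$\sigma^2_a$; windows at or above 0.5% are "informative".

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `call_rate_min` | 0.90 | SNPs strictly below are removed first |
| `maf_min` | 0.05 | minor allele frequency floor (strict) |
| `hwe_p_min` | 1e-6 | 1-df chi-square HWE P floor (strict) |
| `tau` | 0.05 | weight of $A_{22}$ blended into the tuned $G$ |
| `window_size` | 5 SNPs | window span for variance decomposition |
| `window_step` | 1 | moving windows; set to `window_size` for blocks |
| `ve_threshold` | 0.5% | informative-window selection (inclusive) |
| `chain_length` / `burn_in` | 100,000 / 9,000 | Gibbs schedule at study scale |
| `reweight_iters` | 1 | re-weighting passes after the $D=I$ solve |
| `bonferroni_alpha` | 0.01 | genome-wide rate; threshold $-\log_{10}(\alpha/N)$ |

All three QC filters use strict inequalities, so a SNP at exactly the
boundary (call rate 0.90, MAF 0.05, HWE P $10^{-6}$) is retained, and
each removed SNP is attributed to the first filter it fails in the order
call rate → MAF → HWE. At desk scale the analysis scripts and tests use
Gibbs chains of 4,000–10,000 rounds with 800–1,000 burn-in; posterior
summaries stabilise well before that on cohorts of a few hundred
animals, and effective sample sizes are reported so short chains are
visible.

## Numerical choices

* **Relationship matrices.** $A$ is built by the dense tabular method and
  inverted by Henderson's rules with exact inbreeding taken from the
  tabular diagonal; population sizes here (hundreds to a few thousand)
  make the dense path simple to verify against direct inversion, which
  the tests do. $A_{22}^{-1}$ and $G_w^{-1}$ are dense factorizations.
* **Compatibility tuning.** $G$ is adjusted to $A_{22}$ by the two-moment
  scheme: scalars $(a, b)$ match the mean diagonal and the overall mean
  of $a + bG$ to those of $A_{22}$; blending with $\tau = 0.05$ then
  guarantees invertibility. The tuning coefficients are kept in the
  matrix metadata so runs are reproducible.
* **Back-solving.** Column-centering at the observed allele frequencies
  places the ones vector in the null space of $ZDZ'$, so the "raw"
  system in the identity above is singular in every full pipeline run.
  The implementation therefore solves against the blended $G_w$ (with
  $\lambda$ reinstated, since it no longer cancels) and warns; when no
  blended matrix is available it returns the minimum-norm least-squares
  solution, which reduces to the textbook single-SNP projection
  $\sum_i z_i \hat a_i / \sum_i z_i^2$.
* **Weight normalisation.** Next-iteration weights are rescaled to a
  constant trace $\sum d_i = M$, preventing variance-scale drift across
  iterations; with all-zero effects the weights fall back to 1.
* **Gibbs sampler.** Conjugate two-block Gibbs: $(\beta, a)$ jointly from
  the multivariate-normal full conditional through a Cholesky solve of
  the mixed-model coefficient matrix, then $\sigma^2_a$ and $\sigma^2_e$
  from scaled inverse chi-squares with flat priors (degrees of belief
  $-2$). Joint location sampling mixes better than single-site updates
  and is exactly reproducible under a seed. A Metropolis–Hastings
  sub-step is sometimes layered into such samplers for non-Gaussian
  extensions; nothing in the Gaussian model here requires one, so the
  sampler is pure Gibbs.
* **Significance testing.** The default per-SNP t statistic
  $\hat u_i / \sqrt{\hat\sigma^2_{u,i}/n}$ is retained for fidelity to
  the published formula even though plugging
  $\hat\sigma^2_{u,i} = \hat u_i^2 2p_i(1-p_i)$ into it makes $|t|$
  independent of $\hat u_i$ — a degenerate test. An `"empirical"` mode
  (effects scaled by their genome-wide SD) is provided as the usable
  alternative; the shipped tests check its calibration on a pure-noise
  simulation (the fraction of SNPs at P < 0.05 must fall in [0.02,
  0.10]). The genome-wide threshold is
  computed from $-\log_{10}(\alpha/N)$, which gives 7.77 at
  $\alpha = 0.01$ and $N = 586{,}304$.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults encode the target study design: 614 cows bred
from 19 founder sires (two generations below the founders), 598 of them
genotyped, 19 farms and 3 lactation/parity classes as fixed effects
(SDs 0.3/0.2/0.1 of the phenotypic SD — herd effects are the largest
non-genetic source in dairy traits, parity the smallest), the trait on
the alpha-s1-casein scale (mean 35.45, SD 17.46 wt/wt%), heritability
0.3 (mid-range of published milk protein composition estimates), and
one QTL absorbing 25% of $\sigma^2_a$, echoing the DGAT1-region window
that dominates alpha-s2-casein in the reference results. Genotypes are
gene-dropped: founder allele frequencies uniform on (0.05, 0.5),
Bernoulli transmission per parent per locus.

Loci are simulated **without linkage disequilibrium**. That is a
deliberate simplification: it makes window variances additive (the sum
of disjoint-window VEs is ~100% of the genic variance, a property the
tests exploit) and supports parameter-recovery and calibration checks,
but it understates the multi-window signal spread that LD produces
around a real QTL, and panel SNPs tag a hidden causal variant only
through family co-segregation (`hide_qtl = TRUE` exposes that regime).
Passing tests therefore validate the machinery and its statistical
calibration, not the LD fine-mapping behaviour on real chips. Marker
density (2,000 SNPs on 5 chromosomes by default) is desk-scale, chosen
so the full pipeline runs in seconds; all stages are dense-linear-algebra
bound and scale as $O(n^3)$ in pedigree size.

## Known limitations

* No metafounders or unknown-parent groups in $A$; unknown parents
  contribute founder variance.
* Univariate analyses only; traits are fitted one at a time.
* No binary PLINK or VCF ingestion — genotypes come from additive text
  plus a 4-column map.
* The QC mean-imputation path exists for synthetic/degenerate inputs;
  real panels are expected to arrive fully imputed.
* Window ids are assigned on the post-QC panel, so they are not
  comparable to ids assigned on a pre-QC panel.
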