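---
title: "Gene-based multi-marker tests for quantitative traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based multi-marker tests for quantitative traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genebin)
```

## The problem

A gene region typically contains several SNPs in linkage disequilibrium
(LD). When a causal variant is untyped — common in array-based studies
supplemented with sparse low-frequency genotyping — the typed SNPs carry
only *indirect* association signal, attenuated by their correlation with
the causal variant. Testing each SNP separately then loses power, and a
gene-level (multi-marker) test is preferable. `genebin` implements a
family of such global tests for a quantitative trait, built on joint and
marginal linear regression, together with the LD-binning machinery,
omitted-causal-variant theory, and a seeded simulation engine for
evaluating type-I error and power.

Genotypes are coded additively as minor-allele counts $X_j \in \{0,1,2\}$.
SNPs are classified by sample minor allele frequency (MAF): *common*
(MAF $\ge 0.05$), *low frequency* ($0.01 \le$ MAF $< 0.05$); SNPs under
1% are excluded at load time. Three analysis sets are supported — all
SNPs, common only, low frequency only — reflecting the combined-analysis
question: which subset should enter the gene-level model when causal
variants may be rare?

## Regression framework

The joint model regresses the trait on all $K$ SNPs at once,

$$E[Y] = \beta_0 + \beta_1 X_1 + \cdots + \beta_K X_K,$$

yielding $\hat\beta$ with covariance $\Sigma_B = \hat\sigma^2
[(X'X)^{-1}]_{\text{SNP block}}$ (`fit_joint()`). The marginal models fit
one simple regression per SNP (`fit_marginals()`); the cross-covariance
of the marginal estimates is obtained by a GEE-type construction on
centered genotype columns,

$$\mathrm{Cov}(\hat\beta^M_i, \hat\beta^M_j) =
  \hat\sigma_0^2 \,\frac{\tilde x_i'\tilde x_j}
  {(\tilde x_i'\tilde x_i)(\tilde x_j'\tilde x_j)},$$

with $\hat\sigma_0^2$ the trait variance under the intercept-only null
model (unbiased, $n-1$ denominator — a convention choice documented here
once). A useful exact property follows: the correlation of the marginal
estimates equals the genotype correlation $r_{ij}$, which the test suite
asserts to $10^{-10}$.

Sample-collinear columns (a real possibility when two tightly linked
low-frequency SNPs produce identical genotype columns in a finite
sample) are dropped deterministically before the joint fit, keeping the
lowest column indices. Determinism matters more than the particular
choice here; the dropped indices are reported on the fit object.

## The statistics

Twelve global statistics are available, summarised below. $J$ is the
$K \times L$ 0/1 bin-indicator matrix, $Z_j = \hat\beta_j /
\sqrt{\Sigma_{B,jj}}$, and $\Sigma_Z$ the correlation of $\hat\beta$.

| Statistic | Regression | Form | Null |
|---|---|---|---|
| Wald | joint | $\hat\beta'\Sigma_B^{-1}\hat\beta$ | $\chi^2_K$ |
| MLC-B | joint | $(W_s'\hat\beta)'(W_s'\Sigma_B W_s)^{-1}(W_s'\hat\beta)$, $W_s = \Sigma_B^{-1}J(J'\Sigma_B^{-1}J)^{-1}$ | $\chi^2_L$ |
| MLC-Z | joint | as MLC-B with $(Z, \Sigma_Z)$ | $\chi^2_L$ |
| LC-B / LC-Z | joint | MLC with the single all-ones bin | $\chi^2_1$ |
| PC80 | joint | Wald form on the leading principal components | $\chi^2_S$ |
| MinP-J / MinP-M | joint / marginal | min two-sided p, MVN-adjusted | MVN$(0,R)$ |
| SSB | marginal | $\sum_i (\hat\beta^M_i)^2$ | $\sum_i c_i\chi^2_1$ |
| SSBw | marginal | $\sum_i (\hat\beta^M_i)^2/\mathrm{Var}(\hat\beta^M_i)$ | $\sum_i c_i\chi^2_1$ |
| SKAT | marginal score | $y_c'X_c W X_c' y_c$, $w_i = \beta(p_i;1,25)^2$ | $\sum_i c_i\chi^2_1$ |
| SKAT-C | marginal score | $\varphi\,\mathrm{SKAT}_{LF} + (1-\varphi)\,\mathrm{SKAT}_{common}$ | $\sum_i c_i\chi^2_1$ |

Identities tie the family together and serve as exact regression tests:
MLC-B with singleton bins *is* the Wald test; MLC with one bin *is* LC;
PC80 with all components retained *is* Wald; at $K=1$ everything
collapses to the squared Z test.

### MLC and LD binning

The MLC compromise — linear combination within a bin of highly
correlated SNPs, quadratic across bins — needs two ingredients:

1. **Bins** (`ldselect_bins()`): a greedy clustering at $r^2 > 0.5$
   (configurable). Among unassigned SNPs, the one with the most
   unassigned partners above threshold seeds the next bin together with
   those partners, so bigger bins form first. Ties are broken by lowest
   SNP index: the greedy literature is silent on ties, and
   reproducibility requires a fixed rule. Binning uses $r^2$, so it is
   invariant to allele-coding flips.
2. **Coding correction** (`coding_correction()`): within each bin,
   members are scanned in ascending index; a member whose count of
   strictly negative correlations with the other members exceeds half of
   them (strict inequality: flip when `neg > (size-1)/2`) is recoded
   $g \to 2-g$ and the bin correlations recomputed immediately. One full
   sequential pass per bin reaches a fixed point on the structures
   binning produces, which the suite asserts by re-running the
   correction. Correction is applied within bins only; gene-wide
   correction would alter SNPs whose coding never enters a linear
   combination. Since flips do not change $r^2$, the order
   binning-then-correction is internally consistent and bins are not
   recomputed after flips. MAF metadata always refers to the minor
   allele and is untouched by flips.

### Mixture-of-chi-square nulls

SSB, SSBw, SKAT and SKAT-C are quadratic forms in asymptotically normal
quantities, so their null laws are weighted mixtures
$\sum_i c_i \chi^2_1$ with $c_i$ the eigenvalues of the relevant
(weighted) covariance: $\Sigma^M_B$ for SSB, its correlation matrix for
SSBw, and $\hat\sigma_0^2 \cdot \mathrm{eig}(W^{1/2}X_c'X_cW^{1/2})$ for
SKAT. Eigenvalues that come out slightly negative from floating-point
noise (within $10^{-10}$ of the largest) are clipped to zero; larger
negative values trigger a warning.

Tail probabilities default to Liu-type moment matching (mean, variance
and skewness matched to a chi-square surrogate): it is dependency-free,
smooth, and accurate to a few times $10^{-3}$ at the 0.05 level used
throughout, which the suite verifies against $10^6$-draw Monte-Carlo
tails. An exact alternative (`method = "davies"`) inverts the
characteristic function by Imhof's integral, truncated where the
integrand envelope bounds the remaining tail below $10^{-5}$; one-weight
and equal-weight cases are recognised as scaled chi-squares and computed
exactly. P-values are clipped to $[10^{-16}, 1]$.

**SKAT centering.** The textbook SKAT quadratic form is written in raw
$Y$, but under an intercept-only null model it is the *centered* trait
(and centered genotypes) that make the mixture null exact; `skat_test()`
therefore centers both. This is a deliberate deviation from the literal
formula, made so that the stated null distribution is the correct one.

**SKAT-C.** The combined statistic mixes a Beta(1,25)-weighted
low-frequency component and a Beta(0.5,0.5)-weighted common component
with $\varphi = SD_{LF}/(SD_{LF}+SD_{common})$. The defining "SD of the
SKAT statistic" is read as the *null* SD, $\sqrt{2\sum_i c_i^2}$ — the
natural analytic choice and the only one available without replicate
data; a sampling SD across replicates would be an alternative reading.
The combined null weights are the eigenvalues of the kernel built on the
concatenated genotype blocks with $\varphi$-scaled weight blocks, so
correlation between the two components is honored; for exactly
orthogonal blocks this reduces to the union of the scaled block spectra
(asserted in the suite).

### MinP

Per-SNP p-values are two-sided — the Z statistics are signed and the
rest of the framework is chi-square based, so a one-sided convention
would be inconsistent. The adjusted p-value is
$1 - P(|Z_j| \le z^\* \,\forall j)$ under MVN$(0, R)$, computed by
quasi-Monte-Carlo rectangle integration (absolute tolerance $10^{-6}$)
with an internally fixed RNG state, so MinP p-values are bit-reproducible
regardless of the caller's RNG. A non-PSD correlation matrix (possible
after aggressive collinearity handling) is repaired by eigenvalue
clipping with the perturbation norm reported in a warning. Independent
Z's recover the Šidák form $1-(1-p)^K$; perfectly correlated Z's recover
the raw minimum — both asserted in the suite.

### PC80

Principal components are taken from the *covariance* PCA of centered
genotypes: the selection criterion is genotypic variance explained, and
covariance PCA preserves the MAF-driven variance structure that
motivates it. `standardize = TRUE` offers correlation PCA. $S$ is the
smallest leading set explaining strictly more than the threshold
(default 0.80); with equal eigenvalues this gives the expected ceiling
behaviour.

## Omitted-causal-variant theory

With an untyped causal variant $C$ and trait $Y = a_1 C + \varepsilon$,
the expected joint coefficients of the typed SNPs are $a_1 d$, where $d$
holds the least-squares slopes of $C$ on the typed SNPs; with two
causals, $a_1 e + a_2 f$ by linearity. Marginally,
$E[\hat\beta^M_i] = \sum_m a_m \rho_{C_m i}\,\sigma_{C_m}/\sigma_i$.

When genotypes are supplied as a finite sample, the slopes are the
*sample* least-squares slopes: this makes the simulation-consistency
property exact — averaging fitted $\hat\beta$ over trait replicates on
fixed genotypes converges to exactly these values, which the suite
checks to 3 Monte-Carlo standard errors over 2000 replicates for both a
one-causal and an opposing-effects two-causal model. Pool-based
(design-stage) expectations are available via `pool_expected_betas()`,
using the fact that genotype covariance under random haplotype pairing
is twice the haplotype allele covariance. SDs from MAFs use the
Hardy-Weinberg form $\sqrt{2p(1-p)}$.

These expectations explain the characteristic power patterns: opposing
low-frequency causals in one bin produce joint coefficients of opposing
sign (sum near zero) — the worst case for linear-combination tests — and
near-zero marginal expectations, degrading marginal statistics.

## The synthetic-data engine

`generate_pool()` emulates the structural features the study design
needs, without claiming population-genetic realism:

- a pool of 340 haplotypes (170 diploid founders, configurable);
- 8–15 biallelic sites with MAF $\ge$ 1% after filtering;
- at least one $r^2 > 0.5$ bin containing 3+ low frequency SNPs,
  realised directly by a carrier-copy scheme (correlated rare carrier
  sets), because thresholded latent-Gaussian variables reach the
  required rare-rare correlations only at extreme latent correlations;
- remaining sites from a latent first-order Gaussian chain thresholded
  at target frequencies, giving a decaying LD profile;
- mean pairwise $|r|$ constrained to a band (default $[0.17, 0.59]$,
  the range observed across real gene panels of this size, with typical
  accepted values near the middle of the band).

Pools failing any constraint are rejected and redrawn (cap 500
attempts, with the dominant failing constraint reported). Diploid
genotypes are sums of two haplotypes drawn uniformly with replacement,
so Hardy-Weinberg variance $2p(1-p)$ holds at the sample level
(asserted). Everything is driven by integer seeds through a fixed
sub-stream derivation, so pools, genotypes and traits are reproducible
across runs and platforms.

What the generator does *not* emulate: coalescent genealogy,
recombination hotspots, population structure, genotyping error, or the
site frequency spectrum of sequencing data. Passing tests therefore
demonstrate correctness of the statistics and the study machinery under
a controlled LD/MAF structure, not performance claims for any particular
real population.

Causal assignment follows the five trait models: low-frequency causals
are drawn from a qualifying bin (3+ correlated low frequency SNPs),
common causals from all common SNPs; effects are $(1)$, $(1,1)$,
$(1,-1)$, $(1,1)$, $(1,-1)$ for models 1–5. Traits are
$Y = a_1C_1 (+ a_2C_2) + \varepsilon$, $\varepsilon \sim N(0,\sigma^2)$,
and the causal columns are excluded from every analysis set.

## Variance calibration

To make power comparable across genes and models, $\sigma$ is chosen so
the joint Wald test has analytic power 0.8 at $\alpha = 0.05$. The Wald
noncentrality under the omitted-causal model is

$$\lambda = \frac{E[\hat\beta]'\,(\tilde X'\tilde X)\,E[\hat\beta]}
                 {\sigma^2 + v_{res}},$$

where $v_{res}$ is the variance of the causal combination *not*
captured by the typed SNPs (the residual variance of $a'C$ regressed on
the analysis design). Including $v_{res}$ in the denominator is the
package's own refinement: the analysis-model residual variance is
$\sigma^2 + v_{res}$, not $\sigma^2$, and using the total gives analytic
power that matches the empirical rejection rate. For well-tagged causals
$v_{res}$ is negligible and the two formulations agree. The calibration
solves for the unique $\lambda^\*$ with
$P(\chi^2_K(\lambda^\*) > \chi^2_{K,1-\alpha}) = 0.8$ (a monotone
root-find) and inverts in closed form, then clamps $\sigma$ to
$[10^{-4}, 100]$; a clamp is flagged and warned about, reflecting that
the target power is unattainable for some gene/model combinations.
Power is strictly decreasing in $\sigma$, asserted over a grid.

## Study runner and reproducibility

`run_study()` fixes genotypes per gene-by-model batch (fresh genotypes
for each model, fresh trait noise per replicate) — the reading adopted
for the replicate structure; redrawing genotypes per replicate would
only inflate Monte-Carlo variance for these estimands. Every replicate
derives its RNG stream from (master seed, model, replicate index), so
results are independent of evaluation order and amenable to
parallelism. Empirical type-I error and power are rejection proportions
at $\alpha = 0.05$, reported with Clopper-Pearson intervals over
replicates (note: interval *over replicates* for one panel, not across
a panel collection).

The shipped test suite and acceptance script use desk-scale sizes
chosen as the package's own defaults for verification runs: a 12-SNP
panel, $n = 2000$ individuals, $N = 1000$ replicates for the null and
power calibrations, and 2000 replicates for the theory-recovery checks.
These sizes put the binomial 99% acceptance bands at roughly
$[0.033, 0.069]$ around the nominal 0.05 and $[0.767, 0.832]$ around
the 0.8 power target.

## Known limitations

- Binary traits, covariates, dosage genotypes and genotype imputation
  are out of scope; the model contract is intercept + additive genotype
  codes.
- Liu moment matching is tuned for moderate tail probabilities; for
  genome-wide-scale thresholds use `method = "davies"`.
- MinP's MVN adjustment inherits the known mild anticonservatism of the
  normal approximation for low-frequency-SNP Z statistics.
- The single-panel study runner cannot reproduce between-gene summary
  intervals that average over a panel collection.
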