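---
title: "Multipopulation fine-mapping from marginal summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipopulation fine-mapping from marginal summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

After a multi-ancestry GWAS, a region typically contains dozens of
associated SNPs in linkage disequilibrium (LD), only one or a few of which
are causal. `mjamr` fine-maps such regions using only per-study *marginal*
summary statistics (effect estimate, standard error, effect-allele
frequency, sample size) together with a per-population reference dosage
panel that supplies the LD.

Within population $i$ the phenotype follows the linear model
$y^{(i)} = G^{(i)}\beta^{(i)} + \epsilon^{(i)}$ with mean-centered $y$ and
$G$ and common residual variance $\sigma^2$. Under a fixed-effect
hierarchy the population-specific joint effects share a pooled value,
$\beta^{(i)} = \beta_{\mathrm{global}}$, so stacking the populations gives
a single mega-regression whose sufficient statistics are elementwise sums
of the per-study ones:

$$A = \sum_i {G^{(i)}}'G^{(i)}, \qquad b = \sum_i {G^{(i)}}'y^{(i)},
\qquad y'y = \sum_i {y^{(i)}}'y^{(i)}, \qquad N = \sum_i N^{(i)}.$$

Each study's cross-products are reconstructed from summary data: diagonals
$d_j = N^{(i)} \cdot 2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)$ (Hardy–Weinberg
dosage variance), off-diagonals $\hat r_{jk}\sqrt{d_j d_k}$ with
$\hat r$ the panel dosage correlation, and $X'y_j = d_j \hat\beta_j$ (the
marginal-effect identity). $y'y$ defaults to $N^{(i)}-1$, i.e. a
phenotype standardized to unit variance. A SNP missing from one study's
summary statistics or panel simply contributes a zero row/column for that
study — differential missingness costs information, not SNPs.

Joint and conditional inference uses a Zellner g-prior,
$\beta \mid \sigma^2 \sim \mathcal N(0, g\sigma^2 A_S^{-1})$, giving the
posterior mean $\frac{g}{1+g}A_S^{-1}b_S$ and closed-form Bayes factors.
The default $g = N$ is the unit-information prior standard in this model
family; it is exposed as a parameter because any concrete choice of $g$
directly controls how sharply one-SNP model probabilities concentrate
(see *Limitations*).

## Index SNPs and mediation-weighted credible sets

`mjam_forward()` selects index SNPs greedily: the remaining SNP with the
smallest conditional p-value (marginal in round one) is admitted while it
passes the genome-wide threshold $5\times10^{-8}$; its credible set is
built from the still-unpruned pool; then SNPs in LD with the new index are
pruned — $r^2 \ge 0.5$ in *any* population, or $r^2 \ge 0.2$ in *all*
populations. Populations lacking either SNP are skipped for the first
rule and count as non-satisfying for the second: missing evidence never
prunes. Ties in the minimal p-value break by larger $|z|$, then
lexicographic id, so results are byte-for-byte reproducible.

Each candidate $W$ in the set of index $X$ receives a posterior credible
set probability,

$$\mathrm{PCSP}_W = \Pr(M_W \mid \mathrm{Data}) \cdot
  \Pr(\mathrm{Mediation} \mid \mathrm{Data}),$$

the product of (i) the one-SNP g-prior model probability of $W$ among all
one-SNP models in the pool and (ii) the probability that $X$ mediates
$W$'s marginal signal. The mediation term compares $W$'s *total* effect
$\tau_W$ (model without $X$) with its *direct* effect $\tau'_W$ (model
with $X$): the observed gap $t = \hat\tau_W - \hat\tau'_W$ is standardized
by its delta-method standard error (both estimators are linear in the
shared score vector $b$, with model covariance $\sigma^2 A$), and

$$\Pr(\mathrm{Mediation} \mid \mathrm{Data}) =
  1 - 2\Phi(-|t|/\mathrm{se}(t)).$$

This operationalization was a genuinely open design point: a literal
p-value-style reading of the mediation quantity is *small* exactly when
mediation is strong, which would de-prioritize the SNPs the weighting is
meant to promote. We therefore use the monotone-increasing complement
(0 when the total and direct effects coincide, 1 as $|t|/\mathrm{se} \to
\infty$) and keep the other direction available via
`mediation_probability(..., printed_form = TRUE)`. The index SNP is
assigned mediation probability 1 so it can appear in its own set. Scaled
PCSPs are ranked (ties: smaller marginal p, then id) and accumulated until
they reach the coverage level $\rho$, 0.95 by default. Sets can be built
around *any* user-supplied index SNPs with `compute_pcsp()` +
`build_credible_set()`; `use_mediation = FALSE` gives the
model-probability-only ablation.

## The sum-of-single-effects engine

`susie_fit_sufficient()` fits the same stacked statistics with a sum of
$L$ single-effect vectors (default $L = 10$) by deterministic coordinate
ascent from a zero initialization. Each sweep residualizes $b$ against the
other effects, performs the closed-form single-effect regression, selects
each effect's prior variance by empirical Bayes (an effect whose best
prior variance is 0 is switched off), and re-estimates $\sigma^2$;
convergence is declared when the evidence lower bound moves by less than
`tol` ($10^{-3}$). Because every step is an exact coordinate maximization
of the ELBO, the ELBO trace is non-decreasing — this is asserted by a
property test. Per effect, the smallest group of SNPs whose inclusion
weights reach the coverage level forms a candidate credible set; sets
whose minimum absolute pooled-LD correlation falls below `purity_min`
(0.5) are discarded, so a diffuse effect spread over unlinked SNPs reports
nothing. Purity uses the sample-size-weighted pooled correlation
`cov2cor(A)`; a per-population minimum would be a stricter alternative and
is easy to compute from `pop_corr`, but the pooled form matches how the
likelihood itself weights populations. With $L = 1$ the engine can never
report more than one set; with $L > 1$ and an extremely significant causal
SNP it tends to add spurious extra sets — both behaviors are covered by
tests, and the second is the reason results for very strong signals
should be screened before interpretation.

## What the simulator emulates

`scenario_config()` encodes the study design used throughout the tests:
a region of 50 SNPs in five LD blocks, three populations with three
studies each and balanced $n = 16{,}000$ per study (total $N = 144{,}000$),
one causal SNP with pooled per-allele effect 0.03 at allele frequency
0.21 — per-SNP heritability $2 \cdot 0.21 \cdot 0.79 \cdot 0.03^2 \approx
3\times10^{-4}$ (0.03% of a unit-variance trait) — non-causal MAFs drawn
uniformly on (0.1, 0.5), reference panels of 5,000 per population, and
within-block dosage correlation 0 / 0.5 / 0.9 for the independent /
moderate / high LD levels. The sample size was chosen so that a
fixed-effect meta-analysis detects the causal SNP at $5\times10^{-8}$ in
roughly 87% of replicates, i.e. realistic single-region GWAS power rather
than a toy regime. Between-population heterogeneity is available as
`heterogeneity_sd` (population effects $\beta^{(i)} = \beta(1 +
\delta^{(i)})$-style deviations), and `missing_spec` masks SNPs from
chosen populations.

Two statistically matched generators are provided. `simulate_region()`
draws individual-level haplotypes from a Gaussian copula thresholded at
the allele frequency — two independent haplotype layers per SNP, so
dosages are Hardy–Weinberg — and computes marginal statistics by actual
per-SNP regression; the latent copula correlation is solved numerically
(bivariate-normal orthant probability by quadrature plus root-finding) so
the *realized dosage* LD hits the configured target.
`simulate_sumstats_fast()` skips individual data and draws the marginal
estimate vector from its asymptotic sampling law (mean = LD-projected
marginal effects, covariance $\frac{\sigma^2}{n}S^{-1}RS^{-1}$), allele
frequencies from their binomial law, and panel correlations from a
Wishart with $n_\mathrm{ref}-1$ degrees of freedom. A property test
verifies the two paths agree in mean and spread at $n = 20{,}000$.

One constraint worth knowing: the correlation between two biallelic HWE
dosages is bounded by
$(\min(p_1,p_2)-p_1p_2)/\sqrt{p_1q_1p_2q_2}$ — SNPs at MAF 0.21 and 0.5
cannot reach $r = 0.9$. Both generators therefore cap each pairwise
target at 98% of this bound, so "high LD" blocks are heterogeneous in
realized $r^2$ exactly as frequency-mismatched real blocks are.

What the simulator does *not* emulate: real haplotype mosaics (LD decays
smoothly, not in clean blocks), population-specific allele frequencies
and block boundaries, imputation noise, and summary statistics computed
on covariate-adjusted or related samples. Passing the simulation suite
therefore demonstrates correctness of the machinery under the stated
generative model, not performance on any particular real region.

## Numerical choices

* Positive definiteness is defined by Cholesky success; a failing $A$
  receives a relative ridge starting at $10^{-6}\cdot
  \overline{\mathrm{diag}(A)}$, doubled until the factorization succeeds,
  and the applied ridge is recorded.
* The residual variance in `gprior_fit()` is clamped to $\ge 10^{-8}$;
  inconsistent summary inputs that imply a negative residual sum of
  squares warn and clamp.
* Conditional p-values use the normal approximation (GWAS $N$ makes the
  $t$ correction irrelevant); a candidate whose variance inflation factor
  against the index set exceeds $10^5$ is treated as collinear: flagged,
  $p = 1$, and for mediation purposes a perfect proxy (probability 1).
* One-SNP Bayes factors are computed in log space via
  $-\tfrac{k}{2}\log(1+g) - \tfrac{N}{2}\log\!\big(1 -
  \tfrac{g}{1+g}R^2\big)$, which is cancellation-free at small $R^2$; a
  2-D quadrature oracle over $(\beta, \sigma^2)$ confirms it to six
  significant digits in the tests.
* Binary-outcome summary statistics (log odds ratios) are accepted as-is,
  with `logistic_to_linear()` providing the observed-scale conversion
  $\beta_{\mathrm{lin}} \approx \hat\beta_{\mathrm{logOR}}\,\phi(1-\phi)$
  for a case fraction $\phi$.
* Multi-allelic ids and (by default) strand-ambiguous A/T and C/G SNPs
  with MAF > 0.4 are dropped during harmonization, since strand flips are
  undetectable for them.
* The evaluation harness derives one RNG substream per replicate from the
  master seed, so any replicate can be regenerated in isolation.

The test suite runs each scenario at 200 replicates and the acceptance
script at 500; at the default region size (50 SNPs) a full
simulate–analyze replicate costs well under 0.1 s, so these counts keep
Monte-Carlo error on proportions near 0.015–0.022 while remaining quick
to run.

## Known limitations

* The fixed-effect assumption is load-bearing: a population with a truly
  null effect drags the pooled estimate; `heterogeneity_sd` lets you
  quantify the degradation (at 50% effect-size variation the credible-set
  sensitivity moves by well under 0.10 in the shipped test).
* With $g = N$ and well-powered signals ($|z| \gtrsim 6$), one-SNP model
  probabilities are extremely concentrated, so credible sets are often
  singletons and their empirical coverage sits above the nominal level
  (conservative). Diffuse sets at high power would require a materially
  smaller $g$; `g` is exposed everywhere for that reason.
* The region is held in dense matrices; practical up to a few thousand
  SNPs per region.
* No liftover, imputation, INFO-score QC, or PLINK binary parsing;
  summary statistics and panels are expected as delimited text or VCF.
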