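---
title: "Gene-based association from summary statistics, with expression and MR follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based association from summary statistics, with expression and MR follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumgene)
```

## The statistical model

A gene with $m$ QC-passed variants contributes a vector of GWAS
Z-scores $z = (z_1, \dots, z_m)$, with $z_j = \log(\mathrm{OR}_j) /
\mathrm{SE}_j$.  Under the gene-level null, and with LD between the
variants summarized by the correlation matrix $R$ estimated from a
reference panel, $z \sim \mathrm{MVN}(0, R)$.  Three tests are
computed per gene:

* **Sum (burden) test**: $B = \sum_j z_j$, with null variance
  $1'R1$, so $p_{ST} = 2\Phi(-|B| / \sqrt{1'R1})$.  Most powerful
  when variant effects share a direction.
* **Squared-sum (SKAT-type) test**: $Q = \sum_j z_j^2$.  Under the
  null $Q$ is distributed as $\sum_k \lambda_k \chi^2_{1,k}$ with
  $\lambda_k$ the eigenvalues of $R$.  Robust to mixed directions.
* **Adaptive (omnibus) test**: $Q_\rho = (1 - \rho) Q + \rho B^2$ for
  $\rho$ on a grid in $[0, 1]$ ($\rho = 0$ is the squared-sum test,
  $\rho = 1$ the squared burden test).  The null weights of $Q_\rho$
  are the eigenvalues of $R^{1/2} A_\rho R^{1/2}$,
  $A_\rho = (1-\rho) I + \rho 1 1'$.  The reported statistic is
  $T = \min_\rho p(Q_\rho)$, and `p_at` is the calibrated probability
  $P(\min_\rho p_\rho \le T)$ under the null, so taking the minimum
  over the grid carries no multiplicity advantage.

The default grid is $\{0, 0.1, \dots, 1\}$ (11 points).  The grid is
configurable; results at other grids are exposed through the
`rho_grid` argument everywhere rather than baked in.

## Weighted chi-square tails

`mixture_tail()` evaluates $P(\sum_k \lambda_k \chi^2_{1,\delta_k} >
q)$ by numerical inversion of the characteristic function (Imhof's
formula).  The integrand decays only algebraically, like
$u^{-(1 + m/2)}$, while oscillating with period $4\pi/q$; for small
$m$, blind adaptive quadrature on $(0, \infty)$ cannot reach the
absolute accuracies the calibration needs.  The implementation
therefore integrates adaptively up to a cut point beyond which the
phase is provably monotone, then sums the single-signed panels
between consecutive phase zeros and accelerates the alternating panel
series with an Euler transformation.  Measured against the
$\chi^2_m$ closed forms (all weights equal), absolute deviations stay
below $10^{-8}$.

Below tail values of $10^{-8}$ the quadrature's absolute error would
swamp the value itself; there a Lugannani–Rice saddlepoint
approximation of the same cumulant generating function takes over.
Its error is *relative*, so genome-wide-significant p-values around
$10^{-7}$–$10^{-12}$ remain meaningful.  A mixture with a single
positive weight is evaluated exactly with `pchisq()`.  Eigenvalues
down to $-10^{-10}$ (numerical noise on near-singular LD matrices
after pruning) are clamped to zero; anything more negative is treated
as a genuine input error.

## Calibrating the minimum p-value

`calibrate_min_p()` computes $P(\min_\rho p_\rho \le t_{\min})$
analytically, which is what makes p-values at the $10^{-9}$ scale
possible (a Monte-Carlo calibration cannot reach them).  Write
$c = 1'R1$ and decompose $z = R1\,b/c + e$ with $b = 1'z \sim N(0, c)$
independent of the residual $e$.  Each per-$\rho$ acceptance region
$\{Q_\rho < q_\rho(t_{\min})\}$ is a bound on
$S = e'e + (2b/c)(R1)'e$ given $b$.  Conditional on $b$, $S$ is
*exactly* a noncentral weighted chi-square: diagonalizing
$\mathrm{Cov}(e) = R - (R1)(R1)'/c$ and completing the square per
component gives weights equal to the nonzero eigenvalues and
noncentralities proportional to $b^2$.  That conditional tail is
evaluated with the same Imhof machinery and integrated over $b$ by
Gauss–Legendre quadrature (48 nodes on the half-line the $\rho = 1$
constraint leaves, using the symmetry of the integrand in $b$).

An early design draft approximated the conditional law by a
moment-matched scaled chi-square; the exact noncentral route replaced
it because the package's own validation target — agreement with a
$10^6$-draw Monte-Carlo evaluation of the full min-p statistic to
within 3 Monte-Carlo standard errors — demands roughly 0.1% absolute
accuracy at moderate p-values, beyond what moment matching reliably
delivers.  The result is finally clamped into the Bonferroni sandwich
$[t_{\min}, \min(1, t_{\min} \cdot |\mathrm{grid}|)]$, which the exact
answer must satisfy, absorbing residual quadrature error.  Ties in
the minimizing $\rho$ are reported at the smallest $\rho$.

## Summary-statistic QC and LD

The QC rules, in their documented attribution order: autosomes only;
both alleles single-base A/C/G/T (which also removes indels and
multi-allelic records); no strand-ambiguous A/T or C/G pairs; INFO
$\ge 0.9$ (the boundary value 0.9 is retained; *missing* INFO fails
the filter — a conservative choice, flagged in the QC report, since
upstream sources differ in whether they report INFO at all); and
duplicated rsIDs removed in *all* copies, because keeping one would
require guessing which record is right.  Each removed record counts
against the first rule that rejects it, so per-rule counts plus
retained records always equal the input.

Variants are assigned to a gene if they fall within 1000 bp
(inclusive) of the transcription start or end; the window uses the
annotation's numeric coordinates for both strands (for minus-strand
genes "start" is the numerically smaller coordinate — the window is
symmetric, so the distinction has no effect).  Genes keep a variant
set only if at least two variants survive matching.  Alleles are
harmonized to the panel's ref/alt orientation, flipping the Z sign
when the effect/other order is reversed; rsID is the primary match
key with chrom:pos as fallback, and a shared rsID at a conflicting
position is dropped rather than guessed.  LD is the Pearson
correlation of panel dosages.  Pruning removes one member of each
pair with $r \ge 1 - 10^{-8}$ — only $r = +1$, matching the rule as
stated for the pipeline being reproduced; $r = -1$ pairs carry
independent sign information and are retained.  The removal order is
deterministic (later-by-position member of the first offending pair
in row-major order) so repeated runs agree exactly.

## Differential expression

**Dichotomized logistic model.**  For cohort-style data with
covariates, each gene's counts are split at the median ("low" iff
count $\le$ median, computed on the samples actually analyzed — the
all-samples and white-only fits therefore recompute it), and
diagnosis is regressed on age at death (years), sex, race (white
indicator, non-white reference, matching the single reported race
row), postmortem interval (hours) and the high-expression indicator.
Wald $z = \beta/\mathrm{se}$ and $p = 2\Phi(-|z|)$ per term.
Quasi-complete separation is detected (non-convergence or runaway
coefficient with inflated SE) and reported as an explicit
non-estimability error naming the term, rather than returning a
meaningless fit.

**Negative-binomial count test.**  For small two-group designs: genes
with total count below 10 are removed (the customary pre-filter,
interpreted as *total across samples* and configurable);
median-of-ratios size factors (normalized to geometric mean one)
enter as offsets in a per-gene NB log-link GLM with a diagnosis term;
dispersion is method-of-moments on the normalized scale, floored at
$10^{-8}$; the diagnosis Wald statistic is referred to a *t*
distribution on $n - 2$ degrees of freedom.  The t reference is the
one deliberate small-sample choice: with six samples, the plug-in
dispersion makes the normal reference visibly anti-conservative
(measured near 14% type-I error at nominal 5% in the package's null
simulation), while the t reference restores the nominal rate and
converges to the normal as $n$ grows — the package's Poisson-limit
oracle test checks exactly that convergence.  Benjamini–Hochberg
adjustment is applied over the retained genes.  This stage is a
minimal NB test in its own right, validated by calibration properties
rather than by comparing numbers against any particular published
tool.

## Mendelian randomization

One instrument per tissue: the tissue's top eQTL matched to the same
variant in the outcome GWAS.  Harmonization aligns the outcome to the
exposure's effect allele (swapped order negates the outcome effect
and reflects its allele frequency); palindromic A/T and C/G variants
are kept only when both sides have a known effect-allele frequency,
both minor-allele frequencies fall below 0.42 (the conventional
inferability limit), and the orientations agree — otherwise dropped
with a reason, never guessed.  The causal effect is the Wald ratio
$\hat\theta = \beta_{\mathrm{out}} / \beta_{\mathrm{exp}}$ with the
first-order delta SE $\mathrm{se}_{\mathrm{out}} /
|\beta_{\mathrm{exp}}|$ (a second-order SE including the exposure
variance is available behind a flag).  Outcome effects are used on
the log-odds scale, consistent with $Z = \log(\mathrm{OR})/\mathrm{SE}$
upstream.  The per-tissue Bonferroni threshold divides $\alpha$ by
the number of tissues actually tested, i.e. surviving harmonization.

## What the synthetic data emulates — and what it does not

The generators are pure functions of a `sim_config()` (fixed seed
$\Rightarrow$ byte-identical outputs) and default to the emulated
study conditions: a 503-sample reference panel, gene LD blocks with
exchangeable correlation 0.5, INFO drawn on $[0.85, 1]$ so the 0.9
filter does real work, 20 case / 19 control and 3 case / 3 control
expression designs, logistic coefficients at the scale of the
reported fit (GE term 2.58, race 2.71, PMI 0.11, age $-0.01$), a
signal log2 fold change of 1.17, and 30 MR tissues with strong
instruments (exposure SE 0.03 against strengths near 0.5, keeping the
first-order weak-instrument bias of the Wald ratio an order of
magnitude below the recovery criterion's resolution).

Summary statistics are generated *at the Z level* — $z \sim
\mathrm{MVN}$ around the configured mean shift with the panel's
sample LD — and OR/SE are back-filled so $\log(\mathrm{OR})/\mathrm{SE}$
reproduces $z$ exactly, making gene-level truth exact rather than
approximate.  Panel dosages are continuous ("imputed-dosage-like"):
an affine map of an exchangeable-correlation Gaussian clipped to
$[0, 2]$, with the scale chosen so clipping is negligible.  This
makes the dosage Pearson correlation equal the configured
`ld_block_rho` in expectation; a thresholded discrete-genotype model
would attenuate the correlation and break that equality.  Injected
QC violations (strand-ambiguous rows, duplicate-rsID pairs, swapped
alleles, duplicated dosage columns) are placed so the bookkeeping
identities are exact.

Consequently, passing tests show that the *statistical machinery* is
correct under its stated assumptions.  They do not show robustness to
features of real data the generators deliberately omit: realistic
haplotype LD (block-exchangeable only), population stratification,
allele-frequency-dependent effect sizes, imputation error structure
beyond a uniform INFO draw, batch effects or covariate confounding in
expression data, or pleiotropy in MR instruments.

## Numerical choices and degenerate inputs

* Eigenvalues of LD kernels clamped at zero within $-10^{-10}$.
* Adaptive-test quantile inversion: saddlepoint Newton iterations
  polished by accurate Imhof evaluations to $10^{-8}$ relative on the
  probability.
* `calibrate_min_p` inner conditional tails run with slightly relaxed
  quadrature settings; the outer Gauss–Legendre integral smooths
  them and the sandwich clamp bounds the result.
* Degenerate inputs fail loudly and specifically: zero-variance
  panel dosages name the variant; constant count rows refuse
  dichotomization; a gene pruned below two variants is dropped with a
  reason; an all-zero diagnosis class clamps the fold-change estimate
  at $\pm 30$ log2 units and flags it.
* Problem sizes in the test-suite simulations (2000-gene null scans
  with 4–5 SNPs per gene and a 300-sample panel, 200-replicate
  logistic recovery at $n = 200$, 1000-replicate MR recovery,
  $10^6$-draw Monte-Carlo oracles on up to 5 variants) were chosen as
  the smallest designs at which the distributional assertions have
  stable power.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, n_genes = 50, causal_gene_fraction = 0.06,
                  signal_mean_shift = 3)
sim <- sim_reference_panel(cfg)
gw <- sim_gwas_sumstats(sim, cfg)
disc <- run_discovery(gw$sumstats, sim$panel, sim$genes,
                      out_dir = "discovery_run")
subset(disc$results, significant)
gw$truth[gw$truth$causal, ]
```

The `discovery_run` directory then holds `gene_results.tsv`,
`manhattan.tsv` (chromosome, window midpoint, $-\log_{10} p$),
`qc_report.json` and a `manifest.json` with input digests and stage
counts; re-running the same configuration reproduces the files
byte-for-byte.

## Known limitations

* The adaptive-test calibration is exact up to quadrature only under
  the MVN null with the *estimated* $R$; reference-panel sampling
  noise in $R$ is not propagated.
* Gene windows may overlap, so neighboring genes can share variants
  and their tests are correlated; the Bonferroni threshold is
  conservative under that correlation.
* The NB stage models diagnosis only (no covariates or batch terms),
  matching the minimal two-group design it targets.
* Single-instrument MR cannot detect or correct pleiotropy; the Wald
  ratio inherits any violation of the exclusion restriction.
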