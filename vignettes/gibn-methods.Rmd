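---
title: "Methods: latent genetic factors of regional brain structure from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent genetic factors of regional brain structure from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gibnet` treats the genome-wide association results of $p$ regional brain
measures (in the motivating application, cortical surface area or thickness
for the 34 bilateral Desikan–Killiany regions) as indirect observations of a
$p \times p$ genetic covariance matrix $S_g$, and asks whether a small
number $k \ll p$ of latent factors explains it:

$$S_g^{*} = \Lambda \Psi \Lambda^{\top} + \Theta,$$

where $S_g^{*}$ is $S_g$ rescaled to the genetic correlation metric,
$\Lambda$ is a $p \times k$ pattern loading matrix, $\Psi$ a factor
correlation matrix with unit diagonal (factors are identified by unit
variance), and $\Theta$ diagonal residual genetic variances. Each factor's
supra-threshold regions define a *genetically informed brain network*: a
subset of the region universe that can then be compared spatially with
reference parcellations, and whose own multivariate GWAS can be correlated
with external phenotypes.

Everything operates on summary statistics. The key assumptions are those of
LD score regression: polygenic architecture, so that the expected
association statistic rises linearly in the LD score
$\mathrm{E}[\chi^2_j] = 1 + N h^2 \ell_j / M$; an intercept that absorbs
confounding and (in the cross-trait regression) sample overlap; and
homogeneous per-SNP effects on the standardized-genotype scale.

## Estimating (S, V) by LD score regression

Univariate fits regress winsorized $\chi^2_j$ on $N_j \ell_j / M$;
cross-trait fits regress $Z_{1j} Z_{2j}$ on $\sqrt{N_1 N_2}\,\ell_j / M$,
so the slope is the genetic (co)variance directly. Design choices:

* **Weights.** Iteratively reweighted least squares with
  $w_j = 1/[\ell_j\, d_j^2]$, $d_j = \hat b_0 + N \hat h^2 \ell_j / M$
  (the fitted conditional scale), three reweighting iterations from
  $h^2 = 0$, intercept $1$. For a trait pair the denominator is
  $\ell_j\, d_{1j} d_{2j}$, the geometric analogue of the univariate
  heteroskedasticity weight. $d_j$ is floored at 0.05 so early iterations
  with negative slopes cannot produce negative weights.
* **Winsorization.** $\chi^2$ values above 80 (products clipped to
  $\pm 80$) guard against single-locus leverage. When simulating, sample
  sizes are scaled together with $M$ so that per-SNP expectations stay well
  below this bound; otherwise the clipping biases slopes in an LD-dependent
  way.
* **Intercepts** are always estimated freely; the diagonal of the intercept
  matrix estimates confounding, the off-diagonal sample overlap.
* **Jackknife.** $V$, the sampling covariance of $\operatorname{vech}(S)$
  ($q = p(p+1)/2$ elements, column-major lower triangle), comes from a
  joint delete-one-block jackknife over contiguous equal-count SNP blocks
  (default 200): every element's leave-one-block-out slope is computed from
  the same blocks, so $V$ captures cross-element sampling covariance.

Standardization to the correlation metric uses the delta method for
$r_{tu} = s_{tu}/\sqrt{s_{tt} s_{uu}}$; the diagonal becomes exactly 1 with
zero sampling variance, and the operation is idempotent. Because an
estimated correlation matrix can be indefinite, it is smoothed by clipping
eigenvalues below $10^{-6}$ and re-normalizing to unit diagonal before any
factor analysis.

## Factor discovery: split-parity EFA then CFA

Running discovery and confirmation on the same data overfits. The package
therefore splits the autosomes by parity: exploratory factor analysis on the
structure estimated from odd chromosomes, confirmatory re-estimation on the
even-chromosome structure (a sensitivity switch swaps the parities).

**EFA.** Maximum-likelihood extraction (`stats::factanal`) followed by
oblique promax rotation (power 4), for each candidate factor count (default
1–10, clipped to $p-1$). Neither step is stochastic. One numerical wrinkle:
promax pre-rotates with varimax, and an *exactly* symmetric input (as arises
with idealized block matrices) sits on a varimax saddle point where the
gradient vanishes; a fixed small Givens pre-rotation (0.3 rad between
consecutive factor pairs) breaks the symmetry deterministically and is
absorbed into the reported rotation. Factor signs are fixed so each column
of loadings sums positive. A solution whose uniquenesses hit the
estimator's lower bound is flagged as a Heywood case and not carried
forward.

**Thresholding.** Positive rotated loadings strictly above a cutoff become
free parameters of the confirmatory specification; both 0.3 and 0.5 are run
for every factor count and all resulting specifications compete in
selection. Cross-loadings survive whenever they clear the cutoff. Factors
left with fewer than two indicators are deleted (single regions are not
networks), and regions with no surviving loading leave the specification.

**CFA by DWLS.** The free parameters $\theta = (\Lambda, \Psi, \Theta)$
minimize

$$F(\theta) = (s - \sigma(\theta))^{\top} W^{-1} (s - \sigma(\theta)),
\qquad W = \operatorname{diag}(V),$$

with $s = \operatorname{vech}(S^{*})$. The gradient is analytic
(the Jacobian $\Delta = \partial \sigma / \partial \theta$ is assembled in
closed form), and L-BFGS-B runs from three deterministic starts (the
EFA-derived loadings, a flat 0.5 start, and a perturbed start); the best
objective wins, so fits are bit-reproducible without a seed. Residual
variances are bounded below at $10^{-6}$; touching the bound (a Heywood
residual) or a factor correlation at $\pm0.995$ flags non-convergence, which
is a reportable outcome rather than an error. The unit diagonal of a
standardized $S$ has zero sampling variance; those elements receive the
smallest positive weight and are fitted exactly through $\Theta$.

**Standard errors** use the sandwich
$(\Delta^{\top} W^{-1} \Delta)^{-1} \Delta^{\top} W^{-1} V W^{-1}
\Delta (\Delta^{\top} W^{-1} \Delta)^{-1}$.

**Fit statistics.** The model chi-square is the residual quadratic form
against the eigen-pseudoinverse of the full $V$,
$\chi^2 = (s-\hat\sigma)^{\top} V^{+} (s-\hat\sigma)$, with
$df = q - (\text{free parameters})$; AIC $= \chi^2 + 2\,\text{npar}$;
CFI compares against the closed-form independence baseline
($\Sigma = \Theta$, fitted exactly on the diagonal); SRMR is the root mean
square of the $q$ standardized residuals. Calibration of this statistic is
established by simulation, not by numerical identity with any external
implementation: the acceptance suite verifies that the mean $\chi^2$ over
200 replicates under the true model is within 15% of $df$. That check uses
2000 jackknife blocks — the pseudoinverse of a $q \times q$ jackknife
estimate is noisy, and the resulting upward inflation of the statistic
decays roughly as $1 + c/n_{blocks}$; at the 200-block default the
statistic runs some tens of percent above $df$, which cancels in model
*comparisons* but should be kept in mind when quoting absolute $\chi^2$.

**Pruning and selection.** After fitting, the loading with the largest
two-sided Wald $p \ge 0.05$ is removed and the model refitted, repeatedly;
a factor reduced below two indicators is deleted with its correlations.
Selection minimizes AIC over all converged candidates, with ties broken by
fewer free parameters, then fewer factors. One correction proved necessary:
specifications that drop regions span fewer unique covariance elements, so
their raw $\chi^2$ (hence AIC) shrinks mechanically and a small spurious
model can beat the truth. When candidates differ in coverage,
`select_model` therefore embeds each in the common region universe —
excluded regions enter as residual-only variables whose implied covariance
with everything is zero, counted as free parameters — making the comparison
like-with-like. Candidates with identical coverage are unaffected.

## Multivariate factor GWAS

For each SNP the structure is expanded with
$\operatorname{var}(g) = 2\,\mathrm{maf}(1-\mathrm{maf})$ (standardized
genotype, reference-panel frequency) and
$\operatorname{cov}(g, y_t) = \beta_t \operatorname{var}(g)$; the expanded
sampling covariance carries the per-trait variances
$se_t^2 \operatorname{var}(g)^2$ with zero cross-terms. The SNP's effects
on all factors are then estimated jointly by weighted least squares with
the measurement model fixed at the CFA estimates. With the block-diagonal
expanded $V$ this collapses to a per-SNP generalized regression of trait
betas on the $\sqrt{h^2}$-scaled loading matrix, and the sandwich
covariance reduces to its bread — which is also why the whole genome runs
in seconds. Per-SNP re-estimation of the full model is deliberately not
the default: holding the measurement model fixed is an approximation
validated by parameter recovery (planted causal effects through a factor
are recovered at the planted size; genome-wide significance power matches
the normal-approximation prediction within the acceptance tolerance).

Effects are reported per allele on the unit-variance factor scale, so a
unit-loading single indicator passes its trait beta through unchanged.
Genomic inflation $\lambda$ (median $\chi^2$ over 0.4549) is attached per
factor; under a pure null it sits near 1, while on polygenic data values
far above 1 reflect true signal aggregated across indicators, not
confounding — the univariate LDSC intercept of the factor's own summary
statistics is the confounding diagnostic. Downstream LDSC uses the
effective sample size $N_{\mathrm{eff}} = 1/(2\,\mathrm{maf}(1-\mathrm{maf})\,se_f^2)$,
capped at its 99th percentile.

Genome-wide significant SNPs ($p < 5\times10^{-8}$) are clumped greedily:
the most significant remaining SNP leads a locus absorbing all significant
SNPs within a window (default 250 kb) on its chromosome; locus spans are
padded by the window and overlapping spans merged, which makes the result
identical to merging the union of per-SNP windows.

## Overlap statistics and external correlations

A factor's region set is compared with reference parcellations by the Dice
coefficient $2 w(A \cap B) / (w(A) + w(B))$ with optional non-negative
region weights (weights emulate percent-volume overlap when region volumes
are supplied; voxel-level overlap is out of scope). Significance comes from
a permutation null that redraws the factor's set *at its observed size*
uniformly from the universe (1000 iterations by default) with the add-one
estimator $p = (1 + \#\{DC_{perm} \ge DC\})/(1 + n_{iter})$ — never exactly
zero, floor $1/(n_{iter}+1)$. Each comparison grid (factors × one reference
scheme) forms a single Benjamini–Hochberg FDR family, as does the full
factor × external-trait genetic-correlation grid.

## The synthetic generator

`truth_params()` + `simulate_sumstats()` plant a factor model and emit
complete per-trait summary-statistics tables plus LD scores. Defaults are
the package's reference conditions: 8 traits, 2 factors with loading blocks
0.7 and 0.6, factor correlation 0.7 (mirroring the strongly correlated
networks this method targets), $h^2 = 0.25$, $N = M = 50{,}000$, MAF
uniform on (0.05, 0.5), INFO 1, LD scores log-normal (median 10, log-sd
0.5) constant within 40 blocks.

*Covariance mode* (default) draws each SNP's Z-vector from
$\mathcal{N}(0,\; I_{ov} + \sqrt{NN^{\top}} \circ S_g\, \ell_j / M)$ — the
exact second-moment structure LDSC fits, with the intercept matrix
$I_{ov}$ planting confounding/overlap. *Causal mode* draws explicit
per-SNP factor effects $\gamma_j \sim \mathcal{N}(0, \Psi\,\ell_j/M)$ plus
listed large-effect causal SNPs and trait-specific residual effects; the
markers are unlinked, but scaling effect variances with $\ell_j$ reproduces
the LDSC moment identity without physical LD smearing (physical smearing
while keeping the stated LD scores would break that identity). A
`background = FALSE` switch drops the polygenic background — the regime in
which the normal-approximation power formula for a causal SNP applies, used
by the power and null-inflation checks.

What the generator does *not* emulate: actual LD between markers (jackknife
blocks are exchangeable by construction, which real genomes only
approximate), allele-frequency-dependent architecture, minor/major allele
coding errors, population stratification beyond a constant intercept, and
the heavy cross-cohort heterogeneity of real meta-analyses. Passing tests
demonstrate internal statistical correctness under the stated model, not
robustness to those features.

## Problem sizes used by the checks

The acceptance suite runs 50 replicates of the reference conditions for
LDSC and factor-structure recovery; the chi-square calibration uses 200
scaled-down replicates (6 traits, $M = 20{,}000$, $N = 10{,}000$, 2000
jackknife blocks — sizes chosen so the pseudoinverse statistic is in its
well-estimated regime and per-SNP signals stay clear of the winsorization
bound); the power check uses 50 replicates of 20 causal SNPs at
$\gamma = 0.08$, $N = 50{,}000$. These sizes are the package's reference
benchmark, balancing Monte Carlo error against desk-scale runtimes.

## Known limitations

* The $\chi^2$'s absolute calibration depends on the number of jackknife
  blocks (see above); with few blocks relative to $q$ the statistic is
  inflated, and with $q$ approaching the block count $V$ becomes singular —
  at the full 34-region scale ($q = 595$) more than 595 blocks are required
  and the pseudoinverse becomes the operative safeguard.
* AIC values across specifications covering different region subsets are
  only comparable through the embedding correction; absolute AICs from
  different structures (odd vs even parity) are never comparable.
* The measurement model is held fixed during the factor GWAS; SNPs with
  very large effects on a single indicator can violate this approximation.
* rg estimates are clamped to $[-1, 1]$ (flagged); heritability estimates
  are deliberately unconstrained, so null traits can return negative
  $\hat h^2$, in which case rg is reported as undefined.
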