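---
title: "Modeling multi-trait, trans-ancestry genetic architecture from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multi-trait, trans-ancestry genetic architecture from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transgsem)
```

# The problem

Psychiatric disorders such as schizophrenia (SCZ), bipolar disorder types I
and II (BD1, BD2) and major depressive disorder (MDD) share a large part of
their common-variant genetic architecture, and the pattern of sharing
differs between ancestries.  Pairwise genetic correlations quantify sharing
one pair at a time; a factor model over the full genetic correlation matrix
describes the *joint* architecture — e.g. whether a country's BD1 behaves
genetically like its psychotic disorders or like its mood disorders.

`transgsem` implements the whole chain needed for that analysis using only
GWAS summary statistics:

1. **LD score regression (LDSC)** for SNP heritability and genetic
   covariance, with block-jackknife uncertainty;
2. a **moment estimator of the trans-ancestry genetic-effect correlation**
   for trait pairs measured in different populations;
3. assembly of the multi-trait genetic covariance matrix **S** and the
   sampling covariance **V** of its unique elements from a joint jackknife;
4. **exploratory factor analysis (EFA)** of the smoothed genetic
   correlation matrix; and
5. **confirmatory factor models fitted by diagonally weighted least squares
   (DWLS)** against (S, V), with sandwich standard errors and CFI / SRMR /
   AIC fit statistics.

Because real psychiatric GWAS inputs of this kind are access-restricted,
the package also ships a **synthetic-data generator** with a known latent
factor structure.  Every stage is validated end to end against that ground
truth.

# Models and estimators

## The LDSC moment conditions

For variant $j$ with LD score $\ell_j$ in a GWAS of $N$ individuals over
$M$ reference variants, LDSC regresses the association statistic on the LD
score:

$$\mathrm{E}[\chi^2_j] = a + \frac{N h^2}{M}\,\ell_j ,$$

where the slope carries the SNP heritability $h^2$ and the free intercept
$a$ absorbs confounding.  For two traits,

$$\mathrm{E}[z_{tj} z_{uj}] = c + \frac{\sqrt{N_t N_u}\,\rho_g}{M}\,\ell_j ,$$

with $\rho_g$ the genetic covariance and the cross-trait intercept
$c = \rho_{ph} N_s / \sqrt{N_t N_u}$ proportional to phenotypic correlation
times sample overlap $N_s$.  The genetic correlation is
$r_g = \rho_g / \sqrt{h^2_t h^2_u}$.

Weights follow standard LDSC practice,
$w_j = 1/\big(\ell_j\,(\hat a + \hat b x_j)^2\big)$ (heteroskedasticity and
over-counting), initialized from an unweighted pass with one reweighting
iteration.  A deliberate detail: the bivariate weights reuse the
*unweighted first-pass* univariate fits for their variance terms.  With
that convention the bivariate weights for a trait paired with itself are
exactly proportional to the univariate weights, so the self-pairing
identity $r_g(t,t) = 1$ holds to machine precision rather than merely
approximately.

For a cross-ancestry pair the same regression runs on *cross-population* LD
scores (sums of products of the two populations' correlations) with the
intercept fixed at zero, since samples do not overlap across populations.
The slope then estimates the cross-population genetic covariance, and
normalizing by the two within-population heritabilities yields the
**genetic-effect correlation** $\rho_{ge}$ — the same estimand a
likelihood-based trans-ancestry method targets under this generative model,
here estimated by moments so it is desk-scale and jackknife-compatible.
The genetic-*impact* variant (allele-frequency weighted) is deliberately
not implemented: no frequency reference is assumed.

## Block jackknife, S and V

All uncertainty comes from a delete-one-block jackknife over contiguous
blocks in the (lexicographic) variant ordering — 200 blocks by default.
Every cell of S (T heritabilities, T(T−1)/2 genetic covariances) is
re-estimated on every leave-block-out subsample over one *common* block
map; the jackknife covariance of those replicates is V, a
$t^\ast \times t^\ast$ matrix with $t^\ast = T(T+1)/2$, indexed in fixed
column-major lower-triangle (`vech`) order.  Because all cells share
blocks, sampling dependence between cells — e.g. between an $r_g$ and the
heritabilities that normalize it — is captured.

Standardization to correlation scale divides cell $(t,u)$ by
$\sqrt{\hat h^2_t \hat h^2_u}$.  For V we re-standardize *each delete-block
replicate* with that replicate's heritabilities (default
`v_method = "jackknife"`), so the noise contributed by the normalization —
and the covariance it induces between cells sharing a trait — propagates
into V.  We measured the cheaper fixed-scale delta alternative
(`v_method = "delta"`) to be ~25% conservative for off-diagonal cells at
the preset's precision and to miss exactly the cross-cell covariance that
matters for factor loadings of low-heritability traits, which is why it is
not the default.  Diagonal cells always use the fixed-scale value: the
standardized diagonal is constant 1, and a literal jackknife of a constant
would give those cells zero variance and hence infinite weight in a
diagonally weighted fit.

Before factor analysis the correlation matrix is smoothed to positive
semidefiniteness by eigenvalue clipping at $\varepsilon = 10^{-6}$
(iterating the clip-and-renormalize step because restoring the unit
diagonal can push an eigenvalue back below the floor).  Smoothing is
applied only at that point, never to S itself.

## EFA

Exploratory analysis uses principal-axis factoring with iterated
communalities (SMC start, tolerance $10^{-6}$, at most 100 iterations)
followed by an oblique promax rotation (power 4, varimax pre-rotation).
Principal axes are used rather than maximum likelihood because a genetic
correlation matrix has no well-defined sample size.  Results are
canonicalized — factors ordered by sum of squared loadings, each factor's
largest loading made positive — so output is invariant to trait reordering.
Communalities capped at 1 flag a Heywood case without aborting.  The factor
count scan (`efa_scan()`) reports variance explained, cross-loading and
weak-factor counts, and an advisory parsimony score; it never auto-commits
a k.

## Confirmatory DWLS fit

A model text (factors, their indicators, free factor covariances, optional
fixed loadings/residuals) is fitted by minimizing

$$F(\theta) = (s - \sigma(\theta))^\top \mathrm{diag}(V)^{-1} (s - \sigma(\theta)),
\qquad \sigma(\theta) = \mathrm{vech}(\Lambda \Psi \Lambda^\top + \Theta),$$

with factor variances fixed to 1 for identification and residual variances
free (negative values permitted and flagged, since slightly negative
residuals are a recognized feature of genomic factor models).  The
optimizer is a damped Newton iteration: Gauss–Newton term from the analytic
Jacobian plus the exact analytic residual-curvature correction (the second
derivatives of $\sigma$ are simple in $\Lambda$ and $\Psi$), preceded by a
quasi-Newton warm start.  Convergence requires gradient norm below
$10^{-8}$.  Multi-start: an EFA-informed start, a generic start, and three
jittered restarts under fixed seeds; the minimum-F converged solution wins.

Parameter uncertainty uses the sandwich
$(\Delta^\top W \Delta)^{-1} \Delta^\top W\, V\, W \Delta\,
(\Delta^\top W \Delta)^{-1}$ with $W = \mathrm{diag}(V)^{-1}$ and $\Delta$
computed by *central finite differences* (step $10^{-6}$, cross-checked
against forward differences) — deliberately independent of the optimizer's
analytic derivatives, so an error in either surfaces as disagreement.

Fit statistics: $\chi^2 = r^\top V^{+} r$ on $t^\ast - q$ degrees of
freedom ($V^{+}$ an eigen pseudo-inverse with relative tolerance
$10^{-12}$; a condition number above $10^{12}$ raises a warning), CFI
against the independence model (free diagonal, zero off-diagonals), SRMR
over the lower triangle including the diagonal, and
$\mathrm{AIC} = \chi^2 + 2q$.  P-values are two-sided normal on
$\hat\theta/\mathrm{SE}$; one-sided reporting is left to the user.

# The synthetic generator

The generator defines the study conditions, not a tuning surface.  Z-scores
are drawn per variant from the exact LDSC moment model:

$$\mathrm{Cov}[z_t, z_u] = \frac{\sqrt{N_t N_u}\,\ell_j(t,u)}{M} S_{tu} + \delta_{tu},$$

independently across variants, where $S$ is the covariance-scale genetic
matrix implied by a standardized loading matrix $\Lambda$, factor
correlations $\Psi$ and residuals $\Theta = 1 - \mathrm{diag}(\Lambda \Psi
\Lambda^\top)$, scaled by per-trait heritabilities, with cross-ancestry
cells additionally multiplied by an effect correlation $\rho_{ge}$;
$\delta$ is 1 on the diagonal and $\rho_{ph} N_s/\sqrt{N_t N_u}$ for
overlapping within-population pairs.  LD is block-structured: blocks of $m$
variants with intra-block correlation $r$ give within-population LD score
$1 + (m-1)r^2$ and cross-population score $1 + (m-1) r_1 r_2$.  The
intra-block correlations may vary across blocks (a fixed cycle of five
values in the presets); a single genome-wide $r$ would make every LD score
identical and the free-intercept regression unidentifiable, which the
estimator correctly rejects as a degenerate design.

Simulating Z directly from the moment model makes LDSC consistent *by
construction*: recovery tests are sharp tests of the estimation code, not
of how well block LD approximates a real genome.  The corresponding
limitation is explicit: between-variant dependence, MAF structure,
selection and stratification are not emulated, so passing tests say
nothing about LDSC's robustness to those features of real data — only that
the estimators, jackknife and SEM machinery are correct under the model
they assume.

## Preset study conditions

The default scenario (`scenario_fourfactor9()`) mirrors a nine-trait,
two-ancestry psychiatric panel: SCZ, BD1, BD2, MDD measured in European
samples and SCZ (two cohorts), BD1, BD2, MDD in East Asian/Japanese
samples; M = 20,000 variants in 2,000 LD blocks of 10; N = 50,000 per
trait; 200 jackknife blocks aligned with LD-block boundaries; heritabilities
0.06–0.23 (observed scale, psychiatric-GWAS magnitudes); modest
within-population sample overlap (shared controls, e.g. $N_s$ = 10–15k with
$\rho_{ph}$ = 0.1–0.2).  Four correlated factors (European psychosis, Asian
psychosis, BD, MDD) carry loadings 0.35–0.85, including one small negative
cross-loading (−0.25) of Japanese BD2 on the European psychosis factor —
the hardest feature to recover, and a deliberate part of the preset.

The preset fixes $\rho_{ge} = 1$: cross-ancestry attenuation is carried by
the ancestry-specific factor structure itself (the two psychosis factors
correlate 0.5), not by a second per-pair attenuation knob, which keeps the
factor model exactly true on the observation scale.  Dedicated two-trait
scenarios vary $\rho_{ge} \in \{0, 0.6, 1\}$ to exercise the trans-ancestry
estimator, and `scenario_pair()` / `scenario_single()` cover the
correlation- and heritability-recovery designs.

Alleles are written A/G throughout; an optional scramble mode swaps A1/A2
(negating Z) for 20% of records, strand-flips 20%, and injects 5%
strand-ambiguous variants, to exercise harmonization.  Strand-ambiguous
variants are always dropped — no frequency reference is assumed that could
resolve them.

# Numerical choices and degenerate inputs

* Regression weights floor the LD score at 1 and the fitted mean statistic
  at 0.1 to keep weights finite in the tails; weights are held fixed across
  jackknife deletions (the delete-block estimates are then closed-form in
  per-block sufficient statistics, making the joint 45-cell jackknife
  essentially free).
* `vech` order is column-major over the lower triangle including the
  diagonal, everywhere; `vech_index()` is the single source of truth.
* Eigenvalue smoothing floor $\varepsilon = 10^{-6}$; the PSD projection is
  compared against a brute-force eigen-clip in the tests.
* DWLS convergence: gradient norm $< 10^{-8}$, at most 200 damped-Newton
  iterations after the warm start; non-convergence across all five starts
  is an error carrying the best-so-far diagnostics.
* Degenerate designs fail loudly: constant LD scores (free-intercept fit),
  empty variant intersections, missing LD contexts, non-PSD per-variant
  covariance (reported with the offending trait pair), empty jackknife
  blocks, over-parameterized model specs.
* Heritability estimates can be negative under the null; any normalization
  by a non-positive $\hat h^2$ returns a missing value with the reason
  recorded rather than a spurious number.  Trans-ancestry estimates with
  $|\hat\rho_{ge}| > 1$ are reported as-is and flagged, never clipped.

# Problem sizes

The validation suite runs the full study conditions where the statistical
claim needs them: heritability/correlation recovery and interval coverage
at M = 20,000 with 50–200 replicates; SE calibration of all twelve factor
loadings across 200 replicates of the complete pipeline (simulate →
S, V → DWLS → sandwich); model selection across 20 replicates.  Structural
unit tests (parsers, harmonization rules, closed-form oracles) use compact
designs of 1,000–2,000 variants, which is ample for exact identities.

# Known limitations

* No genotype-level simulation; no MAF spectrum, selection, stratification
  or annotation-stratified (partitioned) LDSC.
* Observed-scale heritability only; no liability conversion.
* The trans-ancestry estimator is the moment version of the effect
  correlation; the likelihood-based estimator and the impact correlation
  are out of scope.
* No latent-factor GWAS, per-SNP heterogeneity statistics, or multi-group
  SEM.
* The EFA parsimony score is advisory; factor-count choice remains a
  modeling decision.
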