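---
title: "Validating metabolic flux analysis as a regression problem"
author: "glsmfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating metabolic flux analysis as a regression problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glsmfa)
```

## The model

Overdetermined metabolic flux analysis (MFA) starts from the pseudo
steady-state mass balance $S v = 0$, where $S$ is the species-by-reaction
stoichiometric matrix and $v$ the flux vector (here in nmol per $10^6$ cells
per hour).  Splitting the columns into observed transport fluxes $v_o$
(measured extracellularly) and calculated intracellular fluxes $v_c$ gives

$$-S_o v_o = S_c v_c + \varepsilon,$$

which is a linear regression of the observed balance load on the reduced
stoichiometry $S_c$, with $\varepsilon$ collecting measurement error and any
lack of fit.  The error is not i.i.d.: propagating the observation
covariance gives $\mathrm{Cov}(\varepsilon) = S_o\,\mathrm{Cov}(v_o)\,S_o^T$.
Writing $\mathrm{Cov}(\varepsilon) = \sigma^2 V$ with $\sigma = 1$ and
$V = P P$, both sides are whitened by $P^{-1}$ (the inverse symmetric square
root, which is unique because a covariance matrix is positive
semi-definite), and the whitened system is solved by ordinary least squares
— i.e. generalized least squares (GLS).  Everything the regression framework
offers then applies directly:

* **t-tests** per calculated flux, $t_i = \hat v_{c,i}/\mathrm{se}(\hat
  v_{c,i})$, to ask whether a flux is statistically distinct from zero;
* **confidence intervals** on $\hat v_c$ and **prediction intervals** on
  predicted balances;
* the classical **$\chi^2$ gross-measurement-error test** on the whitened
  residual sum of squares, with the system redundancy $n_b - n_c$ as
  degrees of freedom;
* the **residual variance estimate** $\hat\sigma^2$, which should be close
  to 1 when both the model and the assumed covariance are correct.

Balances on species with no observed transport have zero rows in the
propagated covariance; a small jitter (default $10^{-6}\times$ the median
nonzero diagonal, hence scale-free) is added to every diagonal entry before
inversion.  It can be read as residual uncertainty that each balance truly
closes, and can be supplied per balance to encode extra doubt about
specific species.

## Separating model error from measurement error

A non-significant flux can mean noisy data or a wrong model.  To tell the
two apart, the package simulates data that carry measurement error but *no
model error*: flux profiles are drawn directly from the model's nullspace
($v = K b$, so $S v = 0$ by construction) with the observed components
constrained to confidence bands $v_i \pm a\,\mathrm{sd}(v_i)$, then
perturbed with the assumed measurement noise and re-fit.  The distribution
of t-test decisions, percent errors and $\chi^2$ outcomes over these
replicates is the best the model could possibly do; an observed fit with
markedly worse significance is evidence of lack of fit.  An *infeasible*
constrained space is an even stronger verdict: no stoichiometrically exact
profile is compatible with the observations at all.

The polytope in basis coordinates is sampled by two Markov chain schemes,
hit-and-run (random direction, uniform point on the chord) and a mirror
sampler (Gaussian steps reflected off violated constraint hyperplanes).
Both target the uniform distribution; the mirror sampler tends to cover
corners more evenly at higher cost.  Feasibility and the starting point
come from a Chebyshev-center linear program, which also classifies a space
as empty (certified by the simplex phase-1) versus merely lower-dimensional.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `jitter` | `1e-6 * median` nonzero diag | balance-closure uncertainty (flux units$^2$) |
| `a` | `qnorm(0.995)` = 2.576 | half-width multiplier of the observed-flux bands (a 99 % band; a t-quantile may be passed when df is small) |
| `alpha` | 0.05 | significance level for t and $\chi^2$ decisions |
| `nProfiles`, `mNoise` | 100, 100 | balanced profiles and noise replicates (10 000 total) |
| `cv` | 0.05–0.20 | uniform observation noise level in CV mode |
| `boxFactor` | 10 | box half-width on basis coordinates, in units of the largest observed bound |
| `burnIn`, `thin` | 1000, 10 | chain settings for the samplers |
| `dryMass` | 0.24 mg/$10^6$ cells | dry cell mass for biomass pseudo-fluxes |

The box on the basis coordinates exists because the observed-flux bands
alone can leave directions of the nullspace unbounded; it is reported with
a message whenever a space is built.  Chain defaults were chosen for small
polytopes (basis dimension up to a few tens); the effective sample sizes
reported in the sample diagnostics indicate when longer thinning is needed.

## Degrees of freedom: two conventions

The residual variance is commonly printed as
$\hat\sigma^2 = \sum \hat\varepsilon_i'^2 / (n_b - n_c - 1)$, the
intercept-style formula.  This regression has no intercept, so its exact
residual degrees of freedom are $n_b - n_c$, and under the printed
convention $E[\hat\sigma^2] = (n_b - n_c)/(n_b - n_c - 1) > 1$, noticeably
so at low redundancy.  Both conventions are exposed
(`dfConvention = "textbook"` / `"residual"`); the textbook form is the
default for continuity with common practice, while the calibration checks
in this package (type-I error of the t-test, $\chi^2$ false-positive rate,
centering of $\hat\sigma^2$ on 1) use the residual convention, under which
they are exact.  The $\chi^2$ test always defaults to the redundancy
$n_b - n_c$.

Sign convention throughout: transport reactions are written in the uptake
direction and consumption of an extracellular species is positive (glucose
positive, lactate negative).  Timecourse-derived fluxes therefore use
$v = -\tfrac{1}{X}\tfrac{dC}{dt}$ by default; the raw-derivative
convention is available via `convention = "derivative"`.

## Observed fluxes from timecourses

Concentration and cell-density timecourses are fit with an unpenalized
cubic B-spline basis of dimension 4 — exactly the cubic polynomial space,
the smallest basis that supports a curved trend and an analytic first
derivative (larger bases place interior knots at quantiles of the sampling
times).  The B-spline representation is used rather than a natural-spline
design precisely so the derivative of the fitted expansion is exact, not a
finite difference.  Measurement variance is estimated as the residual mean
square about the fit; flux uncertainty is propagated by simulating
perturbed prediction sets (variance = leverage-weighted regression variance
plus measurement variance), re-fitting, and evaluating
$-\dot C(t^\ast)/X(t^\ast)$ per replicate.  Biomass pseudo-fluxes are a
composition-table product: $-\,c_j\,\mu\,m_{dry}$ with $\mu = \dot X/X$,
the composition $c_j$ (nmol/mg) supplied as data.

## What the synthetic generator emulates — and what it does not

`makeToyNetwork()` produces random sparse integer stoichiometries with a
guaranteed nontrivial nullspace, transport (exchange) reactions as the
observed subset, an overdetermined partition, and ground-truth fluxes
spanning three decades (0.1–400 nmol/$10^6$ cells/h), mirroring the
magnitude spread of real CHO exometabolome data.  Ground truth is obtained
by projecting a log-uniform target vector onto the nullspace and redrawing
until no flux falls below the lower magnitude bound, so relative noise and
band constraints stay well defined.  The generator reproduces the *size and
magnitude statistics* of a curated mammalian-cell model, not its topology:
pathway structure (glycolysis/TCA coupling, cofactor balancing), reaction
reversibility patterns and realistic compartmentation are absent.  Passing
tests on these networks therefore demonstrate the statistical machinery is
calibrated — not that any particular biological model fits.

Calibration experiments use two dedicated shapes, chosen from the
distribution theory before running them:

* $\chi^2$ false-positive rate: 10 species / 16 reactions with an exchange
  per species, so the propagated covariance is full rank and the whitened
  residuals follow their nominal null (otherwise noise confined to
  $\mathrm{range}(S_o)$ makes the test conservative);
* $\hat\sigma^2$ centering: 24 species / 36 reactions (redundancy 12),
  2000 replicates, residual df — the estimator is then exactly unbiased
  and the Monte-Carlo standard error (~0.009) dominates.

The qualitative noise-response experiment (non-significance versus CV,
error split by t-test outcome) uses an 8-species / 14-reaction network with
redundancy 2 — the low-redundancy regime typical of strongly reduced MFA
models, where identifiability is genuinely poor and the pattern of
interest (rejection rates growing with CV; significant fluxes carrying
markedly smaller median errors at 5 % CV) emerges.  Problem sizes
(100 profiles × 100 replicates per CV level; 1000–20 000 fits per
statistic elsewhere) keep every experiment to seconds on one core while
holding Monte-Carlo error well inside the tolerances asserted.

## Numerical choices and degenerate inputs

* Nullspace and rank via SVD with singular values below
  $10^{-10}\times$ the largest treated as zero, for a reproducible
  dimension under float noise; the basis is orthonormal.
* The whitened system is solved by QR; the explicit normal-equations path
  is retained behind `method = "normal"` for equivalence testing only.
* Bands of width zero (sd = 0) are widened to $\pm 10^{-9}$ with a warning
  rather than being silently treated as equalities; genuinely contradictory
  bounds raise an error at build time.
* The Chebyshev LP is solved in row-normalized, box-scaled units;
  structurally vacuous (all-zero) constraint rows are removed, and an
  all-zero row with a negative bound is itself a certificate of emptiness.
  Simplex vertices are nudged strictly inside by cyclic projection before a
  chain starts.
* Magnitude ties in the rank analysis are broken by model column order;
  percent errors are undefined (`NA`) where $|v_{true}| < 10^{-9}$.
* Zero observed noise (sd = 0 everywhere) leaves only the jitter in the
  covariance: fits are exact, $\hat\sigma^2 = 0$, and intervals collapse
  to zero width.

## Known limitations

* The containment fraction reported by `compareToObserved()` — the share
  of simulated replicates whose non-significant set contains the observed
  one — is a descriptive tail probability, not a calibrated test.
* No measurement reconciliation (adjustment of $v_o$), no serial
  elimination of suspect measurements, no isotope-labelling information,
  and no automatic model correction: infeasibility or lack of fit is
  reported, fixing the model is the modeler's task.
* Pooling of cyclic or parallel pathways required to make $S_c$
  (over)determined is expected to happen in the input file; the package
  only detects and reports determinacy failure.
* The SBML reader consumes stoichiometry only (no kinetics, rules or
  annotations); the plain-text reaction table is the canonical format.

## A compact worked example

```{r example, eval = FALSE}
sc <- makeToyNetwork(nSpecies = 8, nReactions = 12, seed = 3)
part <- partitionModel(sc@model, sc@observed)
conditionNumber(part@Sc)

fit <- fitGLS(part, sc@obs)
tTest(fit)
chi2GrossErrorTest(fit)

space <- fluxSpace(sc@model, sc@observed, sc@obs)
design <- simulationDesign(nProfiles = 100, mNoise = 100,
                           noiseSource = "cv", cv = 0.05, seed = 1)
res <- runValidation(part, space, sc@obs, design)
rankSummaries(res, bySignificance = TRUE)
compareToObserved(fit, res)
```
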