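---
title: "Multivariate UV calibration with PLS1 and linear SVR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate UV calibration with PLS1 and linear SVR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccalib)
```

## The calibration problem

A major analyte (cefoperazone sodium, CEF) must be quantified by UV
spectrophotometry in the presence of two trace impurities
(7-aminocephalosporanic acid and 5-mercapto-1-methyl-tetrazole) whose
absorption spectra overlap CEF's across the whole 210–300 nm range. At any
single wavelength the impurity contribution is confounded with the analyte;
a full-spectrum regression model resolves it. The workflow is:

1. prepare a balanced multilevel calibration design of mixtures spanning
   the expected concentration space (16 training mixtures; CEF 18–26
   µg/mL, impurities at trace levels corresponding to at most ~3 % of CEF
   on a molar basis);
2. record each mixture's spectrum, mean-center spectra and concentrations;
3. fit a regression model from spectra to CEF concentration — here PLS1
   and linear ε-SVR, compared head to head;
4. validate on nine independent mixtures inside the design space, with
   recovery %, RMSEC and RMSEP as figures of merit, and compare replicate
   assays against a reference method by t- and F-tests.

## The calibration design

The training design assigns each of the three components four concentration
levels such that every level occurs exactly four times per component and
the mean-centered coded-level columns are mutually orthogonal — so each
component's variation can be estimated free of the others. The published
16-mixture table is shipped verbatim (`cef_training_design()`); its
orthogonality is verified by `validate_design()` with |Pearson r| below
1e-10 between all coded column pairs.

`build_balanced_design()` generates designs of the same family for any
number of levels L: a full factorial in the first two coded factors (a, b)
and, for the third, (a + k·b) mod L with k coprime to L. A counting
argument shows any two such columns have exactly zero covariance, so
orthogonality is exact by construction, not approximate. The seed selects
among per-factor cyclic relabelings, all of which preserve balance and
orthogonality. Coded levels are assigned 0..L−1 by ascending concentration;
the printed concentrations are the ground truth.

## Mean centering

All preprocessing is mean centering only, of spectra columns and of the
response, fitted on training data (`center_fit()`) and applied unchanged
to any new data — test spectra are always centered with *training* means,
which the tests verify as a leakage guard. No variance scaling is applied:
absorbance columns share units and comparable magnitudes, and scaling
would inflate the noise-only wavelengths at the spectrum edges.

## PLS1

`pls1()` implements NIPALS PLS1 with deflation of X and orthogonal scores.
For a single response the weight vector of each latent variable is obtained
directly (no inner iteration):

* w_a = X_a' y_a / ‖X_a' y_a‖, t_a = X_a w_a,
* q_a = t_a'y_a / t_a't_a, p_a = X_a' t_a / t_a' t_a,
* deflation X_{a+1} = X_a − t_a p_a'.

Prediction uses B = W (P'W)⁻¹ q on centered spectra. Numerical guards: the
fit stops early (with a warning, returning a smaller model) if the X
residual norm falls below 1e-12 of its initial value or no covariance with
the response remains — both occur when more components are requested than
the data's effective rank supports. At the data's rank on noiseless linear
mixtures the model interpolates the training concentrations; the tests
assert this to RMSEC < 1e-8 µg/mL, and agreement with an independently
coded textbook NIPALS (y-deflation variant, sequential-deflation
prediction) to 1e-8.

## Selecting the number of latent variables

`select_ncomp_bootstrap()` repeats, 1000 times by default: divide the
training set into two-thirds (11 of 16 rows; rounding 2I/3) and one-third,
fit PLS1 on the inner split for every candidate component count (one
NIPALS pass at the maximum count yields all nested sub-models), and record
the held-out RMSEP. Division is *without* replacement, following the
procedure's description as dividing the set; a with-replacement resampling
variant is available behind the `replace` flag for sensitivity analysis.

**Selection rule.** The default is the one-standard-error parsimony rule:
the fewest components whose mean RMSEP lies within one Monte-Carlo
standard error of the curve's minimum (`rule = "min"` gives the plain
global minimum). The global minimum is the natural reading of "pick the
minimum of the RMSEP plot", but it is ill-posed exactly where this
workflow operates: the reference concentrations of a calibration design
are known essentially without error, so all noise lives in the spectra,
and beyond the chemical rank the mean RMSEP curve is flat to within
Monte-Carlo fluctuation — its argmin then wanders over 4–6 components
arbitrarily. The one-SE rule returns the rank whenever the curve truly
flattens there and is standard practice in cross-validated model-complexity
selection.

A caveat the simulations surface honestly: for a minority of noise
realizations (roughly 2 of 10 seeds at the default 0.002 AU) the curve
does not merely flatten but keeps a genuine shallow descent to 4–5
components, larger than one standard error. This is a real
errors-in-variables effect — extra latent variables partially compensate
noise interacting with the dominant spectral direction of that particular
training matrix — not a defect of the rule; for those training matrices
the extra components *do* cross-validate better.

## Linear ε-SVR

`svr_linear()` fits ε-insensitive support vector regression with the
linear kernel. The fitted function is f(x) = w·x + b with
w = Σ (αᵢ − αᵢ*) xᵢ, found by solving the standard dual

maximize −½ Σᵢⱼ (αᵢ−αᵢ*)(αⱼ−αⱼ*) xᵢ·xⱼ − ε Σ (αᵢ+αᵢ*) + Σ cᵢ (αᵢ−αᵢ*)

subject to 0 ≤ αᵢ, αᵢ* ≤ C and Σ(αᵢ−αᵢ*) = 0. C trades flatness against
training error; ε sets the tube half-width inside which residuals are
free. Both act on the *centered* response scale.

**Solver.** A primal-dual interior-point method on the (α, α*) box QP:
each Newton step solves a (2I+1)-dimensional KKT system, trivial at
calibration-design sample sizes, and converges in ~15–40 steps. The
central-path barrier is indifferent to the severe rank deficiency of the
Gram matrix that heavily collinear spectra produce (where coordinate-wise
methods zigzag). The barrier diagonal is capped near convergence to keep
the KKT system solvable, and dual coefficients within 1e-12·C of a bound
or of zero are snapped. The bias b is the mean of the KKT equalities over
unbounded support vectors, or the midpoint of the KKT-feasible interval
when none exist. Fits are verified in the tests against a brute-force QP
grid on 3-point problems (objective to 1e-3) and against an independent
reference implementation (libsvm via `e1071`, tolerance 1e-8) to 1e-4 in
predictions.

One property worth spelling out because it is easy to mis-state: on data
lying exactly on a line, the SVR optimum is *not* the generating line but
the flattest line through the ε-tube — for c = 2x on x ∈ [0.5, 4] with
ε = 0.1 the fitted slope is 2 − 2ε/range(x) ≈ 1.943. The tests assert
this optimum.

**Hyperparameter search.** `svr_grid_search()` evaluates log-spaced grids
ε ∈ {0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1} and C ∈ {30, 56, 100, 180, 280,
560, 1000} (spanning the primary ranges 0.01–1 and 30–1000) by 4-fold
cross-validation: a seeded random partition of the 16 training mixtures
into folds of 4, each fold predicted by a model trained and centered on
the other 12; RMSECV is the root mean square over all 16 held-out
predictions. Ties break toward smaller C, then smaller ε (the flatter,
simpler model).

## Figures of merit and method comparison

`assay_report()` produces the taken/found/recovery table with mean and SD
of recovery and RMSEC or RMSEP; recovery is reported to 2 decimals in text
output with full precision retained internally. `f_test_summary()` puts
the larger variance in the numerator (so F ≥ 1 and the test is symmetric
in its arguments) with degrees of freedom ordered accordingly;
`t_test_summary()` is the classical pooled-variance two-sample t on
summary statistics. Critical values are the two-tailed t and upper-tail F
quantiles from R's `qt`/`qf` (t = 2.228 at df 10, F = 5.050 at df (5,5),
P = 0.05).

## The synthetic scenario: what it does and does not emulate

No measured spectra are distributed with the study this workflow targets,
so `default_scenario()` generates a stand-in with the statistical
structure the analysis assumes:

* **Pure spectra** are sums of two Gaussian bands per component on the
  210–300 nm grid at 1 nm steps (91 points; the common export resolution
  of benchtop double-beam instruments). CEF's maximum is at 229 nm.
  Pairwise cosine similarities are 0.78–0.92 — heavily overlapped, as in
  the real system.
* **Absorptivity scale.** Band coefficients give CEF ~0.8 AU at 10 µg/mL.
  The impurity per-mass coefficients are set so that, accounting for
  molecular weight (≈667, 272, 116 g/mol), the impurities are strong
  chromophores of a few times CEF's molar absorptivity. This is the one
  place the generator takes a deliberate stance: at the trace levels of
  the design (≤3 % molar), weaker impurity absorptivities would leave the
  third spectral direction below the 0.002 AU noise floor — the system
  would have effective rank two, and no three-component calibration story
  to emulate.
* **Mixing** is exactly linear (Beer–Lambert at unit path length) with the
  published design concentrations; **noise** is additive iid Gaussian,
  0.002 AU by default (a typical double-beam UV noise floor), from a
  seeded generator, independent streams for training and test sets.

Not emulated: baseline drift, stray light, wavelength-correlated noise,
formulation excipients, or any nonlinearity. Passing tests on this
scenario therefore demonstrate correctness of the estimators and the
selection machinery under the model's own assumptions — not robustness to
real-instrument artifacts.

## Problem sizes and reproducibility

Default study sizes are the published ones: 16 training and 9 test
mixtures, 1000 random splits for component selection, a 7×7
hyperparameter grid with 4 folds. Every stochastic stage (simulation
noise, split draws, fold assignment) takes an explicit integer seed, and
the pipeline log records all of them; identical configuration and seeds
reproduce byte-identical CSV outputs. Property-style tests run reduced
Monte-Carlo sizes (100–400 splits) where the assertion concerns shape
rather than precision.

## Known limitations

* PLS1 only (single response); no PLS2, SIMPLS or kernel PLS. Impurity
  concentrations can be calibrated by separate per-component fits.
* Linear SVR only; no nonlinear kernels or ν-SVR.
* The JCAMP-DX reader supports the uncompressed AFFN `(X++(Y..Y))` dialect
  of a single block — sufficient for typical UV exports, not the full
  standard.
* The interior-point solver targets the small dense problems of
  calibration designs (tens of samples); it makes no attempt at the
  sparse/large-I regime.
* The balanced-design builder requires multipliers coprime with L and so
  cannot generate, e.g., 4 mutually orthogonal factors at 4 levels; the
  3-factor case that matters here always exists.
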