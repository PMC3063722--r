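---
title: "Maximum noise entropy models: theory, fitting and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum noise entropy models: theory, fitting and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnemodel)
library(dplyr)
```

## The modeling problem

Many input/output systems — here, neurons encoding a sensory stimulus — are
characterized experimentally through a handful of input/output moments: the
mean output rate, the spike-triggered average, the spike-triggered
covariance. Any model built from such limited knowledge risks smuggling in
assumptions about everything the measurements did not constrain. The maximum
noise entropy (MNE) principle removes that bias: among all response
functions `P(y = 1 | x)` consistent with the measured moments, choose the
one that maximizes the noise entropy

$$ S_{noise} = -\sum_x P(x) \sum_y P(y|x) \log_2 P(y|x), $$

i.e. the model that is maximally noncommittal about everything else. For a
binary output constrained on moments $\langle y f_\mu(x) \rangle$ the
solution is a logistic function of the monomial features,

$$ P(y=1|x) = \frac{1}{1 + \exp\!\big(a + \sum_i h_i x_i +
   \sum_{i \le j} J_{ij} x_i x_j + \cdots\big)}, $$

one Lagrange multiplier per constrained moment. Because the response
entropy of a binary output is fixed by the mean rate alone, constraining
the rate makes the maximum-noise-entropy model simultaneously the
*minimum mutual information* model: its information

$$ I_{model} = H_2(\bar{y}) - S_{noise} $$

is the least any model consistent with the constraints can carry, so
$I_{model}/I_{empirical}$ measures how much of the system's information is
attributable to the constrained moments themselves. Adding constraints can
only raise this lower bound, which yields a principled model-selection
loop: raise the interaction order until the ratio is close enough to one
(`scan_orders()`).

### Sign convention

The exponent's sign is not fixed by the theory (negating all coefficients
and the convention gives the identical model). This package fixes
`P(y=1|x) = 1/(1+exp(z))` with `z` the coefficient-feature inner product —
probability *decreasing* in `z` — records it in every serialized model, and
never compares raw coefficients across conventions.

## Fitting by moment matching

The Lagrange multipliers are determined by the moment-matching conditions:
model moments must equal empirical moments for every feature. For binary
outputs this is exactly the stationarity condition of the average
log-likelihood of the logistic model, and the gradient of that objective
*is* the moment mismatch, up to the sign fixed by the exponent convention
(the package tests this identity numerically). `fit_mne()` therefore minimizes the penalized
negative average log-likelihood with a deterministic quasi-Newton method
(L-BFGS-B) started at the all-zero coefficient vector — the constant-1/2
model — so fits are reproducible bit-for-bit with no seed sensitivity. The
objective is convex, and convergence is declared on the max-norm of the
moment mismatch (default `1e-6`).

Three numerical guards matter in practice:

* **Deterministic systems.** Exact logic gates drive coefficients to
  infinity (probabilities to 0 or 1). A box bound (`coefficient_cap`,
  default 50) and a tiny ridge penalty (`l2_penalty`, default `1e-8`) keep
  fits finite; the information ratio then approaches its limit from below,
  which is why gate analyses quote tolerances rather than exact 100%. For
  exact-ensemble work we raise the cap (some three-input gates need
  coefficient magnitudes near 175 before the conditional table is correct
  to `1e-6` per state) and drop the ridge.
* **Clamped logarithms.** Probabilities are floored at `1e-12` inside
  entropies so near-deterministic tables stay finite; probabilities exactly
  0 or 1 contribute exactly zero, so deterministic tables have exactly zero
  noise entropy.
* **Binary redundancy.** For 0/1 inputs, powers are idempotent, so
  repeated-index monomials are excluded from binary feature maps; including
  them cannot change the achievable models (tested).

### The brute-force oracle

Because the logistic solution is a theorem, not an assumption of the
implementation, the package carries an independent check:
`maxent_oracle()` maximizes the noise entropy directly over the per-state
conditional probabilities — an augmented-Lagrangian optimization in
per-state logits under linear moment constraints, with no
logistic-in-features parameterization anywhere. On every enumerable
ensemble the oracle table and the fitted logistic model must agree per
state; the test suite verifies this across Boolean gate ensembles at all
orders, and verifies that random constraint-preserving perturbations of the
oracle table never increase the entropy. Infeasible constraint sets are
detected by a residual threshold (`1e-8`) and reported with the violated
constraint's name.

## Exact gate ensembles

Boolean truth gates under a uniform input distribution are the package's
exactly solvable laboratory (`named_gate()`, `gate_dataset()`,
`enumerate_gates()`). They make the information decomposition vivid:

```{r gates}
xor <- gate_dataset(named_gate("XOR"))
scan_orders(xor, max_order = 2, threshold = 90) |>
  select(order, model_information_bits, percent)
```

AND and OR are completely described at first order; XOR carries nothing at
first order and everything at second. An order-N model on N binary inputs
has as many constraints as states, so it reproduces any truth table — the
acceptance suite sweeps all 256 three-input gates to confirm the guarantee.

## The two-dimensional neural pipeline

For neurons driven by a temporal stimulus the package follows the standard
reduced-dimensionality workflow: responses binned at 4 ms (binary per bin),
inputs taken as the 200 ms (50-bin) stimulus window ending at and including
the response bin, projected onto two temporal filters (obtained elsewhere,
e.g. by maximally informative dimensions — they are inputs here), and each
projection normalized by its maximum absolute value into [-1, 1]. The
window-inclusivity convention ("ending at and including") is a documented
choice, verified by a delta-stimulus alignment test.

Models are fitted on the continuous reduced inputs; a 14x14 uniform grid
over the input plane is used only for the empirical reference information
(plug-in mutual information between grid cell and response) and for
display. Unvisited cells are reported as `NA` — unsampled inputs — which is
deliberately distinct from visited cells with zero spike probability.
Out-of-range projections (possible on held-out data) are clipped into the
edge bins and tallied.

Two diagnostics probe what the constraints missed: `
predict_unconstrained_moments()` compares model-implied and observed
moments the model was never fitted to (third-order moments, by default),
and `compare_cross_term()` quantifies the information contributed by the
mixed second-order coefficient, which rotates the conic-section contours of
the 2-D response surface away from the filter axes. Both are nested-model
comparisons, so gains are nonnegative up to numerical tolerance.

## The synthetic-data generator

No recordings ship with the package; every pipeline stage is exercised on
synthetic data with planted ground truth (`simulate_neuron()`).

* **Stimulus.** An exponentiated mean-reverting Gaussian (log-normal AR(1))
  process, standardized with its exact log-normal moments: temporally
  correlated (default correlation time 40 ms = 10 bins at 250 Hz),
  positively skewed and heavy-tailed, as luminance fluctuations are.
  Defaults `sigma = 0.4` (skewness about 1.3, excess kurtosis about 3).
  This is a designed stand-in for naturalistic luminance statistics, not a
  reproduction of any measured sequence; passing tests demonstrate the
  estimator's behavior on correlated non-Gaussian inputs, not fidelity to
  any particular retina's operating regime.
* **Filters.** A deterministic orthonormal biphasic pair (difference of
  Gaussians and a lagged copy, Gram-Schmidt orthonormalized) spanning the
  50-bin window.
* **Spikes.** Bernoulli draws per bin from a planted logistic model in the
  *normalized* reduced coordinates — the same coordinates the pipeline
  recovers, so coefficient comparisons are well posed. The default planted
  model is second order with no mixed term,
  `(a, h1, h2, J11, J22, J12) = (2, -8, 6, -20, 14, 0)`: mean rate about
  0.18 per 4 ms bin (about 45 spikes/s, within the range of primate retinal
  ganglion and geniculate cells under naturalistic stimulation) and about
  0.15 bits of information per bin. The max-abs normalization concentrates
  typical projections well inside [-1, 1] for heavy-tailed stimuli, so
  coefficients of this magnitude are what realistic modulation depths
  require in these coordinates.
* **Conditional independence.** Responses are conditionally independent
  Bernoulli across bins: no spike history, refractoriness or adaptation.
  Real spike trains violate this, which is one reason real cells fall short
  of 100% explained information while the planted model does not.

Parameter recovery at `T = 2e5` bins (about 13 minutes of recording)
reaches a relative coefficient error of a few percent, improving with
duration, and the matched-order information ratio exceeds 95%; both are
asserted in the acceptance suite at fixed seeds. Problem sizes in the test
suite (2e4 bins for smoke tests, 2e5 for recovery, 5e5 for stimulus
statistics) were chosen as the smallest that make these properties
statistically unambiguous.

## Numerical and design choices

* Logarithms are base 2 in every user-facing quantity; natural logs are
  used only inside the optimizers.
* The empirical reference is the plug-in (maximum-likelihood) mutual
  information with no bias correction: exact on exact gate ensembles, and
  biased upward by finite sampling on binned neural data. With 196 cells
  and `T = 2e5` the bias is of order `1e-3` bits — negligible against the
  planted information — but on short recordings the reference can exceed
  the truth and depress ratios. Conversely, the 14-bin discretization
  loses some continuous-input information, so a well-matched continuous
  model can slightly exceed the binned reference; ratios above 1 are
  clipped to 1 with a warning rather than silently reported.
* Moments are matched on their natural scale (no standardization): gate
  ensembles are exact and the reduced neural inputs are already confined
  to [-1, 1].
* `info_ratio()` treats a zero reference with positive model information as
  an error (inconsistent inputs), and a zero/zero case as `NA` — constant
  gates simply carry no information to decompose.
* Degenerate datasets (all-zero or all-one responses) return the constant
  model with a warning instead of failing, so ensemble sweeps over all
  truth tables run unattended.

## Limitations

* Binary outputs only: the general multinomial Boltzmann form is outside
  the package's scope.
* The dimensionality-reduction step itself (finding the filters) is not
  implemented; filters are inputs.
* No debiased information estimators (jackknife, shuffle corrections); on
  real, short recordings the plug-in reference should be treated with care.
* The self-consistent minimum-information iteration needed when the mean
  output is *not* constrained is not implemented; the closed-form binary
  MNE case assumes the rate is among the constraints.
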