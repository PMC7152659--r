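---
title: "Mechanistic kinetics and Markov state models for haloalkane dehalogenase catalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic kinetics and Markov state models for haloalkane dehalogenase catalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhalokin)
```

# The model

Haloalkane dehalogenases hydrolyze carbon–halogen bonds through a
multi-step catalytic cycle. `dhalokin` models the cycle as a chain of
elementary reactions,

$$E + S \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} ES
  \xrightarrow{k_2} EI \xrightarrow{k_3} EP
  \underset{k_{-4}}{\overset{k_4}{\rightleftharpoons}} E + P,$$

where $ES$ is the Michaelis complex, $EI$ the covalent alkyl–enzyme
intermediate formed by the S$_\mathrm{N}$2 attack of the catalytic
aspartate ($k_2$), $k_3$ the hydrolysis of the intermediate and $k_4$
product release. A simplified three-step scheme
($EI \xrightarrow{k_3} E + P$, no $EP$ species) serves datasets in which
the fluorescence of intermediate and product cannot be distinguished, so
the last two steps are not separable; $k_3$ then lumps hydrolysis and
release. Units are fixed package-wide: concentrations in µM, time in s,
bimolecular constants in µM⁻¹s⁻¹.

Two binding regimes are supported. With explicit binding, $k_1$ and
$k_{-1}$ are model parameters and the dissociation constant is derived as
$K_S = k_{-1}/k_1$. For substrates whose binding equilibrates much faster
than chemistry (1,2-dibromoethane in LinB), only $K_S$ is identifiable;
the mechanism is then parameterized by $K_S$ directly. Internally the
rapid-equilibrium case substitutes a fast explicit pair
($k_1 = 10$ µM⁻¹s⁻¹, $k_{-1} = K_S k_1$) rather than solving a
differential–algebraic system: this keeps a single ODE path through the
package, and in the regimes of interest ($k_{-1} \gg k_2$) the
approximation error on observable quantities is below 0.5% (checked in
the test suite against the explicit model).

Species trajectories are obtained by numerical integration with an
adaptive stiff-capable solver (`deSolve::lsoda`) at `rtol = 1e-8`,
`atol = 1e-10`. Mass conservation (enzyme ledger $E+ES+EI+EP=E_0$ and
substrate ledger $S+ES+EI+EP+P=S_0$) holds on every trajectory to
$10^{-6}\,\max(E_0,S_0)$; tiny negative excursions from solver noise are
clamped to zero, and any clamp larger than that tolerance is an
integration error rather than a silent fix.

## Derived steady-state constants

For irreversible post-binding steps the turnover number is the harmonic
combination $k_\mathrm{cat} = (1/k_2 + 1/k_3 + 1/k_4)^{-1}$ (or
$(1/k_2+1/k_3)^{-1}$ for the three-step scheme), and under
rapid-equilibrium binding $K_m = K_S\, k_\mathrm{cat}/k_2$. Both are
cross-checked in the tests against the saturating ODE flux and against
Michaelis–Menten fits of ODE-generated initial rates. Product rebinding
$k_{-4}$ defaults to zero — it is part of the scheme and remains settable
for simulation, but no value is available for the studied systems and all
closed-form derivations assume irreversible release. Rate constants known
only as lower bounds ("$> 10$ s⁻¹") carry a `lower_bound_only` status and
are treated as $+\infty$ in closed forms, making the derived
$k_\mathrm{cat}$ an upper bound rather than a fake point estimate.

# Observable models

Stopped-flow fluorescence is modelled as a weighted sum of species
concentrations with one scaling factor per distinct fluorophore state.
At direct fluorophore excitation (500 nm),

$$V_1 = f\,\bigl(S + ES + a\,EI + b\,(EP + P)\bigr),$$

and at tryptophan excitation (280 nm, FRET-modulated),

$$V_2 = f\,\bigl(S + o\,ES + p\,EI + q\,EP + r\,P\bigr).$$

The grouping $b\,(EP+P)$ treats enzyme-bound and free product as one
fluorophore state — the alternative reading ($b\,EP + P$) would make a
spectroscopically identical species change intensity upon release, which
has no physical basis here. The factors $p$ and $q$ combine FRET and
intensity changes without a separable functional form, so they are
treated as free empirical scalars. An optional additive per-trace
baseline models instrument drift (default 0). DBE has no fluorogenic
signal in this system; its synthetic traces use an identity observable
that reads a species concentration (typically released product) directly.

# Synthetic data

The generators define the study conditions; they are first-class, tested
code. Defaults mirror typical experimental designs for these enzymes:

* stopped-flow single-turnover traces — substrate 2–10 µM mixed with
  30 µM enzyme; a 1 ms instrument dead time discards earlier samples;
* steady-state initial rates — the Michaelis–Menten law at the enzyme
  concentrations of the plate assays (0.2 µM), replicated;
* noise — additive i.i.d. Gaussian with known per-point sigma, specified
  either absolutely or as a fraction of trace amplitude. Defaults of 1%
  (traces) and 2% (initial rates) of amplitude are realistic fluorimeter
  noise levels; no standardized instrument sigmas exist for these assays,
  so these are package choices, held fixed;
* optional ±10% jitter of nominal concentrations, exercising the
  fitter's bounded concentration-adjustment feature while recording the
  true values;
* Markov chains — state sequences from a known row-stochastic matrix
  with optional state-conditioned spherical-Gaussian feature emissions.
  This is deliberately minimal: enough structure for TICA, clustering
  and estimators to have a recoverable ground truth, with none of the
  geometric realism of molecular dynamics;
* reaction geometries — frames with a known fraction inside the
  near-attack window, for scoring the classifier.

Every generator is a pure function of its arguments and seed: the same
seed reproduces a dataset bit for bit. Passing synthetic-recovery tests
therefore demonstrates correctness of the estimators under the stated
noise model — it does not certify behaviour under instrument artifacts,
correlated noise, or model misspecification, which real data can exhibit.

# Global fitting and uncertainty

The fitter minimizes $\chi^2 = \sum_i \left((y_i - m_i(\theta))/\sigma_i\right)^2$
over all traces and initial-rate blocks simultaneously, with the model
evaluated by ODE integration per trace. Optimization is
Levenberg–Marquardt on the sigma-normalized residual vector
(`minpack.lm::nls.lm`). Rates and intensity factors are optimized on the
log scale — they are positive by nature, and the transform conditions
the problem across the several orders of magnitude the rate constants
span. A deterministic multi-start (default 5 restarts, log-uniform
perturbations of half-width 0.5 decades) guards against the local minima
that multi-phase traces can produce; the lowest-$\chi^2$ start is
reported, and identical inputs always give identical results.

Standard errors come from the covariance at the optimum,
$\hat\sigma^2 (J^\top J)^{-1}$ with
$\hat\sigma^2 = \chi^2_\mathrm{min}/(n-p)$, delta-transformed back to the
natural scale. A singular $J^\top J$ flags the fit unidentifiable rather
than reporting meaningless SEs.

## Confidence contours

Beyond covariance SEs, `confidence_contours()` profiles one parameter at
a time: the parameter is fixed on a grid and all other free parameters
re-optimized. The confidence region is bounded where the profile crosses
$\chi^2_\mathrm{min}/0.98$ — the ratio convention of the FitSpace-style
boundary, in which a parameter value is acceptable while the best
attainable fit stays within 2% of the global optimum. Whether that
boundary is a ratio or an F-statistic cannot be settled from the
available description; the ratio convention is implemented and the
boundary is configurable. Crossings are interpolated log-linearly
between grid points. A profile that never recrosses the threshold on one
side yields a one-sided bound (the "$>10$ s⁻¹" pattern); flat on both
sides flags the parameter unidentifiable. Note the implied confidence
level depends on the number of points through $\chi^2_\mathrm{min}$:
with hundreds of points the 0.98 boundary corresponds to a multi-unit
$\Delta\chi^2$ and the tests verify ≥90% coverage by simulation.

Derived constants ($K_S$, $k_\mathrm{cat}/K_m$) get standard errors by
first-order independent-error propagation of the ratio. Variant
comparisons use Welch's unequal-variances $t$-test from summary
statistics, with significance tiers at $p<0.05$ and $p<0.01$ and no
multiple-testing correction (raw tiers are the field's reporting
convention here; adjust externally when screening many comparisons).

# Markov state models

The MSM toolkit operates on featurized trajectories — the package
deliberately does not parse MD trajectory binaries; distance tables and
geometry records are expected as plain columns, decoupling the analysis
from any simulation engine.

* **Featurization.** Binary contacts at a strict `distance < 8` Å cutoff
  (strict inequality, following the contact-map convention; the NAC
  window below is inclusive by contrast).
* **TICA.** The symmetrized lag-covariance generalized eigenproblem
  $C(\tau)w = \lambda C(0)w$, solved by Cholesky whitening. Eigenvalues
  sort descending; component signs are arbitrary and tests compare up to
  sign. A near-singular $C(0)$ receives a logged $10^{-8}$ ridge.
* **Clustering.** Seeded k-means on the projections. The production
  convention of 200 microstates is the default in configs, but cluster
  count is a knob — synthetic tests run with 2–10 clusters, which is the
  honest scale for chains with a handful of true states.
* **Estimation.** Sliding-window counts at the lag, restricted to the
  largest strongly connected state set (dropped states are reported).
  Default is the non-reversible row-normalized estimator, with a
  detailed-balance maximum-likelihood option; which estimator the
  original MSM software applied is not stated, so both are provided and
  the default is the assumption-free one. Lags are in frames; converting
  a physical lag (e.g. 5 ns) requires the frame interval, which is
  configuration, not a constant. The TICA lag and the MSM estimation lag
  are independent settings.
* **Validation.** Implied timescales $t_i(\tau) = -\tau/\ln\lambda_i(\tau)$
  across lags (plateau ⇒ Markovian at that lag) and Chapman–Kolmogorov
  comparison of $T(\tau)^k$ against a direct estimate at $k\tau$.
* **Pathway flux.** Committor-based transition-path-theory decomposition
  of source→sink reactive flux among disjoint channels of intermediate
  states (the main p1 and auxiliary p3 tunnels, in the motivating
  system). The backward committor uses the time-reversed chain, so the
  decomposition is valid for non-reversible estimates too. Tested against
  Monte-Carlo first-passage path sampling on toy chains.
* **NAC classification.** A frame is a near-attack conformer iff the
  nucleophile–carbon distance is ≤ 3.41 Å and the
  nucleophile–carbon–halide angle lies in [157°, 180°], all bounds
  inclusive.

Published equilibrium populations and tunnel-flux percentages for these
enzymes derive from microsecond-scale MD trajectory data that is not
publicly deposited; reproducing those numbers is therefore out of scope,
and the MSM machinery is validated by exact oracles (hand-countable chains,
stationary eigenvectors, closed-form timescales, path-sampling
equivalence) instead.

# Numerical choices and problem sizes

* ODE tolerances `rtol 1e-8 / atol 1e-10`; Euler cross-validation at step
  $10^{-4}$ s in the tests.
* Log-scale optimization; LM with up to 200 iterations; restarts are
  seeded and deterministic.
* Profile grids default to 41 log-spaced points spanning 4× either side
  of the estimate; crossing interpolation is log-linear.
* Reversible MLE iterates the standard symmetric-flux fixed point to
  $10^{-12}$.
* Tie-breaks: rate-limiting-step ties return all tied labels; k-means
  ties follow the seeded `stats::kmeans` behaviour.
* Recovery studies in the tests and the acceptance script use 10 seeded
  replicates of 5-trace stopped-flow experiments (about 1000 points per
  dataset) and 36-point initial-rate designs; coverage is assessed on 200
  replicates of a 240-point design. These sizes give comfortable
  identifiability for the parameters studied while keeping the full suite
  fast on a single CPU.

# Known limitations

* The kinetic ODE model covers the single-substrate cycle only — no
  temperature or pH dependence, no substrate inhibition, no abiotic
  hydrolysis background.
* The rapid-equilibrium substitution is an approximation, accurate when
  binding is at least ~100-fold faster than chemistry.
* The noise model is independent Gaussian with known sigma; the fitter's
  $\chi^2$ weighting and its SEs inherit that assumption.
* The Markov generators emit spherical Gaussians; they exercise the
  estimators, not MD realism.
* Steady-state and microscopic parameter sets are treated as independent
  inputs: the package does not constrain a global fit to reproduce the
  analytic $k_\mathrm{cat}$, since the published steady-state and
  pre-steady-state values were measured in separate experiments (and for
  some variant–substrate pairs the analytic combination of microscopic
  constants does not reproduce the measured turnover, e.g. where the
  published table lists only lower bounds).
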