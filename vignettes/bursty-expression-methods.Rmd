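---
title: "Methods: deterministic and stochastic descriptions of bursty gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic and stochastic descriptions of bursty gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstmodes)
```

## The model and its assumptions

`burstmodes` analyzes the reduced, protein-only description of an
autoregulated gene: promoter switching and mRNA turnover are assumed fast
relative to protein turnover and are averaged out, leaving a single discrete
species whose production arrives in bursts. A burst event fires with
propensity $f(n)/\mu^*$, adds $\mu \sim \mathrm{Geometric}(1/\mu^*)$
molecules ($\mu \ge 1$, mean $\mu^*$), and each molecule degrades with rate
$\delta$. The production rate $f$ is a smooth, monotone nondecreasing
function of the current copy number $n$, which encodes the feedback:

| variant | $f(n)$ | interpretation |
|---|---|---|
| constant | $b$ | no feedback |
| linear | $b + vn$ | linear activation ($v < \delta$ for stationarity) |
| `michaelis_menten` | $b + vn/(n+K)$ | non-cooperative saturation |
| `hill` | $b + vn^h/(n^h+K)$ | cooperative activation, $h > 1$ |

The $1/\mu^*$ frequency scaling keeps the mean production flux equal to
$f(n)$ for every burst size, so varying $\mu^*$ changes the *noise
structure* of production while leaving the deterministic rate equation
$\dot n = f(n) - \delta n$ untouched. The cell volume $V$ is fixed
(no growth dilution); concentrations are always derived as $n/V$ and never
stored separately. Copy numbers are nonnegative integers throughout the
stochastic computations; the deterministic side evaluates $f$ at real
arguments.

Assumptions inherited from this reduction: the system is well mixed; bursts
are instantaneous and geometrically distributed; degradation is first order;
$f$ is evaluated at the protein level only (no separate promoter state). The
package does not model explicit mRNA, time-varying volume, or
tau-leaping/Langevin approximations — all stochastic sampling is exact.

## Exact stationary solution

The stationary distribution of the burst master equation satisfies the
two-term recursion

$$p_1 = \frac{f(0)}{\delta\mu^*}p_0, \qquad
(n+1)\,p_{n+1} = \frac{f(n)}{\delta\mu^*}\,p_n
 + \frac{\mu^*-1}{\mu^*}\,n\,p_n .$$

`stationary_pmf()` carries the recursion in log space because the
unnormalized weights span hundreds of orders of magnitude whenever
$f/\delta$ is large. Truncation uses two joint criteria: the support must
extend past every analytic mode candidate (guaranteed once
$n > \sup f/\delta$, beyond which the ratio $p_{n+1}/p_n$ stays below 1),
and the geometric tail bound $p_n r/(1-r)$ with $r = p_{n+1}/p_n$ must fall
below `tail_tol` (default $10^{-12}$). If $f(0) = 0$ the zero state is
absorbing and the stationary law is a point mass there — returned directly
rather than through the recursion.

Two degenerate conventions worth stating: for $\mu^* = 1$ the burst-size
distribution is a point mass at 1 (the $0^0$ convention in the geometric
pmf), and the recursion then collapses to the birth–death balance, giving a
Poisson law for constant $f$. For $\mu^* > 1$ and constant $f$ the result is
negative binomial with size $b/(\delta(\mu^*-1))$ and success probability
$1/\mu^*$; both closed forms serve as oracles in the test suite, alongside a
brute-force null-space solve of the truncated generator.

## Modes, ties, and the boundary

Because the recursion links $p_{n+1}-p_n$ to the sign of the discrepancy
$d(n) = f(n)/\delta - (n + \mu^*)$, the PMF's interior extrema sit at the
integer crossings of $f/\delta$ with the shifted identity line $n+\mu^*$ —
the ceiling condition $n = \lceil f(n)/\delta - \mu^*\rceil$. This is the
structural reason bursts displace modes to the *left* of deterministic fixed
points (which solve $f(n)/\delta = n$): by up to $\mu^*+1$ molecules for
slowly varying $f$.

Numerical conventions, chosen once and used by both the scanned
(`find_extrema()`) and analytic (`analytic_extrema()`) routes so their
outputs are directly comparable:

* **Plateaus.** Probabilities equal within a relative $10^{-12}$ are merged
  into plateau extrema `{n_lo, n_hi}`. Exact ties are not an edge case —
  they occur whenever $d(n) = 0$ at an integer (e.g. Poisson with integer
  mean has the plateau $\{b/\delta - 1,\ b/\delta\}$). The ceiling-condition
  candidate maps to the plateau's left edge.
* **Boundary.** One extremum always sits at $n = 0$: a maximum iff
  $p_0 > p_1$ strictly; a tie joins the first plateau.
* **Mode significance.** For regime classification only, maxima whose peak
  probability is below $10^{-6}$ of the global maximum are ignored — they
  are numerically real but irrelevant phantom structure in flat tails. The
  scaling experiment does *not* apply this filter, because there the
  relative weight of the two basins diverges exponentially in the system
  size while both modes remain well defined.

## Deterministic side

`find_fixed_points()` brackets sign changes of $f(n)-\delta n$ on a
2048-point grid over $[0, n_\max]$ (default $n_\max = 2\sup f/\delta + 50$)
with two rounds of 32-fold refinement near sign changes — Hill systems close
to a saddle-node have nearly tangent crossings — and polishes each root with
bisection. Stability follows the sign of $f'(n^*)-\delta$; when
$|f'(n^*)-\delta| < 10^{-9}\delta$, below the accuracy of the numeric
derivative, the point is flagged `marginal` instead of being force-labelled.
Trajectories integrate $\dot n = f(n)-\delta n$ with `deSolve` (lsoda,
tolerances $10^{-10}$).

## Transient master equation and moment diagnostics

`transient_cme()` integrates the truncated master equation on the lattice
$0..n_{\mathrm{cap}}$ with a stiff-capable solver. Burst mass that would
jump past the cap flows into an absorbing leak bin, so probability over
lattice-plus-leak is conserved exactly and the leaked mass is reported per
output time; exceeding `leak_tol` is an error naming the cap, never a silent
renormalization. A matrix-exponential computation (`Matrix::expm`) serves as
an independent oracle in the tests.

The burst CME implies exact ODEs for the mean and variance,

$$\frac{d\,\mathbb E[N]}{dt} = \mathbb E[f(N)] - \delta\,\mathbb E[N],
\qquad
\frac{d\sigma^2}{dt} = 2\,\mathrm{Cov}(N, f(N))
 - (\mathbb E[f(N)] - \delta \mathbb E[N])
 + 2\mu^*\mathbb E[f(N)] - 2\delta\sigma^2 ,$$

which we re-derived from the geometric burst moments
($\mathbb E[\mu^2] = 2\mu^{*2}-\mu^*$) and verified to be exact as stated.
`moment_ode_residuals()` differentiates the empirical moment series of a
transient solution (fourth-order five-point stencil on uniform grids) and
compares against these right-hand sides evaluated from the same PMFs;
residuals at the $10^{-8}$ relative level confirm solver consistency. For
constant or linear $f$ the mean equation closes, so the CME mean coincides
with the deterministic trajectory to integrator tolerance; for nonlinear $f$
the stationary gap $|\,c^*V - \mathbb E[N]\,|$ is strictly positive and
grows with $\mu^*$, which `taylor_mean_expansion()` quantifies through the
central-moment series $f(\mathbb E[N]) + \sum_{r\ge2} z_r f^{(r)}(\mathbb
E[N])/r!$. The truncated series is exact for polynomials of degree $\le R$;
for saturating $f$ on multimodal distributions it need not improve
monotonically in $R$, so the function reports the error rather than
promising convergence.

Derivatives of $f$ are analytic for constant/linear/Michaelis–Menten
variants and numeric (`pracma::fderiv`) for Hill and custom functions.

## Stochastic simulation

All samplers are exact direct-method Gillespie implementations, written in
C++ for the two-channel burst model (and for general elementary networks)
because ensemble and passage-time experiments need $10^8$–$10^9$ events.
Burst sizes use the inverse-CDF geometric sampler
$\mu = 1 + \lfloor \ln u / \ln(1 - 1/\mu^*)\rfloor$ with a separate branch
returning 1 when $\mu^* = 1$. Randomness flows through R's RNG stream, and
every stochastic entry point takes an explicit `seed` applied locally (the
caller's RNG state is restored), so identical seeds give identical
trajectories, histograms and hitting times.

`ensemble_endpoint()` mirrors the histogram protocol used for comparing
simulated and analytic distributions: many independent trajectories, one
endpoint each at $t_f$ (default $40/\delta$, i.e. 40 protein lifetimes), and
a stationarity check that repeats the ensemble from a second initial
condition and warns when the two histograms differ by more than a
total-variation threshold. For metastable bimodal systems no fixed horizon
guarantees equilibration — relaxation is exponentially slow in the barrier —
which is precisely why the cross-initial-condition check exists and why the
deep-convergence assertions in the test suite are made on presets whose
mixing at $40/\delta$ was verified with the transient solver.

## Mean first-passage times

`mfpt()` solves the exact hitting-time system $Q_T\tau = -\mathbf 1$ on the
transient states of the truncated chain; bursts overshooting the cap are
lumped at the cap after validating that the stationary mass beyond it is
negligible ($<10^{-10}$), so the lumping cannot distort the answer. The SSA
route averages simulated hitting times and reports a standard error;
replicates that fail to hit within the horizon raise an error rather than
biasing the mean. Since the basin notion is not intrinsic to the model,
`mfpt_between_modes()` adopts the standard operationalization: start at one
mode of the stationary PMF and absorb upon crossing the interior minimum
into the other basin (downward targets are exact thresholds because death
steps are unit-sized; upward targets are upward-closed because bursts can
overshoot).

## Matched scenarios

Three constructions isolate how burst size and feedback shape the local
sharpness $s(n) = d(n)/(\mu^*(n+1))$ of the stationary distribution:

1. **Shifted basal rate** — $f_2 = f_1 + \delta(\mu_2^*-\mu_1^*)$ makes the
   discrepancy functions identical, so both systems share all extrema while
   the larger-burst system has uniformly damped $|s(n)|$: broader
   distribution, faster inter-mode switching.
2. **Hill vs Michaelis–Menten** — an MM curve is solved through the same two
   intersection points with $n+\mu^*$ (a $2\times2$ linear system), sharing
   basal rate and mode locations; the sigmoid's larger $|d(n)|$ makes the
   cooperative system locally sharper. Note that local sharpness constrains
   peak-to-trough contrast, not absolute peak heights: how total mass splits
   between basins is a normalization (large-deviation) effect, and the MM
   system can carry the taller positive peak. The package's checks therefore
   assert the contrast ordering.
3. **MM vs MM at different burst sizes** — both curves are solved through
   their own shifted lines at shared mode locations; the larger-$\mu^*$
   system has the pointwise larger $|d(n)|$, which counteracts its burst
   noise, so neither effect wins a priori and both PMFs must be computed.

Each constructor verifies its defining constraints and inequalities on a
dense integer grid at build time and fails loudly otherwise.

## System-size scaling

`scale_system()` implements the thermodynamic-limit embedding $V \to sV$,
$f \to s f(\cdot/s)$, which maps each analytic feedback family onto itself
(Hill: $K \to s^hK$) and leaves every fixed-point concentration unchanged.
`thermodynamic_convergence()` pairs each mode of the scaled stationary law
with the nearest stable fixed-point concentration and checks the deviation
against the ceiling-condition bound $(\mu^*+1)/(sV)$. The bound as stated
ignores a $1/(1-f'(n^*)/\delta)$ slope factor, so the packaged scaling
demonstration (`sharp_bistable_model()`) uses a Hill system whose stable
fixed points sit in the nearly saturated regime ($f' \approx 0.07$ at the
upper point), where the bound is honest at $s \in \{1, 10, 50\}$; for
systems with appreciable slope at a fixed point the bound can fail at small
$s$ even though the $1/s$ convergence itself is universal.

## Presets and the certification search

The canonical presets (four feedback families $\times$
$\mu^* \in \{1, 6, 11\}$, all with $\delta = 1$, $V = 1$) are the package's
study conditions. Their parameters were fixed by a grid search over
$(b, v, K, h)$ certified by `classify_regime()` to realize each
stability-by-modality quadrant, and are frozen in `preset_model()`:
constant $f=20$; MM $2 + 100n/(n+30)$; Hill $4 + 60n^4/(n^4+30^4)$
(bistable); Hill $10 + 80n^4/(n^4+25^4)$ (monostable yet bimodal with both
modes positive at $\mu^*=6$). `certify_presets()` re-runs the certification
and errors on any drift. The synthetic models emulate the qualitative
regimes of real autoregulatory circuits — burst-driven mode shifts,
extinction peaks, bimodality without bistability — but not extrinsic noise,
cell division, or promoter-state correlations; passing tests therefore
validate the mathematics of the reduced model, not the biology of any
particular gene.

## Problem sizes and numerical choices

Default tolerances: stationary tail $10^{-12}$; ODE/CME integration
$10^{-10}$; plateau ties $10^{-12}$ relative; marginal-stability flag
$10^{-9}\delta$; MFPT truncation validation $10^{-10}$ stationary mass. The
packaged experiments use supports up to a few thousand states (the $s=50$
scaled system), dense-matrix hitting-time solves up to a few hundred states,
ensembles of $5\times10^4$ endpoint trajectories, and $10^4$ simulated
passage times — sizes chosen so the full validation suite runs in a few
minutes on a laptop while keeping Monte-Carlo standard errors small enough
for four-standard-error acceptance bands.

## Known limitations

* Custom feedback functions fall back to a pure-R SSA path and numeric
  derivatives; they are not serializable to config files.
* The exact MFPT solver uses dense linear algebra; targets requiring caps of
  $10^4$ states or more would need a sparse solver.
* Regime classification near bifurcation boundaries inherits the
  grid-resolution limits of the root bracketing; genuinely tangent
  (saddle-node) crossings are reported as marginal rather than resolved.
* The transient solver's leak bin tracks loss past the cap but does not
  redistribute it; long integrations of models with heavy stationary tails
  need a correspondingly larger cap.
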