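---
title: "Non-equilibrium free energy estimation with neqfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-equilibrium free energy estimation with neqfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqfe)
```

## The model

Alchemical absolute binding free energy (ABFE) calculations switch a
ligand's interactions with its environment off and on along a coupling
parameter $\lambda \in [0,1]$. In the non-equilibrium variant, only the
two physical end states are sampled at equilibrium; many short
transitions are then driven through $\lambda$ at a fixed rate, and the
work of each transition is obtained by integrating the Hamiltonian
derivative along the path:

$$W = \int \frac{\partial H}{\partial \lambda}\, d\lambda .$$

`neqfe` implements the analysis layer of this protocol: reading
$\partial H/\partial\lambda$ traces (GROMACS-style XVG files),
trapezoidal work integration, free energy estimators on the resulting
work samples, an overlap-based convergence diagnostic, the analytical
restraint correction, thermodynamic-cycle assembly, and the benchmark
statistics used to compare methods against experiment. A built-in
Langevin toy simulator with analytically known answers validates the
whole stack.

## Sign convention for work

All stored works are *work performed on the system during that
transition in its own direction*: a reversible forward transition
yields $W_F = \Delta G$ and a reversible reverse transition yields
$W_R = -\Delta G$. Reverse traces are integrated from $\lambda = 1$ to
$0$ with no extra sign flip. This makes the Crooks fluctuation theorem
$p_F(W)/p_R(-W) = e^{\beta(W - \Delta G)}$ explicit and is the
convention assumed by every estimator in the package; it is asserted
by the reversible-limit and Crooks-symmetry tests. (An alternative
convention negates reverse works into the forward frame; mixing the
two flips the sign of the reverse contribution in BAR, which is why
the convention is fixed package-wide and documented here once.)

## Estimators

**Jarzynski (uni-directional).**
$\Delta G = -kT\,\ln\langle e^{-W/kT}\rangle$ over one direction,
computed with a log-sum-exp shift so overflow cannot occur. The
estimator is biased from above for finite samples of dissipative work
(Jensen's inequality); the bias decays only slowly with sample size,
which is the statistical reason uni-directional estimates need long
switching times. The test suite measures this bias directly on
Crooks-consistent Gaussian samples and on toy campaigns.

**BAR / Crooks maximum likelihood (bi-directional).** The estimate is
the root of

$$g(f) = \sum_i \phi(M + u^F_i - f) - \sum_j \phi(-M + u^R_j + f), \qquad
\phi(x) = \frac{1}{1+e^x},$$

with reduced works $u = W/kT$ and $M = \ln(n_F/n_R)$. $g$ is strictly
monotone in $f$, so the bracketed root (Brent, $10^{-8}$ kT tolerance,
bracket $\pm(\max|u| + |M| + 10)$) is unique. With one work per
direction the closed form $f = (u^F - u^R)/2$ is used and the standard
error is reported as 0 with a warning flag. $M$ is retained for
unequal counts, which arise after truncation even though full
campaigns use equal counts. The independent oracle in the test suite
maximises the equivalent logistic log-likelihood instead of solving
the score equation; the two agree to $10^{-6}$ kT.

**Uncertainties.** The default uncertainty for every work-based
estimate is a bootstrap standard error (the analytic ML variance is
deliberately omitted): each direction is resampled independently with
replacement, the estimator re-run, and the sd (n−1 denominator) of the
replicate estimates returned. Replicate RNG streams derive from the
splitting rule `seed + replicate index`, making results reproducible
and order-independent; the caller's RNG state is restored. The
replicate count defaults to 1000 (the source protocol does not state
its count; this is configurable).

**Window chaining.** For stratified calculations,
$\Delta G = \sum_w \Delta G_w$ with errors in quadrature, each window
estimated by BAR or by exponential averaging (Zwanzig). The test suite
checks a split-at-$\lambda$=0.5 toy calculation against the
single-stage result.

## Convergence (overlap) measure

Bi-directional estimates are only trustworthy when the forward and
reverse work distributions overlap. The diagnostic compares two
internal estimates of the same overlap integral — first-moment
($a_1 = \tfrac12(\overline{\phi_F} + \overline{\phi_R})$) and
second-moment ($a_2 = \overline{\phi_F^2} + \overline{\phi_R^2}$),
with $\phi$ evaluated at the estimate itself — and reports
$(a_1 - a_2)/(a_1 + a_2) \in [-1, 1]$. Values near 0 indicate a
reliable estimate; values near 1 indicate vanishing overlap; if every
$\phi$ underflows the measure is exactly 1. The exact normalisation
was reconstructed from the overlap identity (first- vs second-moment
estimators of one integral) to satisfy all stated properties of the
published measure — range, 0 at convergence, $\approx 1$ for fast
switches — and is isolated in a single function should a different
normalisation ever be required.

Two practical caveats, established empirically by the test suite and
reflected in how its assertions are phrased:

* wherever the overlap is adequately sampled the measure fluctuates
  around 0 with width $\sim n^{-1/2}$, so "monotone degradation" with
  dissipation holds for seed-averaged means above a small noise floor,
  not for every seed;
* in the crossover regime (forward/reverse separation a few work-sd),
  the measure is dominated by rare tail samples and is intrinsically
  noisy — exactly the regime where it warns, correctly, that the
  estimate is fragile.

## Boresch restraint correction

Releasing a decoupled, Boresch-restrained ligand (one distance $r_0$,
two angles, three dihedrals, six force constants $K$) to the
standard-state volume $V^0$ has the closed form

$$\Delta G_{restr} = -kT \ln\!\left[\frac{8\pi^2 V^0 \sqrt{\prod_i K_i}}
{r_0^2 \sin\theta_{A0} \sin\theta_{B0}\,(2\pi kT)^3}\right],$$

with $kT$ in kcal/mol, distances in Å, angles in rad and
$V^0 = 1660$ Å$^3$ (1 M) by default. This is the stiff-spring
approximation to the exact restrained configurational integral; the
package implements the closed form because that is what the ABFE
protocol prescribes. The difference from the exact integral is the
second-order correction
$kT^2/K - kT\ln(1 + kT/(K r_0^2))$ (for equal $K$): about 0.067
kcal/mol at $K = 5$ kcal/mol/rad², 0.034 at $K = 10$, and below 0.02
only for $K \gtrsim 17$. The test suite verifies this deviation law
against a factorised quadrature oracle rather than pretending the two
agree at soft force constants; for typical restraint strengths
($K \gtrsim 20$) the distinction is well below the statistical noise
of any simulated leg.

## Thermodynamic cycle and repeats

The ABFE preset is
$\Delta G_{bind} = \Delta G_{prot} - \Delta G_{solv} + \Delta G_{restr}$
("prot" couples the restrained ligand in the protein, "solv" couples
the ligand in water, "restr" releases the restraints), with standard
errors in quadrature. Independent repeats are combined by treating
each repeat as a normal distribution (mean = estimate, sd = bootstrap
uncertainty): the combined variance is the mixture variance
$\overline{se_i^2} + \mathrm{var}(dg_i)$ and the combined standard
error divides by $\sqrt{n}$. The between-repeat variance uses the
n−1 denominator — with the 3–6 repeats typical of these campaigns the
unbiased sample variance is the defensible choice (the source
protocol does not state the denominator).

## Benchmark statistics

Accuracy against a reference is summarised by AUE, RMSE, Pearson,
Spearman (average ranks) and Kendall $\tau_b$ (tie-corrected — the
standard tie conventions, unstated in the source). Error bars come
from a combined parametric + non-parametric bootstrap: rows are
resampled with replacement and each drawn calculated value is
re-drawn from $N(dg, se^2)$. Reference values are fixed by default
(experimental references typically carry no uncertainty); a `ref_se`
argument perturbs them too. Iterations with undefined correlations
(constant resample) are discarded; more than 20% discards is an
error. Bias against sampling time is the mean over systems of
$|dg(\tau) - dg(T_{final})|$; truncation of a work set keeps
transitions whose equilibrium snapshot origin lies within the first
fraction of the sampled time (threshold from the global maximum
origin, matching the shared equilibrium-trajectory length that
truncation emulates).

## The toy simulator: what it emulates, and what not

The toy engine mirrors the two-step protocol at desk scale: sample
the two end states at equilibrium, extract equidistant snapshots,
drive one fixed-length switch per snapshot in each direction. The
system is a single particle under overdamped Langevin dynamics
(Euler–Maruyama, stability bound $dt\,k_{eff}/\gamma < 0.1$ enforced),
in reduced units ($kT = 1$; a `work_set` is exported at the matching
temperature so kJ/mol values equal reduced works numerically).
$\lambda$ advances after each coordinate update and the work
accumulates by the trapezoid over the $(x, \lambda)$ pairs actually
visited, so the $O(\Delta\lambda)$ bookkeeping is explicit.
Instantaneous switches reduce to $\Delta U$ between end-state
Hamiltonians, making Jarzynski coincide with Zwanzig by construction.

Two potentials are provided. The harmonic pair
($k(\lambda), x_0(\lambda)$ interpolated; $\Delta F =
\tfrac{kT}{2}\ln(k_B/k_A)$ exactly) isolates switching error from
sampling error because end-state draws are exact Gaussians. The
double-well/harmonic pair emulates a system with two metastable
conformations: exact inverse-CDF draws (the default) give unbiased
starts, while a Langevin stream started in one basin below an 8 kT
barrier never crosses, reproducing the systematic shift seen when
alchemical calculations are initialised from the wrong conformer.
The `gaussian_cft_sample()` generator produces work pairs satisfying
the Crooks theorem *exactly* at a known $\Delta G$
($W_F \sim N(\Delta G + \sigma^2/2, \sigma^2)$,
$W_R \sim N(-\Delta G + \sigma^2/2, \sigma^2)$).

What the toys do **not** emulate: many-particle systems, soft-core
potentials, inertia, force-field error, or the paper-scale MD
timescales. A green toy test therefore establishes the correctness of
the estimators and diagnostics on data obeying the assumed
fluctuation theorems — not the convergence of any particular
molecular system.

Default toy parameters state the emulated world once: 100 snapshots
per direction (the protocol's per-repeat transition count is of this
order), switch lengths spanning 20–2000 steps (the analogue of the
0.1–20 ns transition-time scan), friction and $dt$ chosen inside the
stability bound with relaxation times of order unity.

## Numerical choices

* $k_B = 0.0083144621$ kJ/mol/K exactly; kcal conversions divide by
  4.184 at the reporting layer only.
* Exponential averages use log-sum-exp shifts; Fermi functions use
  `plogis` for tail stability; underflow of every overlap term
  returns measure 1 by definition.
* BAR root tolerance $10^{-8}$ kT; quadrature oracles integrate to
  relative tolerance $10^{-10}$.
* Duplicate XVG timestamps keep the last occurrence (restarted
  trajectories append corrected frames).
* Truncation uses a non-strict threshold (`origin <= fraction * max`),
  making `fraction = 1` the identity and truncation monotone.
* All stochastic entry points take one integer seed and derive
  replicate streams by `seed + index`; global RNG state is preserved.

## Known limitations

* MBAR, WHAM, Crooks-Gaussian intersection and cumulant estimators
  beyond the Gaussian-limit identity are out of scope; stratified
  results are chained pairwise.
* The restraint correction covers the 1-distance/2-angle/3-dihedral
  scheme only, in the stiff-spring closed form discussed above.
* The XVG reader handles the two-column (plus optional extra
  $\lambda$-component columns) dH/dλ dialect, not full energy files or
  expanded-ensemble output.
* The convergence measure's sign semantics (which tail is missing)
  are not hardened; only magnitudes are interpreted.
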