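---
title: "Stationary stochastic activity in low-rank linear recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary stochastic activity in low-rank linear recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowrankOU)
```

## The model and its assumptions

`lowrankOU` works with the linear stochastic rate model

$$\frac{dx}{dt} = -x + Wx + U\chi(t),$$

where the leak timescale is the unit of time, $\chi$ is a Gaussian white
process with unit spectral density, uncorrelated across channels, and the
connectivity is low rank, $W = k\sum_{r=1}^R m^r n^{r\top}$ with unit-norm
connectivity vectors. The assumptions that buy the closed forms are:

* **linearity** — the model is a multivariate Ornstein–Uhlenbeck process,
  so the stationary law is Gaussian and fully described by its covariance;
* **stability** — all connectivity eigenvalues $\lambda^r = k\,
  \rho_{m^r n^r}$ below one (covariance functions refuse unstable specs;
  the simulator only warns, so divergence can be demonstrated);
* **commuting rank-one components** — for $R > 1$ we require
  $n^{r\top} m^{r'} = 0$ for $r \neq r'$. This is the subclass for which
  the components commute, the nonzero eigenvalues are real and equal
  $\lambda^r$ with eigenvectors $m^r$, and the propagator and covariance
  take closed forms. Low-rank matrices with complex eigenvalues are out of
  scope by construction.

Activity decomposes as $x = x^{loc} + \sum_r x^{rec,r}$: a local
component (leak-filtered noise, potentially high-dimensional) and one
recurrent component per rank-one term, each confined to its $m^r$
direction. The stationary covariance
$$\Sigma = \tfrac12\Big\{\bar\Sigma_{inp}
  + \sum_r \tfrac{k}{2-\lambda^r}\big[d^r m^{r\top} + m^r d^{r\top}\big]
  + \sum_{r,r'} \sigma_{rr'}\beta_{rr'}\, m^r m^{r'\top}\Big\}$$
(with $d^r = \bar\Sigma_{inp} n^r$, $\sigma_{rr'} = n^{r\top}
\bar\Sigma_{inp} n^{r'}$, and $\beta_{rr'}$ a rational function of the
$\lambda$'s) is kept with its three mechanistic terms separated, so
variance can be attributed to local filtering, local–recurrent
interference, and recurrence.

The central scientific point the package operationalizes is that the
*input dimensionality* $C$ (the rank of $\bar\Sigma_{inp} = UU^\top$)
switches the regime:

* $C = 1$: the covariance is rank $R + 1$; recurrence only engages through
  the overlaps $\rho_{n^r u}$, and the connectivity enters through the
  $m$-vectors alone. Dimensionality is bounded by $R + 1$ (by 2 for rank
  one).
* $C = N$: the covariance is an additive low-rank perturbation of
  $\tfrac12 I$; $N - 2R$ eigenvalues sit at the reference value
  $\mu_{ref} = \tfrac12$ and up to $2R$ are perturbed, half above
  (amplified) and half below (suppressed), with principal components in
  the span of *both* vector sets $\{m^r\}$ and $\{n^r\}$.
* intermediate $C$: no closed spectral form is attempted
  (`stationary_covariance()` still applies; spectra come from a dense
  eigensolve) — simulations suggest $C+1$ non-vanishing eigenvalues of
  which roughly $C-2$ stay near the reference value, but the package
  deliberately reports this regime numerically only.

## Parameters that matter

| parameter | meaning | default / constraint |
|---|---|---|
| `N` | network size | any; vector entries scale as $1/\sqrt N$ through normalization |
| `k` | coupling scale, order 1 in `N` | `> 0`; never rescaled by the constructors |
| `rho_mn` (per component) | connectivity symmetry; sets $\lambda^r = k\rho$ | stable range $(-1, 1/k)$ |
| `C` | input dimensionality | `1..N` |
| `tau` | Euler–Maruyama step (leak timescales) | 0.01 |
| `t_total`, `burn_in` | simulated / discarded duration | 2000, 20 (the leak transient decays as $e^{-t}$, so 20 timescales are negligible) |
| stability margin | specs flagged stable iff $\max_r \lambda^r < 1 - \text{margin}$ | $10^{-6}$ |

## Construction of vector geometries

All constructors draw a seeded orthonormal scaffold $\{z_i\}$ (QR of a
standard-normal matrix, columns sign-fixed so results are reproducible
across LAPACK builds) and place the connectivity vectors in it:

* rank one: $m = z_1$, $n = \rho_{mn} z_1 + \sqrt{1-\rho_{mn}^2}\, z_2$;
* rank R, *orthogonal subspaces*: $m^r = z_r$, $n^r = \rho_r z_r +
  \sqrt{1-\rho_r^2}\, z_{R+r}$ — internal overlaps free, everything else
  orthogonal;
* rank two, *cross-overlap*: $m$-span built from $(z_1, z_2)$ with overlap
  $\rho_{m^1m^2}$, $n$-span from $(z_3, z_4)$ with overlap
  $\rho_{n^1n^2}$. All four $\rho_{m^r n^s}$ vanish. The second
  parametrization leaves open whether the mixed overlaps
  $\rho_{m^1n^2}, \rho_{m^2n^1}$ vanish; we set them to zero — the
  minimal choice consistent with the cross-orthogonality constraint that
  the closed forms require, recorded here as an explicit modelling
  assumption.

Requested overlaps are reproduced to $10^{-12}$ and round-trip through
the JSON serializers exactly.

## Numerical choices

* **$\lambda \to 0$ branches.** $(e^{\lambda t}-1)/\lambda$ in the
  propagator switches to the series $t + \lambda t^2/2$ below
  $|\lambda| < 10^{-8}$; the lagged-covariance coefficients $c_2, c_3,
  c_4$ switch to their analytic $\lambda\to 0$ limits at the same
  threshold. Continuity across the switch is tested.
* **Lagged cross coefficient for $R > 1$.** The $t > s$ branch of the
  cross coefficient $c_4^{rr'}$ was re-derived from the stationary
  integral; the implementation uses the form that satisfies both the
  equal-time limit ($\Sigma(t,t)$ equals the stationary covariance
  exactly) and the transpose symmetry $\Sigma(t,s) = \Sigma(s,t)^\top$,
  which the test suite checks against direct numerical quadrature.
* **Degenerate eigenvector ansatz.** For one-dimensional input with
  $\rho_{mu} + \alpha\rho_{nu} = 0$ the standard expression for
  $\gamma_\pm$ is ill-defined; the implementation falls back on the other
  eigen-system equation, and to $\gamma = 0$ when both degenerate
  ($\rho_{nu}=\rho_{mu}=0$). At $\rho_{mn} = \pm 1$ the $m$–$n$ plane
  collapses to a line: the eigenvector whose eigenvalue merges with the
  reference value has no preferred direction and is reported as `NA`.
* **PSD tolerance.** Covariance eigenvalues down to
  $-10^{-10}\,\mathrm{tr}\,\Sigma$ are treated as numerical zeros.
* **Sort and sign conventions.** Eigenvalues descend, ties broken by
  original index; principal components are oriented to have non-negative
  overlap with $m$ (high-dimensional input) or $u$ (one-dimensional), and
  comparisons with estimated PCs always use absolute overlaps, since the
  sign of a principal component is arbitrary.
* **Stability boundary.** Specs may be *built* arbitrarily close to (or
  beyond) $\lambda = 1$; only covariance-level operations refuse them.
  The margin $10^{-6}$ can be lowered explicitly when probing the
  line-attractor limit.

## The simulator and what passing tests show

`simulate_network()` integrates the Euler–Maruyama update
$x(t+\tau) = (1-\tau)x + \tau Wx + \sqrt\tau\, U\chi$ from $x(0)=0$, with
per-step i.i.d. standard-normal $\chi$ — the discrete counterpart of
unit-spectral-density white noise. With component tracking on, the local
and recurrent parts are integrated with the *same* noise draws via
$x^{loc} \mapsto (1-\tau)x^{loc} + \sqrt\tau\,\xi$ and
$x^{rec} \mapsto (1-\tau)x^{rec} + \tau W x$, so $x = x^{loc} + x^{rec}$
holds exactly at every step. `discrete_map_simulate()` implements the
$\tau = 1$ map $x(t+1) = Wx(t) + \xi$, whose local part is memoryless and
exactly uncorrelated with the recurrent part.

The synthetic trajectories emulate a stationary, Gaussian, white-driven
linear circuit — exactly the regime the theory covers. They do *not*
emulate features of real recordings (nonlinearity, nonstationarity,
temporally correlated or shared-latent noise, subsampling, measurement
noise), so agreement between simulation and closed forms validates the
implementation of this model class, not the model's adequacy for any
particular dataset.

**Monte-Carlo budget.** The sample covariance of an OU process has entry
variance $\approx (\Sigma_{ii}\Sigma_{jj} + \Sigma_{ij}^2)/T_{\!e\!f\!f}$,
giving a relative Frobenius floor of roughly $\sqrt{N/T}$: about 16 % for
one realization of 2000 time units at $N = 50$. Consistency checks at the
5 % level therefore average 12 realizations (floor $\approx 4.6\,\%$);
qualitative checks (PC alignment, stationarity of halves) use shorter
runs with tolerances set from the same formula. Trajectory recording may
be thinned (`record_every`) without bias, since every retained sample is
stationary. Problem sizes used by the test suite ($N \le 60$,
simulations up to $2.4\times10^6$ unit-steps in total) keep the full run
near a minute on one core.

## Design choices where the design was open

* **"Variance explained"** in the E-I maps is $\mu_i/\sum_j\mu_j$, the
  standard fraction-of-total-variance reading; the maps additionally
  report the raw PC variances $\mu_i$, because for inputs aligned with
  $m$ the fraction saturates at 1 (activity collapses onto one line)
  while the amplification amplitude $\mu_+$ is what distinguishes input
  directions at fixed connectivity — the non-normal signature.
* **Monotonicity of the suppressed eigenvalue.** $\mu_+$ grows with $k$
  everywhere; $\mu_-$ decreases with $k$ only for $\rho_{mn} \le 0$ — for
  positive overlap it turns back towards $\tfrac12$ as $\lambda \to 1$,
  consistent with the line-attractor limit $\mu_- \to \tfrac12$. The
  property tests assert exactly this.
* **Rank-R spectra** are computed from the analytic $2R \times 2R$
  reduced matrix built from overlap tables alone; the corresponding
  principal components are extracted from the (exactly low-rank)
  covariance perturbation, which is cheaper and better conditioned than
  eigendecomposing the full $N \times N$ covariance and is verified
  against it.
* **Simulator convergence in $\tau$** is established in two exact steps:
  the empirical covariance is checked against the *exact* stationary law
  of the discrete map at the simulated $\tau$ (a discrete Lyapunov
  solve), and that law is shown to converge to the continuous-time
  covariance as $\tau$ decreases — separating Monte-Carlo error from
  discretization bias.
* **Export formats** are plain text: CSV for matrices/tables with JSON
  sidecars for metadata, JSON for specs and spectra.

## Known limitations

* Only connectivity with real eigenvalues and mutually orthogonal
  rank-one components is supported; generic low-rank matrices (complex
  spectra, non-commuting components) have no closed-form propagator here.
* Intermediate input dimensionality has no analytic spectrum; it is
  served numerically.
* Noise is white and Gaussian by construction; colored or non-Gaussian
  inputs, and deterministic time-varying drives, are out of scope.
* The Euler–Maruyama scheme is first order; for strongly amplified modes
  ($\lambda$ near 1) the discretization bias scales like
  $\tau/(1-\lambda)$ and small steps are needed.
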