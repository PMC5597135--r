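---
title: "Carrier transport in nanostructures: the model behind nanodrude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier transport in nanostructures: the model behind nanodrude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodrude)
```

## The model

`nanodrude` evaluates a generalized Drude–Lorentz description of a carrier
moving in a nanostructure. The carrier has effective mass $m^*$ (a multiple
of the electron mass $m_e$), scatters with relaxation time $\tau$, and feels
a harmonic restoring force of center frequency $\omega_0$; the bath
temperature is $T$. The three linked observables are the velocity
autocorrelation function (ACF) $\langle \vec v(t)\cdot\vec v(0)\rangle$, the
time-dependent diffusion coefficient

$$D(t) = \int_0^t \langle \vec v(t')\cdot\vec v(0)\rangle\, dt',$$

and the mean-squared displacement

$$R^2(t) = 2\int_0^t (t - t')\,\langle \vec v(t')\cdot\vec v(0)\rangle\, dt'
         = 2\int_0^t D(t')\,dt',$$

equivalently $D = \tfrac12\, dR^2/dt$. The dimensionless discriminant
$4\tau^2\omega_0^2$ selects the analytic branch, parameterized by
$\alpha_I = \sqrt{1 - 4\tau^2\omega_0^2}$ (overdamped) or
$\alpha_R = \sqrt{4\tau^2\omega_0^2 - 1}$ (underdamped). Writing
$A = k_B T/m^*$ for the thermal velocity scale, the closed forms are

| branch        | condition                 | $D(t)$ |
|---------------|---------------------------|--------|
| overdamped    | $4\tau^2\omega_0^2 < 1$   | $A\,(\tau/\alpha_I)\left[e^{-(1-\alpha_I)t/2\tau} - e^{-(1+\alpha_I)t/2\tau}\right]$ |
| underdamped   | $4\tau^2\omega_0^2 > 1$   | $2A\,(\tau/\alpha_R)\,\sin(\alpha_R t/2\tau)\,e^{-t/2\tau}$ |
| critical      | $4\tau^2\omega_0^2 = 1$   | $A\,t\,e^{-t/2\tau}$ |
| drude         | $\omega_0 = 0$            | $A\,\tau\,(1 - e^{-t/\tau})$ |

The ACF and $R^2(t)$ are their exact derivative and antiderivative. Three
identities pin the forms down and are enforced by the test suite:
equipartition $\langle v^2\rangle = k_BT/m^*$ (one translational degree of
freedom — the model's convention, which also matches the magnitude of the
published peak values; no factor-3 variant is offered), pointwise continuity
of all branches across the critical boundary as $\alpha \to 0$, and the
confined-carrier plateau $R^2(\infty) = 2k_BT/(m^*\omega_0^2)$, twice the
harmonic-oscillator equipartition variance, whenever $\omega_0 > 0$. On the
underdamped branch $D(t)$ swings negative between lobes, so $R^2(t)$
overshoots its plateau and rings down rather than growing monotonically;
only the non-oscillatory branches have monotone $R^2$.

The model is deterministic throughout: no random number generation enters
any computation.

### Parameters and defaults

* `m_eff_ratio` — effective mass in units of $m_e$; the shipped presets are
  the tabulated values for semiconducting carbon nanotubes of chirality
  (3,1) (`0.507`) and (7,3) (`0.116`).
* `tau` — relaxation time in seconds. Preset default `1e-13` s, the middle
  of the $10^{-12}$–$10^{-14}$ s range typical of soft condensed matter.
* `temperature` — kelvin; preset default `310` K (body temperature, the
  nanomedicine context the presets target).
* `omega0` or (`alpha`, `regime`) — exactly one of the two
  parameterizations; the other is derived at construction and both are
  stored. Only the principal non-negative root of $\alpha$ is used.
* Constants: $k_B = 1.380649\times10^{-23}$ J/K (exact SI);
  $m_e = 9.109\times10^{-31}$ kg by default, overridable through
  `transport_constants()`.
* Units are SI internally; $D$ is additionally reported in cm²/s (exact
  factor $10^4$), the unit of the published peak table.

### Peaks

`peak_diffusion()` returns the closed-form stationary point: overdamped
$t^* = (\tau/\alpha_I)\ln\frac{1+\alpha_I}{1-\alpha_I}$, underdamped
$t^* = (2\tau/\alpha_R)\arctan\alpha_R$ (the first, global maximum — later
oscillation extrema are visible in `make_curve()` output), critical
$t^* = 2\tau$. The drude branch has no interior maximum; the long-time
Drude–Einstein asymptote $k_BT\tau/m^*$ is reported with `t_star = Inf`.
At every interior maximum the ACF is exactly zero — the peak/zero duality
the tests exercise.

```{r peaks}
p <- params_from_preset("cnt_3_1", alpha = 0.1, regime = "overdamped")
peak_diffusion(p)
```

## Numerical choices

* **Critical band.** $|4\tau^2\omega_0^2 - 1| \le$ `tol` (default `1e-6`)
  routes evaluation to the critical closed form, avoiding the $0/0$
  cancellation of the overdamped expression as $\alpha_I \to 0$. Tests that
  deliberately probe small-$\alpha$ convergence narrow the band via the
  constructor's `tol` argument.
* **Overdamped MSD** uses `expm1` so the $\alpha \to 0$ and small-$t$
  regimes do not lose precision to cancellation.
* **Oracle quadrature.** The `*_quad` functions transcribe the defining
  integrals literally — `msd_quad` keeps the $(t - t')$ weight rather than
  integrating $D$, so it independently checks the exchange-of-order
  identity — using base R's adaptive Gauss–Kronrod integrator at
  `rel.tol = 1e-12`. Strongly oscillatory underdamped integrands
  ($\alpha_R > 10$) are split at the sine zeros so each panel is smooth.
* **Oracle error floor.** `oracle_report()` divides by
  $\max(|\text{quadrature}|, A\tau \times 10^{-5})$. The floor guards the
  $D(0)=0$ point, and its magnitude is set by double-precision arithmetic:
  the quadrature's absolute error cannot fall below roughly
  $\epsilon \int |\mathrm{ACF}|$, which reaches
  $\sim 10^{-13} A\tau$ for small $\alpha_R$ (the integrand has mass
  $\sim 2A\tau/\alpha_R$ that cancels to $e^{-t/2\tau}$, e.g. $10^{-11}$ of
  itself at $t = 50\tau$). A floor of $A\tau\times10^{-5}$ keeps the
  $10^{-8}$ relative-agreement requirement meaningfully above that rounding
  floor with a safety margin; a much smaller floor would report pure
  rounding noise as model error at exponentially suppressed tail values.
* **Finite differences.** `d_from_msd` is the centered second-order
  stencil; its error quarters when the step halves, which the tests verify
  down to the rounding floor. The membrane module's flux and Fisher
  utilities use the same stencil with steps `1e-6`/`1e-5` on probability
  coordinates, and refuse parameters within one step of the 0/1 boundary.

## The worked carbon-nanotube example

With the shipped presets, $T = 310$ K, $\tau = 10^{-13}$ s and
$\alpha_I \in \{0.1, 0.5, 0.9\}$ on the overdamped branch, the peak
diffusion values in cm²/s are:

```{r cnt}
sapply(c(cnt_3_1 = "cnt_3_1", cnt_7_3 = "cnt_7_3"), function(ps)
  sapply(c(0.1, 0.5, 0.9), function(a)
    peak_diffusion(params_from_preset(ps, alpha = a,
                                      regime = "overdamped"))$D_max_cm2_s))
```

The published table these reproduce reads 6.74, 7.05, 8.15 for the (3,1)
tube and 28.89, 30.29, 35.15 for (7,3). Agreement is 1.2–3.3%, consistent
with values read off printed figures rather than computed: the two
published rows differ by a factor 4.286 where the exact mass-ratio scaling
$0.507/0.116 = 4.371$ must hold (mass enters only through the $k_BT/m^*$
prefactor, an invariant the tests assert exactly). One value — the (7,3)
tube at $\alpha_I = 0.1$ — therefore sits at 3.3%, just outside a 3%
band, and no faithful implementation can bring both rows inside it
simultaneously. The package reports its computed values unadjusted.

## The toy membrane

A deliberately minimal patch of excitable membrane: `n_channels` potassium
channels with `gates_per_channel` independent gates each, of which exactly
`n_open_gates` are open; in the Hodgkin–Huxley $n^4$ spirit a channel
conducts only when all four of its gates are open. For 3 channels × 4
gates with 9 open gates, exhaustive enumeration gives
$\binom{12}{9} = 220$ configurations splitting 64/144/12 by 0/1/2 open
channels — two channels at most can be open, never all three.

Two probability measures appear, the only canonical choices for a model
this schematic: the *uniform* measure over the constrained ensemble (used
for the enumeration distribution above) and the *independent Bernoulli*
measure with per-gate open probability `p_gate` (used for
`config_probability()` and as the parametrized family behind the
information-geometry utilities). Enumeration is capped at 24 gates
($\sim 2.7$M configurations at worst); beyond that the exact pmf would need
a combinatorial rather than enumerative route, which this toy scope does
not attempt.

The flux invariant $\Phi_j + \lambda\, \partial P/\partial q_j = 0$ is
implemented over a continuous relaxation of the state (per-gate
probabilities), since differentiation with respect to a binary gate state
is ill-defined; $\lambda$ carries no prescribed value or units and is a
user parameter. The invariant holds identically by construction — the
contract is that `probability_flux()` returns exactly
$-\lambda\,\partial P/\partial q_j$ (centered difference), hence zero flux
for constant $P$. `kl_divergence()` and `fisher_information()` supply the
associated information geometry; the quadratic-form link
$\mathrm{KL}(P(q)\,\|\,P(q+\delta)) \approx \tfrac12\delta^\top G(q)\delta$
is verified for small $\delta$. The "ionic/noise powers" sometimes named
alongside this construction ($W_1$, $W_{1,2}$, $W_2$) have no defining
equations to implement and are deliberately absent.

```{r membrane}
open_channel_distribution(membrane_spec(3, 4, 9))
```

## Problem sizes used in validation

The test suite compares every closed form against the quadrature oracle on
100 random parameter draws ($\tau$ log-uniform in $[10^{-14}, 10^{-12}]$ s,
$\alpha$ in $[0.05, 0.95]$ on both branches, with some underdamped draws
stretched to $\alpha_R \approx 1.9$) at four times spanning $[0, 50\tau]$,
plus property checks on smaller draws; the whole suite runs in a few
seconds. Sampled curves use 500–2000 grid points, enough to locate peaks to
$10^{-4}$ relative against the closed forms.

## What the package does not model

Quantum and relativistic corrections to the transport model, fitting to
experimental transient-conductivity data, frequency-domain conductivity
$\sigma(\omega)$, Langevin trajectory simulation of the underlying process,
and — on the membrane side — geodesics on the Fisher manifold, percolation
thresholds and memristive circuit dynamics. The toy membrane is a
combinatorial cartoon: gates are independent and voltage-free, so passing
its tests says nothing about real channel kinetics beyond the counting
structure.
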