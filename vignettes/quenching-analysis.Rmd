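---
title: "Stern-Volmer quenching analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stern-Volmer quenching analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svquench)
```

## The problem

A fluorophore's emission is reduced ("quenched") by a quencher through two
distinct mechanisms. *Dynamic* (collisional) quenching deactivates the
excited state during a diffusive encounter, shortening the lifetime in
proportion to the intensity loss. *Static* quenching removes fluorophores
from the emitting population instantaneously — either through a
non-emissive ground-state complex or because a quencher already sits
inside a "sphere of action" around the fluorophore at the moment of
excitation — and leaves the lifetime untouched. An intensity-vs-quencher
titration, optionally complemented by lifetime measurements, is the
standard experiment for telling the mechanisms apart and extracting rate
and distance parameters. `svquench` implements that analysis chain for
titration tables such as the bundled study of a coumarin probe quenched by
aniline in six acetonitrile (ACN) / 1,4-dioxane (DXN) mixtures.

## Models and estimators

**Linear Stern-Volmer.** Pure dynamic quenching gives
$I_0/I = 1 + K_{SV}[Q]$ with $K_{SV} = k_q \tau_0$. `linear_sv_fit()`
estimates the slope by ordinary least squares (OLS). An upward-curving
plot signals an additional static component; `curvature_diagnostic()`
fits a free-intercept quadratic and calls the curvature positive when the
quadratic coefficient exceeds twice its standard error. With the 5-6
points of a typical titration this 2-sigma rule is a pragmatic screen;
we chose it over a formal F-test because the residual degrees of freedom
(2-3) make p-values uninformative anyway.

**Modified Stern-Volmer (quenched fraction).** `modified_sv_fit()`
assumes the ratio model
$$\frac{I_0}{I} = \frac{1 + K_{SV}[Q]}{1 - b[Q]}, \qquad W = 1 - b[Q],$$
where $W$ is the fraction of fluorophores not statically quenched and the
intercept $b = (1-W)/[Q]$ is treated as constant over the titration.
Rearranged, $(1 - I/I_0)/[Q] = b + K_{SV}\,(I/I_0)$: an OLS regression of
$y = (1 - I/I_0)/[Q]$ on $x = I/I_0$ returns $K_{SV}$ as slope and $b$ as
intercept. On data generated by this model the estimator is exact (the
test suite asserts recovery to $10^{-9}$ relative); on sphere-of-action
data it overestimates $K_{SV}$, a model-mismatch bias the recovery
harness documents (fitting the DXN-like truth $K_{SV} = 2.545$,
$V = 8.472$ gives a fitted slope near 7).

**Sphere of action.** Under the active-sphere picture
$W = e^{-V[Q]}$, so `static_volume_fit()` regresses $\ln(1/W)$ on $[Q]$;
the slope is the static quenching constant $V$ (M$^{-1}$), and
`kinetic_radius()` inverts $V = \tfrac{4}{3}\pi r^3 N_A \times 10^{-3}$
to the kinetic distance $r$ in Angstrom. The regression keeps a free
intercept: forcing it through the origin changes $V$ by ~10% (e.g. ~5.5
instead of 6.12 M$^{-1}$ for the 100% ACN series) and no longer matches
the published parameter set the package reproduces, so the free-intercept
form is the contract. $W$ is taken from the fitted $b$ (i.e.
$W = 1 - b[Q]$), not from $e^{-V[Q]}$, keeping the two-step linearised
procedure self-consistent.

**Ground-state complex test.** If static quenching came from a 1:1
ground-state complex with association constant $k_g$,
$I_0/I = (1 + K_{SV}[Q])(1 + k_g[Q]) = 1 + S[Q] + P[Q]^2$ with
$S = K_{SV} + k_g$, $P = K_{SV} k_g$. `ground_state_complex_fit()`
estimates $(S, P)$ with the intercept pinned at 1 (the model's exact
value at $[Q] = 0$) and recovers the pair as roots of
$z^2 - Sz + P = 0$. Complex roots ("imaginary $k_g$") reject the model.
The discriminant test is strict — no tolerance band — except that
$|S^2 - 4P| \le 10^{-12}$ is reported as a degenerate repeated root
rather than imaginary. On all six bundled mixtures the roots are
complex, rejecting the ground-state-complex mechanism in favour of the
sphere of action.

**Finite-sink approximation.** For diffusion-limited quenching the
apparent constant $K_{SV}([Q]) = (I_0/I - 1)/[Q]$ grows with
concentration; $1/K_{SV}([Q])$ is linear in $[Q]^{1/3}$.
`finite_sink_fit()` extrapolates that line to $[Q] = 0$: the reciprocal
intercept is $K_{SV}^0$, and the distance parameter and encounter rate
follow as
$$R' = \frac{K_{SV}^0}{4\pi N' D \tau_0}, \qquad
  k_d = 4\pi N' R' D = \frac{K_{SV}^0}{\tau_0},$$
with $N' = N_A \times 10^{-3}$ (molecules cm$^{-3}$ per mol L$^{-1}$) so
the rates carry M$^{-1}$s$^{-1}$ units. The identity
$k_d \equiv K_{SV}^0/\tau_0$ holds by construction and is asserted to
$10^{-9}$ relative. The slope-to-diffusion conversion uses
$D = c/(4\pi N' \tau_0 |\mathrm{slope}|)$ with the default coefficient
$c = (4\pi N'/3)^{1/3}$ from the standard linearisation; in our hands
this recovers published finite-sink diffusion coefficients only to
10-15%, so `D_fs` carries a method tag, the coefficient is an argument,
and downstream conclusions rest on the better-pinned $K_{SV}^0$, $R'$
and $k_d$.

One property worth stating because it is counterintuitive: on
quenched-fraction data the apparent constant is
$(K_{SV}+b)/(1-b[Q])$, decreasing towards $K_{SV}+b$ as $[Q] \to 0$,
yet the *linear-in-$[Q]^{1/3}$* extrapolation lands **below** the
smallest observed apparent constant (the reciprocal curve is convex in
$[Q]^{1/3}$). The property tests therefore assert
$0 < K_{SV}^0 < \min K_{SV}([Q])$, which is what the algebra supports,
rather than any bracketing between $\min K_{SV}([Q])$ and $K_{SV}+b$.

**Stokes-Einstein.** `stokes_einstein_diffusion()` computes per-species
$D_i = k_B T/(a \pi \eta R_i)$ and their sum as the mutual coefficient.
The slip/stick parameter $a$ defaults to 6 (stick) and is restricted to
$[4, 6]$; viscosities are stored as reciprocals in P$^{-1}$, the form
tabulated in solvent-mixture studies. Published tables that report
Stokes-Einstein coefficients for this system are not reproduced exactly
because the $a$ used there is not stated; the function exists for trend
analysis, not table reproduction, and the tests pin it to the hand-
evaluated formula instead.

**Mechanism classification.** `classify_quenching()` combines the
pieces: upward curvature plus a positive $V$ establish a static
component alongside the dynamic one; $r$ is compared with the encounter
distance $R = R_S + R_Q$ (for the bundled system $R = 6.52$ Å and $r$
comes out roughly $2R$); and the diffusion-limited verdict follows the
$R'$-vs-$R$ dichotomy — for $R' > R$ the reaction is diffusion-limited
when the quenching rate exceeds $k_d = 4\pi N' R' D$, for $R' < R$ when
the (usually unknown) activation rate $k_a$ exceeds $k_d$, reported
"indeterminate" if $k_a$ is absent.

The rate compared against $k_d$ deserves a note. The purely dynamic
$k_q = K_{SV}/\tau_0$ understates the total quenching flux when static
processes dominate — in the bundled data it falls below $k_d$ for five
of six mixtures even though every diagnostic points at transport
control. The classification therefore uses the *total* initial rate
$k_{q,\mathrm{tot}} = (K_{SV} + b)/\tau_0$, the $[Q] \to 0$ derivative
of $I_0/I$ under the quenched-fraction model, which counts both static
and dynamic channels. Both rates are reported in the classification
record so the choice is auditable.

## Lifetime analysis

`fit_multiexponential()` fits
$\mathrm{counts}(t) = \mathrm{bg} + \sum_i A_i e^{-(t - t_{peak})/\tau_i}$
to the bins after the histogram maximum (tail fitting — no
instrument-response deconvolution, which matches how single-point
lifetimes are usually quoted for ns-scale probes), by Levenberg-Marquardt
least squares with Poisson weights $1/\max(c_j, 1)$ and positivity
enforced on the log scale. Initialisation is deterministic exponential
peeling (log-linear fits on time segments, slowest component first) plus
a fixed ladder of lifetime rescalings; identical inputs give identical
fits. Both the amplitude-weighted mean $\sum \alpha_i \tau_i$ and the
intensity-weighted mean $\sum \alpha_i \tau_i^2 / \sum \alpha_i \tau_i$
are reported, because published single-number lifetimes from
biexponential fits rarely state the averaging rule; the pipeline default
is the amplitude-weighted mean. `transient_sv_fit()` regresses
$\tau_0/\tau$ on $[Q]$ to isolate the dynamic constant, and
`quenching_divergence()` flags static dominance when the steady-state
slope exceeds the transient one by more than a factor of 2.

## Synthetic data: what it emulates, what it does not

`simulate_quench_table()` draws titrations from the three ratio models
(`pure_dynamic`, `linear_w`, `sphere_of_action`) with multiplicative
Gaussian intensity noise (CV-parameterised — appropriate for
steady-state detectors at the $10^3$-count intensity scale), and
`simulate_decay()` builds photon histograms from the exact
multiexponential bin integrals realised as Poisson draws. Defaults
mirror the bundled study: the concentration grid 0.02-0.10 M in
0.02 M steps, intensities of a few thousand counts, lifetimes around
1.1 ns. All generators are seeded and bit-reproducible.

The generators deliberately omit features of real data: inner-filter
attenuation at high quencher absorbance, wavelength-dependent detector
response, instrument response convolution in decays, and any
solvent-dependent spectral shift. Passing recovery tests therefore
demonstrates estimator correctness under the stated models, not
robustness to those instrumental effects.

Problem sizes in the shipped tests were chosen to characterise the
estimators adequately at interactive run times: 500 replicates for the
Monte-Carlo recovery of $(K_{SV}, b)$ at 1% noise, 200 for the
grid-densification RMSE comparison, 20 seeded replicates for the
biexponential mean-lifetime stability check, and $10^5$ total counts
(a routine TCSPC acquisition) for single-decay recovery.

## Numerical choices and degenerate inputs

* All regressions are unweighted OLS with free intercepts (except the
  ground-state-complex quadratic, whose unit intercept is part of the
  model); standard errors are computed in closed form.
* $W$ values within $10^{-9}$ above 1 are clamped to 1 (round-off at
  $b \approx 0$); genuinely out-of-range $W$ is an error, as is an
  intercept with $b \cdot \max[Q] \ge 1$.
* A flat apparent-constant series (pure-dynamic limit) has zero
  finite-sink slope; $D$ is then reported `NA` and $k_d$ falls back to
  $K_{SV}^0/\tau_0$.
* Titrations must carry a $[Q] = 0$ reference row; intensity
  *enhancement* (ratios below 1) loads with a warning, is flagged by
  `intensity_ratios()`, and stops the fitting chain with a "no net
  quenching" error that `quench_analysis()` isolates per solvent.
* Spectral peaks are refined parabolically through the three bracketing
  points; peaks on the grid edge return the edge with a warning.
* `peak_wavelength`, `kinetic_radius` and the rate identities are exact
  arithmetic; tolerances in the tests reflect the precision of the
  published values they are compared against (3-4 significant figures,
  with ratios truncated rather than rounded to 3 decimals).

## Known limitations

* The modified Stern-Volmer estimator is exact only under the linear-$W$
  model; no simultaneous nonlinear fit of $(K_{SV}, V)$ to the
  sphere-of-action equation is offered (the linearised two-step chain is
  the established procedure this package reproduces; a nonlinear
  fit exists only as a test oracle).
* Finite-sink `D_fs` depends on a linearisation coefficient that cannot
  be pinned more tightly than ~15% against published tables; treat it as
  order-of-magnitude.
* No inner-filter correction is applied; intensities are taken as given.
* The activation-rate branch of the diffusion-limited test is
  implemented but reports "indeterminate" unless $k_a$ is supplied.

## A worked run

```{r example}
tabs <- example_titrations()
fit <- quench_fit(tabs[["0% ACN + 100% DXN"]])
fit
coef(fit)
report <- quench_analysis(tabs)
report
```
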