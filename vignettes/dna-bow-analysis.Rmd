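---
title: "Analyzing DNA hybridization kinetics under weak tension with bowkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing DNA hybridization kinetics under weak tension with bowkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowkit)
```

## The system and the measurement

A *DNA bow* is a construct in which a double-stranded DNA arc (74-252 bp)
is closed by a short single-stranded "bowstring" (15 nt). The bending
rigidity of the arc keeps the bowstring under a constant weak tension,
roughly 2-6 pN depending on arc length. A fluorescently labeled
oligonucleotide probe (8-9 nt) binds and unbinds the central 9 nt of the
bowstring, and the binding state is read out by single-molecule FRET:
high acceptor fraction means bound, low means unbound. From the dwell
times in the two FRET states one obtains the hybridization rate
$k_{on} = 1/([c]\,\bar\tau_{off})$ and the dehybridization rate
$k_{off} = 1/\bar\tau_{on}$ at each tension.

bowkit implements the full analysis chain for such experiments: tension
calibration from polymer mechanics, two-state kinetics from intensity
trajectories, force-dependent rate models, and umbrella-reweighted
free-energy landscapes of duplex melting. Every input class can be
generated synthetically with seeded generators, so the whole chain is
testable without external data.

## Tension calibration

The arc is modeled as a worm-like chain (WLC). The tension it exerts when
held at end-to-end distance $x_0$ follows from the distribution $p(x)$ of
the scalar end-to-end distance of the free chain,

$$ f(x_0) = -k_BT \, \partial_x \log p(x)\big|_{x_0}. $$

Two conventions matter here and are easy to get wrong:

* $p(x)$ is the distribution of the *scalar* distance, i.e. it includes
  the $4\pi x^2$ Jacobian relative to the vector density. The two differ
  by $2 k_BT/x$ in the force.
* Below the most probable extension the raw log-derivative force is
  negative (a compressive load); `entropic_force()` reports by default the
  *tension* on the bowstring (positive when the arc pushes its ends
  apart), with `convention = "signed"` exposing the raw value.

For $p(x)$ we use an interpolated closed form that is accurate from the
flexible-coil to the stiff-rod regime (the relevant regime here is stiff:
$L/P \approx 0.5$-$1.7$ for the arcs). The test suite validates it
against a discrete-WLC Monte-Carlo oracle (`gen_wlc_chains()`, $10^5$
chains of 100 segments) and against the exact analytic second moment,
which it reproduces to better than 0.5% for $L/P \le 2$. Derivatives of
tabulated densities are taken on a cubic spline of $\log p$ to avoid
noise amplification; for model-backed densities the analytic log-density
is differenced directly with step $10^{-6} L$.

The experimental route obtains the mean extension $\bar x$ and spread
$\sigma(x)$ from coarse-grained simulation of the full construct and
propagates $\sigma_f = |\partial f/\partial x|_{\bar x}\,\sigma(x)$
(`bow_force_estimate()`, which accepts external extension-sample tables
via `read_extension_samples()`). As a deterministic substitute,
`bow_self_consistent()` solves for the extension at which the arc tension
balances the bowstring tension; with the default parameters this places
the seven arc sizes between about 2 and 6 pN, decreasing monotonically
with arc length, and agrees with the simulation-derived calibration for
the smallest bow to well within the expected accuracy of the substitute
(the arc's entropic fluctuations and the finite bowstring geometry are
not modeled).

```{r bow}
arc <- wlc_model(74 * 0.34, 50)                 # 74 bp arc
string <- linear_fer_per_nt(30.7, 0.21, 15)     # unbound 15-nt bowstring
bow_self_consistent(arc, string)
```

An independent route treats the arc at the rigid base-pair level
(`rbp_chain()`, `rbp_restrained_minimize()`): each base-pair step has
ground-state roll/tilt/twist angles and harmonic stiffnesses, an
end-to-end restraint of stiffness $\kappa$ mimics the bowstring, and the
force follows from the minimizer as $f = 2\kappa(r - r_0)$. Nonzero
ground-state roll/tilt encode sequence-dependent intrinsic curvature;
parameter tables are user-supplied (`read_rbp_table()`), with a neutral
sequence-independent B-DNA default (twist 34.3 deg, rise 0.34 nm, bend
stiffnesses matching a 50 nm persistence length). The minimization is a
monotone first-order descent (preconditioned conjugate gradient with an
Armijo backtracking line search; energy tolerance $10^{-8}\,k_BT$ on two
consecutive steps) started from a conformation uniformly curved toward a
rotational register angle, with the initial bend amplitude chosen to
satisfy the restraint as closely as possible. Because different registers
can relax into different local minima, `register_scan()` repeats the
minimization over random registers and reports the force spread.

## Force-extension relations

Four FER families are provided, all evaluated through the common
`fer_extension()` interface:

* **Linear** (`linear_fer()`, `linear_fer_per_nt()`): $x = f/a + b$, or
  per nucleotide $x = n f/\kappa + n x_0$. Short oligonucleotide states
  behave linearly below ~6 pN.
* **Marko-Siggia** (`wlc_model`): the standard interpolation, inverted by
  a vectorized 100-step bisection of its cubic form (round-trip accurate
  to $10^{-8}$).
* **Finite-chain** (`short_chain_fer()`): the transverse-fluctuation mode
  sum for chains of finite contour length,
  $x/L = 1 - \tfrac12\sqrt{k_BT/(fP)} \coth(L\sqrt{f/(k_BT P)}) + k_BT/(2fL)$.
  Its low-force branch is unphysical (it assumes small transverse
  fluctuations), so crossover searches against it should bracket above
  ~0.5 pN.
* **Arbitrary functions** `f -> x`.

Defaults (overridable everywhere, `polymer_defaults()`): ssDNA 0.68 nm/nt
contour and $P = 1.04$ nm; dsDNA 0.34 nm/bp and $P = 50$ nm. With these
values the Marko-Siggia extensions of ssDNA and dsDNA cross near 4.25 pN
and the finite-chain ssDNA curve moves the crossover to about 1.8 pN --
the two benchmark forces for this assay's force window.

```{r crossover}
ss <- wlc_model(9 * 0.68, 1.04)
ds <- wlc_model(9 * 0.34, 50)
crossover_force(ss, ds)
crossover_force(short_chain_fer(ss), ds, bracket = c(0.5, 20))
```

## From intensity traces to rates

`fret_efficiency()` computes $E = I_A/(I_A+I_D)$ framewise (frames with
non-positive total intensity are flagged and carry the previous state).
`call_states()` smooths with a centered moving average and applies
hysteresis thresholding: enter the bound state above `high_thr`, leave
below `low_thr`. The window and thresholds are free analysis parameters;
`auto_thresholds()` places the band at the midpoint of the two efficiency
modes $\pm 0.1$. With well-separated states (the synthetic default is
0.2/0.8 with noise 0.1) smoothing is unnecessary and `window = 1` avoids
the ~1-frame transition delay that a 5-frame average introduces.

`dwell_times()` converts state runs into dwells. The first and last runs
are censored (their start/end is unobserved) and dropped by default, but
always recorded separately with a flag for whether their exit was
observed. `rates_from_dwells()` offers two estimators:

* `"mean_dwell"` (default): the assay's standard
  $k_{off} = 1/\bar\tau_{on}$, $k_{on} = 1/([c]\bar\tau_{off})$.
* `"censored_mle"`: observed exits divided by total time in state
  (including censored edge runs), times the sampled-chain correction
  $-\log(1-x)/x$ where $x$ is the summed per-frame transition
  probability. Use this when traces are not much longer than the slower
  dwell: conditioning on dwell completeness biases interior dwell means
  short (we measured up to -12% for windows ~8 dwell times), and frame
  discretization adds a $-(k_{on}[c]+k_{off})\,dt/2$ relative bias; the
  MLE removes both.

Both analytic ($k/\sqrt{N}$) and seeded-bootstrap SEMs are computed;
the bootstrap is reported. Dwells are pooled across all trajectories of
a condition before rates are formed (`pool_dwells()`,
`analyze_traces()`).

The recovery tests run this chain end-to-end on telegraph traces from
`gen_fret_telegraph()` over a 3x3 grid of rates (0.1, 0.5, 2 s$^{-1}$;
200 traces per cell, frame time 1/40 of the fastest rate, trace length
eight times the summed dwell scale) and require agreement within 2 SEM.

## Force-dependent rate models

The central model is

$$ k_\alpha(f) = k_\alpha(0) \exp\!\Big(\int_0^f \Delta x^\ddagger(f')\,df'/k_BT\Big), \qquad
   \frac{d\log k_\alpha}{df} = \frac{\Delta x^\ddagger(f)}{k_BT}, $$

with $\Delta x^\ddagger$ the extension of the transition state (the
nucleated duplex with one base pair formed) relative to the unbound
(binding) or bound (unbinding) state. `rate_vs_force()` evaluates the
integral by adaptive quadrature for arbitrary FERs; with linear
per-nucleotide FERs the closed forms `kon_closed_form()` /
`koff_closed_form()` apply, and the two routes agree to $10^{-8}$
relative (a central oracle of the test suite). Because the transition
state is stiff, $k_{off}(f)$ is nearly a pure Bell exponential, while
$k_{on}(f)$ is concave in $\log$ and becomes stationary where
$(1/\kappa_\ddagger - 1/\kappa_u)f = -(x_{0,\ddagger} - x_{0,u})$.

`fit_rate_model()` fits $k_{on}(f)$ and $k_{off}(f)$ jointly in log-rate
space, weighted by $1/\sigma_{\log}^2$ (multiplicative errors match the
exponential model family). For the linear-FER model the log transform
makes the six-parameter problem *linear* in
$(\log k_{on}(0), \log k_{off}(0), 1/\kappa_\ddagger, 1/\kappa_u,
x_{0,\ddagger}, x_{0,u})$, so the optimum is computed exactly by weighted
linear least squares rather than iteratively; standard errors follow by
the delta method, and compliances outside the physical bounds
$\kappa \in [1, 10^4]$ pN/nm (possible under noise, since a stiff state's
curvature signal $n f^2/(2\kappa k_BT)$ can vanish below the noise) are
clamped to the boundary with a warning. The bound state is fixed at
$0.34 n$ nm, force-independent. The Marko-Siggia variant fixes the
unbound/bound WLC parameters and fits $(P_\ddagger, L_\ddagger,
k_{on}(0), k_{off}(0))$ by multi-start Levenberg-Marquardt (10 seeded
starts by default; the surface has a near-degeneracy between stiffness
and zero-force rate). The two models' transition-state stiffnesses are
strongly rank-correlated on synthetic data where the stiffness is
identifiable.

Thermodynamics: `delta_g()` gives
$\Delta G^\circ = k_BT\log(k_{on}[c_0]/k_{off})$ with $c_0 = 1$ M
(positive = stable), and `delta_g_vs_force()` integrates
$\Delta G^\circ(f) = \Delta G^\circ(0) - \int_0^f (x_u - x_b)\,df'$,
which with WLC FERs is concave with its maximum at the extension
crossover. `nn_duplex_dg()` provides the nearest-neighbor reference
(unified DNA dimer parameters shipped as an editable CSV, evaluated at
the configured temperature), with additive corrections of ~1 $k_BT$ per
dangling-flanked duplex end and ~2 $k_BT$ for a terminal cyanine dye.

## Melting landscapes under tension

Biased samples over (extension $x$, intact base pairs $n_{bp}$) are
inverted by `umbrella_reweight()` -- counts divided by the per-stratum
weight $W(n_{bp})$, renormalized -- and turned into
$G(x, n_{bp}) = -k_BT\log p_{eq} + C$ by `build_surface()` ($C$ set so
the global minimum is zero; empty bins are `Inf` and excluded; default
$x$ bin 0.085 nm, i.e. 0.1 simulation length units, see `sim_units()`).
`min_energy_path()` traces the most probable pathway (per-column argmin,
ties toward smaller $x$) and `path_offset()` zeroes each column minimum
to expose the extension profile. `hbond_count()` calls a base pair intact
below -0.1 simulation energy units (~1 $k_BT$ at 22 C). Strata observed
with fewer than 50 samples are flagged rather than silently trusted.

The synthetic `zipper_surface()` places Gaussian extension basins on
state-appropriate FER centers with a per-pair melting cost (default
1.5 $k_BT$/bp and a 3 $k_BT$ drop from the one-pair barrier to the fully
melted state). The one-pair column is pinned to be at least as extended
as every other column -- the defining qualitative feature of the
nucleated transition state, attributed to steric repulsion between its
dangling strands. `gen_landscape_samples()` draws exact samples from the
discretized biased distribution; `weights = "flatten"` uses
inverse-marginal weights (the idealized umbrella protocol) so every
stratum including the barrier is sampled, while the plain exponential
default `exp(c * n_bp)` mirrors the simplest published weighting scheme
but can leave high-energy strata empty on this toy surface.

## Pipeline and configuration

`run_pipeline()` ties the stages together into a run directory: rates
table (synthetic or from CSV), optional trace-level analysis, model fit
(JSON + model curves), $\Delta G^\circ(f)$ table, and landscapes, with a
line-oriented ISO-timestamped provenance log. All randomness derives
from the configured seed; a stage whose resolved parameters are
unchanged (MD5 content hash) is skipped on rerun, and reruns are
byte-identical. Configuration is YAML merged over
`default_run_config()`; YAML was chosen over TOML because it is the
serialization format with first-class R support in this stack, with an
identical schema. There is no separate shell binary: the exported
functions, `run_pipeline()`, and the scripts directory are the intended
interfaces for an R-driven analysis.

## Numerical and scale choices

* $k_BT = 0.0138065 \times 295.15 \approx 4.075$ pN nm at the assay
  temperature of 22 C; all temperatures overridable.
* Root finding: bracketed Brent (`uniroot`) at tolerance $10^{-10}$;
  Marko-Siggia inversion by 100-step bisection (machine accurate).
* Quadratures: adaptive `integrate` at `rel.tol` $10^{-12}$ for rate
  laws; cumulative trapezoids on a 257-point grid inside the
  Marko-Siggia fit's objective for speed.
* Test problem sizes were chosen to keep the default suite under a few
  minutes while leaving clear statistical margins: $10^5$ Monte-Carlo
  chains for the distribution oracle, 100 seeds for fit recovery,
  200 traces per kinetic grid cell, $10^6$ draws for the umbrella
  inversion, $2\times10^5$ per landscape.

## Limitations

* The polymer models are inextensible WLC/linear; above ~10 pN (twist,
  overstretching) they do not apply, and the linear FERs are trusted only
  below ~6 pN.
* The self-consistent bow force neglects arc fluctuations and treats the
  bowstring as a one-dimensional spring; it is a calibration substitute,
  accurate here to a fraction of a pN but not a replacement for
  simulating the construct.
* The synthetic telegraph model has Gaussian efficiency noise, no
  blinking or photobleaching, and midpoint-state frames (a `blur` option
  exists); passing its recovery tests demonstrates the estimator chain,
  not robustness to real photophysics.
* The toy zipper surface is sequence-free; it reproduces the qualitative
  barrier structure, not sequence-resolved thermodynamics.
* Whether dehybridization rolls over below ~1.5 pN remains open
  experimentally; the model family permits it and nothing here asserts
  its absence.
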