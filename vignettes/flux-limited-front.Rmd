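---
title: "A flux-limited five-species model of the glioblastoma invasion front"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A flux-limited five-species model of the glioblastoma invasion front}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`gbfront` simulates the advancing edge of a glioblastoma (GB) on a
one-dimensional tissue slab $\Omega = [0, b_\Omega]$, with migration fixed
in the $+x$ direction. Five fields interact on a shared grid:

* $N(t,x)$ — tumor cell density, bounded by a carrying capacity $K_N$;
* $P(t,x)$ — matrix metalloprotease (MMP1) concentration;
* $E(t,x)$ — extracellular matrix (ECM) density;
* $A(t,x)$, $I(t,x)$ — active and inactive integrin receptors.

Two geometric objects organize all source terms. The **tumor support**
$[0, b_N]$ ends at the front edge $b_N$, detected as the rightmost
crossing of a threshold $\delta_N$ (linearly interpolated between nodes;
`tumor_support()`). The **tumor-microtube (TM) band**
$[b_N, b_N + h_p]$ is the strip of width $h_p$ ahead of the edge where
membrane protrusions reach into healthy tissue (`tm_region()`). A
nonlocal **activity functional**

$$F(N)(x) = \Big(\textstyle\int_{x-h_p}^{x+h_p} N\,dy + \epsilon\Big)^{-\alpha_F}$$

is large where little tumor mass surrounds a point, concentrating
protease production and integrin activation at the front
(`activity_functional()`).

The tumor flux combines three mechanisms (`flux_saturated()`,
`taxis_flux()`):

$$J_N = \underbrace{\frac{\nu_N N\, N_x}{\sqrt{m_N^2 + (\nu_N/v_N)^2 N_x^2}}}_{\text{flux-saturated}}
+ \underbrace{\frac{a_1 N\, P_x}{1 + P_x^2}}_{\text{chemotaxis}}
+ \underbrace{\frac{a_2 N\, A_x}{1 + A_x^2}}_{\text{haptotaxis}},
\qquad \partial_t N = -\partial_x J_N + a_3 N\big(1 - N/K_N\big).$$

The flux-saturated term behaves like a porous-medium flux
$(\nu_N/m_N)\,N N_x$ at small gradients but caps the transport speed:
$|J| \le v_N N$ always, which is what produces a sharp front that
advances at a bounded velocity instead of the infinite-speed smearing of
linear diffusion. The square-root denominator is adopted deliberately:
it is the standard flux-limited form and the only reading of the
equations that yields the bounded-speed property the model is built
around. The saturated taxis response $s/(1+s^2)$ peaks at unit gradient
and shuts down on near-discontinuities.

MMP1 follows the same flux-saturated transport (with its own triplet
$\nu_P, m_P, v_P$), is produced on the TM band at rate $a_4 E F(N)$ and
degraded by the tumor at rate $a_5 P N$. ECM obeys
$\partial_t E = -a_6 (E - E_{floor}) P$ with $E_{floor} = E_{basal}$
inside the support and $0$ outside — a relaxation form that maintains
the residual matrix observed inside the bulk while reducing exactly to
plain proteolysis $-a_6 E P$ where there is no tumor. Integrins exchange
via ECM-dependent activation $a_7 E I F(N)$ and support-gated
inactivation $a_8 A$, are replenished by exocytosis
$a_9(K_I - A - I)$ on the support-plus-band region, and are transported
at speed $v_{Int}$ (`integrin_rates()`, `integrin_transport()`). The sum
of the two exchange rates equals the exocytosis term identically — a
property tested to machine precision.

### Design choices made where the design was open

* **Support detection.** Numerical detection of $Sup(N)$ is not part of
  the continuum model; we define $b_N$ by the rightmost
  $\delta_N$-crossing with linear interpolation (default
  $\delta_N = 10^{-3} K_N$), which is robust to floating-point noise at
  the foot of sharp fronts.
* **Convolution at the walls.** The moving window of $F(N)$ is truncated
  at the domain boundaries rather than zero-padded: no tissue exists
  outside $\Omega$, and padding would inflate $F$ artificially at the
  walls.
* **Union gating of exocytosis.** The support and the TM band share only
  the point $b_N$; their indicator sum is treated as the indicator of
  the union so production is never double-counted at a node.
* **Transport orientation.** The transport term $v_{Int}\partial_x$
  written with a plus sign advects profiles *toward the bulk* for a
  front migrating in $+x$. Because the biological intent of the term is
  to carry receptors with the migrating cells toward the front,
  `integrin_transport()` exposes an orientation switch defaulting to
  `"toward_front"` (rate $-v_{Int}\,u_x$, upwinded); the literal printed
  sign remains available as `"toward_bulk"`.
* **Basal levels.** Basal active integrins in the bulk and basal
  inactive integrins on the TM band are imposed through the initial
  state (`baseline_initial()`), not through extra source terms.
* **Characteristic functions** are evaluated sharply on nodes; at the
  shipped resolution the IMEX scheme tolerates the discontinuity.

## Numerics

The spatial discretization is a mass-lumped linear-element Galerkin
scheme on a uniform grid — algebraically a conservative finite-volume
stencil with fields on nodes and fluxes on faces, under no-flux boundary
conditions. Each time step:

1. recompute $Sup(N)$, $L_{TM}$ and $F(N)$ (no caching across steps, so
   the gating never lags the front);
2. advance $N$: the nonlinear mobilities of the flux-saturated and taxis
   fluxes are frozen at the current state (one Picard refresh optional)
   and the resulting linear transport operator is inverted implicitly as
   a tridiagonal $\theta$-solve (backward Euler by default), with
   logistic growth taken semi-implicitly in the same solve. The matrix
   is an M-matrix: the step preserves positivity, and for $a_3 = 0$ the
   column sums telescope so mass is conserved exactly;
3. advance $P$ the same way, with the linear degradation implicit and
   the TM-band production explicit;
4. advance $E, A, I$ jointly with classical RK4, the upwinded integrin
   transport inside the right-hand side, $N$ and $P$ frozen over the
   step.

The mobility density at a face is interpolated at fourth order (clipped
at zero at the degenerate foot, arithmetic mean at the wall-adjacent
faces). This choice reduces the $O(\Delta x)$ bias of the front position
markedly: the front edge at $t = 5$ h moves by less than 1% between 500
and 1000 nodes, and with saturation disabled the solution matches an
independent explicit porous-medium reference on a four-fold finer grid
to better than $10^{-3}$ in $L^\infty$ at $t = 1$ h.

Explicit advection of the integrin fields is guarded by a CFL check
($v_{Int}\,\Delta t/\Delta x \le$ `cfl_safety`); `check_stability()`
reports all limits. Negative RK4 overshoots would be floored at zero and
counted — the counter is zero in every shipped scenario at default
resolution. Simulations are fully deterministic.

**Problem sizes.** The shipped study conditions are a 500-node grid (the
model's reference resolution) and $\Delta t = 5\times10^{-4}$ h, i.e.
$3\times10^4$ steps over the 15 h observation window. We verified that
the accuracy checks above hold at this resolution, so the package uses
it as its desk default; substantially finer time resolutions (up to the
$10^6$–$10^7$-step range) remain a plain `solver_config()` choice.

## Default parameters

No fitted parameter set is shipped with this model family, so the
defaults in `model_params()` are this package's own calibration, fixed
once against three qualitative anchors: (i) the front traverses an $O(1)$ fraction of
the domain in 15 h ($b_N$ moves from 0.36 to about 0.72 at defaults);
(ii) the TM band spans 5–7 cell diameters, with a cell diameter of 0.01
domain units ($h_p = 0.06$); (iii) the 10 h snapshot shows the
characteristic pattern — an MMP1 peak on the TM band shifted
migration-ward of the tumor shoulder, an MMP1 outer front ahead of
$b_N$, an active-integrin plateau over the band, and integrin exchange
localized at the support edge. Units are hours and domain lengths;
densities are scaled so $K_N = K_I = E_0 = 1$.

Two defaults deserve comment:

* $v_{Int} = 0.035$ exceeds the front speed ($\approx v_N = 0.03$). This
  is what produces the plateau: activated integrins produced mid-band
  are delivered to the band tip faster than the band advances. With
  transport slower than the front, the leading edge of the band is
  always freshly swept tissue and $A$ ramps instead of plateauing.
* $a_1 = a_2 = 5\times10^{-4}$ keep baseline taxis well below the
  saturation speed, so the measured front speed stays within the
  flux-limitation bound $v_N$ (the acceptance suite checks
  $\max$ speed $< 1.05\,v_N$).

## Scenarios

* **baseline** — the 15 h invasion run described above.
* **porosity** — ECM degradation raises tissue porosity, which feeds
  back on the tumor saturation speed: porosity 50% (intact matrix) maps
  to $v_{min}$ and porosity 66% (degraded) to $v_{max}$ through a
  smoothstep ramp, constant outside the band (`porosity_velocity()`).
  The functional form of the ramp between the two anchors is our
  choice; any monotone smooth ramp with the same endpoints behaves
  equivalently at these parameters. The **porosity_reduced** preset
  pairs it with the flux-saturated-only tumor equation
  (`reduced_model`), isolating the transport effect.
* **splitting** — raising the chemotactic sensitivity to the calibrated
  value $a_1 = 0.4$ (800× baseline) makes the leading front material
  chase the MMP1 peak sitting on the TM band, detach across the
  detection threshold, and register as a second tumor component at the
  preset's report time ($t = 1$ h). At homogeneous logistic
  proliferation the break is transient — the advancing main front later
  re-absorbs the detached material — and the detached mass is small
  (foot material; the flux-saturation bound $|J| \le v_N N$ limits how
  much bulk mass can follow). Persistent macroscopic splitting is
  expected to require heterogeneous proliferation, whose defining
  equations are not available to this package; no stand-in model is
  shipped. The `chemosensitivity_sweep()` operation reproduces the
  calibration.

```{r example}
library(gbfront)
pre <- scenario_preset("baseline")
traj <- simulate_front(pre$initial, pre$params, pre$cfg)
front_report_table(traj)
```

## The synthetic line-scan pipeline

The `profiles` functions emulate the quantification of multi-channel
confocal line scans across the front (tumor membrane, MMP1, FAK, Talin).
`generate_scans()` draws replicated scans from a declared design — per
channel a Gaussian bump (or dip, for Talin) over a baseline plus
additive zero-mean Gaussian noise clipped at zero intensity.
`smooth_scan()` implements the weighted penalized-least-squares smoother

$$\min_f \sum_i w_i (y_i - f_i)^2 + \lambda \sum_i h\Big(\frac{f_{i-1} - 2f_i + f_{i+1}}{h^2}\Big)^2,$$

a discrete second-difference penalty solved directly as
$(W + \lambda D^\top D) f = W y$. $\lambda = 0$ is the identity;
$\lambda \to \infty$ converges to the weighted least-squares line; the
smoother is linear in the data. Weights default to uniform, with any
positive weighting (e.g. intensity-proportional) accepted; an optional
generalized cross-validation selector (`lambda = "gcv"`) chooses the
penalty per channel. Real measured line scans come with no declared
weighting or penalty, so all quantitative claims about this pipeline
are made on synthetic designs only.

`peak_ordering()` smooths each replicate, locates channel peaks
(leftmost argmax with parabolic refinement when the neighbors are
strictly lower), and reports signed shifts plus the fraction of
replicates in which the first channel peaks before the second along the
migration direction; flat channels are flagged and excluded rather than
guessed. `channel_anticorrelation()` computes the Pearson correlation
of two smoothed channels inside a window — negative at the front for a
FAK-bump/Talin-dip design.

What the generator does *not* emulate: correlated (speckle) noise,
bleaching trends, irregular sampling along hand-drawn measurement
lines, and channel crosstalk. Passing the pipeline's checks therefore
demonstrates correctness of the estimators under the declared noise
model, not robustness to every artifact of real microscopy data.

## Degenerate inputs and numerical edges

* Empty tumor (all of $N$ below $\delta_N$): all gated sources evaluate
  to zero; simulation proceeds; metrics report `NA` markers instead of
  erroring.
* $b_N$ at the wall: the TM band clips to zero width.
* $\epsilon \le 0$ in $F(N)$ is rejected — $F$ would blow up where the
  local mass vanishes.
* Ties in peak detection resolve to the leftmost argmax; parabolic
  refinement is applied only with strictly lower neighbors, so plateaus
  are not refined.
* Component counting (`front_count()`) uses strict super-threshold runs
  and is invariant under joint positive rescaling of field and
  threshold.

## Known limitations

* One spatial dimension; no curvature or 2D/3D morphology.
* First-order upwinding for taxis and transport: steep taxis fronts are
  smeared over a few cells at 500 nodes.
* The integrin subsystem is explicit (RK4): very stiff
  activation/exocytosis parameter choices would require a smaller step.
* Defaults are a calibration, not fitted constants; quantitative
  positions and magnitudes should be read as model output under this
  package's declared conditions.
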