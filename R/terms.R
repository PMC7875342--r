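# Pure evaluation of the model's spatial and reaction terms: no time
# stepping happens here. Fields are node vectors on a gb_grid; flux
# operations are elementwise and can be evaluated on nodes or faces.

#' Nonlocal tumor activity functional
#'
#' \eqn{F(N)(x) = \left(\int_{x-h_p}^{x+h_p} N(y)\,dy + \epsilon\right)^{-\alpha_F}}.
#' The moving integral (convolution with the indicator of
#' `[-h_p, h_p]`) is computed by trapezoidal quadrature on the grid, with the
#' window truncated at the domain boundaries: no tissue exists outside
#' \eqn{\Omega}, so the boundary windows simply contain less mass.
#'
#' `F` is large where little tumor mass surrounds a point — i.e. at the
#' front — and small inside the bulk, concentrating MMP1 production and
#' integrin activation on the advancing edge.
#'
#' @param N Tumor density field.
#' @param h_p Window semi-amplitude (the maximum microtube length).
#' @param eps_F Strictly positive regularization; caps `F` at
#'   `eps_F^-alpha_F` where the local mass vanishes.
#' @param alpha_F Modulation exponent.
#' @param grid A [grid1d()] object.
#' @return Strictly positive field of length `n_nodes`.
#' @export
activity_functional <- function(N, h_p, eps_F, alpha_F, grid) {
  .check_grid(grid)
  .check_field(N, grid, "N")
  if (!is.numeric(eps_F) || length(eps_F) != 1L || eps_F <= 0)
    stop("eps_F must be strictly positive (F would blow up where local mass vanishes)")
  n <- grid$n_nodes
  # cumulative trapezoid C(x_i) = int_0^{x_i} N
  C <- c(0, cumsum((N[-1] + N[-n]) / 2) * grid$dx)
  right <- pmin(grid$x + h_p, grid$b_omega)
  left <- pmax(grid$x - h_p, 0)
  Cf <- approx(grid$x, C, xout = c(left, right))$y
  mass <- Cf[(n + 1):(2 * n)] - Cf[1:n]
  (mass + eps_F)^(-alpha_F)
}

#' Flux-saturated (flux-limited) transport flux
#'
#' \eqn{J = \nu u u_x / \sqrt{m^2 + (\nu/v)^2 u_x^2}}. For small gradients
#' this reduces to a porous-medium flux \eqn{(\nu/m) u u_x}; for steep
#' gradients the transport speed saturates, \eqn{|J| \le v\,u}, which is the
#' mechanism producing sharp fronts with finite propagation speed.
#'
#' @param u Density field (or face values), nonnegative.
#' @param du_dx Spatial gradient of `u` at the same locations.
#' @param nu Viscosity-like coefficient (> 0).
#' @param m Saturation constant (> 0).
#' @param v Maximum propagation speed (> 0); may be a vector (porosity-
#'   dependent speed).
#' @return Flux values, same length as `u`.
#' @export
flux_saturated <- function(u, du_dx, nu, m, v) {
  if (any(u < 0)) stop("invalid field 'u': negative entries")
  if (nu <= 0 || m <= 0 || any(v <= 0))
    stop("flux-saturation parameters nu, m, v must be strictly positive")
  nu * u * du_dx / sqrt(m^2 + (nu / v)^2 * du_dx^2)
}

#' Saturated taxis flux
#'
#' \eqn{J = a\,u\,g_x / (1 + g_x^2)}: advection of `u` up the gradient of a
#' cue `g` (MMP1 for chemotaxis, active integrins for haptotaxis), with a
#' response that peaks at unit gradient and shuts down on
#' near-discontinuities. Consequently \eqn{|J| \le a\,u/2}.
#'
#' @param u Density field, nonnegative.
#' @param dg_dx Gradient of the tactic cue.
#' @param a Tactic sensitivity (nonnegative).
#' @return Flux values, same length as `u`.
#' @export
taxis_flux <- function(u, dg_dx, a) {
  if (any(u < 0)) stop("invalid field 'u': negative entries")
  if (a < 0) stop("taxis sensitivity must be nonnegative")
  a * u * dg_dx / (1 + dg_dx^2)
}

#' Logistic tumor proliferation
#'
#' @param N Tumor density field.
#' @param a3 Growth rate (1/h).
#' @param K_N Carrying capacity.
#' @return Rate field `a3 * N * (1 - N / K_N)`.
#' @export
logistic_growth <- function(N, a3, K_N) {
  if (any(N < 0)) stop("invalid field 'N': negative entries")
  a3 * N * (1 - N / K_N)
}

#' MMP1 reaction terms
#'
#' Production `a4 * E * F` gated to the TM band (where microtubes release
#' proteases into ECM-rich tissue) minus tumor-mediated degradation
#' `a5 * P * N`.
#'
#' @param P,N,E,F MMP1, tumor, ECM and activity fields on a shared grid.
#' @param tm TM band region (see [tm_region()]).
#' @param a4 Production rate.
#' @param a5 Degradation rate.
#' @param grid A [grid1d()] object.
#' @return Rate field for `P`.
#' @export
mmp_reaction <- function(P, N, E, F, tm, a4, a5, grid) {
  .check_grid(grid)
  chi <- region_indicator(tm, grid)
  a4 * E * F * chi - a5 * P * N
}

#' ECM degradation with a basal residual
#'
#' Relaxation form \eqn{\partial_t E = -a_6 (E - E_{floor}) P} with
#' `E_floor = E_basal` inside the tumor support and 0 outside. Inside the
#' bulk the matrix is degraded down to a residual basal level rather than to
#' zero; outside the support the form reduces exactly to plain proteolysis
#' `-a6 * E * P`.
#'
#' @param E ECM field.
#' @param P MMP1 field.
#' @param a6 Degradation rate per unit MMP1.
#' @param E_basal Residual level inside the support.
#' @param support Tumor support region.
#' @param grid A [grid1d()] object.
#' @return Rate field for `E`.
#' @export
ecm_rate <- function(E, P, a6, E_basal, support, grid) {
  .check_grid(grid)
  floor_E <- E_basal * region_indicator(support, grid)
  -a6 * (E - floor_E) * P
}

#' Integrin activation/inactivation/exocytosis rates
#'
#' Active integrins are produced by ECM-mediated activation `a7 * E * I * F`
#' (strongest on the TM band where `F` is large and ECM still intact) and
#' inactivated at rate `a8` inside the tumor support, once the cells have
#' crawled on the matrix and moved forward. Inactive integrins balance the
#' exchange and are replenished by exocytosis
#' `a9 * (K_I - A - I)` on the union of the support and the TM band (the two
#' share only the point `b_N`, so the union caps the gating indicator at 1).
#' The sum of the two returned rates equals the exocytosis term exactly:
#' activation/inactivation only exchanges mass between the two pools.
#'
#' Transport is handled separately by [integrin_transport()].
#'
#' @param A,I,E,F Active/inactive integrin, ECM and activity fields.
#' @param support,tm Tumor support and TM band regions.
#' @param params A [model_params()] object (uses `a7`, `a8`, `a9`, `K_I`).
#' @param grid A [grid1d()] object.
#' @return List with rate fields `dA` and `dI`.
#' @export
integrin_rates <- function(A, I, E, F, support, tm, params, grid) {
  .check_grid(grid)
  chi_sup <- region_indicator(support, grid)
  chi_union <- region_indicator(.region_union(support, tm), grid)
  exch <- params$a7 * E * I * F - params$a8 * A * chi_sup
  list(dA = exch,
       dI = -exch + params$a9 * (params$K_I - A - I) * chi_union)
}

#' Upwinded integrin transport rate
#'
#' Rate contribution of the advective term carrying membrane receptors with
#' the moving cells, discretized with first-order upwinding (one-sided
#' differences at the boundary nodes).
#'
#' With `direction = "toward_front"` (default) profiles are advected in the
#' migration direction +x: the rate is \eqn{-v_{Int}\,\partial_x u} with
#' backward differences. `"toward_bulk"` gives the literal
#' \eqn{+v_{Int}\,\partial_x u} (forward differences), which advects
#' profiles toward the bulk; for a linear field of slope `s` it returns
#' `v_Int * s` at every interior node.
#'
#' @param u Field to transport.
#' @param v_Int Transport speed (>= 0).
#' @param grid A [grid1d()] object.
#' @param direction `"toward_front"` or `"toward_bulk"`.
#' @return Rate field.
#' @export
integrin_transport <- function(u, v_Int, grid,
                               direction = c("toward_front", "toward_bulk")) {
  .check_grid(grid)
  direction <- match.arg(direction)
  if (v_Int < 0) stop("v_Int must be nonnegative")
  if (v_Int == 0) return(numeric(grid$n_nodes))
  n <- grid$n_nodes
  d <- diff(u) / grid$dx
  if (direction == "toward_front") {
    # du/dt = -v u_x, upwind = backward difference; one-sided at node 1
    -v_Int * c(d[1], d)
  } else {
    # du/dt = +v u_x, upwind = forward difference; one-sided at node n
    v_Int * c(d, d[n - 1])
  }
}

#' Porosity-dependent propagation speed
#'
#' ECM degradation increases the void fraction (porosity) of the tissue,
#' which in turn modulates how fast tumor mass can propagate. ECM is mapped
#' affinely to porosity, \eqn{\epsilon = \epsilon_{min} +
#' (\epsilon_{max}-\epsilon_{min})(1 - E/E_0)} (clipped to the band), and
#' the speed follows a smoothstep ramp from `v_min` at porosity 0.50 to
#' `v_max` at porosity 0.66, constant outside that band: intact matrix
#' (porosity 50%) offers the most resistance, fully degraded matrix
#' (porosity 66%) the least.
#'
#' @param E ECM field.
#' @param E0 Reference (undegraded) ECM level (> 0).
#' @param eps_min,eps_max Porosity band, `0 <= eps_min < eps_max <= 1`.
#' @param v_min,v_max Speeds at the two ends of the ramp.
#' @return Speed field `v_N(eps(E))`, same length as `E`.
#' @export
porosity_velocity <- function(E, E0, eps_min = 0.50, eps_max = 0.66,
                              v_min, v_max) {
  if (E0 <= 0) stop("E0 must be strictly positive")
  if (!(eps_min >= 0 && eps_min < eps_max && eps_max <= 1))
    stop("porosity band needs 0 <= eps_min < eps_max <= 1")
  if (any(E > E0)) {
    warning("ECM exceeds the reference level E0; clipping to E0")
    E <- pmin(E, E0)
  }
  E <- pmax(E, 0)
  eps <- eps_min + (eps_max - eps_min) * (1 - E / E0)
  s <- (eps - eps_min) / (eps_max - eps_min)
  s <- pmin(pmax(s, 0), 1)
  v_min + (v_max - v_min) * (3 * s^2 - 2 * s^3)
}
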