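# IMEX discretization of the coupled system on a gb_grid under no-flux
# boundary conditions. Spatial discretization is a mass-lumped linear-element
# Galerkin scheme on the uniform grid, algebraically identical to a
# conservative finite-volume stencil: fields live on nodes, fluxes on the
# n-1 interior faces, boundary faces carry zero flux. The nonlinear
# mobilities of the flux-saturated and taxis terms are frozen at the current
# state (optionally refreshed by Picard iteration) and the resulting linear
# transport operator is inverted implicitly as a tridiagonal solve; ECM and
# integrins advance with classical RK4.

#' Time-stepping configuration
#'
#' @param dt Time step (hours). The default 5e-4 gives 3e4 steps over the
#'   15 h study window, a desk-scale resolution at which the shipped
#'   accuracy checks (grid convergence, porous-medium oracle) hold; finer
#'   production resolutions are reached by lowering `dt`.
#' @param t_end Simulation horizon (hours).
#' @param output_times Times at which states are recorded; sorted, within
#'   `[0, t_end]`. Default `NULL`: the standard snapshot times 0/5/10/15 h
#'   clipped to the horizon, always including `t_end`.
#' @param theta_implicit Implicitness of the transport solve for `N` and
#'   `P`: 1 = backward Euler (default), 0.5 = Crank–Nicolson.
#' @param cfl_safety Safety factor in (0, 1] for the explicit advection
#'   (integrin transport) CFL limit.
#' @param picard_iters Number of mobility refreshes per implicit step
#'   (default 1 = single frozen-coefficient solve).
#' @param tol Convergence tolerance for the Picard refresh.
#' @return A `gb_solver_config` object.
#' @export
solver_config <- function(dt = 5e-4, t_end = 15,
                          output_times = NULL,
                          theta_implicit = 1, cfl_safety = 0.9,
                          picard_iters = 1L, tol = 1e-8) {
  if (dt <= 0) stop("dt must be positive")
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(output_times)) {
    snaps <- c(5, 10, 15)
    output_times <- c(0, snaps[snaps < t_end], t_end)
  }
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0) || any(output_times > t_end + 1e-12))
    stop("output_times must lie within [0, t_end]")
  if (!(theta_implicit >= 0.5 && theta_implicit <= 1))
    stop("theta_implicit must lie in [0.5, 1]")
  if (!(cfl_safety > 0 && cfl_safety <= 1))
    stop("cfl_safety must lie in (0, 1]")
  picard_iters <- as.integer(picard_iters)
  if (picard_iters < 1L) stop("picard_iters must be >= 1")
  structure(list(dt = dt, t_end = t_end, output_times = output_times,
                 theta_implicit = theta_implicit, cfl_safety = cfl_safety,
                 picard_iters = picard_iters, tol = tol),
            class = "gb_solver_config")
}

#' Conservative divergence of a face flux
#'
#' Maps a flux defined on the `n_nodes + 1` cell faces (boundary faces
#' first and last, which must be exactly zero under the no-flux boundary
#' condition) to node rates `-diff(flux)/dx`. The grid sum of the returned
#' rates telescopes to zero.
#'
#' @param flux_at_faces Numeric vector of length `n_nodes + 1`.
#' @param grid A [grid1d()] object.
#' @return Rate field of length `n_nodes`.
#' @export
divergence <- function(flux_at_faces, grid) {
  .check_grid(grid)
  if (length(flux_at_faces) != grid$n_nodes + 1L)
    stop("flux_at_faces must have length n_nodes + 1 (boundary faces included)")
  if (flux_at_faces[1] != 0 || flux_at_faces[length(flux_at_faces)] != 0)
    stop("contract violation: boundary faces must carry zero flux")
  -diff(flux_at_faces) / grid$dx
}

# ---- shared IMEX machinery --------------------------------------------------

# per-step geometry: support, TM band, activity functional, indicators.
# Inlined equivalent of tumor_support()/tm_region()/region_indicator() for
# the inner loop (identical arithmetic, no per-call validation).
.step_aux <- function(state, params) {
  grid <- state$grid
  N <- state$N
  x <- grid$x
  n <- grid$n_nodes
  delta <- params$delta_N
  if (max(N) < delta) {
    support <- region_empty()
    tm <- region_empty()
    zero <- numeric(n)
    chi_sup <- zero; chi_tm <- zero; chi_union <- zero
  } else {
    idx <- max(which(N >= delta))
    b_N <- if (idx == n) grid$b_omega
           else x[idx] + grid$dx * (N[idx] - delta) / (N[idx] - N[idx + 1])
    tm_hi <- min(b_N + params$h_p, grid$b_omega)
    support <- structure(list(intervals = cbind(lo = 0, hi = b_N)),
                         class = "gb_region")
    tm <- structure(list(intervals = cbind(lo = b_N, hi = tm_hi)),
                    class = "gb_region")
    chi_sup <- as.numeric(x <= b_N)
    chi_tm <- as.numeric(x >= b_N & x <= tm_hi)
    chi_union <- as.numeric(x <= tm_hi)
  }
  list(support = support, tm = tm,
       Fv = activity_functional(N, params$h_p, params$eps_F,
                                params$alpha_F, grid),
       chi_sup = chi_sup, chi_tm = chi_tm, chi_union = chi_union)
}

# One theta-implicit solve of du/dt = div(D u_x) - div(w u) + extra terms,
# with D, w frozen on interior faces (length n-1), upwinded advection, and
# no-flux boundaries. extra_diag enters the matrix diagonal, extra_rhs the
# right-hand side (both already scaled by dt).
.implicit_transport_solve <- function(u, Dface, wface, dt, dx, theta,
                                      extra_diag = 0, extra_rhs = 0) {
  n <- length(u)
  wp <- pmax(wface, 0)
  wm <- pmin(wface, 0)
  # face quantities indexed per node: *_lo = face i-1/2, *_hi = face i+1/2
  D_lo <- c(0, Dface);  D_hi <- c(Dface, 0)
  wp_lo <- c(0, wp);    wp_hi <- c(wp, 0)
  wm_lo <- c(0, wm);    wm_hi <- c(wm, 0)
  # linear operator L: (Lu)_i = sum of flux differences
  L_low <- D_lo / dx^2 + wp_lo / dx          # coeff of u[i-1], rows 2..n
  L_up <- D_hi / dx^2 - wm_hi / dx           # coeff of u[i+1], rows 1..n-1
  L_diag <- -(D_hi + D_lo) / dx^2 - (wp_hi - wm_lo) / dx
  rhs <- u + extra_rhs
  if (theta < 1) {
    Lu <- L_diag * u +
      c(0, L_low[-1] * u[-n]) +
      c(L_up[-n] * u[-1], 0)
    rhs <- rhs + (1 - theta) * dt * Lu
  }
  thomas_solve(-theta * dt * L_low,
               1 - theta * dt * L_diag + extra_diag,
               -theta * dt * L_up,
               rhs)
}

.face_mean <- function(u) (u[-1] + u[-length(u)]) / 2

# fourth-order face interpolation of the mobility density, clipped at zero
# (degenerate foot) and falling back to the arithmetic mean at the two
# boundary-adjacent faces; reduces the O(dx) bias of the front position
.face_interp <- function(u) {
  n <- length(u)
  f <- (u[-1] + u[-n]) / 2
  if (n >= 4) {
    i <- 2:(n - 2)
    f[i] <- (-u[i - 1] + 7 * u[i] + 7 * u[i + 1] - u[i + 2]) / 12
  }
  pmax(f, 0)
}

# effective saturation speed for the tumor flux on faces
.tumor_vface <- function(state, params) {
  if (!params$porosity_on) return(params$v_N)
  vnode <- porosity_velocity(state$E, params$E0, params$eps_min,
                             params$eps_max, params$v_por_min,
                             params$v_por_max)
  .face_mean(vnode)
}

.step_tumor_core <- function(state, params, cfg) {
  grid <- state$grid
  dx <- grid$dx
  N <- state$N
  sP <- diff(state$P) / dx
  sA <- diff(state$A) / dx
  if (params$reduced_model) {
    wface <- numeric(grid$n_nodes - 1L)
    growth_diag <- 0
  } else {
    wface <- params$a1 * sP / (1 + sP^2) + params$a2 * sA / (1 + sA^2)
    # semi-implicit logistic growth: a3 * N_new * (1 - N_old / K_N)
    growth_diag <- -cfg$dt * params$a3 * (1 - N / params$K_N)
  }
  vf <- .tumor_vface(state, params)
  u <- N
  for (it in seq_len(cfg$picard_iters)) {
    s <- diff(u) / dx
    Dface <- params$nu_N * .face_interp(u) /
      sqrt(params$m_N^2 + (params$nu_N / vf)^2 * s^2)
    u_new <- .implicit_transport_solve(N, Dface, wface, cfg$dt, dx,
                                       cfg$theta_implicit,
                                       extra_diag = growth_diag)
    if (it > 1L && max(abs(u_new - u)) < cfg$tol) { u <- u_new; break }
    u <- u_new
  }
  if (any(u < 0)) u <- pmax(u, 0)  # roundoff guard; scheme is an M-matrix
  u
}

.step_mmp_core <- function(state, params, cfg, aux) {
  grid <- state$grid
  dx <- grid$dx
  P <- state$P
  source <- params$a4 * state$E * aux$Fv * aux$chi_tm
  u <- P
  for (it in seq_len(cfg$picard_iters)) {
    s <- diff(u) / dx
    Dface <- params$nu_P * .face_interp(u) /
      sqrt(params$m_P^2 + (params$nu_P / params$v_P)^2 * s^2)
    u_new <- .implicit_transport_solve(P, Dface, numeric(grid$n_nodes - 1L),
                                       cfg$dt, dx, cfg$theta_implicit,
                                       extra_diag = cfg$dt * params$a5 * state$N,
                                       extra_rhs = cfg$dt * source)
    if (it > 1L && max(abs(u_new - u)) < cfg$tol) { u <- u_new; break }
    u <- u_new
  }
  if (any(u < 0)) u <- pmax(u, 0)
  u
}

.step_others_core <- function(state, params, cfg, aux) {
  grid <- state$grid
  if (params$v_Int * cfg$dt / grid$dx > cfg$cfl_safety)
    stop(sprintf(
      "CFL violation: v_Int*dt/dx = %.3g exceeds cfl_safety = %.3g",
      params$v_Int * cfg$dt / grid$dx, cfg$cfl_safety))
  P <- state$P
  a6 <- params$a6; a7 <- params$a7; a8 <- params$a8; a9 <- params$a9
  K_I <- params$K_I
  floor_E <- params$E_basal * aux$chi_sup
  n <- grid$n_nodes
  dx <- grid$dx
  v <- params$v_Int
  # upwinded transport, match.arg and validation hoisted out of the RK4 loop
  transport <- if (v == 0) {
    function(u) 0
  } else if (params$transport_direction == "toward_front") {
    function(u) { d <- (u[-1] - u[-n]) / dx; -v * c(d[1], d) }
  } else {
    function(u) { d <- (u[-1] - u[-n]) / dx; v * c(d, d[n - 1]) }
  }
  rhs <- function(E, A, I) {
    exch <- a7 * E * I * aux$Fv - a8 * A * aux$chi_sup
    list(dE = -a6 * (E - floor_E) * P,
         dA = exch + transport(A),
         dI = -exch + a9 * (K_I - A - I) * aux$chi_union + transport(I))
  }
  E <- state$E; A <- state$A; I <- state$I
  h <- cfg$dt
  k1 <- rhs(E, A, I)
  k2 <- rhs(E + h / 2 * k1$dE, A + h / 2 * k1$dA, I + h / 2 * k1$dI)
  k3 <- rhs(E + h / 2 * k2$dE, A + h / 2 * k2$dA, I + h / 2 * k2$dI)
  k4 <- rhs(E + h * k3$dE, A + h * k3$dA, I + h * k3$dI)
  En <- E + h / 6 * (k1$dE + 2 * k2$dE + 2 * k3$dE + k4$dE)
  An <- A + h / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA)
  In <- I + h / 6 * (k1$dI + 2 * k2$dI + 2 * k3$dI + k4$dI)
  floored <- sum(En < 0) + sum(An < 0) + sum(In < 0)
  list(E = pmax(En, 0), A = pmax(An, 0), I = pmax(In, 0),
       floored = floored)
}

# ---- public single-step operations ------------------------------------------

#' Advance the tumor field by one IMEX step
#'
#' Mobility coefficients of the flux-saturated and taxis fluxes are frozen
#' at the current state (with optional Picard refreshes) and the resulting
#' linear transport operator is inverted as a tridiagonal backward-Euler /
#' theta solve; logistic growth is taken semi-implicitly in the same solve.
#' The assembled matrix is an M-matrix, so the returned field is
#' nonnegative and, for `a3 = 0`, total mass is conserved exactly.
#'
#' @param state A [new_state()] object.
#' @param params A [model_params()] object.
#' @param cfg A [solver_config()] object.
#' @return The advanced tumor field `N`.
#' @export
step_tumor <- function(state, params, cfg) {
  stopifnot(inherits(state, "gb_state"))
  .step_tumor_core(state, params, cfg)
}

#' Advance the MMP1 field by one IMEX step
#'
#' Same frozen-mobility implicit transport as [step_tumor()]; the linear
#' degradation `-a5 P N` is treated implicitly, the TM-band production
#' `a4 E F(N)` explicitly.
#'
#' @inheritParams step_tumor
#' @return The advanced MMP1 field `P`.
#' @export
step_mmp <- function(state, params, cfg) {
  stopifnot(inherits(state, "gb_state"))
  .step_mmp_core(state, params, cfg, .step_aux(state, params))
}

#' Advance ECM and integrins by one RK4 step
#'
#' Classical fourth-order Runge–Kutta on the coupled ECM/integrin kinetics
#' ([ecm_rate()], [integrin_rates()]) with upwinded transport
#' ([integrin_transport()]) inside the right-hand side; `N` and `P` are
#' frozen at the current state. Negative overshoots (none at the shipped
#' resolutions) are floored at zero and counted.
#'
#' @inheritParams step_tumor
#' @return List with fields `E`, `A`, `I` and the integer `floored`.
#' @export
step_others <- function(state, params, cfg) {
  stopifnot(inherits(state, "gb_state"))
  .step_others_core(state, params, cfg, .step_aux(state, params))
}

# ---- orchestration ----------------------------------------------------------

#' Simulate the coupled front model
#'
#' Advances the five fields from `initial` to `cfg$t_end`, recomputing the
#' tumor support, TM band and activity functional every step, and recording
#' states at `cfg$output_times`. Deterministic: two runs with identical
#' inputs produce bit-identical trajectories.
#'
#' @param initial Initial [new_state()] (see [baseline_initial()]).
#' @param params A [model_params()] object.
#' @param cfg A [solver_config()] object.
#' @return A `gb_trajectory`: list with `states` (one `gb_state` per output
#'   time), `params`, `solver`, and `diagnostics` (per-step time, grid
#'   totals of `N` and `P`, front position `b_N`, and the flooring counter).
#' @examples
#' g <- grid1d(1, 64)
#' st <- baseline_initial(scenario_spec(), model_params(), g)
#' tr <- simulate_front(st, model_params(), solver_config(
#'   dt = 0.01, t_end = 0.05, output_times = c(0, 0.05)))
#' length(tr$states)
#' @export
simulate_front <- function(initial, params, cfg) {
  stopifnot(inherits(initial, "gb_state"),
            inherits(params, "gb_params"),
            inherits(cfg, "gb_solver_config"))
  grid <- initial$grid
  if (params$h_p >= grid$b_omega)
    stop("h_p must be smaller than the domain length b_omega")
  stab <- check_stability(params, cfg, grid)
  if (!stab$ok)
    stop(sprintf("unstable configuration: advective CFL limit dt <= %.3g h (v_Int)",
                 stab$dt_limit_v_Int))
  n_steps <- as.integer(round(cfg$t_end / cfg$dt))
  if (abs(n_steps * cfg$dt - cfg$t_end) > 1e-9 * max(1, cfg$t_end))
    n_steps <- as.integer(ceiling(cfg$t_end / cfg$dt))
  out_steps <- unique(as.integer(round(cfg$output_times / cfg$dt)))
  state <- initial
  states <- vector("list", length(out_steps))
  names(states) <- NULL
  rec <- 0L
  diag_t <- numeric(n_steps + 1L)
  diag_mN <- numeric(n_steps + 1L)
  diag_mP <- numeric(n_steps + 1L)
  diag_bN <- numeric(n_steps + 1L)
  floored_total <- 0L
  record_diag <- function(k, st, sup) {
    diag_t[k] <<- st$t
    diag_mN[k] <<- sum(st$N) * grid$dx
    diag_mP[k] <<- sum(st$P) * grid$dx
    diag_bN[k] <<- if (is_region_empty(sup)) NA_real_
                   else max(sup$intervals[, 2])
  }
  aux <- .step_aux(state, params)
  record_diag(1L, state, aux$support)
  if (0L %in% out_steps) { rec <- rec + 1L; states[[rec]] <- state }
  for (k in seq_len(n_steps)) {
    N_new <- .step_tumor_core(state, params, cfg)
    P_new <- .step_mmp_core(state, params, cfg, aux)
    oth <- .step_others_core(state, params, cfg, aux)
    floored_total <- floored_total + oth$floored
    flds <- list(N = N_new, P = P_new, E = oth$E, A = oth$A, I = oth$I)
    for (nm in names(flds)) {
      if (any(!is.finite(flds[[nm]])))
        stop(sprintf("non-finite value in field '%s' at step %d (t = %.4g h)",
                     nm, k, k * cfg$dt))
    }
    state <- structure(list(t = k * cfg$dt, N = N_new, P = P_new,
                            E = oth$E, A = oth$A, I = oth$I, grid = grid),
                       class = "gb_state")
    aux <- .step_aux(state, params)
    record_diag(k + 1L, state, aux$support)
    if (k %in% out_steps) { rec <- rec + 1L; states[[rec]] <- state }
  }
  structure(list(states = states[seq_len(rec)],
                 params = params, solver = cfg,
                 diagnostics = list(
                   t = diag_t, mass_N = diag_mN, mass_P = diag_mP,
                   b_N = diag_bN, floored = floored_total,
                   n_steps = n_steps)),
            class = "gb_trajectory")
}

#' @export
print.gb_trajectory <- function(x, ...) {
  ts <- vapply(x$states, `[[`, numeric(1), "t")
  cat(sprintf("<gb_trajectory> %d snapshots at t = %s h (%d steps, %d floored nodes)\n",
              length(ts), paste(signif(ts, 4), collapse = ", "),
              x$diagnostics$n_steps, x$diagnostics$floored))
  invisible(x)
}

#' Advisory stability report
#'
#' Advective CFL limits for the explicit integrin transport and (advisory,
#' since those terms are implicit) for the saturation speeds, plus a
#' pass/fail flag for the current `dt`.
#'
#' @param params A [model_params()] object.
#' @param cfg A [solver_config()] object.
#' @param grid A [grid1d()] object.
#' @return List with the dt limits, the Picard budget, and `ok`.
#' @export
check_stability <- function(params, cfg, grid) {
  .check_grid(grid)
  lim <- function(v) if (v > 0) cfg$cfl_safety * grid$dx / v else Inf
  out <- list(dt = cfg$dt,
              dt_limit_v_Int = lim(params$v_Int),
              dt_limit_v_N = lim(params$v_N),
              dt_limit_v_P = lim(params$v_P),
              picard_iters = cfg$picard_iters)
  out$ok <- cfg$dt <= out$dt_limit_v_Int
  out
}
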