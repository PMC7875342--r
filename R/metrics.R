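# Front-geometry and pattern metrics: the quantitative observables behind
# the invasion-pattern claims (MMP1 front ahead of the support edge, MMP1
# peak shifted migration-ward of the tumor shoulder, active-integrin
# plateau on the TM band, integrin exchange at the front boundary, front
# splitting under strong chemotaxis). Migration direction is +x throughout;
# "ahead"/"migration-ward" means larger x.

# leftmost argmax with parabolic refinement when both neighbours are
# strictly lower (plateaus are left unrefined)
.peak_position <- function(y, x) {
  i <- which.max(y)
  n <- length(y)
  if (i > 1L && i < n && y[i - 1] < y[i] && y[i + 1] < y[i]) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    x[i] + off * (x[2] - x[1])
  } else x[i]
}

# rightmost interpolated crossing of level on the descending flank
.right_crossing <- function(y, x, level) {
  idx <- which(y >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- max(idx)
  if (i == length(y)) return(x[length(x)])
  x[i] + (x[2] - x[1]) * (y[i] - level) / (y[i] - y[i + 1])
}

#' Count disjoint super-threshold tumor components
#'
#' Number of maximal contiguous node runs with `N > theta`. A healthy
#' single invasion front gives 1; chemotaxis-driven splitting gives 2 or
#' more.
#'
#' @param N Tumor density field.
#' @param theta Positive threshold (default in shipped analyses:
#'   `delta_N`).
#' @return Integer count (0 for a field entirely below threshold).
#' @export
front_count <- function(N, theta) {
  if (theta <= 0) stop("theta must be positive")
  r <- rle(N > theta)
  sum(r$values)
}

#' Front-pattern report for one state
#'
#' Computes the front-geometry observables: the support edge `b_N`, the
#' front width (distance over which `N` falls from 90% to 10% of its
#' maximum on the right flank), per-species peak positions (parabolic
#' refinement around the leftmost grid argmax), the tumor membrane-density
#' proxy (position of the steepest descent of `N`, i.e. the front
#' shoulder, where membrane per unit volume is highest), signed peak
#' shifts, the MMP1 outer front, the number of tumor components, the
#' coefficient of variation of the active-integrin plateau over the TM
#' band, and the location of the peak integrin exchange rate.
#'
#' @param state A [new_state()] object.
#' @param params A [model_params()] object.
#' @return A `gb_front_report` list. For an empty tumor all region-based
#'   entries are `NA` and `n_components` is 0 (no error).
#' @export
front_report <- function(state, params) {
  stopifnot(inherits(state, "gb_state"))
  grid <- state$grid
  x <- grid$x
  sup <- tumor_support(state$N, params$delta_N, grid)
  empty <- is_region_empty(sup)
  b_N <- if (empty) NA_real_ else max(sup$intervals[, 2])
  tm <- tm_region(sup, params$h_p, grid)
  peaks <- vapply(state[c("N", "P", "E", "A", "I")],
                  .peak_position, numeric(1), x = x)
  dN <- diff(state$N) / grid$dx
  xf <- (x[-1] + x[-grid$n_nodes]) / 2
  membrane_peak <- if (empty) NA_real_ else xf[which.max(-dN)]
  maxN <- max(state$N)
  w_hi <- .right_crossing(state$N, x, 0.9 * maxN)
  w_lo <- .right_crossing(state$N, x, 0.1 * maxN)
  front_width <- if (empty || is.na(w_hi) || is.na(w_lo)) NA_real_
                 else max(w_lo - w_hi, 0)
  p_front <- if (max(state$P) > 0)
    .right_crossing(state$P, x, max(params$delta_N, 1e-3 * max(state$P)))
  else NA_real_
  plateau_cv <- NA_real_
  if (!empty && !is_region_empty(tm)) {
    Atm <- state$A[region_indicator(tm, grid) == 1]
    if (length(Atm) >= 2L && mean(Atm) > 0)
      plateau_cv <- (max(Atm) - min(Atm)) / mean(Atm)
  }
  exchange_peak <- NA_real_
  if (!empty) {
    Fv <- activity_functional(state$N, params$h_p, params$eps_F,
                              params$alpha_F, grid)
    exch <- params$a7 * state$E * state$I * Fv -
      params$a8 * state$A * region_indicator(sup, grid)
    exchange_peak <- x[which.max(abs(exch))]
  }
  structure(list(
    time = state$t,
    b_N = b_N,
    front_width = front_width,
    peaks = peaks,
    membrane_peak = membrane_peak,
    shift_P_membrane = peaks[["P"]] - membrane_peak,
    mmp_outer_front = p_front,
    n_components = front_count(state$N, params$delta_N),
    plateau_cv = plateau_cv,
    exchange_peak = exchange_peak),
    class = "gb_front_report")
}

#' @export
print.gb_front_report <- function(x, ...) {
  cat(sprintf("<gb_front_report> t = %g h: b_N = %.4g, width = %.4g, components = %d\n",
              x$time, x$b_N, x$front_width, x$n_components))
  cat(sprintf("  MMP1 peak shift vs membrane: %+.4g; MMP1 outer front: %.4g\n",
              x$shift_P_membrane, x$mmp_outer_front))
  cat(sprintf("  A plateau CV on TM band: %.3g; exchange peak at %.4g\n",
              x$plateau_cv, x$exchange_peak))
  invisible(x)
}

#' Front displacement rate along a trajectory
#'
#' Front position `b_N` at each recorded output time and its
#' finite-difference displacement rate (centered differences at interior
#' output times, one-sided at the ends). In valid flux-limited runs every
#' entry is bounded by the saturation speed `v_N` (up to a small
#' front-detection tolerance).
#'
#' @param trajectory A `gb_trajectory` from [simulate_front()] with at
#'   least two recorded states.
#' @param params Optional [model_params()]; defaults to
#'   `trajectory$params`.
#' @return `data.frame` with columns `t`, `b_N`, `speed`.
#' @export
front_speed <- function(trajectory, params = NULL) {
  stopifnot(inherits(trajectory, "gb_trajectory"))
  if (is.null(params)) params <- trajectory$params
  states <- trajectory$states
  if (length(states) < 2L)
    stop("front_speed needs at least two recorded states")
  t <- vapply(states, `[[`, numeric(1), "t")
  b <- vapply(states, function(s) {
    sup <- tumor_support(s$N, params$delta_N, s$grid)
    if (is_region_empty(sup)) NA_real_ else max(sup$intervals[, 2])
  }, numeric(1))
  n <- length(t)
  speed <- numeric(n)
  speed[1] <- (b[2] - b[1]) / (t[2] - t[1])
  speed[n] <- (b[n] - b[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L)
    speed[2:(n - 1)] <- (b[3:n] - b[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  data.frame(t = t, b_N = b, speed = speed)
}

#' Tabulate front reports over a trajectory
#'
#' One row per recorded output time; serializes with
#' [utils::write.table()] or [data.table::fwrite()].
#'
#' @param trajectory A `gb_trajectory`.
#' @param params Optional [model_params()]; defaults to
#'   `trajectory$params`.
#' @return `data.frame` with the scalar report fields plus per-species peak
#'   positions.
#' @export
front_report_table <- function(trajectory, params = NULL) {
  stopifnot(inherits(trajectory, "gb_trajectory"))
  if (is.null(params)) params <- trajectory$params
  rows <- lapply(trajectory$states, function(s) {
    r <- front_report(s, params)
    data.frame(t = r$time, b_N = r$b_N, front_width = r$front_width,
               peak_N = r$peaks[["N"]], peak_P = r$peaks[["P"]],
               peak_E = r$peaks[["E"]], peak_A = r$peaks[["A"]],
               peak_I = r$peaks[["I"]],
               membrane_peak = r$membrane_peak,
               shift_P_membrane = r$shift_P_membrane,
               mmp_outer_front = r$mmp_outer_front,
               n_components = r$n_components,
               plateau_cv = r$plateau_cv,
               exchange_peak = r$exchange_peak)
  })
  do.call(rbind, rows)
}
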