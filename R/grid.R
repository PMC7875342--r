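#' Uniform one-dimensional spatial grid
#'
#' The tissue slab is the interval \eqn{\Omega = [0, b_\Omega]}, sampled on
#' `n_nodes` equispaced nodes. All model fields live on these nodes; fluxes
#' are evaluated on the faces between them.
#'
#' @param b_omega Domain length (dimensionless length units; one unit is the
#'   full slab).
#' @param n_nodes Number of nodes, at least 8. The default 500 is the
#'   resolution used by the shipped scenarios.
#' @return An object of class `gb_grid` with elements `b_omega`, `n_nodes`,
#'   `x` (node positions, `x[1] = 0`, `x[n] = b_omega`) and `dx`.
#' @examples
#' g <- grid1d(1, 101)
#' g$dx
#' @export
grid1d <- function(b_omega = 1, n_nodes = 500L) {
  if (!is.numeric(b_omega) || length(b_omega) != 1L || !is.finite(b_omega) ||
      b_omega <= 0)
    stop("b_omega must be a positive finite scalar")
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 8L)
    stop("n_nodes must be an integer >= 8")
  x <- seq(0, b_omega, length.out = n_nodes)
  structure(list(b_omega = b_omega, n_nodes = n_nodes, x = x,
                 dx = b_omega / (n_nodes - 1)),
            class = "gb_grid")
}

#' @export
print.gb_grid <- function(x, ...) {
  cat(sprintf("<gb_grid> [0, %g], %d nodes, dx = %g\n",
              x$b_omega, x$n_nodes, x$dx))
  invisible(x)
}

.check_grid <- function(grid) {
  if (!inherits(grid, "gb_grid")) stop("grid must be a gb_grid object")
  grid
}

.check_field <- function(u, grid, name = deparse(substitute(u)),
                         nonneg = TRUE) {
  if (!is.numeric(u) || length(u) != grid$n_nodes)
    stop(sprintf("field '%s' must be numeric of length n_nodes = %d",
                 name, grid$n_nodes))
  if (anyNA(u) || any(!is.finite(u)))
    stop(sprintf("invalid field '%s': non-finite entries", name))
  if (nonneg && any(u < 0))
    stop(sprintf("invalid field '%s': negative entries", name))
  u
}

# ---- regions ----------------------------------------------------------------

#' Intervals on the spatial domain
#'
#' A region is an ordered set of disjoint closed intervals within
#' \eqn{[0, b_\Omega]}, used for the tumor support `Sup(N)`, the
#' tumor-microtube band `L_TM`, and the characteristic functions gating the
#' reaction terms.
#'
#' @param lo,hi Interval endpoints (vectors of equal length allowed).
#' @param b_omega Optional domain length used to clip the intervals.
#' @return A `gb_region` object; `region_empty()` returns the empty region.
#' @seealso [region_indicator()], [tumor_support()], [tm_region()]
#' @export
region <- function(lo, hi, b_omega = NULL) {
  if (length(lo) != length(hi)) stop("lo and hi must have equal length")
  if (length(lo) == 0L) return(region_empty())
  if (any(hi < lo)) stop("region intervals need hi >= lo")
  if (!is.null(b_omega)) {
    lo <- pmax(pmin(lo, b_omega), 0)
    hi <- pmax(pmin(hi, b_omega), 0)
  }
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (length(lo) > 1L && any(lo[-1] < hi[-length(hi)]))
    stop("region intervals must be non-overlapping")
  structure(list(intervals = cbind(lo = lo, hi = hi)), class = "gb_region")
}

#' @rdname region
#' @export
region_empty <- function() {
  structure(list(intervals = cbind(lo = numeric(0), hi = numeric(0))),
            class = "gb_region")
}

#' @rdname region
#' @param r A `gb_region`.
#' @export
is_region_empty <- function(r) {
  stopifnot(inherits(r, "gb_region"))
  nrow(r$intervals) == 0L
}

#' Evaluate the indicator of a region on the grid nodes
#'
#' Sharp (unmollified) evaluation: 1 at nodes inside any interval (endpoints
#' included), 0 elsewhere.
#'
#' @param r A `gb_region`.
#' @param grid A [grid1d()] object.
#' @return Numeric 0/1 vector of length `n_nodes`.
#' @export
region_indicator <- function(r, grid) {
  stopifnot(inherits(r, "gb_region"))
  .check_grid(grid)
  out <- numeric(grid$n_nodes)
  iv <- r$intervals
  for (k in seq_len(nrow(iv)))
    out[grid$x >= iv[k, 1] & grid$x <= iv[k, 2]] <- 1
  out
}

#' @export
print.gb_region <- function(x, ...) {
  if (is_region_empty(x)) cat("<gb_region> empty\n")
  else cat("<gb_region>",
           paste(sprintf("[%g, %g]", x$intervals[, 1], x$intervals[, 2]),
                 collapse = " U "), "\n")
  invisible(x)
}

# union of two regions known to be adjacent or disjoint (Sup(N) and L_TM
# share only the point b_N); indicator capped at 1 via merging.
.region_union <- function(r1, r2) {
  iv <- rbind(r1$intervals, r2$intervals)
  if (nrow(iv) == 0L) return(region_empty())
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  lo <- iv[1, 1]; hi <- iv[1, 2]
  los <- c(); his <- c()
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= hi) hi <- max(hi, iv[k, 2])
    else { los <- c(los, lo); his <- c(his, hi); lo <- iv[k, 1]; hi <- iv[k, 2] }
  }
  region(c(los, lo), c(his, hi))
}

# ---- tumor support and TM band ----------------------------------------------

#' Locate the tumor support \eqn{Sup(N) = [0, b_N]}
#'
#' The front edge `b_N` is the rightmost position at which `N` crosses the
#' detection threshold `delta_N`, with linear interpolation between nodes.
#' This makes front tracking robust to floating-point noise at the foot of
#' the sharp profiles produced by flux-limited transport.
#'
#' @param N Tumor density field (nonnegative, length `n_nodes`).
#' @param delta_N Detection threshold, `0 < delta_N < K_N`. The shipped
#'   default is `1e-3 * K_N`.
#' @param grid A [grid1d()] object.
#' @return A `gb_region`, `[0, b_N]`; the empty region when
#'   `max(N) < delta_N`.
#' @examples
#' g <- grid1d(1, 201)
#' N <- pmax(0, 1 - g$x / 0.6)
#' tumor_support(N, 0.1, g) # b_N = 0.54
#' @export
tumor_support <- function(N, delta_N, grid) {
  .check_grid(grid)
  .check_field(N, grid, "N")
  if (!is.numeric(delta_N) || delta_N <= 0)
    stop("delta_N must be a positive scalar")
  if (max(N) < delta_N) return(region_empty())
  idx <- max(which(N >= delta_N))
  if (idx == grid$n_nodes) {
    b_N <- grid$b_omega
  } else {
    # N[idx] >= delta_N > N[idx + 1]: interpolate the crossing
    b_N <- grid$x[idx] +
      grid$dx * (N[idx] - delta_N) / (N[idx] - N[idx + 1])
  }
  region(0, b_N, b_omega = grid$b_omega)
}

#' Tumor-microtube band ahead of the front
#'
#' The TM band collects every point reachable from the support edge by a
#' microtube of length at most `h_p`:
#' \eqn{L_{TM} = [b_N, \min(b_N + h_p, b_\Omega)]}.
#'
#' @param support Tumor support region from [tumor_support()].
#' @param h_p Maximum microtube length (length units).
#' @param grid A [grid1d()] object.
#' @return A `gb_region`; empty if the support is empty.
#' @export
tm_region <- function(support, h_p, grid) {
  stopifnot(inherits(support, "gb_region"))
  .check_grid(grid)
  if (h_p < 0) stop("h_p must be nonnegative")
  if (is_region_empty(support)) return(region_empty())
  b_N <- max(support$intervals[, 2])
  region(b_N, min(b_N + h_p, grid$b_omega))
}

# ---- model state ------------------------------------------------------------

#' Bundle the five model fields at one time point
#'
#' @param t Time (hours).
#' @param N,P,E,A,I Tumor density, MMP1 concentration, ECM density, active
#'   and inactive integrin fields, all nonnegative and sampled on `grid`.
#' @param grid A [grid1d()] object.
#' @return A `gb_state` object.
#' @export
new_state <- function(t, N, P, E, A, I, grid) {
  .check_grid(grid)
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  st <- structure(list(t = t,
                       N = .check_field(N, grid, "N"),
                       P = .check_field(P, grid, "P"),
                       E = .check_field(E, grid, "E"),
                       A = .check_field(A, grid, "A"),
                       I = .check_field(I, grid, "I"),
                       grid = grid),
                  class = "gb_state")
  st
}

#' @export
print.gb_state <- function(x, ...) {
  cat(sprintf("<gb_state> t = %g h on %d nodes; max N = %.4g, max P = %.4g\n",
              x$t, x$grid$n_nodes, max(x$N), max(x$P)))
  invisible(x)
}
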