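# shared fixtures: everything is built in code at test time

tiny_grid <- function(n = 101L, b = 1) grid1d(b, n)

# uniform state with optional overrides, for single-step contract checks
uniform_state <- function(grid, N = 1, P = 0.1, E = 1, A = 0.2, I = 0.8,
                          t = 0) {
  n <- grid$n_nodes
  new_state(t, rep(N, n), rep(P, n), rep(E, n), rep(A, n), rep(I, n), grid)
}

# random nonnegative field with a fixed seed
random_field <- function(grid, seed, scale = 1) {
  set.seed(seed)
  scale * abs(rnorm(grid$n_nodes))
}

# brute-force moving-window trapezoid integral of N over [x-h, x+h],
# truncated at the domain: the independent oracle for activity_functional
brute_window_mass <- function(N, h, grid) {
  vapply(seq_len(grid$n_nodes), function(i) {
    lo <- max(grid$x[i] - h, 0)
    hi <- min(grid$x[i] + h, grid$b_omega)
    xs <- sort(unique(c(lo, hi, grid$x[grid$x > lo & grid$x < hi])))
    ys <- approx(grid$x, N, xs)$y
    sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  }, numeric(1))
}
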