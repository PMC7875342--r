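test_that("activity functional matches closed forms and is monotone", {
  g <- tiny_grid(201)
  hp <- 0.06; eps <- 0.1; alpha <- 1.5
  # empty tissue: F collapses to the regularization cap everywhere
  expect_equal(activity_functional(rep(0, 201), hp, eps, alpha, g),
               rep(eps^(-alpha), 201))
  # constant density, interior nodes with a full window: analytic value
  Fc <- activity_functional(rep(0.7, 201), hp, eps, alpha, g)
  interior <- g$x >= hp & g$x <= 1 - hp
  expect_equal(Fc[interior],
               rep((2 * hp * 0.7 + eps)^(-alpha), sum(interior)),
               tolerance = 1e-10)
  # truncated windows at the boundary hold less mass, so F is larger there
  expect_true(all(Fc[!interior] >= max(Fc[interior]) - 1e-12))
  # agrees with a brute-force windowed trapezoid oracle
  N <- random_field(g, 11)
  Fv <- activity_functional(N, hp, eps, alpha, g)
  F_oracle <- (brute_window_mass(N, hp, g) + eps)^(-alpha)
  expect_equal(Fv, F_oracle, tolerance = 5e-3)
  # pointwise increase of N never increases F
  for (s in 1:5) {
    N1 <- random_field(g, s)
    N2 <- N1 + random_field(g, s + 100, scale = 0.5)
    expect_true(all(activity_functional(N2, hp, eps, alpha, g) <=
                    activity_functional(N1, hp, eps, alpha, g) + 1e-14))
  }
  expect_error(activity_functional(N, hp, 0, alpha, g), "eps_F")
})

test_that("flux-saturated transport is speed-bounded and porous-medium-like at small gradients", {
  nu <- 0.01; m <- 0.5; v <- 0.03
  u <- abs(rnorm(100, 1))
  expect_equal(flux_saturated(u, rep(0, 100), nu, m, v), rep(0, 100))
  # |J| <= v * u for arbitrary gradients, approached as |du| grows
  for (s in 1:5) {
    set.seed(s)
    du <- rnorm(100, 0, 10^s)
    J <- flux_saturated(u, du, nu, m, v)
    expect_true(all(abs(J) <= v * u + 1e-14))
  }
  J_steep <- flux_saturated(1, 1e9, nu, m, v)
  expect_equal(J_steep, v, tolerance = 1e-6)
  # Taylor regime: J = (nu/m) u du + O(du^3), within 1% for small gradients
  du_small <- seq(-0.1, 0.1, length.out = 21) * m / (nu / v)
  J_small <- flux_saturated(1, du_small, nu, m, v)
  J_pm <- (nu / m) * du_small
  rel <- abs(J_small - J_pm) / pmax(abs(J_pm), 1e-300)
  expect_true(all(rel[du_small != 0] < 0.01))
  expect_error(flux_saturated(u, rep(0, 100), -1, m, v), "positive")
})

test_that("taxis flux saturates at a*u/2 and shuts down on discontinuities", {
  u <- c(0.5, 1, 2)
  expect_equal(taxis_flux(u, rep(0, 3), 0.4), rep(0, 3))
  expect_equal(taxis_flux(u, rep(1, 3), 0.4), 0.4 * u / 2)
  set.seed(2)
  s <- rnorm(200, 0, 5)
  J <- taxis_flux(rep(1, 200), s, 0.4)
  expect_true(all(abs(J) <= 0.4 / 2 + 1e-14))
  expect_lt(abs(taxis_flux(1, 1e8, 0.4)), 1e-7)
})

test_that("logistic growth has the textbook fixed points and vertex", {
  expect_equal(logistic_growth(0, 0.3, 1), 0)
  expect_equal(logistic_growth(1, 0.3, 1), 0)
  expect_equal(logistic_growth(0.5, 0.3, 1), 0.3 / 4)
})

test_that("MMP1 reaction gates production to the TM band", {
  g <- tiny_grid(101)
  tm <- region(0.5, 0.6)
  n <- g$n_nodes
  # direct evaluation at a node inside the band
  r <- mmp_reaction(P = rep(1, n), N = rep(0.5, n), E = rep(1, n),
                    F = rep(2, n), tm = tm, a4 = 0.3, a5 = 0.1, grid = g)
  inside <- region_indicator(tm, g) == 1
  expect_equal(unique(r[inside]), 0.3 * 2 - 0.1 * 0.5)
  # outside the band with no tumor: nothing happens
  r0 <- mmp_reaction(rep(1, n), rep(0, n), rep(1, n), rep(2, n), tm,
                     0.3, 0.1, g)
  expect_equal(unique(r0[!inside]), 0)
  # inside the band with no matrix left: pure degradation
  r1 <- mmp_reaction(rep(1, n), rep(0.5, n), rep(0, n), rep(2, n), tm,
                     0.3, 0.1, g)
  expect_equal(unique(r1[inside]), -0.1 * 0.5)
})

test_that("ECM rate relaxes to the basal floor inside the support", {
  g <- tiny_grid(101)
  sup <- region(0, 0.4)
  n <- g$n_nodes
  expect_equal(ecm_rate(rep(1, n), rep(0, n), 1, 0.15, sup, g), rep(0, n))
  # at the floor inside the support the rate vanishes
  r <- ecm_rate(rep(0.15, n), rep(1, n), 1, 0.15, sup, g)
  inside <- region_indicator(sup, g) == 1
  expect_equal(unique(r[inside]), 0)
  # outside the support the form reduces to plain proteolysis
  expect_equal(unique(r[!inside]), -1 * 0.15 * 1)
})

test_that("integrin exchange conserves total pool up to exocytosis", {
  g <- tiny_grid(101)
  p <- model_params()
  sup <- region(0, 0.4)
  tm <- tm_region(sup, p$h_p, g)
  for (s in 1:5) {
    A <- random_field(g, s, 0.5)
    I <- random_field(g, s + 10, 0.5)
    E <- random_field(g, s + 20, 0.8)
    Fv <- activity_functional(random_field(g, s + 30), p$h_p, p$eps_F,
                              p$alpha_F, g)
    r <- integrin_rates(A, I, E, Fv, sup, tm, p, g)
    chi_u <- region_indicator(gbfront:::.region_union(sup, tm), g)
    expect_equal(r$dA + r$dI, p$a9 * (p$K_I - A - I) * chi_u,
                 tolerance = 1e-14)
  }
  # at saturation the exocytosis vanishes and only exchange remains
  A <- rep(0.3, g$n_nodes); I <- rep(p$K_I - 0.3, g$n_nodes)
  r <- integrin_rates(A, I, rep(1, g$n_nodes), rep(1, g$n_nodes),
                      sup, tm, p, g)
  expect_equal(r$dA + r$dI, rep(0, g$n_nodes), tolerance = 1e-14)
  # no matrix and outside the support: no activation, no inactivation
  r0 <- integrin_rates(A, I, rep(0, g$n_nodes), rep(1, g$n_nodes),
                       region_empty(), region_empty(), p, g)
  expect_equal(r0$dA, rep(0, g$n_nodes))
})

test_that("integrin transport is exact on linear profiles and upwinded", {
  g <- tiny_grid(101)
  u_const <- rep(2, 101)
  expect_equal(integrin_transport(u_const, 0.05, g), rep(0, 101))
  expect_equal(integrin_transport(g$x, 0, g), rep(0, 101))
  s <- 1.7
  u_lin <- 5 + s * g$x
  # literal printed sign +v u_x: rate v*s at every node (one-sided at ends)
  expect_equal(integrin_transport(u_lin, 0.05, g, "toward_bulk"),
               rep(0.05 * s, 101), tolerance = 1e-12)
  # front-directed orientation advects in +x: rate -v u_x
  expect_equal(integrin_transport(u_lin, 0.05, g, "toward_front"),
               rep(-0.05 * s, 101), tolerance = 1e-12)
})

test_that("porosity-velocity map spans the 50-66% porosity band", {
  n <- 51
  # intact matrix = 50% porosity = slowest front
  expect_equal(porosity_velocity(rep(1, n), 1, v_min = 0.03, v_max = 0.045),
               rep(0.03, n))
  # fully degraded matrix = 66% porosity = fastest front
  expect_equal(porosity_velocity(rep(0, n), 1, v_min = 0.03, v_max = 0.045),
               rep(0.045, n))
  # monotone non-decreasing in porosity (non-increasing in E)
  E <- seq(1, 0, length.out = n)
  v <- porosity_velocity(E, 1, v_min = 0.03, v_max = 0.045)
  expect_true(all(diff(v) >= -1e-14))
  expect_warning(porosity_velocity(c(1.5, 0.5), 1, v_min = 1, v_max = 2),
                 "clipping")
})
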