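test_that("divergence is conservative and rejects boundary flux", {
  g <- tiny_grid(101)
  n <- g$n_nodes
  # constant interior flux: zero divergence away from the walls
  flux <- c(0, rep(0.3, n - 1), 0)
  d <- divergence(flux, g)
  expect_equal(d[2:(n - 1)], rep(0, n - 2))
  # telescoping: grid sum vanishes for any admissible flux
  set.seed(4)
  for (s in 1:5) {
    f <- c(0, rnorm(n - 1), 0)
    expect_equal(sum(divergence(f, g)), 0, tolerance = 1e-12)
  }
  # linear interior flux profile: constant divergence in the interior
  flin <- c(0, 2 * seq_len(n - 1), 0)
  dlin <- divergence(flin, g)
  expect_equal(diff(dlin[2:(n - 1)]), rep(0, n - 3), tolerance = 1e-10)
  expect_error(divergence(rep(1, n + 1), g), "contract violation")
})

test_that("tumor step is a fixed point on homogeneous states and conserves mass", {
  g <- tiny_grid(101)
  p <- model_params()
  cfg <- solver_config(dt = 1e-3, t_end = 1)
  # homogeneous state at carrying capacity: no gradients, no growth
  st <- uniform_state(g, N = p$K_N)
  expect_equal(step_tumor(st, p, cfg), rep(p$K_N, g$n_nodes),
               tolerance = 1e-13)
  # without proliferation the discretization conserves mass exactly
  p0 <- model_params(a3 = 0)
  st2 <- baseline_initial(scenario_spec(bulk_extent = 0.4), p0, g)
  mass0 <- sum(st2$N)
  u <- st2$N
  for (k in 1:50) {
    st2 <- new_state(st2$t, u, st2$P, st2$E, st2$A, st2$I, g)
    u <- step_tumor(st2, p0, cfg)
  }
  expect_equal(sum(u), mass0, tolerance = 1e-10)
})

test_that("tumor step reduces to a reference backward-Euler diffusion solve", {
  # saturation pushed out of reach and taxis off: the IMEX step must agree
  # with an independently assembled dense backward-Euler solve of the same
  # linear diffusion operator
  g <- tiny_grid(64)
  n <- g$n_nodes
  p <- model_params(a1 = 0, a2 = 0, a3 = 0, v_N = 1e9, nu_N = 0.01, m_N = 1)
  cfg <- solver_config(dt = 1e-3, t_end = 1)
  st <- baseline_initial(scenario_spec(bulk_extent = 0.4), p, g)
  got <- step_tumor(st, p, cfg)
  Dface <- p$nu_N * gbfront:::.face_interp(st$N) / p$m_N
  A <- diag(n)
  r <- cfg$dt / g$dx^2
  for (i in seq_len(n)) {
    if (i > 1) A[i, i - 1] <- A[i, i - 1] - r * Dface[i - 1]
    if (i < n) A[i, i + 1] <- A[i, i + 1] - r * Dface[i]
    A[i, i] <- A[i, i] + r * ((if (i > 1) Dface[i - 1] else 0) +
                              (if (i < n) Dface[i] else 0))
  }
  ref <- solve(A, st$N)
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("MMP1 step respects its local fixed point and decay law", {
  g <- tiny_grid(101)
  cfg <- solver_config(dt = 1e-3, t_end = 1)
  # no tumor, no protease: nothing is created
  p <- model_params()
  st0 <- new_state(0, rep(0, 101), rep(0, 101), rep(1, 101), rep(0, 101),
                   rep(0, 101), g)
  expect_equal(step_mmp(st0, p, cfg), rep(0, 101))
  # immobile proteases (nu_P = 0): the local balance a4*E*F/(a5*N) is a
  # nodewise fixed point of the step inside the band, and iteration from
  # below approaches it monotonically
  p1 <- model_params(nu_P = 0, a4 = 0.05, a5 = 1, delta_N = 0.5)
  st <- baseline_initial(scenario_spec(bulk_extent = 0.4,
                                       shoulder_cells = 6), p1, g)
  aux <- gbfront:::.step_aux(st, p1)
  sel <- aux$chi_tm == 1 & st$N > 0.05
  expect_true(any(sel))
  target <- p1$a4 * st$E * aux$Fv * aux$chi_tm / (p1$a5 * pmax(st$N, 1e-12))
  Pfix <- ifelse(sel, target, 0)
  st_fix <- new_state(0, st$N, Pfix, st$E, st$A, st$I, g)
  expect_equal(step_mmp(st_fix, p1, cfg)[sel], Pfix[sel], tolerance = 1e-10)
  Pk <- rep(0, g$n_nodes)
  err <- abs(Pk - target)[sel]
  for (k in 1:500) {
    stk <- new_state(0, st$N, Pk, st$E, st$A, st$I, g)
    Pk <- step_mmp(stk, p1, cfg)
  }
  expect_true(all(abs(Pk - target)[sel] < err))
  # production off, homogeneous tumor: exponential decay in time
  p2 <- model_params(a4 = 0, a5 = 1, nu_P = 0.005)
  st2 <- uniform_state(g, N = 0.5, P = 1)
  Pk <- st2$P
  for (k in 1:1000) {
    stk <- new_state(0, st2$N, Pk, st2$E, st2$A, st2$I, g)
    Pk <- step_mmp(stk, p2, cfg)
  }
  expect_equal(unique(round(Pk, 12)), exp(-1 * 0.5 * 1),
               tolerance = 1e-3)
})

test_that("RK4 kinetics step hits classical order and conserves the integrin pool", {
  g <- tiny_grid(101)
  p <- model_params(v_Int = 0)
  # zero right-hand side: fields unchanged
  st <- new_state(0, rep(0, 101), rep(0, 101), rep(0.8, 101), rep(0, 101),
                  rep(0, 101), g)
  out <- step_others(st, model_params(a6 = 0, a7 = 0, a9 = 0, v_Int = 0),
                     solver_config(dt = 0.01, t_end = 1))
  expect_equal(out$E, st$E)
  # one RK4 step of dE/dt = -kE matches exp(-k dt) to O(dt^5)
  k <- 2; dt <- 0.05
  pE <- model_params(a6 = k, E_basal = 0, a7 = 0, a8 = 0, a9 = 0, v_Int = 0)
  stE <- uniform_state(g, N = 0, P = 1, E = 1, A = 0, I = 0)
  oE <- step_others(stE, pE, solver_config(dt = dt, t_end = 1))
  expect_equal(unique(oE$E), exp(-k * dt), tolerance = (k * dt)^5 / 50)
  # saturated integrin pool stays saturated without transport
  stI <- uniform_state(g, N = 0.5, P = 0.1, E = 1, A = 0.3, I = 0.7)
  oI <- step_others(stI, p, solver_config(dt = 0.01, t_end = 1))
  expect_equal(oI$A + oI$I, rep(1, 101), tolerance = 1e-13)
  # explicit advection guards its CFL limit
  pC <- model_params(v_Int = 10)
  expect_error(step_others(stI, pC, solver_config(dt = 0.01, t_end = 1)),
               "CFL")
})

test_that("simulation is deterministic and static states stay static", {
  g <- tiny_grid(64)
  p <- model_params()
  cfg <- solver_config(dt = 2e-3, t_end = 0.1, output_times = c(0, 0.1))
  # empty domain: every gated source is off, nothing moves
  st0 <- new_state(0, rep(0, 64), rep(0, 64), rep(1, 64), rep(0, 64),
                   rep(0, 64), g)
  tr0 <- simulate_front(st0, p, cfg)
  s_end <- tr0$states[[2]]
  expect_equal(s_end$N, st0$N)
  expect_equal(s_end$P, st0$P)
  expect_equal(s_end$E, st0$E)
  # two identical runs are bit-identical
  st <- baseline_initial(scenario_spec(), p, g)
  tr1 <- simulate_front(st, p, cfg)
  tr2 <- simulate_front(st, p, cfg)
  expect_identical(tr1$states[[2]], tr2$states[[2]])
})

test_that("stability report computes advisory CFL limits", {
  g <- tiny_grid(101)
  cfg <- solver_config(dt = 1e-3, t_end = 1)
  rep0 <- check_stability(model_params(v_Int = 0), cfg, g)
  expect_equal(rep0$dt_limit_v_Int, Inf)
  expect_true(rep0$ok)
  # v_Int * dt / dx = 2: hard fail
  v_bad <- 2 * g$dx / cfg$dt
  rep_bad <- check_stability(model_params(v_Int = v_bad), cfg, g)
  expect_false(rep_bad$ok)
  # halving dx halves the advective limit
  g2 <- grid1d(1, 201)
  p <- model_params()
  r1 <- check_stability(p, cfg, g)
  r2 <- check_stability(p, cfg, g2)
  expect_equal(r2$dt_limit_v_Int / r1$dt_limit_v_Int, g2$dx / g$dx,
               tolerance = 1e-12)
})
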