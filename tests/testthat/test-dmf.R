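test_that("transfer function handles the removable singularity and limits", {
  # at threshold the rate is exactly 1/d (6.25 Hz for d_E = 0.16)
  expect_equal(transfer_rate(125 / 310, 310, 125, 0.16), 1 / 0.16)
  # canonical excitatory parameters at I = 0.382 nA
  expect_equal(transfer_rate(0.382, 310, 125, 0.16), 3.526895,
               tolerance = 1e-6)
  # linear asymptote: r / (aI - b) -> 1 for large drive
  x <- 310 * 2 - 125
  expect_equal(transfer_rate(2, 310, 125, 0.16) / x, 1, tolerance = 1e-10)
  # monotone increasing and non-negative over a wide range
  I <- seq(-1, 2, by = 0.01)
  r <- transfer_rate(I, 310, 125, 0.16)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0))
  # continuity across the singularity
  eps <- 1e-8
  expect_equal(transfer_rate(125 / 310 + eps, 310, 125, 0.16),
               transfer_rate(125 / 310 - eps, 310, 125, 0.16),
               tolerance = 1e-5)
})

test_that("noise-free dynamics hold the single-node fixed point", {
  c1 <- connectome(matrix(0, 1, 1))
  p <- dmf_params(G = 0, sigma = 0)
  ss <- bf_node_steady_state(1, p)
  st <- list(S_E = ss$S_E, S_I = ss$S_I)
  for (k in 1:5) {
    st2 <- dmf_step(st, c1, p, J = 1)
    expect_equal(st2$S_E, st$S_E, tolerance = 1e-8)
    expect_equal(st2$S_I, st$S_I, tolerance = 1e-8)
    st <- st2
  }
})

test_that("noise-free trajectories match an RK4 reference at t = 1 s", {
  set.seed(4)
  W <- matrix(0, 3, 3)
  W[upper.tri(W)] <- c(0.8, 0.3, 0.5)
  c3 <- toy_connectome(W + t(W))
  p <- dmf_params(G = 0.5, sigma = 0)
  J <- c(1.0, 1.2, 0.9)
  s0 <- list(S_E = c(0.1, 0.3, 0.2), S_I = c(0.05, 0.1, 0.15))
  sim <- simulate_dmf(c3, p, J, duration = 1, transient = 0.5, state = s0)
  ref <- bf_dmf_rk4(s0$S_E, s0$S_I, unclass(c3), J, p, t_ms = 1000, dt = 0.01)
  expect_lt(max(abs(sim$S_E - ref$S_E)), 1e-4)
  expect_lt(max(abs(sim$S_I - ref$S_I)), 1e-4)
})

test_that("simulations are reproducible and respect the gating bounds", {
  c2 <- toy_connectome(c(0.5), n = 2)
  p <- dmf_params(G = 0.3)
  s1 <- simulate_dmf(c2, p, J = c(1, 1), duration = 2, transient = 1,
                     record_dt = 10, seed = 99)
  s2 <- simulate_dmf(c2, p, J = c(1, 1), duration = 2, transient = 1,
                     record_dt = 10, seed = 99)
  expect_identical(s1$r_E, s2$r_E)
  expect_identical(s1$activity, s2$activity)
  expect_true(all(s1$activity >= 0 & s1$activity <= 1))
  # huge noise: clipping keeps the state in [0, 1]
  pn <- dmf_params(G = 0, sigma = 5)
  sn <- simulate_dmf(c2, pn, J = c(1, 1), duration = 0.5, transient = 0.1,
                     record_dt = 1, seed = 1)
  expect_true(all(sn$activity >= 0 & sn$activity <= 1))
  expect_true(any(sn$activity == 1) || any(sn$activity == 0))
})

test_that("identical decoupled nodes produce identical deterministic rates", {
  c2 <- connectome(matrix(0, 4, 4))
  p <- dmf_params(G = 0, sigma = 0)
  sim <- simulate_dmf(c2, p, J = rep(1.1, 4), duration = 3, transient = 1)
  expect_equal(max(sim$r_E) - min(sim$r_E), 0, tolerance = 1e-12)
})

test_that("raising J lowers a node's deterministic firing rate", {
  c1 <- connectome(matrix(0, 1, 1))
  p <- dmf_params(G = 0, sigma = 0)
  r <- vapply(c(0.8, 1.0, 1.3, 1.8), function(J)
    simulate_dmf(c1, p, J, duration = 6, transient = 5)$r_E, 0)
  expect_true(all(diff(r) < 0))
})

test_that("dimension mismatches and bad durations error cleanly", {
  c2 <- toy_connectome(c(0.5), n = 2)
  expect_error(simulate_dmf(c2, J = c(1, 1, 1), duration = 1, transient = 0),
               "one entry per region")
  expect_error(simulate_dmf(c2, duration = 1, transient = 2), "exceed")
  expect_error(dmf_step(list(S_E = 0.1, S_I = 0.1), c2, dmf_params(),
                        J = c(1, 1)), "dimension")
})
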