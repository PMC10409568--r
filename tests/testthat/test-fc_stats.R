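mk_fc <- function(m, cond = "healthy") fc_matrix(m, condition = cond)

rand_fc <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * 30), n)
  fc_from_bold(x)
}

test_that("paired edge t-test matches the closed-form formula", {
  set.seed(12)
  n <- 4
  fcs_a <- lapply(1:4, function(s) rand_fc(n, s))
  fcs_b <- lapply(1:4, function(s) rand_fc(n, s + 100))
  cmp <- paired_edge_ttest(fcs_a, fcs_b)
  # hand computation for one edge on Fisher-z values
  za <- sapply(fcs_a, function(m) atanh(m[1, 2]))
  zb <- sapply(fcs_b, function(m) atanh(m[1, 2]))
  d <- zb - za
  t_manual <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(cmp$t_stat[1, 2], t_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value[1, 2],
               2 * pt(-abs(t_manual), df = 3), tolerance = 1e-12)
  # symmetric outputs, diagonal excluded
  expect_equal(cmp$t_stat, t(cmp$t_stat))
  expect_true(all(is.na(diag(cmp$q_value))))
  # identical conditions: all t = 0, empty mask
  cmp0 <- paired_edge_ttest(fcs_a, fcs_a)
  expect_true(all(cmp0$t_stat == 0))
  expect_false(any(cmp0$significant))
  expect_error(paired_edge_ttest(fcs_a[1:2], fcs_b[1:2]), "3 subjects")
})

test_that("BH correction behaves at its boundary and monotonically", {
  # all p equal and below alpha: every edge survives BH
  base <- matrix(0.1, 4, 4); diag(base) <- 1
  bump <- matrix(0.3, 4, 4); diag(bump) <- 1
  fcs_a <- lapply(1:5, function(s) mk_fc(base))
  fcs_b <- lapply(1:5, function(s) {
    m <- bump; m[1, 2] <- m[2, 1] <- 0.3 + 0.001 * s; mk_fc(m)
  })
  cmp <- paired_edge_ttest(fcs_a, fcs_b, alpha = 0.05)
  ut <- upper.tri(cmp$p_value)
  expect_true(all(cmp$significant[ut][cmp$p_value[ut] < 1e-6]))
  # BH mask grows monotonically with alpha
  set.seed(13)
  fcs_c <- lapply(1:5, function(s) rand_fc(6, s))
  fcs_d <- lapply(1:5, function(s) rand_fc(6, s + 50))
  masks <- lapply(c(0.01, 0.05, 0.2, 0.8), function(a)
    paired_edge_ttest(fcs_c, fcs_d, alpha = a)$significant)
  for (k in seq_len(length(masks) - 1))
    expect_true(all(masks[[k + 1]][masks[[k]]]))
  # and agrees with p.adjust on the upper triangle
  cmp2 <- paired_edge_ttest(fcs_c, fcs_d)
  expect_equal(cmp2$q_value[upper.tri(cmp2$q_value)],
               p.adjust(cmp2$p_value[upper.tri(cmp2$p_value)], "BH"))
})

test_that("graph metrics match brute-force oracles on small graphs", {
  # complete unweighted graph: transitivity 1, characteristic path length 1
  K5 <- matrix(1, 5, 5) - diag(5)
  gm <- fc_graph_metrics(K5)
  expect_equal(gm$transitivity, 1, tolerance = 1e-10)
  expect_equal(gm$char_path_length, 1, tolerance = 1e-10)
  expect_equal(gm$global_efficiency, 1, tolerance = 1e-10)
  # two disconnected equal cliques: modularity equals the exhaustive best
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 0.8; W[5:8, 5:8] <- 0.8; diag(W) <- 0
  gm2 <- fc_graph_metrics(W)
  expect_equal(gm2$modularity, bf_best_modularity(W), tolerance = 1e-10)
  # ring lattice n=8, k=2: distances from Floyd-Warshall
  R <- matrix(0, 8, 8)
  for (i in 1:8) {
    R[i, (i %% 8) + 1] <- 1
    R[(i %% 8) + 1, i] <- 1
  }
  gm3 <- fc_graph_metrics(R)
  D <- bf_distances(R)
  off <- D[upper.tri(D)]
  expect_equal(gm3$char_path_length, mean(off), tolerance = 1e-10)
  expect_equal(gm3$global_efficiency, mean(1 / off), tolerance = 1e-10)
  # weighted transitivity against the triple loop
  set.seed(14)
  Wr <- matrix(0, 7, 7)
  Wr[upper.tri(Wr)] <- runif(21) * rbinom(21, 1, 0.7)
  Wr <- Wr + t(Wr)
  expect_equal(fc_graph_metrics(Wr)$transitivity, bf_transitivity(Wr),
               tolerance = 1e-10)
  # negative weights are zeroed before analysis
  Wn <- Wr; Wn[1, 2] <- Wn[2, 1] <- -0.5
  Wz <- Wn; Wz[Wz < 0] <- 0
  expect_equal(fc_graph_metrics(Wn)$transitivity,
               fc_graph_metrics(Wz)$transitivity)
  # empty graph is flagged degenerate
  expect_true(fc_graph_metrics(matrix(0, 4, 4))$degenerate)
})

test_that("global coupling fit recovers a self-consistent target", {
  spec <- cohort_spec(n_subjects = 1, n_regions = 10, n_per_hemisphere = 5,
                      n_modules = 2, seed = 21)
  c10 <- generate_connectome(spec, 1)
  p <- dmf_params()
  # build the target as the simulated FC at G* = 0.4
  p_star <- p; p_star$G <- 0.4
  f <- fic(c10, p_star, seed = 31)
  sim <- simulate_dmf(c10, p_star, coef(f), duration = 60, transient = 10,
                      state = f$state, record_dt = 10, seed = 77)
  target <- fc_from_bold(bold_from_activity(sim, TR = 2, transient = 10))
  fit <- fit_global_coupling(c10, p, target, grid = c(0.2, 0.4, 0.6),
                             duration = 60, transient = 10, seed = 5)
  expect_equal(fit$G, 0.4)
  expect_equal(nrow(fit$fit), 3)
  expect_true(fit$fit$admissible[fit$fit$G == 0.4])
  # single-value grid returns that value when the band is satisfied
  fit1 <- fit_global_coupling(c10, p, target, grid = 0.4,
                              duration = 30, transient = 5, seed = 6)
  expect_equal(fit1$G, 0.4)
})
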