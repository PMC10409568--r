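test_that("connectome constructor enforces the matrix contract", {
  m <- matrix(c(0, 1, 1, 0), 2)
  expect_s3_class(connectome(m), "connectome")
  expect_error(connectome(matrix(0, 2, 3)), "square")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2)), "non-negative")
  expect_error(connectome(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(connectome(m, region_labels = "a"), "labels")
  # diagonal is forced to zero
  expect_equal(diag(connectome(diag(2) + m)), c(A = 0, B = 0),
               ignore_attr = TRUE)
})

test_that("TSV round trip preserves the connectome", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.5, 0, 1.25, 2, 0.125, 3)
  c0 <- connectome(w + t(w), region_labels = c("lA", "lB", "rA", "rB"),
                   hemisphere = c("L", "L", "R", "R"))
  path <- tempfile(fileext = ".tsv")
  write_connectome(c0, path)
  c1 <- read_connectome(path)
  expect_equal(unclass(c1), unclass(c0), tolerance = 1e-12)
  expect_identical(attr(c1, "hemisphere"), c("L", "L", "R", "R"))
  # malformed inputs are rejected
  writeLines(c("region\tA\tB", "A\t0\t-1", "B\t-1\t0"), path2 <- tempfile())
  expect_error(read_connectome(path2), "non-negative")
  writeLines(c("region\tA\tB", "A\t0\t1"), path3 <- tempfile())
  expect_error(read_connectome(path3), "square")
})

test_that("weighted Jaccard matches hand and brute-force evaluation", {
  # 4 regions: A-{C,D} weights (2,1); B-{C,D} weights (1,3)
  w <- matrix(0, 4, 4)
  w[1, 3] <- 2; w[1, 4] <- 1
  w[2, 3] <- 1; w[2, 4] <- 3
  c0 <- toy_connectome(w + t(w))
  jc <- jaccard_profile(c0, 1)
  expect_equal(as.numeric(jc[2]), (1 + 1) / (2 + 3))   # = 0.4
  expect_equal(as.numeric(jc[1]), 1)                   # self, by convention

  # identical neighbourhoods give 1, disjoint give 0
  w2 <- matrix(0, 4, 4)
  w2[1, 3] <- w2[2, 3] <- 1.5; w2[1, 4] <- w2[2, 4] <- 0.5
  expect_equal(as.numeric(jaccard_profile(toy_connectome(w2 + t(w2)), 1)[2]), 1)
  w3 <- matrix(0, 4, 4); w3[1, 3] <- 1; w3[2, 4] <- 1
  expect_equal(as.numeric(jaccard_profile(toy_connectome(w3 + t(w3)), 1)[2]), 0)

  # random instances up to 20 nodes: exact match with the double loop,
  # and symmetry in (A, B)
  set.seed(1)
  for (n in c(5, 11, 20)) {
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- rexp(n * (n - 1) / 2) * rbinom(n * (n - 1) / 2, 1, 0.6)
    cW <- toy_connectome(W + t(W))
    jm <- jaccard_matrix(cW)
    expect_equal(jm, bf_jaccard_matrix(unclass(cW)) + diag(0, n),
                 ignore_attr = TRUE, tolerance = 1e-14)
    expect_equal(jm, t(jm), ignore_attr = TRUE)
    a <- sample(n, 1)
    expect_equal(as.numeric(jaccard_profile(cW, a))[-a], jm[a, -a],
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
})

test_that("zero-strength reference yields a degenerate-profile warning", {
  w <- matrix(0, 4, 4); w[2, 3] <- 1
  c0 <- toy_connectome(w + t(w))
  expect_warning(jc <- jaccard_profile(c0, 1), "zero strength")
  expect_equal(as.numeric(jc[-1]), rep(0, 3))
})

test_that("SSA selection follows N = round(fraction * n) and the tie rule", {
  prof <- structure(c(0.3, 0.9, 0.5, 0.5, 0.1), reference = 1L,
                    class = "similarity_profile")
  names(prof) <- paste0("R", 1:5)
  # N = round(0.4 * 5) = 2; reference excluded; tie at 0.5 -> lower index
  sel <- select_ssa(prof, fraction = 0.4)
  expect_identical(as.integer(sel), c(2L, 3L))
  # a 68-region profile keeps 17 areas at the default fraction
  set.seed(2)
  prof68 <- structure(runif(68), reference = 5L,
                      class = "similarity_profile")
  expect_length(select_ssa(prof68), round(0.25 * 68))
  expect_length(select_ssa(prof68), 17L)
  expect_false(5L %in% as.integer(select_ssa(prof68)))
  # singleton when the fraction admits one region
  expect_identical(as.integer(select_ssa(prof, fraction = 0.2)), 2L)
})

test_that("virtual lesion zeroes exactly one row/column and is idempotent", {
  set.seed(3)
  W <- matrix(runif(64), 8); W <- W + t(W); diag(W) <- 0
  c0 <- connectome(W)
  les <- apply_lesion(c0, 3)
  expect_equal(unname(nodal_strength(les)[3]), 0)
  expect_equal(unclass(les)[-3, -3], unclass(c0)[-3, -3])
  expect_equal(unclass(apply_lesion(les, 3)), unclass(les))
  # neighbour strengths drop by exactly the lost edge weight
  drop <- unclass(c0)[, 3]
  drop[3] <- sum(unclass(c0)[3, ])
  expect_equal(nodal_strength(c0) - nodal_strength(les), drop,
               ignore_attr = TRUE)
  expect_error(apply_lesion(c0, 9), "out of range")
  # zero-strength node: lesion is a no-op on the weights
  W0 <- W; W0[5, ] <- W0[, 5] <- 0
  c5 <- connectome(W0)
  expect_equal(unclass(apply_lesion(c5, 5)), unclass(c5),
               ignore_attr = TRUE)
})

test_that("nodal strength and degree match independent summation", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 2.5; w[1, 3] <- 0.5; w[2, 4] <- 1
  c0 <- toy_connectome(w + t(w))
  expect_equal(as.numeric(nodal_strength(c0)), c(3, 3.5, 0.5, 1))
  expect_equal(nodal_degree(c0), c(2L, 2L, 1L, 1L))
  empty <- connectome(matrix(0, 3, 3))
  expect_equal(as.numeric(nodal_strength(empty)), rep(0, 3))
  expect_equal(nodal_degree(empty), rep(0L, 3))
  full <- connectome(matrix(1, 5, 5) - diag(5))
  expect_equal(nodal_degree(full), rep(4L, 5))
})
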