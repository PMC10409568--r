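# Independent oracles and fixture builders. Everything here is written
# directly from the model definitions (not from the package internals) so
# the tests compare two independent code paths.

# small symmetric weighted connectome from an upper-triangle specification
toy_connectome <- function(w_upper, n = NULL) {
  if (is.matrix(w_upper)) {
    m <- (w_upper + t(w_upper)) / 2
    diag(m) <- 0
    return(connectome(m))
  }
  stopifnot(!is.null(n))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w_upper
  m <- m + t(m)
  connectome(m)
}

# brute-force weighted Jaccard: explicit double loop over all third parties
bf_jaccard <- function(W, a, b) {
  n <- nrow(W)
  num <- den <- 0
  for (k in seq_len(n)) {
    if (k == a || k == b) next
    num <- num + min(W[a, k], W[b, k])
    den <- den + max(W[a, k], W[b, k])
  }
  if (den == 0) 0 else num / den
}

bf_jaccard_matrix <- function(W) {
  n <- nrow(W)
  out <- diag(n)
  for (a in seq_len(n)) for (b in seq_len(n))
    if (a != b) out[a, b] <- bf_jaccard(W, a, b)
  out
}

# right-hand side of the deterministic mean-field equations, written from
# the printed model (time in ms, rates in Hz)
bf_dmf_rhs <- function(S_E, S_I, W, J, p) {
  phi <- function(I, a, b, d) {
    x <- a * I - b
    ifelse(abs(x) < 1e-12, 1 / d, x / (1 - exp(-d * x)))
  }
  I_E <- p$w_E * p$I_0 + p$w_plus * p$J_N * S_E +
    p$G * p$J_N * as.numeric(W %*% S_E) - J * S_I
  I_I <- p$w_I * p$I_0 + p$J_N * S_E - p$w_II * S_I
  r_E <- phi(I_E, p$a_E, p$b_E, p$d_E)
  r_I <- phi(I_I, p$a_I, p$b_I, p$d_I)
  list(dS_E = -S_E / p$tau_E + (1 - S_E) * p$gamma * r_E / 1000,
       dS_I = -S_I / p$tau_I + r_I / 1000,
       r_E = r_E, I_E = I_E)
}

# classical RK4 reference integrator for the noise-free system
bf_dmf_rk4 <- function(S_E, S_I, W, J, p, t_ms, dt = 0.01) {
  n_steps <- round(t_ms / dt)
  for (i in seq_len(n_steps)) {
    k1 <- bf_dmf_rhs(S_E, S_I, W, J, p)
    k2 <- bf_dmf_rhs(S_E + dt / 2 * k1$dS_E, S_I + dt / 2 * k1$dS_I, W, J, p)
    k3 <- bf_dmf_rhs(S_E + dt / 2 * k2$dS_E, S_I + dt / 2 * k2$dS_I, W, J, p)
    k4 <- bf_dmf_rhs(S_E + dt * k3$dS_E, S_I + dt * k3$dS_I, W, J, p)
    S_E <- S_E + dt / 6 * (k1$dS_E + 2 * k2$dS_E + 2 * k3$dS_E + k4$dS_E)
    S_I <- S_I + dt / 6 * (k1$dS_I + 2 * k2$dS_I + 2 * k3$dS_I + k4$dS_I)
  }
  list(S_E = S_E, S_I = S_I)
}

# deterministic steady state of an isolated node for a given J, by damped
# fixed-point iteration on the printed steady-state equations
bf_node_steady_state <- function(J, p, iters = 5000) {
  S_E <- 0.15; S_I <- 0.05
  for (i in seq_len(iters)) {
    rhs <- bf_dmf_rhs(S_E, S_I, matrix(0, 1, 1), J, p)
    S_E_new <- p$gamma * rhs$r_E * p$tau_E / 1000 /
      (1 + p$gamma * rhs$r_E * p$tau_E / 1000)
    x <- p$a_I * (p$w_I * p$I_0 + p$J_N * S_E - p$w_II * S_I) - p$b_I
    r_I <- ifelse(abs(x) < 1e-12, 1 / p$d_I, x / (1 - exp(-p$d_I * x)))
    S_I_new <- p$tau_I / 1000 * r_I
    S_E <- S_E + 0.2 * (S_E_new - S_E)
    S_I <- S_I + 0.2 * (S_I_new - S_I)
  }
  rhs <- bf_dmf_rhs(S_E, S_I, matrix(0, 1, 1), J, p)
  list(S_E = S_E, S_I = S_I, r_E = rhs$r_E, I_E = rhs$I_E)
}

# brute-force shortest paths (Floyd-Warshall) on lengths 1/w
bf_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Newman weighted modularity of a given partition
bf_modularity <- function(W, membership) {
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + W[i, j] - k[i] * k[j] / m2
  q / m2
}

# best modularity over all partitions of <= 10 nodes (restricted growth
# string enumeration)
bf_best_modularity <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 10)
  best <- -Inf
  part <- integer(n)
  recurse <- function(i, maxg) {
    if (i > n) {
      q <- bf_modularity(W, part)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (g in seq_len(maxg + 1)) {
      part[i] <<- g
      recurse(i + 1, max(maxg, g))
    }
  }
  recurse(1, 0)
  best
}

# weighted transitivity: geometric-mean triangle intensity over connected
# triples, computed by explicit loops
bf_transitivity <- function(W) {
  n <- nrow(W)
  Wh <- (W / max(W))^(1 / 3)
  tri <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (i != j && j != k && i != k)
      tri <- tri + Wh[i, j] * Wh[j, k] * Wh[k, i]
  deg <- rowSums(W > 0)
  den <- sum(deg * (deg - 1))
  if (den == 0) NA_real_ else tri / den
}
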