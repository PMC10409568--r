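#' Parameters of the reduced dynamic mean-field model
#'
#' Each region holds one excitatory and one inhibitory population with
#' NMDA/GABA synaptic gating variables \eqn{S^{(E)}, S^{(I)}}. Input
#' currents are
#' \deqn{I_i^{(E)} = w_E I_0 + w_+ J_N S_i^{(E)}
#'       + G J_N \sum_j C_{ij} S_j^{(E)} - J_i S_i^{(I)},}
#' \deqn{I_i^{(I)} = w_I I_0 + J_N S_i^{(E)} - w_{II} S_i^{(I)},}
#' rates follow the sigmoidal f-I curve \code{\link{transfer_rate}}, and the
#' gating variables evolve as
#' \deqn{dS^{(E)}/dt = -S^{(E)}/\tau_E + (1 - S^{(E)})\gamma r^{(E)}
#'       + \sigma\nu(t),}
#' \deqn{dS^{(I)}/dt = -S^{(I)}/\tau_I + r^{(I)} + \sigma\nu(t),}
#' integrated with Euler-Maruyama at \code{dt} (default 1 ms) and clipped to
#' \code{[0, 1]}.
#'
#' Defaults are the canonical reduced two-population working point of the
#' mean-field literature this model class descends from: at rest each
#' region fires at ~3 Hz when the local inhibitory weight J is tuned by
#' feedback inhibition control (\code{\link{fic}}).
#'
#' @param w_E,w_I external-input scalings of the two populations.
#' @param I_0 effective external input (nA).
#' @param w_plus local excitatory recurrence.
#' @param J_N excitatory synaptic coupling (nA).
#' @param w_II local inhibitory recurrence.
#' @param G global coupling scaling long-range excitation. The default 0.5
#'   sits in the regime where, for max-normalized structural matrices, the
#'   homeostatically balanced low-firing state is stable under the default
#'   noise; fit it to data with \code{\link{fit_global_coupling}}.
#' @param a_E,b_E,d_E excitatory f-I gain (nC^-1), threshold (Hz), shape (s).
#' @param a_I,b_I,d_I inhibitory f-I parameters.
#' @param tau_E,tau_I synaptic time constants (ms).
#' @param gamma kinetic rate factor of the excitatory gating.
#' @param sigma noise amplitude (nA).
#' @param dt integration step (ms).
#' @return an object of class \code{"dmf_params"} (a validated list).
#' @export
dmf_params <- function(w_E = 1, w_I = 0.7, I_0 = 0.382, w_plus = 1.4,
                       J_N = 0.15, w_II = 1, G = 0.5,
                       a_E = 310, b_E = 125, d_E = 0.16,
                       a_I = 615, b_I = 177, d_I = 0.087,
                       tau_E = 100, tau_I = 10, gamma = 0.641,
                       sigma = 0.01, dt = 1) {
  p <- as.list(environment())
  for (f in c("tau_E", "tau_I", "a_E", "a_I", "d_E", "d_I", "dt"))
    if (p[[f]] <= 0) stop(f, " must be > 0")
  if (p$sigma < 0) stop("sigma must be >= 0")
  if (p$G < 0) stop("G must be >= 0")
  class(p) <- "dmf_params"
  p
}

#' @export
print.dmf_params <- function(x, ...) {
  cat("DMF parameters: G =", x$G, ", sigma =", x$sigma,
      ", dt =", x$dt, "ms\n")
  invisible(x)
}

#' Sigmoidal transfer (f-I) function
#'
#' \deqn{r(I) = \frac{aI - b}{1 - e^{-d(aI - b)}}}
#' with the removable singularity at \eqn{aI = b} filled by the limit
#' \eqn{1/d}. Non-negative and monotone increasing in I; asymptotically
#' linear with slope a for large input.
#'
#' @param I input current (nA); vectorized.
#' @param a gain (nC^-1).
#' @param b threshold (Hz).
#' @param d shape (s).
#' @return firing rate in Hz.
#' @export
transfer_rate <- function(I, a, b, d) {
  stopifnot(d > 0)
  x <- a * I - b
  r <- ifelse(abs(d * x) < 1e-9, 1 / d + x / 2, x / (1 - exp(-d * x)))
  as.numeric(r)
}

#' Initial state for the mean-field model
#'
#' @param n number of regions.
#' @param S_E,S_I initial gating values (recycled to length n).
#' @return list with elements \code{S_E}, \code{S_I}.
#' @export
dmf_state <- function(n, S_E = 0.1, S_I = 0.1) {
  list(S_E = rep_len(S_E, n), S_I = rep_len(S_I, n))
}

#' One Euler-Maruyama step of the network model
#'
#' Advances all regions' gating variables by one step of \code{p$dt} ms.
#' Exposed mainly for inspection and testing; simulations should use
#' \code{\link{simulate_dmf}}, which runs the same compiled loop.
#'
#' @param state list with \code{S_E}, \code{S_I} vectors.
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{dmf_params}}.
#' @param J per-region inhibitory weight vector (nA).
#' @return updated state list.
#' @export
dmf_step <- function(state, c, p, J) {
  stopifnot(is_connectome(c), inherits(p, "dmf_params"))
  n <- nrow(c)
  if (length(state$S_E) != n || length(state$S_I) != n ||
      length(J) != n)
    stop("state/J dimension does not match connectome (", n, " regions)")
  res <- .dmf_simulate_cpp(unclass(c), as.numeric(J), unclass(p),
                           as.numeric(state$S_E), as.numeric(state$S_I),
                           1L, 0L, 0L)
  list(S_E = as.numeric(res$S_E), S_I = as.numeric(res$S_I))
}

#' Simulate the mean-field network model
#'
#' Integrates the stochastic model for \code{duration} seconds of model
#' time at \code{p$dt} ms; summary statistics (mean excitatory and
#' inhibitory firing rates and mean excitatory input current per region)
#' are computed over the post-transient samples only. Reproducible given
#' the R RNG state (use \code{seed} or \code{set.seed()}).
#'
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{dmf_params}}.
#' @param J per-region inhibitory weights (nA); default 1 everywhere.
#' @param duration total simulated time (s).
#' @param transient initial span (s) excluded from summary statistics.
#' @param state optional initial state from \code{\link{dmf_state}}.
#' @param record_dt sampling interval (ms) for the stored excitatory gating
#'   trajectory; 0 (default) stores none. Recorded samples cover the whole
#'   run including the transient.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   first and the value recorded in the result.
#' @return an object of class \code{"dmf_sim"}: list with per-region
#'   \code{r_E}, \code{r_I} (Hz), \code{I_E} (nA), final \code{S_E},
#'   \code{S_I}, the thinned \code{activity} matrix (regions x samples, or
#'   NULL), and the run metadata.
#' @export
simulate_dmf <- function(c, p = dmf_params(), J = NULL,
                         duration = 600, transient = 120,
                         state = NULL, record_dt = 0, seed = NULL) {
  stopifnot(is_connectome(c), inherits(p, "dmf_params"))
  if (duration <= transient)
    stop("duration must exceed transient")
  n <- nrow(c)
  if (is.null(J)) J <- rep(1, n)
  if (length(J) != n) stop("J must have one entry per region")
  if (any(J <= 0)) stop("inhibitory weights J must be > 0")
  if (is.null(state)) state <- dmf_state(n)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration * 1000 / p$dt)
  transient_steps <- round(transient * 1000 / p$dt)
  record_every <- if (record_dt > 0) max(1L, round(record_dt / p$dt)) else 0L
  res <- .dmf_simulate_cpp(unclass(c), as.numeric(J), unclass(p),
                           as.numeric(state$S_E), as.numeric(state$S_I),
                           as.integer(n_steps), as.integer(transient_steps),
                           as.integer(record_every))
  labels <- attr(c, "region_labels")
  out <- list(r_E = stats::setNames(as.numeric(res$r_E), labels),
              r_I = stats::setNames(as.numeric(res$r_I), labels),
              I_E = stats::setNames(as.numeric(res$I_E), labels),
              S_E = as.numeric(res$S_E), S_I = as.numeric(res$S_I),
              activity = if (record_every > 0) res$activity else NULL,
              record_dt = if (record_every > 0) record_every * p$dt else NA,
              duration = duration, transient = transient,
              J = J, params = p, seed = seed)
  class(out) <- "dmf_sim"
  out
}

#' @export
print.dmf_sim <- function(x, ...) {
  cat("DMF simulation:", length(x$r_E), "regions,",
      x$duration, "s (", x$transient, "s transient )\n")
  cat(sprintf("  mean r_E %.2f Hz (range %.2f-%.2f)\n",
              mean(x$r_E), min(x$r_E), max(x$r_E)))
  invisible(x)
}
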