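#' Fit local inhibitory weights by feedback inhibition control (FIC)
#'
#' Recursive homeostat that tunes each region's local feedback inhibitory
#' weight \eqn{J_i} so that its excitatory population sits at the balanced
#' working point. The working point is a band on the excitatory input
#' current, \code{target +/- tol} (default -0.026 +/- 0.005 nA relative to
#' \eqn{b_E/a_E}), whose edges map through the f-I curve to mean
#' excitatory firing between 2.63 and 3.55 Hz. The model is simulated in
#' windows (default 10 s); after each window, regions whose mean firing
#' lies above the band's rate image get their \eqn{J_i} raised, regions
#' below get it lowered (floored at \code{J_min}), until every region
#' stays inside the band for a full window or the window budget is
#' exhausted. Compliance is measured on the window-mean \emph{rate}
#' (the image of the current band): with stochastic input the convex f-I
#' curve makes the mean rate sit slightly above the rate of the mean
#' current, and the printed firing band is the operational contract.
#'
#' The re-adjustment time of region i, \code{RT[i]}, is the simulated time
#' of the last window in which the region violated the band
#' (\code{window_length * last-violation index}; 0 for regions in band from
#' the first window onward).
#'
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{dmf_params}}.
#' @param J_init initial inhibitory weights (nA). The default (NULL) uses
#'   the analytic balance estimate \code{\link{fic_warm_start}}, which is
#'   exact at the deterministic fixed point; the windowed loop then only
#'   corrects the small stochastic offsets. For post-lesion runs pass the
#'   healthy fit's weights (\code{coef(healthy_fit)}), which is the
#'   protocol the three-condition analysis uses.
#' @param window window length (s); default 10.
#' @param budget maximum number of windows; default 200 (2000 s simulated).
#' @param step additive adjustment per window (nA). Each region keeps its
#'   own step size: it is multiplied by \code{grow} while the region's
#'   error keeps the same sign (1 = fixed steps, making a region's
#'   traversal time proportional to its total weight change) and by
#'   \code{shrink} when the error changes sign (bisecting into the band
#'   and damping collective oscillation).
#' @param step_min,step_max bounds on the per-region step (nA).
#' @param grow,shrink step multipliers on sign repeat / sign reversal.
#' @param target working point of \eqn{\bar I^{(E)} - b_E/a_E} (nA).
#' @param tol half-width of the tolerance band (nA).
#' @param inner fraction of \code{tol} defining the inner (convergence)
#'   band: regions are adjusted until they reach \code{target +/-
#'   inner*tol}, but re-adjustment times count violations of the full
#'   band only. The hysteresis parks converged weights centrally, so a
#'   later refit does not register spurious re-adjustments from regions
#'   left at the band edge.
#' @param J_min floor for the weights (nA).
#' @param exclude optional region indices exempt from the homeostat (not
#'   adjusted, not required for convergence, RT = 0): used for lesioned
#'   regions, which are disconnected and have no balance to restore.
#' @param state optional initial gating state.
#' @param seed optional integer seed (see \code{\link{simulate_dmf}}).
#' @return an object of class \code{"fic"} with components
#'   \code{J} (final weights, nA), \code{RT} (re-adjustment times, s),
#'   \code{converged} (per-region flags), \code{firing} (mean excitatory
#'   rate in the final window, Hz), \code{n_windows},
#'   \code{window_length}, \code{J_history} (weights after each window),
#'   \code{state} (final gating state, reusable as a warm start), and the
#'   fitting settings. \code{coef()} extracts \code{J}.
#' @export
fic <- function(c, p = dmf_params(), J_init = NULL,
                window = 10, budget = 200, step = 0.02,
                step_min = 0.001, step_max = 0.3, grow = 1.2,
                shrink = 0.5, target = -0.026, tol = 0.005,
                inner = 0.5, J_min = 0.001, exclude = NULL,
                state = NULL, seed = NULL) {
  stopifnot(is_connectome(c), inherits(p, "dmf_params"),
            window > 0, budget >= 1, tol > 0)
  n <- nrow(c)
  labels <- attr(c, "region_labels")
  if (is.null(J_init)) J_init <- fic_warm_start(c, p, target = target)
  if (length(J_init) != n) stop("J_init must have one entry per region")
  if (any(J_init <= 0)) stop("J_init must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) {
    bp <- balance_point(p, target)
    state <- dmf_state(n, bp$S_E, bp$S_I)
  }

  # images of the full and inner current bands under the f-I curve
  I_star <- p$b_E / p$a_E + target
  r_target <- transfer_rate(I_star, p$a_E, p$b_E, p$d_E)
  r_band <- transfer_rate(I_star + c(-tol, tol), p$a_E, p$b_E, p$d_E)
  r_inner <- transfer_rate(I_star + inner * c(-tol, tol),
                           p$a_E, p$b_E, p$d_E)

  J <- as.numeric(J_init)
  last_violation <- integer(n)      # 0 = never out of band
  J_history <- matrix(NA_real_, n, budget)
  firing <- rep(NA_real_, n)
  delta <- rep(step, n)
  prev_sign <- integer(n)
  converged_all <- FALSE
  w <- 0L
  while (w < budget) {
    w <- w + 1L
    sim <- simulate_dmf(c, p, J, duration = window, transient = 0,
                        state = state)
    state <- list(S_E = sim$S_E, S_I = sim$S_I)
    firing <- sim$r_E
    viol <- firing < r_band[1] | firing > r_band[2]
    adjust <- firing < r_inner[1] | firing > r_inner[2]
    viol[exclude] <- adjust[exclude] <- FALSE
    J_history[, w] <- J
    last_violation[viol] <- w
    if (!any(viol)) { converged_all <- TRUE; break }
    s <- sign(firing - r_target)
    delta <- ifelse(s == prev_sign, delta * grow, delta * shrink)
    delta <- pmin(pmax(delta, step_min), step_max)
    prev_sign <- s
    J <- ifelse(adjust, pmax(J + s * delta, J_min), J)
  }
  if (!converged_all)
    warning("FIC budget exhausted with ", sum(viol),
            " region(s) unconverged after ", budget, " windows")

  res <- list(J = stats::setNames(J, labels),
              RT = stats::setNames(last_violation * window, labels),
              converged = stats::setNames(
                firing >= r_band[1] & firing <= r_band[2] |
                  seq_len(n) %in% exclude, labels),
              firing = stats::setNames(as.numeric(firing), labels),
              n_windows = w, window_length = window,
              rate_band = r_band,
              J_history = J_history[, seq_len(w), drop = FALSE],
              state = state,
              settings = list(step = step, step_min = step_min,
                              step_max = step_max, grow = grow,
                              shrink = shrink, target = target, tol = tol,
                              inner = inner, J_min = J_min,
                              budget = budget),
              params = p, seed = seed)
  class(res) <- "fic"
  res
}

#' @export
print.fic <- function(x, ...) {
  cat("FIC fit:", length(x$J), "regions,", x$n_windows, "windows of",
      x$window_length, "s\n")
  cat(sprintf("  firing %.2f-%.2f Hz, J %.3f-%.3f nA, %d converged\n",
              min(x$firing), max(x$firing), min(x$J), max(x$J),
              sum(x$converged)))
  invisible(x)
}

#' @export
coef.fic <- function(object, ...) object$J

#' @export
summary.fic <- function(object, ...) {
  df <- data.frame(region = names(object$J), J = as.numeric(object$J),
                   RT = as.numeric(object$RT),
                   firing = as.numeric(object$firing),
                   converged = as.logical(object$converged))
  class(df) <- c("summary.fic", "data.frame")
  df
}

#' @export
plot.fic <- function(x, ...) {
  graphics::matplot(t(x$J_history), type = "l", lty = 1,
                    xlab = "window", ylab = "J (nA)",
                    main = "FIC weight trajectories", ...)
  invisible(x)
}

#' Analytic balance estimate of the inhibitory weights
#'
#' At the deterministic balanced fixed point every region carries the same
#' excitatory gating \eqn{S_E^*} (fixed by the target current through the
#' f-I curve) and the same inhibitory gating \eqn{S_I^*}, so the weight
#' that balances region i's inputs is available in closed form:
#' \deqn{J_i^* = \frac{w_E I_0 + w_+ J_N S_E^* + G J_N s_i S_E^* - I^*}
#'       {S_I^*},}
#' where \eqn{s_i} is region i's nodal strength and
#' \eqn{I^* = b_E/a_E + \mathrm{target}}. Used as the default warm start
#' of \code{\link{fic}}; the windowed loop corrects the residual
#' stochastic offsets (the noise shifts the effective means through the
#' nonlinearities).
#'
#' @inheritParams fic
#' @return numeric vector of per-region weights (nA), floored at 0.001.
#' @export
fic_warm_start <- function(c, p = dmf_params(), target = -0.026) {
  stopifnot(is_connectome(c), inherits(p, "dmf_params"))
  bp <- balance_point(p, target)
  s <- nodal_strength(c)
  J <- (p$w_E * p$I_0 + p$w_plus * p$J_N * bp$S_E +
          p$G * p$J_N * s * bp$S_E - bp$I_star) / bp$S_I
  pmax(as.numeric(J), 0.001)
}

# deterministic balanced working point: gating values at the target current
balance_point <- function(p, target = -0.026) {
  I_star <- p$b_E / p$a_E + target
  r_E <- transfer_rate(I_star, p$a_E, p$b_E, p$d_E)
  tau_E_s <- p$tau_E / 1000
  S_E <- p$gamma * r_E * tau_E_s / (1 + p$gamma * r_E * tau_E_s)
  tau_I_s <- p$tau_I / 1000
  S_I <- 0.05   # damped fixed point of S_I = tau_I * r_I(I_I(S_E*, S_I))
  for (k in 1:200) {
    I_I <- p$w_I * p$I_0 + p$J_N * S_E - p$w_II * S_I
    S_new <- tau_I_s * transfer_rate(I_I, p$a_I, p$b_I, p$d_I)
    if (abs(S_new - S_I) < 1e-12) break
    S_I <- S_I + 0.5 * (S_new - S_I)
  }
  list(S_E = S_E, S_I = S_I, I_star = I_star, r_E = r_E)
}

#' Post-lesion change in inhibitory weights
#'
#' \code{dJJ = J' - J}: the elementwise difference between the inhibitory
#' weights re-fitted after a lesion and the healthy weights. The lesioned
#' region's entry is undefined (it no longer participates in the network)
#' and is masked as \code{NA}.
#'
#' @param J_healthy healthy weights (nA).
#' @param J_lesioned post-lesion weights (nA), same length and order.
#' @param lesion index (or label, if the vectors are named) of the lesioned
#'   region.
#' @return an object of class \code{"weight_change"}: list with
#'   \code{dJJ} (signed, NA at the lesion), \code{abs_dJJ}, and
#'   \code{lesion}.
#' @export
weight_change <- function(J_healthy, J_lesioned, lesion) {
  if (length(J_healthy) != length(J_lesioned))
    stop("weight vectors differ in length (", length(J_healthy), " vs ",
         length(J_lesioned), ")")
  if (is.character(lesion)) {
    lesion <- match(lesion, names(J_healthy))
    if (is.na(lesion)) stop("lesion label not found in J names")
  }
  stopifnot(lesion >= 1, lesion <= length(J_healthy))
  dJJ <- as.numeric(J_lesioned) - as.numeric(J_healthy)
  dJJ[lesion] <- NA_real_
  names(dJJ) <- names(J_healthy)
  structure(list(dJJ = dJJ, abs_dJJ = abs(dJJ), lesion = as.integer(lesion)),
            class = "weight_change")
}

#' @export
print.weight_change <- function(x, ...) {
  cat("Inhibitory weight change (lesion at index", x$lesion, "):\n")
  cat(sprintf("  range %.4f to %.4f nA, mean |dJJ| %.4f nA\n",
              min(x$dJJ, na.rm = TRUE), max(x$dJJ, na.rm = TRUE),
              mean(x$abs_dJJ, na.rm = TRUE)))
  invisible(x)
}
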