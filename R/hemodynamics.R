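#' Balloon-Windkessel BOLD forward model
#'
#' Converts per-region synaptic activity (the excitatory gating trajectory)
#' into a BOLD percent-signal-change time series via the standard
#' four-state vasodilatory signal / inflow / venous volume /
#' deoxyhaemoglobin system:
#' \deqn{\dot s = z - \kappa s - \gamma_h (f - 1), \quad \dot f = s,}
#' \deqn{\tau\dot v = f - v^{1/\alpha}, \quad
#'       \tau\dot q = f E(f,\rho)/\rho - v^{1/\alpha} q / v,}
#' with \eqn{E(f,\rho) = 1 - (1-\rho)^{1/f}} and readout
#' \eqn{y = V_0 (k_1(1-q) + k_2(1 - q/v) + k_3(1 - v))},
#' \eqn{k_1 = 7\rho,\; k_2 = 2,\; k_3 = 2\rho - 0.2}. Parameters are the
#' standard resting-state set. Deterministic given the input.
#'
#' @param activity region-by-time matrix of neural drive (e.g. the
#'   \code{activity} component of a \code{\link{simulate_dmf}} run), or a
#'   \code{"dmf_sim"} object with a recorded trajectory.
#' @param dt_s sampling interval of \code{activity} in seconds (taken from
#'   the simulation object when one is passed).
#' @param TR repetition time of the emitted BOLD series (s); default 2.
#' @param transient initial span (s) discarded from the BOLD output.
#' @param kappa,gamma_h,tau,alpha,rho,V0 haemodynamic constants: signal
#'   decay (s^-1), flow-dependent elimination (s^-1), transit time (s),
#'   vessel stiffness, resting oxygen extraction, resting venous volume
#'   fraction.
#' @return an object of class \code{"bold_series"}: region-by-time matrix
#'   of percent signal change sampled at \code{TR}, with attributes
#'   \code{TR} and \code{duration}.
#' @export
bold_from_activity <- function(activity, dt_s = NULL, TR = 2,
                               transient = 0,
                               kappa = 0.65, gamma_h = 0.41, tau = 0.98,
                               alpha = 0.32, rho = 0.34, V0 = 0.02) {
  if (inherits(activity, "dmf_sim")) {
    if (is.null(activity$activity))
      stop("simulation was run without a recorded trajectory; ",
           "set record_dt > 0 in simulate_dmf()")
    dt_s <- activity$record_dt / 1000
    activity <- activity$activity
  }
  if (is.null(dt_s)) stop("dt_s (sampling interval, s) is required")
  activity <- as.matrix(activity)
  if (any(!is.finite(activity))) stop("non-finite values in neural input")
  bold <- .balloon_bold_cpp(activity, dt_s, kappa, gamma_h, tau, alpha,
                            rho, V0)
  bold <- bold * 100                      # fraction -> percent signal change
  step <- max(1L, round(TR / dt_s))
  idx <- seq(from = step, to = ncol(bold), by = step)
  keep <- idx * dt_s > transient
  out <- bold[, idx[keep], drop = FALSE]
  rownames(out) <- rownames(activity)
  structure(out, TR = TR, duration = ncol(out) * TR,
            class = c("bold_series", "matrix", "array"))
}

#' Functional connectivity container
#'
#' @param values symmetric region-by-region correlation matrix.
#' @param condition tag, e.g. \code{"healthy"}, \code{"altered"},
#'   \code{"reorganized"}.
#' @return object of class \code{"fc_matrix"}.
#' @export
fc_matrix <- function(values, condition = "healthy") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8)
    stop("FC matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(values, condition = condition,
            class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  ut <- x[upper.tri(x)]
  cat("FC matrix (", attr(x, "condition"), "): ", nrow(x), " regions, ",
      sprintf("mean r %.3f, range [%.3f, %.3f]\n", mean(ut), min(ut),
              max(ut)), sep = "")
  invisible(x)
}

#' Functional connectivity from a BOLD series
#'
#' Z-scores each region's time series and computes the pairwise Pearson
#' correlation matrix. Regions with zero temporal variance get correlation
#' 0 to every other region, with a warning.
#'
#' @param b a \code{"bold_series"} (or any region-by-time matrix).
#' @param condition condition tag stored in the result.
#' @return an \code{"fc_matrix"}.
#' @export
fc_from_bold <- function(b, condition = "healthy") {
  m <- as.matrix(b)
  if (ncol(m) < 3) stop("need at least 3 time points for FC")
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " region(s) with zero variance; correlations set to 0")
  z <- m
  z[!flat, ] <- t(scale(t(m[!flat, , drop = FALSE])))
  fc <- matrix(0, nrow(m), nrow(m))
  ok <- which(!flat)
  if (length(ok) >= 2)
    fc[ok, ok] <- stats::cor(t(z[ok, , drop = FALSE]))
  diag(fc) <- 1
  dimnames(fc) <- list(rownames(m), rownames(m))
  fc_matrix(fc, condition = condition)
}
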