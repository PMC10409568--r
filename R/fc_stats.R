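#' Edge-wise paired t-test between two FC conditions
#'
#' For every region pair, the subjects' FC values under condition A and
#' condition B are Fisher r-to-z transformed and compared by a paired
#' t-test; p-values over the upper triangle are Benjamini-Hochberg FDR
#' corrected and thresholded at \code{alpha}. Positive t means condition B
#' exceeds condition A on that edge.
#'
#' @param fcs_a,fcs_b lists of \code{"fc_matrix"} objects (one per
#'   subject, matched order), conditions A and B.
#' @param alpha FDR level; default 0.05.
#' @param exclude optional region indices whose edges are dropped from
#'   testing (e.g. the lesioned region, whose FC rows are degenerate).
#' @return an object of class \code{"fc_comparison"}: list of symmetric
#'   matrices \code{t_stat}, \code{p_value}, \code{q_value}, logical
#'   \code{significant} mask, plus \code{alpha}, \code{n_subjects} and the
#'   contrast tag built from the conditions' names.
#' @export
paired_edge_ttest <- function(fcs_a, fcs_b, alpha = 0.05, exclude = NULL) {
  stopifnot(length(fcs_a) == length(fcs_b))
  ns <- length(fcs_a)
  if (ns < 3) stop("paired t-test needs at least 3 subjects, got ", ns)
  n <- nrow(fcs_a[[1]])
  zclip <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
  za <- vapply(fcs_a, function(m) zclip(as.matrix(m)), matrix(0, n, n))
  zb <- vapply(fcs_b, function(m) zclip(as.matrix(m)), matrix(0, n, n))
  d <- zb - za                              # n x n x ns
  dbar <- apply(d, c(1, 2), mean)
  dsd <- apply(d, c(1, 2), stats::sd)
  t_stat <- ifelse(dsd > 0, dbar / (dsd / sqrt(ns)), 0)
  p <- 2 * stats::pt(-abs(t_stat), df = ns - 1)
  p[dsd == 0] <- 1
  tested <- upper.tri(p)
  if (!is.null(exclude)) tested[exclude, ] <- tested[, exclude] <- FALSE
  q <- matrix(NA_real_, n, n)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  q[t(tested)] <- t(q)[t(tested)]
  sig <- !is.na(q) & q < alpha
  diag(t_stat) <- 0; diag(p) <- 1
  contrast <- paste(attr(fcs_a[[1]], "condition"), "vs",
                    attr(fcs_b[[1]], "condition"))
  structure(list(t_stat = t_stat, p_value = p, q_value = q,
                 significant = sig, alpha = alpha, n_subjects = ns,
                 contrast = contrast),
            class = "fc_comparison")
}

#' @export
print.fc_comparison <- function(x, ...) {
  ut <- upper.tri(x$t_stat) & !is.na(x$q_value)
  cat("FC contrast (", x$contrast, "), ", x$n_subjects, " subjects:\n",
      sep = "")
  cat(sprintf("  %d/%d edges significant at FDR %.3g (t range %.2f..%.2f)\n",
              sum(x$significant[ut]), sum(ut), x$alpha,
              min(x$t_stat[ut]), max(x$t_stat[ut])))
  invisible(x)
}

#' Significant edges of an FC comparison as a table
#'
#' @param x an \code{"fc_comparison"}.
#' @param labels optional region labels.
#' @return data.frame with columns region_i, region_j, t, p, q.
#' @export
significant_edges <- function(x, labels = NULL) {
  stopifnot(inherits(x, "fc_comparison"))
  idx <- which(x$significant & upper.tri(x$significant), arr.ind = TRUE)
  lab <- function(i) if (is.null(labels)) i else labels[i]
  data.frame(region_i = lab(idx[, 1]), region_j = lab(idx[, 2]),
             t = x$t_stat[idx], p = x$p_value[idx], q = x$q_value[idx])
}

#' Graph-theoretic metrics of a functional network
#'
#' Computes modularity (weighted Louvain, best of seeded restarts),
#' weighted transitivity (geometric-mean triangle ratio), global
#' efficiency and characteristic path length of an FC matrix. Negative
#' weights are zeroed first; shortest paths use lengths \code{1/w}.
#'
#' @param fc an \code{"fc_matrix"} (or symmetric matrix).
#' @param restarts Louvain restarts (best modularity kept); default 20.
#' @param seed RNG seed for the restarts.
#' @return an object of class \code{"fc_graph_metrics"}: list with
#'   \code{modularity}, \code{transitivity}, \code{global_efficiency},
#'   \code{char_path_length}, and \code{preprocessing} notes. All metrics
#'   are \code{NA} with a flag if no edges survive thresholding.
#' @export
fc_graph_metrics <- function(fc, restarts = 20, seed = 1L) {
  W <- as.matrix(fc)
  stopifnot(nrow(W) == ncol(W))
  W <- (W + t(W)) / 2
  W[W < 0] <- 0
  diag(W) <- 0
  n <- nrow(W)
  if (all(W == 0)) {
    return(structure(list(modularity = NA_real_, transitivity = NA_real_,
                          global_efficiency = NA_real_,
                          char_path_length = NA_real_,
                          degenerate = TRUE,
                          preprocessing = "negative weights zeroed; empty graph"),
                     class = "fc_graph_metrics"))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # Louvain with seeded restarts; keep the best partition
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) best_q <- q
  }
  # Onnela-style weighted transitivity: geometric-mean triangle intensity
  # over connected triples
  What <- (W / max(W))^(1 / 3)
  cyc3 <- diag(What %*% What %*% What)
  deg <- rowSums(W > 0)
  denom <- sum(deg * (deg - 1))
  trans <- if (denom > 0) sum(cyc3) / denom else NA_real_
  # distances on lengths 1/w
  L <- ifelse(W > 0, 1 / W, 0)
  gl <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  D <- igraph::distances(gl, weights = igraph::E(gl)$weight)
  off <- D[upper.tri(D)]
  geff <- mean(ifelse(is.finite(off), 1 / off, 0))
  cpl <- mean(off[is.finite(off)])
  structure(list(modularity = best_q, transitivity = trans,
                 global_efficiency = geff, char_path_length = cpl,
                 degenerate = FALSE,
                 preprocessing = "negative weights zeroed; lengths = 1/w"),
            class = "fc_graph_metrics")
}

#' @export
print.fc_graph_metrics <- function(x, ...) {
  cat(sprintf(paste0("FC graph metrics: Q = %.3f, T = %.3f, ",
                     "Eglob = %.3f, L = %.3f\n"),
              x$modularity, x$transitivity, x$global_efficiency,
              x$char_path_length))
  invisible(x)
}

#' Fit the global coupling G to a target FC
#'
#' For each candidate G: fit the inhibitory weights with
#' \code{\link{fic}}, simulate the model, build the simulated FC, and
#' correlate its upper triangle with the target FC. The chosen G maximizes
#' the FC-FC correlation among candidates whose regional mean excitatory
#' firing stays within the balanced band (default 2.63-3.55 Hz).
#'
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{dmf_params}}; its \code{G} entry is overridden by
#'   each grid value.
#' @param fc_target target \code{"fc_matrix"}.
#' @param grid numeric vector of candidate G values.
#' @param band admissible firing band (Hz).
#' @param duration,transient simulation length and transient (s) for the FC
#'   runs.
#' @param fic_args list of extra arguments passed to \code{\link{fic}}.
#' @param record_dt sampling interval (ms) of the neural trajectory used
#'   for BOLD.
#' @param seed integer seed; each grid value runs with
#'   \code{seed + its index}.
#' @return list with \code{G} (chosen value), \code{fit} (data.frame of
#'   G, FC-FC correlation, min/max firing, admissible flag) and
#'   \code{best_index}. Errors if no grid value satisfies the band.
#' @export
fit_global_coupling <- function(c, p = dmf_params(), fc_target, grid,
                                band = c(2.63, 3.55),
                                duration = 120, transient = 20,
                                fic_args = list(), record_dt = 10,
                                seed = 1L) {
  stopifnot(length(grid) >= 1)
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    pk <- p
    pk$G <- grid[k]
    f <- do.call(fic, c(list(c = c, p = pk, seed = seed + k), fic_args))
    sim <- simulate_dmf(c, pk, coef(f), duration = duration,
                        transient = transient, state = f$state,
                        record_dt = record_dt)
    bold <- bold_from_activity(sim, TR = 2, transient = transient)
    fc <- fc_from_bold(bold, condition = "simulated")
    ut <- upper.tri(fc)
    rows[[k]] <- data.frame(
      G = grid[k],
      fc_correlation = stats::cor(as.matrix(fc)[ut],
                                  as.matrix(fc_target)[ut]),
      firing_min = min(sim$r_E), firing_max = max(sim$r_E),
      admissible = min(sim$r_E) >= band[1] && max(sim$r_E) <= band[2])
  }
  fit <- do.call(rbind, rows)
  if (!any(fit$admissible))
    stop("no G in the grid keeps regional firing inside [",
         band[1], ", ", band[2], "] Hz")
  ok <- which(fit$admissible)
  best <- ok[which.max(fit$fc_correlation[ok])]
  list(G = fit$G[best], fit = fit, best_index = best)
}
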