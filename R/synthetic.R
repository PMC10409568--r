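#' Specification of a synthetic connectome cohort
#'
#' Describes a cohort of bi-hemispheric, modular, weighted structural
#' connectomes emulating tractography-derived matrices on a 68-region
#' cortical parcellation (34 regions per hemisphere): heavy-tailed
#' (log-normal) edge weights, block-modular wiring mirrored across
#' hemispheres, homotopic inter-hemispheric links that are each region's
#' strongest callosal edge, and multiplicative subject-level variability
#' around a shared group skeleton. Optionally a set of "twin" regions is
#' planted with near-identical connectivity profiles to a designated seed
#' region, giving a ground-truth target for structural-similarity recovery.
#'
#' @param n_subjects number of subjects in the cohort (default 49, a typical
#'   single-site healthy cohort size).
#' @param n_regions total number of regions; must equal
#'   \code{2 * n_per_hemisphere}.
#' @param n_per_hemisphere regions per hemisphere (default 34).
#' @param n_modules modules per hemisphere (default 4, coarse lobe-like
#'   communities).
#' @param intra_module_density,inter_module_density edge probabilities
#'   within / between modules, in \code{[0, 1]} (module membership ignores
#'   hemisphere: region i and its homotopic partner share a module).
#' @param inter_module_strength weight scale of between-module edges
#'   relative to within-module edges (< 1: modules are weight-coherent,
#'   not just denser).
#' @param interhemispheric_scale scale of inter-hemispheric edge weights
#'   relative to the mirrored intra-hemispheric structure (callosal
#'   connectivity is a damped copy of the modular wiring, which makes
#'   homotopic pairs structurally similar).
#' @param homotopic_strength multiplier (> 1) applied to each region's
#'   strongest other inter-hemispheric weight to set its homotopic edge.
#' @param weight_meanlog,weight_sdlog location and scale of the log-normal
#'   multiplicative edge-weight variability.
#' @param subject_jitter standard deviation of the per-subject multiplicative
#'   log-normal edge jitter (0 = identical subjects).
#' @param planted_twin_size number of planted twin regions (0 = none). Twins
#'   are regions 2..(1+size); the twin seed region is region 1.
#' @param seed integer RNG seed for the cohort.
#' @return an object of class \code{"cohort_spec"} (a validated list).
#' @export
cohort_spec <- function(n_subjects = 49, n_regions = 68,
                        n_per_hemisphere = n_regions / 2, n_modules = 4,
                        intra_module_density = 0.8,
                        inter_module_density = 0.2,
                        inter_module_strength = 0.25,
                        interhemispheric_scale = 0.3,
                        homotopic_strength = 1.5,
                        weight_meanlog = 0, weight_sdlog = 0.5,
                        subject_jitter = 0.1,
                        planted_twin_size = 0, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_regions = as.integer(n_regions),
               n_per_hemisphere = as.integer(n_per_hemisphere),
               n_modules = as.integer(n_modules),
               intra_module_density = intra_module_density,
               inter_module_density = inter_module_density,
               inter_module_strength = inter_module_strength,
               interhemispheric_scale = interhemispheric_scale,
               homotopic_strength = homotopic_strength,
               weight_meanlog = weight_meanlog,
               weight_sdlog = weight_sdlog,
               subject_jitter = subject_jitter,
               planted_twin_size = as.integer(planted_twin_size),
               seed = as.integer(seed))
  if (spec$n_regions != 2L * spec$n_per_hemisphere)
    stop("n_regions must equal 2 * n_per_hemisphere")
  if (spec$n_subjects < 1L) stop("n_subjects must be >= 1")
  for (f in c("intra_module_density", "inter_module_density"))
    if (spec[[f]] < 0 || spec[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (spec$homotopic_strength <= 0) stop("homotopic_strength must be > 0")
  if (spec$inter_module_strength <= 0 || spec$interhemispheric_scale <= 0)
    stop("weight scales must be > 0")
  if (spec$weight_sdlog <= 0) stop("weight_sdlog must be > 0")
  if (spec$subject_jitter < 0) stop("subject_jitter must be >= 0")
  if (spec$n_modules < 1 || spec$n_modules > spec$n_per_hemisphere)
    stop("n_modules must lie in 1..n_per_hemisphere")
  if (spec$planted_twin_size < 0 ||
      spec$planted_twin_size >= spec$n_per_hemisphere)
    stop("planted_twin_size must lie in 0..(n_per_hemisphere - 1)")
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_subjects, "subjects,",
      x$n_regions, "regions,", x$n_modules, "modules/hemisphere\n")
  cat(sprintf("  densities %.2f/%.2f, jitter %.2f, twins %d, seed %d\n",
              x$intra_module_density, x$inter_module_density,
              x$subject_jitter, x$planted_twin_size, x$seed))
  invisible(x)
}

#' Per-hemisphere module assignment of a cohort spec
#'
#' Modules are contiguous blocks of regions, mirrored across hemispheres
#' (region i and its homotopic partner share a module id).
#' @param spec a \code{\link{cohort_spec}}.
#' @return integer vector of module ids, length \code{n_regions}.
#' @export
module_assignment <- function(spec) {
  nh <- spec$n_per_hemisphere
  m <- ceiling(seq_len(nh) / (nh / spec$n_modules))
  m <- pmin(m, spec$n_modules)
  rep(m, 2L)
}

# group-level skeleton: edge presence mask and base weights, drawn once per
# cohort from spec$seed. Module membership is mirrored across hemispheres;
# inter-hemispheric wiring is a damped copy of the modular block structure.
group_skeleton <- function(spec) {
  n <- spec$n_regions
  nh <- spec$n_per_hemisphere
  mod <- module_assignment(spec)
  hemi <- rep(c("L", "R"), each = nh)
  set.seed(spec$seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_mod <- mod[i] == mod[j]
      p <- if (same_mod) spec$intra_module_density else
        spec$inter_module_density
      scale <- if (same_mod) 1 else spec$inter_module_strength
      if (hemi[i] != hemi[j]) scale <- scale * spec$interhemispheric_scale
      if (stats::runif(1) < p)
        W[i, j] <- W[j, i] <- scale *
          stats::rlnorm(1, spec$weight_meanlog, spec$weight_sdlog)
    }
  }
  list(W = W, mod = mod, hemi = hemi)
}

#' Generate one synthetic structural connectome
#'
#' Deterministic given \code{(spec$seed, subject_index)}: subjects share a
#' group skeleton (edge presence and base weights) and differ by
#' multiplicative log-normal edge jitter. After jitter, planted twins (if
#' any) are given near-copies of the twin seed region's profile, each
#' region's homotopic edge is raised above its other inter-hemispheric
#' weights, and the matrix is normalized so its maximum entry is 1.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param subject_index subject number in \code{1..n_subjects}.
#' @return a \code{\link{connectome}} with DK-style synthetic labels
#'   (\code{lSYN01..}, \code{rSYN01..}).
#' @export
generate_connectome <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L || subject_index > spec$n_subjects)
    stop("subject_index must lie in 1..n_subjects")
  sk <- group_skeleton(spec)
  W <- sk$W
  n <- spec$n_regions
  nh <- spec$n_per_hemisphere

  set.seed((spec$seed + 7919L * subject_index) %% .Machine$integer.max)
  if (spec$subject_jitter > 0) {
    E <- matrix(0, n, n)
    E[upper.tri(E)] <- stats::rnorm(n * (n - 1) / 2, 0, spec$subject_jitter)
    E <- E + t(E)
    W <- W * exp(E)
  }

  # planted twins: near-copies of region 1's profile
  k <- spec$planted_twin_size
  if (k > 0) {
    seed_row <- W[1, ]
    strong <- stats::quantile(seed_row[seed_row > 0], 0.9)
    for (t in seq(2L, 1L + k)) {
      w_t <- seed_row * exp(stats::rnorm(n, 0, 0.02))
      w_t[t] <- 0
      w_t[1] <- strong          # twins are strongly wired to their seed
      W[t, ] <- w_t
      W[, t] <- w_t
    }
  }

  # homotopic edges: strongest inter-hemispheric link of each region
  for (i in seq_len(nh)) {
    p <- i + nh
    other <- setdiff(seq(nh + 1L, n), p)
    m <- max(W[i, other], W[p, setdiff(seq_len(nh), i)], 1e-3)
    W[i, p] <- W[p, i] <- spec$homotopic_strength * m
  }

  diag(W) <- 0
  W <- W / max(W)
  labels <- c(sprintf("lSYN%02d", seq_len(nh)), sprintf("rSYN%02d", seq_len(nh)))
  connectome(W, region_labels = labels, hemisphere = sk$hemi)
}

#' Generate a full synthetic cohort
#'
#' @inheritParams generate_connectome
#' @return list of \code{n_subjects} \code{\link{connectome}} objects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_subjects), function(s) generate_connectome(spec, s))
}

#' Synthetic reference functional connectivity
#'
#' A deterministic linear-response surrogate of "empirical" FC for testing
#' the global-coupling fit: with \eqn{\hat C} the structural matrix scaled
#' to unit spectral radius, \eqn{\Sigma = (I - \lambda\hat C)^{-1}
#' (I - \lambda\hat C)^{-T}} and the FC is \eqn{\mathrm{cov2cor}(\Sigma)}.
#' This is a synthetic stand-in, not empirical data.
#'
#' @param c a \code{\link{connectome}}.
#' @param lambda effective coupling in (0, 1); default 0.5.
#' @return an \code{"fc_matrix"} (symmetric correlation matrix, unit
#'   diagonal, condition tag \code{"reference"}).
#' @export
reference_fc <- function(c, lambda = 0.5) {
  stopifnot(is_connectome(c), lambda > 0, lambda < 1)
  Chat <- unclass(c) / max(abs(eigen(unclass(c), symmetric = TRUE,
                                     only.values = TRUE)$values))
  B <- solve(diag(nrow(c)) - lambda * Chat)
  fc_matrix(stats::cov2cor(B %*% t(B)), condition = "reference")
}

#' Write a synthetic cohort to disk
#'
#' One TSV matrix per subject plus a JSON sidecar recording the generating
#' spec and seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    paths[s] <- file.path(dir, sprintf("subject%02d_sc.tsv", s))
    write_connectome(generate_connectome(spec, s), paths[s])
  }
  jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
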