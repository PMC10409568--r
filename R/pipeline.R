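#' Healthy-condition model run
#'
#' Fits the inhibitory weights on the intact connectome with
#' \code{\link{fic}}, then simulates the balanced model and builds the
#' healthy functional connectivity. The result can be shared across
#' several \code{\link{virtual_lesion}} analyses of the same subject (the
#' healthy condition is a one-time computation per subject).
#'
#' @inheritParams virtual_lesion
#' @return an object of class \code{"healthy_run"}: list with \code{fit}
#'   (the \code{"fic"} object), \code{sim}, \code{bold}, \code{fc}.
#' @export
healthy_condition <- function(c, p = dmf_params(), duration = 600,
                              transient = 120, record_dt = 10, TR = 2,
                              fic_args = list(), seed = NULL) {
  stopifnot(is_connectome(c))
  if (!is.null(seed)) set.seed(seed)
  fit <- do.call(fic, c(list(c = c, p = p), fic_args))
  # one shared noise stream for the FC runs of all three conditions
  # (common random numbers: condition differences then reflect the
  # lesion and the re-tuned weights, not the noise realization)
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1)
  sim <- simulate_dmf(c, p, coef(fit), duration = duration,
                      transient = transient, state = fit$state,
                      record_dt = record_dt, seed = sim_seed)
  bold <- bold_from_activity(sim, TR = TR, transient = transient)
  fc <- fc_from_bold(bold, condition = "healthy")
  structure(list(fit = fit, sim = sim, bold = bold, fc = fc,
                 sim_seed = sim_seed,
                 connectome = c, params = p,
                 settings = list(duration = duration, transient = transient,
                                 record_dt = record_dt, TR = TR,
                                 fic_args = fic_args)),
            class = "healthy_run")
}

#' Three-condition virtual-lesion analysis of one subject
#'
#' Runs the full per-subject, per-lesion workflow on a structural
#' connectome:
#' \enumerate{
#'   \item \strong{Healthy}: weighted Jaccard profile of the lesion site;
#'     FIC on the intact connectome (inhibitory weights J); simulation of
#'     the balanced model; healthy FC.
#'   \item \strong{Altered}: the lesion is applied (row and column of the
#'     site zeroed) and the model is simulated \emph{without} FIC, J frozen
#'     at the healthy values - the early post-lesion state with lost E-I
#'     balance; altered FC.
#'   \item \strong{Reorganized}: FIC re-run on the lesioned connectome,
#'     initialized at the healthy J, giving the re-adjusted weights J', the
#'     re-adjustment times RT and the weight changes dJJ = J' - J;
#'     simulation of the re-balanced model; reorganized FC.
#' }
#' Then structurally similar areas (SSA, top fraction of the Jaccard
#' profile), dynamically similar areas (DSA, top-RT intersect top-|dJJ|),
#' their overlap, and the JC/RT/|dJJ| correlations are computed.
#'
#' @param c a \code{\link{connectome}} (healthy).
#' @param lesion lesion site: region label or index.
#' @param p \code{\link{dmf_params}}.
#' @param fraction SSA/DSA selection fraction; default 0.25.
#' @param duration,transient simulation length and discarded transient (s)
#'   for the FC runs; defaults 600 and 120 (10-minute runs, 2-minute
#'   transient).
#' @param record_dt neural-trajectory sampling interval (ms) for the BOLD
#'   stage.
#' @param TR BOLD repetition time (s).
#' @param fic_args list of extra arguments for \code{\link{fic}} (e.g.
#'   \code{list(budget = 20)} for a reduced test profile).
#' @param healthy optional precomputed \code{\link{healthy_condition}}
#'   result for this subject.
#' @param seed optional integer seed making the whole run reproducible.
#' @param out_dir optional directory: artifacts (weights, report, FC
#'   matrices, manifest) are written there. If the directory already
#'   contains a run manifest and \code{force} is FALSE, the run is skipped
#'   and the manifest returned.
#' @param force re-run even when a manifest exists.
#' @return an object of class \code{"virtual_lesion"}: list with
#'   \code{lesion} (index), \code{jc} (similarity profile), \code{ssa},
#'   \code{dsa} (a \code{"dsa_selection"}), \code{overlap},
#'   \code{correlations}, \code{RT}, \code{dJJ} (a
#'   \code{"weight_change"}), \code{J}, \code{J_prime}, the three
#'   \code{fc_*} matrices, the underlying fits and simulations, and the
#'   run settings.
#' @export
virtual_lesion <- function(c, lesion, p = dmf_params(), fraction = 0.25,
                           duration = 600, transient = 120,
                           record_dt = 10, TR = 2, fic_args = list(),
                           healthy = NULL, seed = NULL,
                           out_dir = NULL, force = FALSE) {
  stopifnot(is_connectome(c))
  if (!is.null(out_dir) && !force &&
      file.exists(file.path(out_dir, "manifest.json"))) {
    message("run manifest already present in ", out_dir,
            "; returning it (use force = TRUE to recompute)")
    return(read_manifest(file.path(out_dir, "manifest.json")))
  }
  les <- region_index(c, lesion)
  stopifnot(length(les) == 1L)
  if (!is.null(seed)) set.seed(seed)

  # condition 1: healthy
  if (is.null(healthy))
    healthy <- healthy_condition(c, p, duration = duration,
                                 transient = transient,
                                 record_dt = record_dt, TR = TR,
                                 fic_args = fic_args)
  stopifnot(inherits(healthy, "healthy_run"))
  jc <- jaccard_profile(c, les)
  ssa <- select_ssa(jc, fraction = fraction)
  J <- coef(healthy$fit)

  # condition 2: lesioned connectome, J frozen (no FIC) -> altered FC.
  # FC runs of all conditions share the healthy run's noise stream.
  c_les <- apply_lesion(c, les)
  sim_alt <- simulate_dmf(c_les, p, J, duration = duration,
                          transient = transient, record_dt = record_dt,
                          seed = healthy$sim_seed)
  fc_alt <- fc_from_bold(bold_from_activity(sim_alt, TR = TR,
                                            transient = transient),
                         condition = "altered")

  # condition 3: FIC re-run from healthy J -> J', RT, reorganized FC.
  # The lesioned region is disconnected, so it is exempt from the
  # homeostat. Fixed steps (grow = 1) make each region's re-adjustment
  # time proportional to its total weight change.
  refit_args <- utils::modifyList(list(grow = 1), fic_args)
  refit <- do.call(fic, c(list(c = c_les, p = p, J_init = J,
                               exclude = les), refit_args))
  J_prime <- coef(refit)
  sim_reo <- simulate_dmf(c_les, p, J_prime, duration = duration,
                          transient = transient, state = refit$state,
                          record_dt = record_dt, seed = healthy$sim_seed)
  fc_reo <- fc_from_bold(bold_from_activity(sim_reo, TR = TR,
                                            transient = transient),
                         condition = "reorganized")

  dJJ <- weight_change(J, J_prime, les)
  dsa <- select_dsa(refit$RT, dJJ, lesion = les, fraction = fraction)
  ov <- overlap(ssa, dsa)
  cors <- measure_correlations(jc, refit$RT, dJJ$dJJ, les)

  run <- structure(list(
    lesion = les, lesion_label = attr(c, "region_labels")[les],
    jc = jc, ssa = ssa, dsa = dsa, overlap = ov, correlations = cors,
    J = J, J_prime = J_prime, RT = refit$RT, dJJ = dJJ,
    fc_healthy = healthy$fc, fc_altered = fc_alt, fc_reorganized = fc_reo,
    healthy = healthy, refit = refit,
    sim_altered = sim_alt, sim_reorganized = sim_reo,
    fraction = fraction, params = p, seed = seed,
    settings = list(duration = duration, transient = transient,
                    record_dt = record_dt, TR = TR, fic_args = fic_args)),
    class = "virtual_lesion")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.virtual_lesion <- function(x, ...) {
  cat("Virtual-lesion analysis: lesion at", x$lesion_label,
      "(index", x$lesion, ")\n")
  cat(sprintf("  |SSA| = %d, |DSA| = %d, overlap %.1f%% (/%s)\n",
              length(x$ssa), length(x$dsa$dsa),
              100 * x$overlap$overlap_fraction,
              x$overlap$denominator_convention))
  r <- x$correlations
  cat(sprintf("  r(JC,RT) = %.2f, r(JC,|dJJ|) = %.2f, r(RT,|dJJ|) = %.2f\n",
              r$r[1], r$r[2], r$r[3]))
  invisible(x)
}

#' @export
summary.virtual_lesion <- function(object, ...) {
  lesion_report(object)
}

#' @export
plot.virtual_lesion <- function(x, ...) {
  rep <- lesion_report(x)
  keep <- rep$region_index != x$lesion
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(rep$jc[keep], rep$rt[keep], xlab = "JC", ylab = "RT (s)",
                 main = "JC vs RT",
                 col = ifelse(rep$in_overlap[keep], "orange", "steelblue"),
                 pch = 19)
  graphics::plot(rep$jc[keep], abs(rep$djj[keep]), xlab = "JC",
                 ylab = "|dJJ| (nA)", main = "JC vs |dJJ|",
                 col = ifelse(rep$in_overlap[keep], "orange", "steelblue"),
                 pch = 19)
  graphics::plot(rep$rt[keep], abs(rep$djj[keep]), xlab = "RT (s)",
                 ylab = "|dJJ| (nA)", main = "RT vs |dJJ|",
                 col = ifelse(rep$in_overlap[keep], "orange", "steelblue"),
                 pch = 19)
  invisible(x)
}

#' Per-region report of a virtual-lesion run
#'
#' @param run a \code{"virtual_lesion"} object.
#' @return data.frame with one row per region: jc, rt, djj and membership
#'   flags for SSA, DSA and their overlap.
#' @export
lesion_report <- function(run) {
  stopifnot(inherits(run, "virtual_lesion"))
  n <- length(run$jc)
  data.frame(
    region_index = seq_len(n),
    region = names(run$jc),
    jc = as.numeric(run$jc),
    rt = as.numeric(run$RT),
    djj = as.numeric(run$dJJ$dJJ),
    in_ssa = seq_len(n) %in% as.integer(run$ssa),
    in_dsa = seq_len(n) %in% as.integer(run$dsa$dsa),
    in_overlap = seq_len(n) %in% run$overlap$common)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(report = "report.csv", weights = "weights.csv",
                fc_healthy = "fc_healthy.tsv", fc_altered = "fc_altered.tsv",
                fc_reorganized = "fc_reorganized.tsv")
  utils::write.csv(lesion_report(run), file.path(dir, files$report),
                   row.names = FALSE)
  utils::write.csv(data.frame(region = names(run$J), J = as.numeric(run$J),
                              J_prime = as.numeric(run$J_prime),
                              RT = as.numeric(run$RT),
                              dJJ = as.numeric(run$dJJ$dJJ)),
                   file.path(dir, files$weights), row.names = FALSE)
  for (f in c("fc_healthy", "fc_altered", "fc_reorganized"))
    utils::write.table(as.matrix(run[[f]]), file.path(dir, files[[f]]),
                       sep = "\t", quote = FALSE)
  manifest <- list(lesion = run$lesion, lesion_label = run$lesion_label,
                   fraction = run$fraction, seed = run$seed,
                   overlap_fraction = run$overlap$overlap_fraction,
                   files = files,
                   settings = run$settings[c("duration", "transient",
                                             "record_dt", "TR")],
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(m) <- "run_manifest"
  m
}

#' Group-level virtual-lesion analysis
#'
#' Runs \code{\link{virtual_lesion}} for every subject and lesion site,
#' then aggregates: probability of appearance (PA) of each region among
#' the subjects' SSAs and DSAs per lesion site, pooled FC contrasts
#' (healthy vs altered, altered vs reorganized) across subjects, and the
#' per-run overlap fractions.
#'
#' @param cohort list of \code{\link{connectome}}s (one per subject).
#' @param lesions vector of lesion sites (labels or indices), applied to
#'   every subject.
#' @param p \code{\link{dmf_params}}.
#' @param seed integer; run s of subject i uses \code{seed + 1000*i + s}.
#' @param alpha FDR level for the pooled contrasts (needs >= 3 subjects;
#'   skipped otherwise).
#' @param ... further arguments passed to \code{\link{virtual_lesion}}
#'   (fraction, duration, fic_args, ...).
#' @return an object of class \code{"lesion_group"}: list with
#'   \code{runs} (subject x lesion list), \code{pa_ssa}, \code{pa_dsa}
#'   (per lesion site), \code{overlap_fractions} (matrix subject x
#'   lesion), and \code{contrasts} per lesion site (NULL with < 3
#'   subjects).
#' @export
run_group <- function(cohort, lesions, p = dmf_params(), seed = 1L,
                      alpha = 0.05, ...) {
  stopifnot(length(cohort) >= 1, length(lesions) >= 1)
  ns <- length(cohort)
  nl <- length(lesions)
  runs <- vector("list", ns)
  for (i in seq_len(ns)) {
    c_i <- cohort[[i]]
    healthy <- NULL
    runs[[i]] <- vector("list", nl)
    for (s in seq_len(nl)) {
      set.seed(seed + 1000L * i + s)
      run <- virtual_lesion(c_i, lesions[s], p = p, healthy = healthy, ...)
      healthy <- run$healthy            # reuse condition 1 across lesions
      runs[[i]][[s]] <- run
    }
  }
  ov <- matrix(NA_real_, ns, nl,
               dimnames = list(paste0("subject", seq_len(ns)),
                               as.character(lesions)))
  pa_ssa <- pa_dsa <- stats::setNames(vector("list", nl),
                                      as.character(lesions))
  contrasts <- stats::setNames(vector("list", nl), as.character(lesions))
  for (s in seq_len(nl)) {
    per_subj <- lapply(runs, `[[`, s)
    ov[, s] <- vapply(per_subj, function(r) r$overlap$overlap_fraction, 0)
    pa_ssa[[s]] <- probability_of_appearance(lapply(per_subj, `[[`, "ssa"),
                                             measure = "SSA")
    pa_dsa[[s]] <- probability_of_appearance(
      lapply(per_subj, function(r) r$dsa$dsa), measure = "DSA")
    if (ns >= 3) {
      les <- per_subj[[1]]$lesion
      contrasts[[s]] <- list(
        healthy_vs_altered = paired_edge_ttest(
          lapply(per_subj, `[[`, "fc_healthy"),
          lapply(per_subj, `[[`, "fc_altered"),
          alpha = alpha, exclude = les),
        altered_vs_reorganized = paired_edge_ttest(
          lapply(per_subj, `[[`, "fc_altered"),
          lapply(per_subj, `[[`, "fc_reorganized"),
          alpha = alpha, exclude = les))
    }
  }
  structure(list(runs = runs, pa_ssa = pa_ssa, pa_dsa = pa_dsa,
                 overlap_fractions = ov, contrasts = contrasts,
                 lesions = lesions, seed = seed),
            class = "lesion_group")
}

#' @export
print.lesion_group <- function(x, ...) {
  cat("Group virtual-lesion analysis:", nrow(x$overlap_fractions),
      "subjects x", ncol(x$overlap_fractions), "lesion sites\n")
  cat(sprintf("  median SSA/DSA overlap %.1f%%\n",
              100 * stats::median(x$overlap_fractions)))
  invisible(x)
}

#' Reduced simulation profile for quick runs
#'
#' A named list of \code{\link{virtual_lesion}} arguments scaling the
#' protocol down for continuous testing: 60 s simulations with 12 s
#' transient and a 40-window FIC budget (enough for the largest
#' post-lesion weight traversals at the default step). Scientific
#' parameters are untouched.
#'
#' @return named list of arguments.
#' @export
ci_profile <- function() {
  list(duration = 60, transient = 12, record_dt = 10,
       fic_args = list(budget = 40))
}
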