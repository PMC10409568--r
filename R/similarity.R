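#' Select dynamically similar areas (DSAs)
#'
#' Ranks regions by post-lesion re-adjustment time RT and by the magnitude
#' of the inhibitory weight change |dJJ|, both in descending order, keeps
#' the top fraction of each (\code{N = round(fraction * n_regions)}), and
#' intersects the two rank sets:
#' \deqn{DSA = AI_{RT}|_{1:N} \cap AI_{|dJJ|}|_{1:N}.}
#' The lesioned region is excluded from candidacy (NA entries are treated
#' as excluded). Ties break by ascending region index.
#'
#' @param rt per-region re-adjustment times (s), e.g. from a post-lesion
#'   \code{\link{fic}} refit.
#' @param djj per-region signed or absolute weight changes (nA), e.g.
#'   \code{weight_change(...)$dJJ}; the absolute value is ranked.
#' @param lesion index of the lesioned region (masked from both rankings).
#' @param fraction selection fraction; default 0.25.
#' @return an object of class \code{"dsa_selection"}: list with
#'   \code{dsa}, \code{top_rt}, \code{top_djj} (each an area set of region
#'   indices) and \code{fraction}. An all-zero RT vector yields an empty
#'   DSA with a warning.
#' @export
select_dsa <- function(rt, djj, lesion, fraction = 0.25) {
  if (inherits(djj, "weight_change")) djj <- djj$dJJ
  if (length(rt) != length(djj))
    stop("rt and djj differ in length")
  n <- length(rt)
  stopifnot(lesion >= 1, lesion <= n)
  labels <- names(rt)
  rt_m <- as.numeric(rt)
  djj_m <- abs(as.numeric(djj))
  excl <- unique(c(lesion, which(is.na(rt_m)), which(is.na(djj_m))))
  rt_m[is.na(rt_m)] <- -Inf
  djj_m[is.na(djj_m)] <- -Inf
  if (all(rt_m[-excl] == 0))
    warning("all re-adjustment times are zero; no region re-adjusted")
  top_rt <- top_fraction(rt_m, fraction, exclude = excl)
  top_djj <- top_fraction(djj_m, fraction, exclude = excl)
  dsa <- intersect(top_rt, top_djj)
  mk <- function(members, src, scores)
    area_set(members, n_regions = n, fraction = fraction, source = src,
             scores = scores[members], labels = labels)
  structure(list(dsa = mk(dsa, "DSA", pmin(rt_m, Inf)),
                 top_rt = mk(top_rt, "topRT", rt_m),
                 top_djj = mk(top_djj, "top|dJJ|", djj_m),
                 fraction = fraction, lesion = as.integer(lesion)),
            class = "dsa_selection")
}

#' @export
print.dsa_selection <- function(x, ...) {
  cat("DSA selection (lesion index ", x$lesion, ", fraction ",
      x$fraction, "):\n", sep = "")
  cat("  |top RT| =", length(x$top_rt), " |top dJJ| =", length(x$top_djj),
      " |DSA| =", length(x$dsa), "\n")
  invisible(x)
}

#' Overlap between structurally and dynamically similar areas
#'
#' Regions selected by both measures. The overlap fraction is reported as
#' \code{|SSA intersect DSA| / |DSA|} by default: the share of dynamically
#' identified areas that are also structurally similar. The DSA (an
#' intersection of two rank sets) can be smaller than N, so the convention
#' matters and is stamped into the report.
#'
#' @param ssa an \code{"area_set"} from \code{\link{select_ssa}}.
#' @param dsa_sel a \code{"dsa_selection"} from \code{\link{select_dsa}}
#'   (or an \code{"area_set"}).
#' @param denominator \code{"dsa"} (default), \code{"ssa"}, or
#'   \code{"union"}.
#' @return an object of class \code{"overlap_report"}: list with
#'   \code{common} (indices), \code{overlap_fraction},
#'   \code{denominator_convention} and \code{empty_dsa} flag (fraction
#'   reported as 0 when the DSA is empty).
#' @export
overlap <- function(ssa, dsa_sel, denominator = c("dsa", "ssa", "union")) {
  denominator <- match.arg(denominator)
  dsa <- if (inherits(dsa_sel, "dsa_selection")) dsa_sel$dsa else dsa_sel
  if (attr(ssa, "n_regions") != attr(dsa, "n_regions"))
    stop("SSA and DSA come from different region universes")
  common <- intersect(as.integer(ssa), as.integer(dsa))
  den <- switch(denominator,
                dsa = length(dsa), ssa = length(ssa),
                union = length(union(as.integer(ssa), as.integer(dsa))))
  empty <- den == 0
  structure(list(common = sort(common),
                 overlap_fraction = if (empty) 0 else length(common) / den,
                 denominator_convention = denominator,
                 empty_dsa = empty,
                 n_ssa = length(ssa), n_dsa = length(dsa)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "SSA/DSA overlap: %d common of %d SSA / %d DSA; fraction %.3f (/%s)\n",
    length(x$common), x$n_ssa, x$n_dsa, x$overlap_fraction,
    x$denominator_convention))
  invisible(x)
}

#' Correlations between anatomical and dynamical lesion measures
#'
#' Pairwise Pearson correlations and ordinary least-squares lines for the
#' three scatter relations JC-RT, JC-|dJJ| and RT-|dJJ|, with the lesioned
#' region masked. A constant vector makes r undefined; it is reported as 0
#' with a flag.
#'
#' @param jc Jaccard similarity values w.r.t. the lesion site.
#' @param rt re-adjustment times (s).
#' @param djj signed or absolute weight changes (nA); the absolute value
#'   is used.
#' @param lesion index of the lesioned region.
#' @return data.frame with one row per pair: \code{pair}, \code{r},
#'   \code{slope}, \code{intercept}, \code{n}, \code{degenerate}.
#' @export
measure_correlations <- function(jc, rt, djj, lesion) {
  n <- length(jc)
  stopifnot(length(rt) == n, length(djj) == n, lesion >= 1, lesion <= n)
  keep <- setdiff(seq_len(n), lesion)
  vars <- list(JC = as.numeric(jc)[keep], RT = as.numeric(rt)[keep],
               absdJJ = abs(as.numeric(djj))[keep])
  pairs <- list(c("JC", "RT"), c("JC", "absdJJ"), c("RT", "absdJJ"))
  rows <- lapply(pairs, function(pr) {
    x <- vars[[pr[1]]]; y <- vars[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    degen <- stats::sd(x) == 0 || stats::sd(y) == 0 || length(x) < 3
    if (degen) {
      data.frame(pair = paste(pr, collapse = "-"), r = 0,
                 slope = NA_real_, intercept = NA_real_,
                 n = length(x), degenerate = TRUE)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      data.frame(pair = paste(pr, collapse = "-"),
                 r = stats::cor(x, y),
                 slope = fit$coefficients[2],
                 intercept = fit$coefficients[1],
                 n = length(x), degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Common top-ranked areas of two measures
#'
#' The intersection of the top-N rank sets of two per-region measures
#' (same machinery as the DSA rule), used e.g. for the regions jointly
#' top-ranked by JC and RT, or by JC and |dJJ|.
#'
#' @param x,y per-region numeric measures (equal length; NA excluded).
#' @param fraction selection fraction; default 0.25.
#' @param exclude optional indices to bar from candidacy (e.g. the lesion).
#' @return an \code{"area_set"} tagged \code{"common"}.
#' @export
common_top_areas <- function(x, y, fraction = 0.25, exclude = NULL) {
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  excl <- unique(c(exclude, which(is.na(x)), which(is.na(y))))
  xm <- as.numeric(x); xm[is.na(xm)] <- -Inf
  ym <- as.numeric(y); ym[is.na(ym)] <- -Inf
  common <- intersect(top_fraction(xm, fraction, excl),
                      top_fraction(ym, fraction, excl))
  area_set(common, n_regions = n, fraction = fraction, source = "common",
           labels = names(x))
}

#' Group-level probability of appearance (PA)
#'
#' For each region, the fraction of subjects whose selected area set
#' (SSA or DSA) contains it:
#' \deqn{PA = \frac{\textrm{number of appearances of an area across
#' subjects}}{\textrm{total subjects}}.}
#' \code{PA = 1} means the area was selected in every subject.
#'
#' @param sets_per_subject list of \code{"area_set"}s (or integer index
#'   vectors), one per subject.
#' @param n_regions total number of regions (taken from the first area set
#'   when omitted).
#' @param measure tag recorded in the result (\code{"SSA"} or
#'   \code{"DSA"}).
#' @return object of class \code{"group_pa"}: numeric vector of per-region
#'   PA values in \code{[0, 1]} with attributes \code{n_subjects} and
#'   \code{measure}.
#' @export
probability_of_appearance <- function(sets_per_subject, n_regions = NULL,
                                      measure = "SSA") {
  stopifnot(length(sets_per_subject) >= 1)
  if (is.null(n_regions)) {
    n_regions <- attr(sets_per_subject[[1]], "n_regions")
    if (is.null(n_regions))
      stop("n_regions is required when sets are plain index vectors")
  }
  counts <- integer(n_regions)
  for (s in sets_per_subject) {
    idx <- unique(as.integer(s))
    stopifnot(all(idx >= 1 & idx <= n_regions))
    counts[idx] <- counts[idx] + 1L
  }
  structure(counts / length(sets_per_subject),
            n_subjects = length(sets_per_subject), measure = measure,
            class = "group_pa")
}

#' @export
print.group_pa <- function(x, ...) {
  cat("Probability of appearance (", attr(x, "measure"), ", ",
      attr(x, "n_subjects"), " subjects): ",
      sum(x == 1), " region(s) with PA = 1, ",
      sum(x > 0), " with PA > 0\n", sep = "")
  invisible(x)
}
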