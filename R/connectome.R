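#' Construct a structural connectome
#'
#' A connectome is a weighted, symmetric, non-negative region-by-region
#' matrix with a zero diagonal, plus region labels and hemisphere tags.
#' Weights are dimensionless edge strengths (e.g. normalized streamline
#' counts from tractography).
#'
#' @param weights square numeric matrix; symmetric, non-negative, zero
#'   diagonal.
#' @param region_labels character vector of region names, one per row.
#'   Defaults to the matrix dimnames or \code{R1..Rn}.
#' @param hemisphere character vector of \code{"L"}/\code{"R"} tags, one per
#'   region. Defaults to first half \code{"L"}, second half \code{"R"}.
#' @param tol tolerance for the symmetry check.
#' @return an object of class \code{"connectome"}: the weight matrix with
#'   attributes \code{region_labels} and \code{hemisphere}.
#' @export
connectome <- function(weights, region_labels = NULL, hemisphere = NULL,
                       tol = 1e-9) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("connectome matrix must be square, got ", n, "x", ncol(weights))
  if (any(!is.finite(weights)))
    stop("connectome weights must be finite")
  if (any(weights < 0))
    stop("connectome weights must be non-negative")
  if (max(abs(weights - t(weights))) > tol)
    stop("connectome matrix must be symmetric (tolerance ", tol, ")")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  }
  if (length(region_labels) != n)
    stop("need ", n, " region labels, got ", length(region_labels))
  if (is.null(hemisphere))
    hemisphere <- rep(c("L", "R"), times = c(ceiling(n / 2), floor(n / 2)))
  if (length(hemisphere) != n)
    stop("need ", n, " hemisphere tags, got ", length(hemisphere))
  dimnames(weights) <- list(region_labels, region_labels)
  structure(weights,
            region_labels = region_labels,
            hemisphere = as.character(hemisphere),
            class = c("connectome", "matrix", "array"))
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x)
  cat("Structural connectome:", n, "regions (",
      sum(attr(x, "hemisphere") == "L"), "L /",
      sum(attr(x, "hemisphere") == "R"), "R )\n")
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("  density %.3f, weight range [%.4g, %.4g]\n",
              nz / (n * (n - 1) / 2), min(x), max(x)))
  invisible(x)
}

#' @rdname connectome
#' @param x object to test.
#' @export
is_connectome <- function(x) inherits(x, "connectome")

region_index <- function(c, region) {
  labels <- attr(c, "region_labels")
  if (is.character(region)) {
    i <- match(region, labels)
    if (anyNA(i)) stop("unknown region label(s): ",
                       paste(region[is.na(i)], collapse = ", "))
    return(i)
  }
  region <- as.integer(region)
  if (any(region < 1L | region > nrow(c)))
    stop("region index out of range 1..", nrow(c))
  region
}

#' Read / write a connectome as a labelled TSV matrix
#'
#' The on-disk format is a plain-text tab-separated matrix with region labels
#' as header row and first column, optionally accompanied by a
#' \code{<path>.json} sidecar (hemisphere tags and provenance).
#'
#' @param path file path.
#' @return \code{read_connectome} returns a \code{\link{connectome}};
#'   \code{write_connectome} invisibly returns \code{path}.
#' @export
read_connectome <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("connectome file is not square: ", nrow(m), "x", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree in ", path)
  hemi <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$hemisphere)) {
      if (length(meta$hemisphere) != nrow(m))
        stop("sidecar hemisphere tags do not match matrix dimension")
      hemi <- meta$hemisphere
    }
  }
  connectome(m, region_labels = rownames(m), hemisphere = hemi)
}

#' @rdname read_connectome
#' @param c a \code{\link{connectome}}.
#' @export
write_connectome <- function(c, path) {
  stopifnot(is_connectome(c))
  m <- unclass(c)
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(hemisphere = attr(c, "hemisphere")),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Weighted Jaccard similarity profile of one region
#'
#' For a reference region A, the similarity to every other region B is the
#' weighted Jaccard coefficient of their connectivity profiles: the ratio of
#' the summed minimum to the summed maximum of the two regions' edge weights
#' to all shared third-party neighbours,
#' \deqn{JC(A,B) = \frac{\sum_k \min(C_{Ak}, C_{Bk})}
#'                      {\sum_k \max(C_{Ak}, C_{Bk})}, \quad k \notin \{A,B\}.}
#' The self-entries and the mutual edge are excluded so that the coefficient
#' reflects shared third-party wiring only. \code{JC = 1} means identical
#' neighbourhood weights; 0 means disjoint neighbourhoods.
#'
#' @param c a \code{\link{connectome}}.
#' @param reference region index or label of the reference region (e.g. the
#'   prospective lesion site).
#' @return object of class \code{"similarity_profile"}: a named numeric
#'   vector of JC values in \code{[0, 1]} (1 at the reference itself, by
#'   convention), with attribute \code{reference}.
#' @export
jaccard_profile <- function(c, reference) {
  stopifnot(is_connectome(c))
  a <- region_index(c, reference)
  stopifnot(length(a) == 1L)
  n <- nrow(c)
  jc <- numeric(n)
  wa <- c[a, ]
  for (b in seq_len(n)) {
    if (b == a) { jc[b] <- 1; next }
    keep <- setdiff(seq_len(n), c(a, b))
    num <- sum(pmin(wa[keep], c[b, keep]))
    den <- sum(pmax(wa[keep], c[b, keep]))
    if (den == 0) {
      jc[b] <- 0
    } else {
      jc[b] <- num / den
    }
  }
  if (sum(wa) == 0)
    warning("reference region has zero strength; JC profile is degenerate")
  names(jc) <- attr(c, "region_labels")
  structure(jc, reference = a, class = "similarity_profile")
}

#' Full weighted Jaccard similarity matrix
#'
#' @inheritParams jaccard_profile
#' @return symmetric n-by-n matrix of pairwise JC values, unit diagonal.
#' @export
jaccard_matrix <- function(c) {
  stopifnot(is_connectome(c))
  n <- nrow(c)
  jc <- diag(n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      keep <- setdiff(seq_len(n), c(a, b))
      den <- sum(pmax(c[a, keep], c[b, keep]))
      jc[a, b] <- jc[b, a] <-
        if (den == 0) 0 else sum(pmin(c[a, keep], c[b, keep])) / den
    }
  }
  dimnames(jc) <- dimnames(c)
  jc
}

#' Select structurally similar areas (SSAs)
#'
#' Ranks the Jaccard profile of a (prospective) lesion site in descending
#' order and keeps the top fraction of regions (default the top 25\%,
#' \code{N = round(fraction * n_regions)}). The reference region itself is
#' excluded from candidacy. Ties are broken by ascending region index for
#' determinism.
#'
#' @param profile a \code{"similarity_profile"} from
#'   \code{\link{jaccard_profile}}, or a plain numeric vector plus
#'   \code{reference}.
#' @param fraction selection fraction in (0, 1]; default 0.25.
#' @param reference region index to exclude (taken from the profile's
#'   attribute when present).
#' @return an \code{"area_set"}: integer vector of selected region indices
#'   ordered by decreasing score, with attributes \code{scores},
#'   \code{fraction} and \code{source = "SSA"}.
#' @export
select_ssa <- function(profile, fraction = 0.25, reference = NULL) {
  if (is.null(reference)) reference <- attr(profile, "reference")
  sel <- top_fraction(as.numeric(profile), fraction, exclude = reference)
  area_set(sel, n_regions = length(profile), fraction = fraction,
           source = "SSA", scores = as.numeric(profile)[sel],
           labels = names(profile))
}

# ranked top-N selection with the package-wide tie rule:
# descending score, ties broken by ascending index; `exclude` never selected
top_fraction <- function(scores, fraction, exclude = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(scores)
  N <- round(fraction * n)
  cand <- setdiff(seq_len(n), exclude)
  ord <- cand[order(-scores[cand], cand)]
  ord[seq_len(min(N, length(ord)))]
}

area_set <- function(members, n_regions, fraction, source,
                     scores = NULL, labels = NULL) {
  structure(as.integer(members),
            n_regions = as.integer(n_regions),
            fraction = fraction, source = source, scores = scores,
            labels = if (!is.null(labels)) labels[members],
            class = "area_set")
}

#' @export
print.area_set <- function(x, ...) {
  cat(attr(x, "source"), "area set:", length(x), "of", attr(x, "n_regions"),
      "regions (fraction", attr(x, "fraction"), ")\n")
  lab <- attr(x, "labels")
  cat("  ", paste(if (is.null(lab)) as.integer(x) else lab, collapse = " "),
      "\n")
  invisible(x)
}

#' Apply a focal virtual lesion
#'
#' Removes one region from the network by setting all of its incoming and
#' outgoing connections to zero (row and column of the structural matrix);
#' every other entry is unchanged.
#'
#' @param c a \code{\link{connectome}}.
#' @param node region index or label of the lesion site.
#' @return the lesioned \code{\link{connectome}}, with attribute
#'   \code{lesion} recording the lesioned index.
#' @export
apply_lesion <- function(c, node) {
  stopifnot(is_connectome(c))
  i <- region_index(c, node)
  stopifnot(length(i) == 1L)
  out <- c
  out[i, ] <- 0
  out[, i] <- 0
  attr(out, "lesion") <- i
  out
}

#' Nodal strength and degree
#'
#' Strength is the sum of a region's edge weights (row sum); degree is its
#' number of non-zero connections.
#'
#' @param c a \code{\link{connectome}}.
#' @return named numeric (strength) or integer (degree) vector.
#' @export
nodal_strength <- function(c) {
  stopifnot(is_connectome(c))
  rowSums(unclass(c))
}

#' @rdname nodal_strength
#' @export
nodal_degree <- function(c) {
  stopifnot(is_connectome(c))
  as.integer(rowSums(unclass(c) > 0))
}
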