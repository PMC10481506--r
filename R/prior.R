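#' Inter-tooth distance prior
#'
#' A 32 x 32 symmetric matrix `d` of mean center-of-mass distances between
#' FDI code pairs, in millimeters, estimated from labeled scans, plus a
#' matching `support` matrix counting the observations behind each entry.
#' Entries never co-observed are `NA` (missing, distinct from zero); the
#' diagonal is 0. Cross-jaw entries are estimated scans permitting but are
#' not used by the labeling penalties, which only compare same-jaw pairs.
#'
#' @param d 32 x 32 numeric matrix (dimnames = FDI codes), `NA` = missing.
#' @param support 32 x 32 count matrix (or `NA` for analytic priors).
#' @return an object of class `distance_prior`.
#' @export
distance_prior <- function(d, support = NULL) {
  codes <- as.character(fdi_codes())
  stopifnot(is.matrix(d), all(dim(d) == 32))
  if (is.null(dimnames(d))) dimnames(d) <- list(codes, codes)
  d <- d[codes, codes]
  if (!isTRUE(all.equal(d, t(d))))
    stop("distance_prior: d must be symmetric", call. = FALSE)
  if (any(d < 0, na.rm = TRUE))
    stop("distance_prior: distances must be non-negative", call. = FALSE)
  diag(d) <- 0
  if (is.null(support)) {
    support <- matrix(NA_integer_, 32, 32, dimnames = list(codes, codes))
  } else {
    dimnames(support) <- list(codes, codes)
  }
  structure(list(d = d, support = support), class = "distance_prior")
}

#' @export
print.distance_prior <- function(x, ...) {
  filled <- sum(!is.na(x$d[upper.tri(x$d)]))
  cat("<distance_prior> ", filled, "/", sum(upper.tri(x$d)),
      " pairwise entries, mean distance ",
      signif(mean(x$d[upper.tri(x$d)], na.rm = TRUE), 4), " mm\n", sep = "")
  invisible(x)
}

#' Estimate the distance prior from labeled scenes
#'
#' For every pair of FDI codes, the arithmetic mean over all scenes
#' containing both codes of the Euclidean distance between their detection
#' COMs, with the number of contributing scenes recorded as support. Pairs
#' never co-observed stay `NA`.
#'
#' @param scenes a list of arch scenes whose detections carry ground-truth
#'   codes in an `fdi` column (e.g. from [generate_scene()]), or a list of
#'   such detection tibbles.
#' @return a [distance_prior()].
#' @export
estimate_distance_prior <- function(scenes) {
  stopifnot(length(scenes) >= 1)
  codes <- as.character(fdi_codes())
  sums <- matrix(0, 32, 32, dimnames = list(codes, codes))
  counts <- matrix(0L, 32, 32, dimnames = list(codes, codes))
  for (sc in scenes) {
    det <- if (inherits(sc, "arch_scene")) sc$detections else tibble::as_tibble(sc)
    det <- det[!is.na(det$fdi), , drop = FALSE]
    if (nrow(det) < 2) next
    if (anyDuplicated(det$fdi))
      stop("estimate_distance_prior: duplicated FDI code within one scene",
           call. = FALSE)
    dm <- as.matrix(stats::dist(cbind(det$x, det$y, det$z)))
    idx <- as.character(det$fdi)
    sums[idx, idx] <- sums[idx, idx] + dm
    counts[idx, idx] <- counts[idx, idx] + 1L
  }
  d <- ifelse(counts > 0, sums / counts, NA_real_)
  diag(d) <- 0
  diag(counts) <- 0L
  distance_prior(d, counts)
}

#' Read / write a distance-prior CSV
#'
#' The on-disk format is a 33 x 33 grid: a header row and a leading column
#' hold the 32 FDI codes; cells hold mean distances in millimeters; empty
#' cells mark missing entries.
#'
#' @param prior a [distance_prior()].
#' @param path CSV path.
#' @return `read_prior_csv` returns a [distance_prior()] (support unknown,
#'   `NA`); `write_prior_csv` returns `path` invisibly.
#' @export
write_prior_csv <- function(prior, path) {
  stopifnot(inherits(prior, "distance_prior"))
  df <- as.data.frame(prior$d)
  df <- cbind(code = rownames(prior$d), df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_prior_csv
#' @export
read_prior_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  codes <- as.character(df[[1]])
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- codes
  if (!setequal(codes, as.character(fdi_codes())) ||
      !setequal(colnames(d), as.character(fdi_codes())))
    stop("read_prior_csv: header/row codes are not the 32 FDI codes",
         call. = FALSE)
  distance_prior(d)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance prior into a long tibble
#'
#' @param x a [distance_prior()].
#' @param ... unused.
#' @return a tibble with one row per unordered code pair: `code1`, `code2`,
#'   `distance` (mm, `NA` = missing), `support`, `same_jaw`.
#' @method tidy distance_prior
#' @export
tidy.distance_prior <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  c1 <- fdi_codes()[ut[, 1]]; c2 <- fdi_codes()[ut[, 2]]
  tibble::tibble(
    code1 = c1, code2 = c2,
    distance = x$d[ut],
    support = as.integer(x$support[ut]),
    same_jaw = fdi_jaw(c1) == fdi_jaw(c2))
}
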