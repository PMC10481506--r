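#' Default parametric dental-arch template
#'
#' An anatomically plausible adult arch used by the simulator: tooth slots
#' lie on a parabola in the occlusal plane (x left-right, y
#' anterior-posterior, both mm), equally spaced in arc length, with
#' per-code crown extents (mesiodistal x buccolingual x height) drawn from
#' typical adult averages — molars wider than premolars, premolars wider
#' than lower incisors. Upper arches are slightly wider than lower ones.
#'
#' @param jaw `"upper"` or `"lower"`.
#' @param width arch width at the last molars (mm); default 56 (upper) /
#'   52 (lower).
#' @param depth arch depth from molars to incisors (mm); default 46.
#' @return an object of class `arch_template`: list with `jaw`, `width`,
#'   `depth`, `slots` (tibble: `code`, `arch_index`, `x`, `y`, `z`) and
#'   `tooth_sizes` (tibble: `code`, `md`, `bl`, `h` in mm).
#' @examples
#' default_template("upper")$slots
#' @export
default_template <- function(jaw = c("upper", "lower"), width = NULL,
                             depth = 46) {
  jaw <- match.arg(jaw)
  if (is.null(width)) width <- if (jaw == "upper") 56 else 52
  half <- width / 2
  # parabola y(x) = depth * (1 - (x/half)^2); slots equally spaced in arc length
  xs <- seq(-half, half, length.out = 4001)
  ys <- depth * (1 - (xs / half)^2)
  arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  stations <- seq(arc[1], arc[length(arc)], length.out = 16)
  sx <- stats::approx(arc, xs, xout = stations)$y
  sy <- stats::approx(arc, ys, xout = stations)$y
  codes <- fdi_jaw_codes(jaw)
  slots <- tibble::tibble(
    code = codes, arch_index = 0:15,
    x = sx, y = sy, z = rep(0, 16))
  # typical mean crown extents (mm): mesiodistal, buccolingual, height
  pos <- codes %% 10L
  md <- if (jaw == "upper") c(8.5, 6.6, 7.6, 7.1, 6.8, 10.1, 9.6, 8.9)[pos]
        else                c(5.3, 5.9, 6.8, 7.0, 7.1, 11.2, 10.7, 10.5)[pos]
  bl <- if (jaw == "upper") c(7.1, 6.2, 8.1, 9.2, 9.3, 11.1, 11.3, 10.9)[pos]
        else                c(5.7, 6.1, 7.7, 7.8, 8.2, 10.3, 10.1, 9.8)[pos]
  h <- c(10.5, 9.8, 10.6, 8.5, 8.2, 7.5, 7.2, 6.6)[pos]
  structure(list(jaw = jaw, width = width, depth = depth, slots = slots,
                 tooth_sizes = tibble::tibble(code = codes, md = md,
                                              bl = bl, h = h)),
            class = "arch_template")
}

#' @export
print.arch_template <- function(x, ...) {
  cat("<arch_template> ", x$jaw, " jaw, width ", x$width, " mm, depth ",
      x$depth, " mm, 16 slots\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' One flat set of knobs controlling the synthetic arch generator and the
#' detector simulator. The defaults describe a clean scan (no noise, full
#' dentition); studies switch on the error modes they examine. All rates
#' are per-tooth probabilities in \[0, 1\].
#'
#' @param seed integer seed governing every random draw.
#' @param missing_codes either an integer vector of FDI codes to omit, or a
#'   single count of teeth to remove at random (third molars and premolars
#'   preferentially, where real dentitions most often lack teeth).
#' @param com_jitter_sigma sd (mm) of the per-axis Gaussian displacement of
#'   each detected tooth.
#' @param points_per_tooth points sampled per tooth cluster.
#' @param gingiva_points gingiva points along the arch band.
#' @param false_positive_rate expected spurious detections per true tooth.
#' @param miss_rate probability a true tooth is not detected.
#' @param mask_flip_rate fraction of a detection's points whose
#'   tooth/gingiva label is flipped (concentrated at the cluster boundary,
#'   where real segmentations err).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, missing_codes = integer(0),
                              com_jitter_sigma = 0, points_per_tooth = 300L,
                              gingiva_points = 1500L,
                              false_positive_rate = 0, miss_rate = 0,
                              mask_flip_rate = 0) {
  stopifnot(com_jitter_sigma >= 0, points_per_tooth >= 1,
            gingiva_points >= 0,
            false_positive_rate >= 0, false_positive_rate <= 1,
            miss_rate >= 0, miss_rate <= 1,
            mask_flip_rate >= 0, mask_flip_rate <= 1)
  structure(list(seed = as.integer(seed), missing_codes = missing_codes,
                 com_jitter_sigma = com_jitter_sigma,
                 points_per_tooth = as.integer(points_per_tooth),
                 gingiva_points = as.integer(gingiva_points),
                 false_positive_rate = false_positive_rate,
                 miss_rate = miss_rate, mask_flip_rate = mask_flip_rate),
            class = "simulation_config")
}

# resolve missing_codes (count or codes) into a code set, inside the RNG scope
resolve_missing <- function(template, missing_codes) {
  codes <- template$slots$code
  if (length(missing_codes) == 1 && !missing_codes %in% fdi_codes()) {
    k <- as.integer(missing_codes)
    stopifnot(k >= 0, k <= 15)
    if (k == 0) return(integer(0))
    pos <- codes %% 10L
    w <- ifelse(pos == 8L, 8, ifelse(pos %in% c(4L, 5L), 3, 1))
    return(sample(codes, k, prob = w))
  }
  stopifnot(all(missing_codes %in% fdi_codes()))
  as.integer(missing_codes)
}

#' Generate a ground-truth synthetic arch scene
#'
#' Builds one scan worth of ground truth from a template: for each
#' non-missing tooth a box-shaped cluster of points around its slot
#' (recentred so the cluster mean sits exactly on the slot, hence noiseless
#' COMs coincide with slot positions), plus a band of gingiva points along
#' the arch. Deterministic under `config$seed`. The crowns are deliberately
#' primitive — the labeling algorithm only consumes COMs, masks and boxes.
#'
#' @param template an [default_template()] arch template.
#' @param config a [simulation_config()].
#' @param mesh if `TRUE`, additionally triangulate each tooth cluster's
#'   bounding box into a labeled toy mesh (12 triangles per tooth).
#' @return a list: `scene` (ground-truth arch scene, detections carry
#'   `fdi`), `cloud` (full labeled point tibble with `class`/`instance`),
#'   `mesh` (a [labeled_mesh()] or `NULL`), `missing_codes`.
#' @export
generate_scene <- function(template, config = simulation_config(),
                           mesh = FALSE) {
  stopifnot(inherits(template, "arch_template"),
            inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    missing <- resolve_missing(template, config$missing_codes)
    slots <- template$slots[!template$slots$code %in% missing, , drop = FALSE]
    if (nrow(slots) == 0)
      stop("generate_scene: all teeth missing", call. = FALSE)
    dets <- vector("list", nrow(slots))
    clouds <- vector("list", nrow(slots))
    for (i in seq_len(nrow(slots))) {
      sz <- template$tooth_sizes[template$tooth_sizes$code == slots$code[i], ]
      n <- config$points_per_tooth
      pts <- cbind(stats::runif(n, -sz$md / 2, sz$md / 2),
                   stats::runif(n, -sz$bl / 2, sz$bl / 2),
                   stats::runif(n, -sz$h / 2, sz$h / 2))
      pts <- sweep(pts, 2, colMeans(pts))          # exact zero mean
      pts <- sweep(pts, 2, c(slots$x[i], slots$y[i], slots$z[i]), "+")
      dets[[i]] <- tooth_detection(pts, detection_id = i, fdi = slots$code[i])
      clouds[[i]] <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                    class = 1L, instance = i)
    }
    detections <- dplyr::bind_rows(dets)
    gin <- NULL
    if (config$gingiva_points > 0) {
      half <- template$width / 2
      gx <- stats::runif(config$gingiva_points, -half, half)
      gy <- template$depth * (1 - (gx / half)^2) +
        stats::rnorm(config$gingiva_points, 0, 2)
      gz <- stats::runif(config$gingiva_points, -12, -6)  # below the crowns
      gin <- tibble::tibble(x = gx, y = gy, z = gz, class = 0L, instance = 0L)
    }
    cloud <- dplyr::bind_rows(c(clouds, list(gin)))
    msh <- if (mesh) scene_to_mesh(detections) else NULL
    list(scene = build_scene(detections, jaw_hint = template$jaw),
         cloud = cloud, mesh = msh, missing_codes = missing)
  })
}

# toy watertight mesh: one 12-triangle box per tooth bounding box
scene_to_mesh <- function(detections) {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tri <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
               c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
               c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  verts <- NULL; faces <- NULL; labels <- integer(0)
  for (i in seq_len(nrow(detections))) {
    lo <- c(detections$xmin[i], detections$ymin[i], detections$zmin[i])
    hi <- c(detections$xmax[i], detections$ymax[i], detections$zmax[i])
    v <- sweep(sweep(corners, 2, hi - lo, "*"), 2, lo, "+")
    faces <- rbind(faces, tri + if (is.null(verts)) 0L else nrow(verts))
    verts <- rbind(verts, v)
    labels <- c(labels, rep(detections$detection_id[i], 12))
  }
  fdi_map <- stats::setNames(detections$fdi, detections$detection_id)
  fdi_map <- fdi_map[!is.na(fdi_map)]
  labeled_mesh(verts, faces, labels, fdi_map)
}

#' Simulate detector output from a ground-truth scene
#'
#' Applies the error modes of a detection + segmentation front end to a
#' ground-truth scene: each true tooth is missed with probability
#' `miss_rate`; survivors are displaced by an isotropic Gaussian COM jitter
#' of sd `com_jitter_sigma` per axis (the whole point cluster is
#' translated); a `mask_flip_rate` fraction of each detection's points —
#' the ones farthest from the center, mimicking cervical-margin errors —
#' get their tooth/gingiva label flipped; spurious detections appear
#' between slots at an expected `false_positive_rate` per true tooth.
#'
#' @param truth a ground-truth scene from [generate_scene()] (the list or
#'   its `$scene`).
#' @param config a [simulation_config()].
#' @param seed seed for the detector noise; defaults to `config$seed`.
#' @return a list: `scene` (predicted arch scene, `fdi` unset),
#'   `correspondence` (tibble `pred_id`, `truth_id`, `truth_fdi`; one row
#'   per predicted detection, `truth_id` `NA` for spurious ones),
#'   `missed` (tibble of undetected truth ids and codes).
#' @export
simulate_detector <- function(truth, config = simulation_config(),
                              seed = config$seed) {
  if (!inherits(truth, "arch_scene") && !is.null(truth$scene))
    truth <- truth$scene
  stopifnot(inherits(truth, "arch_scene"))
  td <- truth$detections
  withr::with_seed(seed, {
    keep <- stats::runif(nrow(td)) >= config$miss_rate
    preds <- list(); corr <- list()
    next_id <- 1L
    for (i in which(keep)) {
      pts <- td$points[[i]]
      mask <- td$mask[[i]]
      if (config$mask_flip_rate > 0) {
        com <- c(td$x[i], td$y[i], td$z[i])
        dist2 <- rowSums(sweep(pts, 2, com)^2)
        k <- round(config$mask_flip_rate * nrow(pts))
        if (k > 0) {
          flip <- order(dist2, decreasing = TRUE)[seq_len(k)]
          mask[flip] <- !mask[flip]
        }
      }
      jit <- stats::rnorm(3, 0, config$com_jitter_sigma)
      pts <- sweep(pts, 2, jit, "+")
      if (!any(mask)) mask[which.min(rowSums(sweep(pts, 2, colMeans(pts))^2))] <- TRUE
      preds[[length(preds) + 1]] <- tooth_detection(pts, mask, next_id)
      corr[[length(corr) + 1]] <- tibble::tibble(
        pred_id = next_id, truth_id = td$detection_id[i], truth_fdi = td$fdi[i])
      next_id <- next_id + 1L
    }
    n_fp <- stats::rbinom(1, nrow(td), config$false_positive_rate)
    if (n_fp > 0 && nrow(td) >= 2) {
      ord <- order(td$x)
      for (j in seq_len(n_fp)) {
        a <- sample(length(ord) - 1, 1)
        mid <- (c(td$x[ord[a]], td$y[ord[a]], td$z[ord[a]]) +
                c(td$x[ord[a + 1]], td$y[ord[a + 1]], td$z[ord[a + 1]])) / 2
        n <- max(20L, config$points_per_tooth %/% 4L)
        pts <- sweep(matrix(stats::runif(3 * n, -2, 2), ncol = 3), 2, mid, "+")
        preds[[length(preds) + 1]] <- tooth_detection(pts, detection_id = next_id)
        corr[[length(corr) + 1]] <- tibble::tibble(
          pred_id = next_id, truth_id = NA_integer_, truth_fdi = NA_integer_)
        next_id <- next_id + 1L
      }
    }
    if (length(preds) == 0)
      return(list(scene = NULL,
                  correspondence = tibble::tibble(pred_id = integer(0),
                                                  truth_id = integer(0),
                                                  truth_fdi = integer(0)),
                  missed = td[!keep, c("detection_id", "fdi")]))
    list(scene = build_scene(dplyr::bind_rows(preds),
                             jaw_hint = truth$jaw_hint,
                             upper_is_up = truth$upper_is_up),
         correspondence = dplyr::bind_rows(corr),
         missed = td[!keep, c("detection_id", "fdi")])
  })
}

#' Analytic distance prior of a template
#'
#' The pairwise slot distances of a template as a noise-free prior —
#' exactly what [estimate_distance_prior()] converges to on noiseless
#' scenes generated from the same template. Entries outside the template's
#' jaw stay missing; support is marked `NA` (analytic).
#'
#' @param template an [default_template()], or a list of templates (e.g.
#'   upper and lower) whose jaw blocks are combined.
#' @return a [distance_prior()].
#' @export
template_prior <- function(template) {
  if (inherits(template, "arch_template")) template <- list(template)
  codes <- as.character(fdi_codes())
  d <- matrix(NA_real_, 32, 32, dimnames = list(codes, codes))
  for (tpl in template) {
    stopifnot(inherits(tpl, "arch_template"))
    idx <- as.character(tpl$slots$code)
    d[idx, idx] <- as.matrix(stats::dist(
      cbind(tpl$slots$x, tpl$slots$y, tpl$slots$z)))
  }
  diag(d) <- 0
  distance_prior(d)
}
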