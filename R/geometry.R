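#' Axis-aligned 3D box
#'
#' Boxes are axis-aligned in scanner coordinates (millimeters), stored as a
#' pair of corners with `min <= max` componentwise.
#'
#' @param min,max numeric length-3 corners (mm).
#' @return an object of class `box3`.
#' @export
box3 <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  stopifnot(length(min) == 3, length(max) == 3,
            all(is.finite(min)), all(is.finite(max)))
  if (any(min > max)) stop("box3: min corner exceeds max corner", call. = FALSE)
  structure(list(min = min, max = max), class = "box3")
}

#' @export
print.box3 <- function(x, ...) {
  cat("<box3> min =", paste(signif(x$min, 6), collapse = ", "),
      " max =", paste(signif(x$max, 6), collapse = ", "), "\n")
  invisible(x)
}

box3_volume <- function(b) prod(pmax(b$max - b$min, 0))

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (!all(is.finite(points))) stop("points must be finite", call. = FALSE)
  points
}

#' Minimum axis-aligned bounding box of a tooth's points
#'
#' The tooth instance annotation used throughout this package is the minimum
#' 3D bounding box around the tooth's points: every point lies inside or on
#' the box and each face of the box touches at least one point.
#'
#' @param points a numeric matrix (n x 3) or data frame with columns
#'   `x`, `y`, `z`, in mm.
#' @return a [box3()].
#' @examples
#' compute_tooth_bbox(rbind(c(0, 0, 0), c(1, 2, 3)))
#' @export
compute_tooth_bbox <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) == 0) stop("compute_tooth_bbox: no points", call. = FALSE)
  box3(apply(points, 2, min), apply(points, 2, max))
}

#' Expand a box about its center
#'
#' Scales the box by `factor` in each axis while keeping its center fixed.
#' Used to grow a detected tooth's bounding box before sampling points for
#' segmentation, so that the cervical margin and nearby gingiva are included.
#'
#' @param box a [box3()].
#' @param factor positive scale factor per axis; the default 1.2 includes
#'   neighboring tissue without letting adjacent teeth dominate the sample.
#' @return the expanded [box3()].
#' @export
expand_box <- function(box, factor = 1.2) {
  stopifnot(inherits(box, "box3"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("expand_box: factor must be a positive scalar", call. = FALSE)
  center <- (box$min + box$max) / 2
  half <- (box$max - box$min) / 2 * factor
  box3(center - half, center + half)
}

#' Sample a fixed-size point set inside a box
#'
#' Draws exactly `n` points uniformly at random from the cloud points lying
#' inside `box` (boundary inclusive). When fewer than `n` candidates exist
#' the draw is with replacement so the fixed-size contract holds; when at
#' least `n` exist the draw is without replacement. Per-point class labels
#' are carried over.
#'
#' @param cloud a point cloud: data frame with columns `x`, `y`, `z` and
#'   optionally `class` (1 = tooth, 0 = gingiva) and other per-point columns.
#' @param box a [box3()].
#' @param n number of points to return (default 8192, the fixed budget the
#'   segmentation stage expects).
#' @param seed integer seed making the draw reproducible.
#' @return a tibble of `n` rows with the cloud's columns.
#' @export
sample_points_in_box <- function(cloud, box, n = 8192, seed = 1L) {
  stopifnot(inherits(box, "box3"), n >= 1)
  cloud <- tibble::as_tibble(cloud)
  inside <- cloud$x >= box$min[1] & cloud$x <= box$max[1] &
    cloud$y >= box$min[2] & cloud$y <= box$max[2] &
    cloud$z >= box$min[3] & cloud$z <= box$max[3]
  idx <- which(inside)
  if (length(idx) == 0)
    stop("sample_points_in_box: no cloud points inside box (empty detection)",
         call. = FALSE)
  pick <- withr::with_seed(seed,
    sample(idx, n, replace = length(idx) < n))
  cloud[pick, , drop = FALSE]
}

#' Center of mass of a detection's tooth points
#'
#' The unweighted arithmetic mean of the coordinates of the points classified
#' as tooth (the center of the segmentation mask). Gingiva points are
#' ignored.
#'
#' @param points n x 3 matrix or data frame with `x`, `y`, `z`.
#' @param mask logical or 0/1 vector, length n; `TRUE`/1 marks tooth points.
#'   Defaults to all-tooth.
#' @return numeric length-3 center (mm).
#' @export
center_of_mass <- function(points, mask = NULL) {
  points <- as_point_matrix(points)
  if (is.null(mask)) mask <- rep(TRUE, nrow(points))
  mask <- as.logical(mask)
  stopifnot(length(mask) == nrow(points))
  if (!any(mask)) stop("center_of_mass: no tooth-class points", call. = FALSE)
  colMeans(points[mask, , drop = FALSE])
}

#' Build a one-row tooth detection record
#'
#' Packs a detected tooth's point set and binary tooth/gingiva mask into the
#' tabular detection format used by the rest of the package: one row per
#' detection with its center of mass (`x`, `y`, `z`), bounding box columns
#' and mask counts, plus the raw points/mask as list-columns.
#'
#' @param points n x 3 matrix or data frame of the detection's points (mm).
#' @param mask logical/0-1 vector marking tooth points (default all tooth).
#' @param detection_id integer id.
#' @param fdi optional ground-truth FDI code.
#' @return a one-row tibble.
#' @export
tooth_detection <- function(points, mask = NULL, detection_id = 1L, fdi = NA_integer_) {
  points <- as_point_matrix(points)
  if (is.null(mask)) mask <- rep(TRUE, nrow(points))
  mask <- as.logical(mask)
  com <- unname(center_of_mass(points, mask))
  box <- compute_tooth_bbox(points)
  tibble::tibble(
    detection_id = as.integer(detection_id),
    x = com[1], y = com[2], z = com[3],
    xmin = box$min[1], ymin = box$min[2], zmin = box$min[3],
    xmax = box$max[1], ymax = box$max[2], zmax = box$max[3],
    n_points = nrow(points), n_tooth = sum(mask), n_gingiva = sum(!mask),
    fdi = as.integer(fdi),
    points = list(points), mask = list(mask)
  )
}

detection_box <- function(detections, i) {
  box3(c(detections$xmin[i], detections$ymin[i], detections$zmin[i]),
       c(detections$xmax[i], detections$ymax[i], detections$zmax[i]))
}

#' Assemble detections into an arch scene
#'
#' An arch scene holds all tooth detections of one scan plus the scene-wide
#' center-of-mass statistics the labeling algorithm uses: the global COM
#' (mean of all detection COMs) and its axial component, which acts as a
#' watershed separating the two half jaws.
#'
#' @param detections a detection tibble with at least `detection_id` and COM
#'   columns `x`, `y`, `z` (e.g. rows from [tooth_detection()]).
#' @param jaw_hint optional `"upper"`, `"lower"` or `"both"`. Single-jaw
#'   scans should set this: the watershed of a one-jaw scan splits the jaw's
#'   own teeth, so the hint overrides the watershed side test during labeling.
#' @param upper_is_up logical; `TRUE` (default) means upper-jaw teeth are
#'   expected at COM z >= watershed. Set `FALSE` for scans with inverted
#'   axial orientation.
#' @return an object of class `arch_scene`: list with `detections`,
#'   `com_global`, `watershed_z`, `jaw_hint`, `upper_is_up`.
#' @examples
#' det <- dplyr::bind_rows(
#'   tooth_detection(rbind(c(0, 0, 0)), detection_id = 1),
#'   tooth_detection(rbind(c(0, 0, 2)), detection_id = 2))
#' build_scene(det)$watershed_z
#' @export
build_scene <- function(detections, jaw_hint = NULL, upper_is_up = TRUE) {
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) == 0)
    stop("build_scene: at least one detection required", call. = FALSE)
  stopifnot(all(c("detection_id", "x", "y", "z") %in% names(detections)))
  if (!is.null(jaw_hint)) jaw_hint <- match.arg(jaw_hint, c("upper", "lower", "both"))
  com_global <- c(mean(detections$x), mean(detections$y), mean(detections$z))
  structure(list(
    detections = detections,
    com_global = com_global,
    watershed_z = com_global[3],
    jaw_hint = jaw_hint,
    upper_is_up = isTRUE(upper_is_up)
  ), class = "arch_scene")
}

#' @export
print.arch_scene <- function(x, ...) {
  cat("<arch_scene> ", nrow(x$detections), " detections, watershed z = ",
      signif(x$watershed_z, 6),
      if (!is.null(x$jaw_hint)) paste0(", jaw hint: ", x$jaw_hint), "\n", sep = "")
  invisible(x)
}

#' Intersection-over-union of two axis-aligned boxes
#'
#' Volume of the intersection divided by volume of the union; 0 for disjoint
#' boxes, 1 for identical non-degenerate boxes.
#'
#' @param a,b [box3()] objects.
#' @return scalar in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  stopifnot(inherits(a, "box3"), inherits(b, "box3"))
  inter_min <- pmax(a$min, b$min)
  inter_max <- pmin(a$max, b$max)
  inter <- prod(pmax(inter_max - inter_min, 0))
  union <- box3_volume(a) + box3_volume(b) - inter
  if (union <= 0) {
    # degenerate boxes: identical degenerate boxes count as overlapping
    return(if (identical(a$min, b$min) && identical(a$max, b$max)) 1 else 0)
  }
  inter / union
}

#' Max-pool point features onto a Cartesian grid
#'
#' Voxelizes a featured point cloud: the grid spans the cloud's bounding box
#' with cubic cells of side `cell_size`; each occupied cell holds the
#' componentwise maximum of the features of the points falling in it, empty
#' cells hold 0. This is the preprocessing step that turns an irregular
#' surface point cloud into a dense grid a volumetric detector can consume.
#'
#' @param cloud data frame with `x`, `y`, `z` and one or more feature
#'   columns (every non-coordinate numeric column is treated as a feature).
#' @param cell_size cell edge length in mm (> 0). No privileged default: the
#'   resolution is a study choice.
#' @return a list: `grid` (4-d array, dims nx, ny, nz, n_features), `origin`
#'   (grid corner), `cell_size`, `features` (feature column names).
#' @export
grid_max_pool <- function(cloud, cell_size) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0)
  cloud <- tibble::as_tibble(cloud)
  feat_cols <- setdiff(names(cloud)[vapply(cloud, is.numeric, logical(1))],
                       c("x", "y", "z"))
  if (length(feat_cols) == 0)
    stop("grid_max_pool: cloud has no feature columns", call. = FALSE)
  origin <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  span <- c(max(cloud$x), max(cloud$y), max(cloud$z)) - origin
  dims <- pmax(ceiling(span / cell_size), 1)
  # points exactly on the far boundary fall into the last cell
  ix <- pmin(floor((cloud$x - origin[1]) / cell_size), dims[1] - 1)
  iy <- pmin(floor((cloud$y - origin[2]) / cell_size), dims[2] - 1)
  iz <- pmin(floor((cloud$z - origin[3]) / cell_size), dims[3] - 1)
  grid <- array(0, dim = c(dims, length(feat_cols)))
  cell <- ix + dims[1] * (iy + dims[2] * iz)  # linear cell id
  for (k in seq_along(feat_cols)) {
    mx <- tapply(cloud[[feat_cols[k]]], cell, max)
    lin <- as.integer(names(mx)) + 1L + prod(dims) * (k - 1L)
    grid[lin] <- mx
  }
  list(grid = grid, origin = origin, cell_size = cell_size,
       features = feat_cols)
}
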