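#' Read / write arch scenes as JSON
#'
#' Detections serialize as
#' `{detections: [{id, com: [x,y,z], box: {min, max}, n_points,
#' mask_counts: {tooth, gingiva}, fdi}], watershed_z, jaw_hint, ...}`.
#' Point payloads are not embedded; the JSON carries the summary geometry
#' the labeling and evaluation stages consume. Every file written embeds
#' the package version and, when given, the seed/config it came from.
#'
#' @param scene an arch scene.
#' @param path JSON path.
#' @param seed,config optional provenance recorded in the file.
#' @return `read_scene_json` returns an arch scene; `write_scene_json`
#'   returns `path` invisibly.
#' @export
write_scene_json <- function(scene, path, seed = NULL, config = NULL) {
  stopifnot(inherits(scene, "arch_scene"))
  d <- scene$detections
  dets <- lapply(seq_len(nrow(d)), function(i) {
    rec <- list(
      id = d$detection_id[i],
      com = c(d$x[i], d$y[i], d$z[i]),
      box = list(min = c(d$xmin[i], d$ymin[i], d$zmin[i]),
                 max = c(d$xmax[i], d$ymax[i], d$zmax[i])),
      n_points = d$n_points[i],
      mask_counts = list(tooth = d$n_tooth[i], gingiva = d$n_gingiva[i]))
    if (!is.na(d$fdi[i])) rec$fdi <- d$fdi[i]
    rec
  })
  obj <- list(detections = dets,
              watershed_z = scene$watershed_z,
              jaw_hint = scene$jaw_hint,
              upper_is_up = scene$upper_is_up,
              package_version = as.character(utils::packageVersion("dentalabel")))
  if (!is.null(seed)) obj$seed <- seed
  if (!is.null(config)) obj$config <- unclass(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (length(obj$detections) == 0)
    stop("read_scene_json: no detections in ", path, call. = FALSE)
  rows <- purrr::map_dfr(obj$detections, function(rec) {
    tibble::tibble(
      detection_id = as.integer(rec$id),
      x = rec$com[[1]], y = rec$com[[2]], z = rec$com[[3]],
      xmin = rec$box$min[[1]], ymin = rec$box$min[[2]], zmin = rec$box$min[[3]],
      xmax = rec$box$max[[1]], ymax = rec$box$max[[2]], zmax = rec$box$max[[3]],
      n_points = as.integer(rec$n_points %||% NA),
      n_tooth = as.integer(rec$mask_counts$tooth %||% NA),
      n_gingiva = as.integer(rec$mask_counts$gingiva %||% NA),
      fdi = as.integer(rec$fdi %||% NA))
  })
  build_scene(rows,
              jaw_hint = obj$jaw_hint,
              upper_is_up = obj$upper_is_up %||% TRUE)
}

#' Write a labeling result as JSON
#'
#' Schema: `{labels: {<detection_id>: fdi-or-null}, penalties: {f1, f2,
#' f3}, stages: [...]}` plus provenance.
#'
#' @param result a `labeling_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeling_json <- function(result, path) {
  stopifnot(inherits(result, "labeling_result"))
  labs <- as.list(stats::setNames(result$labels$fdi, result$labels$detection_id))
  labs <- lapply(labs, function(v) if (is.na(v)) NULL else v)
  g <- glance(result)
  jsonlite::write_json(list(
    labels = labs,
    penalties = list(f1 = g$f1, f2 = g$f2, f3 = g$f3),
    stages = result$penalties,
    weights = unclass(result$weights),
    package_version = as.character(utils::packageVersion("dentalabel"))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
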