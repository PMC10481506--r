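#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarize a labeling result
#'
#' `tidy()` returns the per-detection label table; `glance()` a one-row
#' summary with the stage penalties and assignment counts.
#'
#' @param x a `labeling_result` from [label_teeth()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy labeling_result
#' @export
tidy.labeling_result <- function(x, ...) {
  x$labels
}

#' @rdname tidy.labeling_result
#' @method glance labeling_result
#' @export
glance.labeling_result <- function(x, ...) {
  p <- x$penalties
  tibble::tibble(
    n_detections = nrow(x$labels),
    n_assigned = sum(!is.na(x$labels$fdi)),
    f1 = p$f1[p$stage == "E1"],
    f2 = p$f2[p$stage == "E2"],
    f3 = p$f3[p$stage == "E3"])
}

#' Plot an arch scene in the occlusal plane
#'
#' Detection COMs in the x-y plane, labeled with their FDI code when the
#' detections carry one.
#'
#' @param object an `arch_scene`.
#' @param labels optional tibble `detection_id`, `fdi` overriding the
#'   scene's own `fdi` column (e.g. from [tidy()] of a labeling result).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot arch_scene
#' @export
autoplot.arch_scene <- function(object, labels = NULL, ...) {
  d <- object$detections
  if (!is.null(labels))
    d <- dplyr::left_join(dplyr::select(d, -dplyr::any_of("fdi")),
                          tibble::as_tibble(labels), by = "detection_id")
  if (!"fdi" %in% names(d)) d$fdi <- NA_integer_
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$fdi), "?",
                                                   .data$fdi)),
                       nudge_y = 1.5, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, patient left-right)",
                  y = "y (mm, posterior-anterior)",
                  title = "Arch scene (occlusal view)") +
    ggplot2::theme_minimal()
}

#' Heatmap of the numbering confusion matrices
#'
#' One tile map per jaw: rows actual FDI codes (plus `unassigned`),
#' columns predicted; brighter tiles mean higher agreement.
#'
#' @param object a `labeling_eval` from [labeling_accuracy()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot labeling_eval
#' @export
autoplot.labeling_eval <- function(object, ...) {
  long <- purrr::imap_dfr(object$confusion, function(mat, jaw) {
    df <- as.data.frame.table(mat, responseName = "count")
    df$jaw <- jaw
    df
  })
  long$actual <- factor(long$actual, levels = rev(levels(long$actual)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~jaw, scales = "free") +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "predicted", y = "actual",
                  title = "FDI numbering confusion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-tooth metric profiles
#'
#' Bar chart of a per-code metric table (detection or numbering), one bar
#' per FDI code.
#'
#' @param data a tibble with a `code` column and the metric columns to
#'   show.
#' @param metric column name to plot (default `"accuracy"`).
#' @return a ggplot.
#' @export
plot_per_tooth <- function(data, metric = "accuracy") {
  data <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$code))
  ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$code),
                                     y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "FDI code", y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
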