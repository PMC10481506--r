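#' Classification metrics from contingency counts
#'
#' Exact evaluation of the four standard counts-based metrics with tooth as
#' the positive class: accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and intersection-over-union
#' `TP/(TP+FP+FN)`. A metric whose denominator is zero is undefined and
#' reported as `NA`, never as 0 — an absent class should not drag a
#' per-tooth mean.
#'
#' @param tp,fp,fn,tn non-negative counts (vectorized).
#' @return a tibble with columns `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `iou`.
#' @examples
#' classification_metrics(tp = 8, fp = 1, fn = 1, tn = 90)
#' @export
classification_metrics <- function(tp, fp, fn, tn = NA_integer_) {
  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    iou = safe_div(tp, tp + fp + fn))
}

# ---- optimal one-to-one box matching -----------------------------------

# Hungarian algorithm (shortest augmenting path with potentials),
# minimizing total cost over a square matrix; returns col index per row
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row matched to column j (0 = free)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) match[p[j]] <- j
  match
}

boxes_of <- function(detections) {
  lapply(seq_len(nrow(detections)), function(i) detection_box(detections, i))
}

#' Match predicted to ground-truth detections by box overlap
#'
#' Computes the one-to-one matching between predicted and ground-truth
#' bounding boxes that maximizes the total box IoU (optimal linear
#' assignment, not greedy), then discards pairs whose IoU falls below
#' `iou_threshold`. Deterministic.
#'
#' @param pred,gt detection tibbles with `detection_id` and box columns
#'   (`xmin` ... `zmax`).
#' @param iou_threshold minimum IoU for a pair to count as matched
#'   (default 0.5, the usual object-detection operating point).
#' @return a `detection_matching` list: `matches` (tibble `pred_id`,
#'   `gt_id`, `iou`), `unmatched_pred`, `unmatched_gt` (id vectors).
#' @export
match_detections <- function(pred, gt, iou_threshold = 0.5) {
  pred <- tibble::as_tibble(pred); gt <- tibble::as_tibble(gt)
  np <- nrow(pred); ng <- nrow(gt)
  empty <- tibble::tibble(pred_id = integer(0), gt_id = integer(0),
                          iou = numeric(0))
  if (np == 0 || ng == 0)
    return(structure(list(matches = empty,
                          unmatched_pred = pred$detection_id,
                          unmatched_gt = gt$detection_id),
                     class = "detection_matching"))
  pb <- boxes_of(pred); gb <- boxes_of(gt)
  iou <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng))
    iou[i, j] <- box_iou(pb[[i]], gb[[j]])
  n <- max(np, ng)
  cost <- matrix(1, n, n)               # dummy pairs behave like IoU 0
  cost[seq_len(np), seq_len(ng)] <- 1 - iou
  assign <- hungarian_solve(cost)
  rows <- seq_len(np)
  cols <- assign[rows]
  ok <- cols <= ng & iou[cbind(rows, pmin(cols, ng))] >= iou_threshold
  matches <- tibble::tibble(
    pred_id = pred$detection_id[rows[ok]],
    gt_id = gt$detection_id[cols[ok]],
    iou = iou[cbind(rows[ok], cols[ok])])
  structure(list(
    matches = matches,
    unmatched_pred = setdiff(pred$detection_id, matches$pred_id),
    unmatched_gt = setdiff(gt$detection_id, matches$gt_id)),
    class = "detection_matching")
}

#' @export
print.detection_matching <- function(x, ...) {
  cat("<detection_matching> ", nrow(x$matches), " matched, ",
      length(x$unmatched_pred), " unmatched predictions, ",
      length(x$unmatched_gt), " unmatched ground truths\n", sep = "")
  invisible(x)
}

labels_lookup <- function(labels) {
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("detection_id", "fdi") %in% names(labels)))
  stats::setNames(labels$fdi, labels$detection_id)
}

#' Per-tooth detection metrics
#'
#' Counts, for each FDI code, label-aware detection outcomes: a true
#' positive is a matched pair where prediction and ground truth both carry
#' the code; predictions carrying the code without such a match are false
#' positives; ground-truth instances of the code without one are false
#' negatives. The mean box IoU is averaged over the code's true-positive
#' pairs. With `label_aware = FALSE` the per-code rows count any matched
#' pair whose *ground truth* carries the code as detected, regardless of
#' the predicted label (pure detection quality). A summary row
#' (`code = NA`) aggregates over all instances.
#'
#' @param matching a [match_detections()] result.
#' @param pred_labels,gt_labels tibbles with `detection_id`, `fdi`.
#' @param label_aware logical, default `TRUE`.
#' @return a tibble: `code`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `mean_box_iou`.
#' @export
detection_metrics <- function(matching, pred_labels, gt_labels,
                              label_aware = TRUE) {
  stopifnot(inherits(matching, "detection_matching"))
  pl <- labels_lookup(pred_labels); gl <- labels_lookup(gt_labels)
  m <- matching$matches
  m$pred_fdi <- unname(pl[as.character(m$pred_id)])
  m$gt_fdi <- unname(gl[as.character(m$gt_id)])
  codes_present <- sort(unique(stats::na.omit(c(m$gt_fdi, m$pred_fdi,
                                                gl[as.character(matching$unmatched_gt)],
                                                pl[as.character(matching$unmatched_pred)]))))
  per_code <- purrr::map_dfr(codes_present, function(cc) {
    if (label_aware) {
      tp_rows <- !is.na(m$gt_fdi) & m$gt_fdi == cc &
        !is.na(m$pred_fdi) & m$pred_fdi == cc
      n_pred_c <- sum(pl == cc, na.rm = TRUE)
      n_gt_c <- sum(gl == cc, na.rm = TRUE)
    } else {
      tp_rows <- !is.na(m$gt_fdi) & m$gt_fdi == cc
      n_pred_c <- NA_integer_   # per-code precision undefined in this mode
      n_gt_c <- sum(gl == cc, na.rm = TRUE)
    }
    tp <- sum(tp_rows)
    tibble::tibble(
      code = cc, tp = tp, fp = n_pred_c - tp, fn = n_gt_c - tp,
      mean_box_iou = if (tp > 0) mean(m$iou[tp_rows]) else NA_real_)
  })
  overall <- tibble::tibble(
    code = NA_integer_, tp = nrow(m),
    fp = length(matching$unmatched_pred),
    fn = length(matching$unmatched_gt),
    mean_box_iou = if (nrow(m)) mean(m$iou) else NA_real_)
  out <- dplyr::bind_rows(per_code, overall)
  cm <- classification_metrics(out$tp, out$fp, out$fn)
  out$precision <- cm$precision
  out$recall <- cm$recall
  out[, c("code", "tp", "fp", "fn", "precision", "recall", "mean_box_iou")]
}

#' Point-mask segmentation metrics
#'
#' Point-wise contingency counts between a predicted and a ground-truth
#' binary tooth/gingiva mask over the same point set (tooth = positive),
#' plus the derived metrics.
#'
#' @param pred_mask,gt_mask logical/0-1 vectors of equal length.
#' @return a one-row tibble from [classification_metrics()].
#' @export
segmentation_metrics <- function(pred_mask, gt_mask) {
  pred_mask <- as.logical(pred_mask); gt_mask <- as.logical(gt_mask)
  if (length(pred_mask) != length(gt_mask))
    stop("segmentation_metrics: mask lengths differ", call. = FALSE)
  classification_metrics(
    tp = sum(pred_mask & gt_mask),
    fp = sum(pred_mask & !gt_mask),
    fn = sum(!pred_mask & gt_mask),
    tn = sum(!pred_mask & !gt_mask))
}

#' Per-tooth numbering accuracy and confusion matrices
#'
#' For each FDI code, the fraction of its ground-truth instances whose
#' matched prediction carries the same code. Also builds one 17 x 17
#' confusion matrix per jaw (the jaw's 16 codes in arch order plus an
#' `unassigned` class): rows are actual codes, columns predicted; an
#' unmatched ground truth, an unlabeled match or a cross-jaw prediction
#' falls in the `unassigned` column, and spurious predictions carrying a
#' jaw code fill the `unassigned` row. Row sums over code rows equal the
#' ground-truth instance counts.
#'
#' @inheritParams detection_metrics
#' @return a `labeling_eval` list: `per_fdi` (tibble `code`, `n`,
#'   `correct`, `accuracy`), `mean_accuracy` (unweighted over present
#'   codes), `confusion` (named list `upper`, `lower` of matrices).
#' @export
labeling_accuracy <- function(matching, pred_labels, gt_labels) {
  stopifnot(inherits(matching, "detection_matching"))
  pl <- labels_lookup(pred_labels); gl <- labels_lookup(gt_labels)
  m <- matching$matches
  pred_of_gt <- stats::setNames(unname(pl[as.character(m$pred_id)]),
                                m$gt_id)
  gt_codes <- sort(unique(stats::na.omit(unname(gl))))
  per_fdi <- purrr::map_dfr(gt_codes, function(cc) {
    ids <- names(gl)[!is.na(gl) & gl == cc]
    pred <- pred_of_gt[ids]
    correct <- sum(!is.na(pred) & pred == cc)
    tibble::tibble(code = cc, n = length(ids), correct = correct,
                   accuracy = correct / length(ids))
  })
  confusion <- lapply(c(upper = "upper", lower = "lower"), function(jaw) {
    codes <- fdi_jaw_codes(jaw)
    lv <- c(as.character(codes), "unassigned")
    conf <- matrix(0L, 17, 17, dimnames = list(actual = lv, predicted = lv))
    for (id in names(gl)) {
      if (is.na(gl[[id]]) || !gl[[id]] %in% codes) next
      pred <- if (id %in% names(pred_of_gt)) pred_of_gt[[id]] else NA
      pc <- if (!is.na(pred) && pred %in% codes) as.character(pred) else "unassigned"
      conf[as.character(gl[[id]]), pc] <- conf[as.character(gl[[id]]), pc] + 1L
    }
    for (id in as.character(matching$unmatched_pred)) {
      pred <- pl[id]
      if (!is.na(pred) && pred %in% codes)
        conf["unassigned", as.character(pred)] <-
          conf["unassigned", as.character(pred)] + 1L
    }
    conf
  })
  structure(list(per_fdi = per_fdi,
                 mean_accuracy = mean(per_fdi$accuracy),
                 confusion = confusion),
            class = "labeling_eval")
}

#' @export
print.labeling_eval <- function(x, ...) {
  cat("<labeling_eval> mean per-tooth accuracy ",
      signif(x$mean_accuracy, 4), " over ", nrow(x$per_fdi),
      " codes\n", sep = "")
  invisible(x)
}

#' Evaluate a predicted scene against ground truth
#'
#' Convenience wrapper running the full evaluation suite: box matching,
#' per-tooth detection metrics, numbering accuracy with confusion
#' matrices, and — when predicted and true detections share index-aligned
#' point sets (as the simulator guarantees) — pooled point-mask
#' segmentation metrics over matched pairs.
#'
#' @param pred_scene,truth_scene arch scenes; truth detections carry `fdi`.
#' @param pred_labels tibble `detection_id`, `fdi` for the predictions
#'   (e.g. `tidy(label_teeth(...))`).
#' @param iou_threshold passed to [match_detections()].
#' @return a `metrics_report` list: `matching`, `detection`, `labeling`,
#'   `segmentation` (or `NULL`).
#' @export
evaluate_scene <- function(pred_scene, truth_scene, pred_labels,
                           iou_threshold = 0.5) {
  stopifnot(inherits(pred_scene, "arch_scene"),
            inherits(truth_scene, "arch_scene"))
  gt_labels <- truth_scene$detections[, c("detection_id", "fdi")]
  matching <- match_detections(pred_scene$detections, truth_scene$detections,
                               iou_threshold)
  seg <- NULL
  if (all(c("mask", "points") %in% names(pred_scene$detections)) &&
      all(c("mask", "points") %in% names(truth_scene$detections))) {
    pm <- list(); gm <- list()
    for (k in seq_len(nrow(matching$matches))) {
      i <- match(matching$matches$pred_id[k], pred_scene$detections$detection_id)
      j <- match(matching$matches$gt_id[k], truth_scene$detections$detection_id)
      a <- pred_scene$detections$mask[[i]]
      b <- truth_scene$detections$mask[[j]]
      if (length(a) == length(b)) { pm[[length(pm) + 1]] <- a; gm[[length(gm) + 1]] <- b }
    }
    if (length(pm))
      seg <- segmentation_metrics(unlist(pm), unlist(gm))
  }
  structure(list(
    matching = matching,
    detection = detection_metrics(matching, pred_labels, gt_labels),
    labeling = labeling_accuracy(matching, pred_labels, gt_labels),
    segmentation = seg), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$matching)
  print(x$labeling)
  invisible(x)
}
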