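test_that("classification metrics evaluate the printed formulas exactly", {
  m <- classification_metrics(tp = 8, fp = 1, fn = 1, tn = 90)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$iou, 0.8)
  expect_equal(m$accuracy, 0.98)
  # perfect prediction
  p <- classification_metrics(tp = 5, fp = 0, fn = 0, tn = 10)
  expect_equal(c(p$precision, p$recall, p$iou, p$accuracy), c(1, 1, 1, 1))
  # nothing right
  z <- classification_metrics(tp = 0, fp = 3, fn = 2, tn = 0)
  expect_equal(c(z$precision, z$recall, z$iou), c(0, 0, 0))
  # undefined denominators are missing, never zero
  u <- classification_metrics(tp = 0, fp = 0, fn = 0, tn = 0)
  expect_true(all(is.na(c(u$accuracy, u$precision, u$recall, u$iou))))
  u2 <- classification_metrics(tp = 0, fp = 0, fn = 2, tn = 0)
  expect_true(is.na(u2$precision))
  expect_equal(u2$recall, 0)
})

test_that("counts-based metrics match a brute-force confusion counter", {
  withr::with_seed(13, {
    for (i in 1:40) {
      n <- sample(10:200, 1)
      pred <- runif(n) > 0.5
      gt <- runif(n) > 0.3
      counts <- oracle_confusion(pred, gt)
      m <- segmentation_metrics(pred, gt)
      expect_equal(m$tp, counts[["tp"]])
      expect_equal(m$fp, counts[["fp"]])
      expect_equal(m$fn, counts[["fn"]])
      expect_equal(m$tn, counts[["tn"]])
      denom <- counts[["tp"]] + counts[["fp"]] + counts[["fn"]]
      if (denom > 0) expect_equal(m$iou, counts[["tp"]] / denom)
    }
  })
})

test_that("segmentation metrics handle the canonical mask examples", {
  expect_equal(segmentation_metrics(rep(1, 50), rep(1, 50))$iou, 1)
  # complementary masks share nothing
  expect_equal(segmentation_metrics(c(1, 1, 0, 0), c(0, 0, 1, 1))$iou, 0)
  # 9000/10000 agreement, balanced errors
  pred <- c(rep(1, 4500), rep(1, 500), rep(0, 500), rep(0, 4500))
  gt <- c(rep(1, 4500), rep(0, 500), rep(1, 500), rep(0, 4500))
  m <- segmentation_metrics(pred, gt)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$iou, 4500 / 5500)
  expect_error(segmentation_metrics(c(1, 0), c(1, 0, 1)), "length")
})

box_det <- function(id, center, half = c(1, 1, 1), fdi = NA_integer_) {
  tibble::tibble(detection_id = id,
                 x = center[1], y = center[2], z = center[3],
                 xmin = center[1] - half[1], ymin = center[2] - half[2],
                 zmin = center[3] - half[3],
                 xmax = center[1] + half[1], ymax = center[2] + half[2],
                 zmax = center[3] + half[3],
                 n_points = 1L, n_tooth = 1L, n_gingiva = 0L, fdi = fdi)
}

test_that("box matching is optimal, thresholded and deterministic", {
  gt <- dplyr::bind_rows(box_det(1L, c(0, 0, 0)), box_det(2L, c(10, 0, 0)))
  # identical sets: perfect matching
  m <- match_detections(gt, gt)
  expect_equal(nrow(m$matches), 2)
  expect_equal(m$matches$iou, c(1, 1))
  expect_length(m$unmatched_gt, 0)
  # empty predictions: everything is a false negative
  m0 <- match_detections(gt[0, ], gt)
  expect_equal(nrow(m0$matches), 0)
  expect_equal(m0$unmatched_gt, c(1L, 2L))
  # crossing configuration: the assignment maximizing total IoU wins over greedy
  pred <- dplyr::bind_rows(box_det(1L, c(0.4, 0, 0)), box_det(2L, c(0.8, 0, 0)))
  gt2 <- dplyr::bind_rows(box_det(1L, c(0.8, 0, 0)), box_det(2L, c(1.6, 0, 0)))
  mx <- match_detections(pred, gt2, iou_threshold = 0.05)
  iou_mat <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    iou_mat[i, j] <- box_iou(
      box3(unlist(pred[i, c("xmin", "ymin", "zmin")]),
           unlist(pred[i, c("xmax", "ymax", "zmax")])),
      box3(unlist(gt2[j, c("xmin", "ymin", "zmin")]),
           unlist(gt2[j, c("xmax", "ymax", "zmax")])))
  expect_equal(sum(mx$matches$iou), oracle_best_matching_iou(iou_mat),
               tolerance = 1e-9)
  # pairs under the threshold are discarded
  far <- dplyr::bind_rows(box_det(1L, c(0, 0, 0)), box_det(2L, c(1.9, 0, 0)))
  mt <- match_detections(far, gt)
  expect_equal(nrow(mt$matches), 1)
  expect_equal(mt$unmatched_pred, 2L)
})

test_that("optimal matching equals exhaustive enumeration on random scenes", {
  withr::with_seed(29, {
    for (i in 1:15) {
      np <- sample(1:5, 1); ng <- sample(1:5, 1)
      pred <- dplyr::bind_rows(lapply(seq_len(np), function(k)
        box_det(k, runif(3, 0, 6))))
      gt <- dplyr::bind_rows(lapply(seq_len(ng), function(k)
        box_det(k, runif(3, 0, 6))))
      m <- match_detections(pred, gt, iou_threshold = 1e-9)
      iou_mat <- matrix(0, np, ng)
      for (a in seq_len(np)) for (b in seq_len(ng))
        iou_mat[a, b] <- box_iou(detection_box(pred, a), detection_box(gt, b))
      expect_equal(sum(m$matches$iou), oracle_best_matching_iou(iou_mat),
                   tolerance = 1e-9)
    }
  })
})

labels_of <- function(det) det[, c("detection_id", "fdi")]

test_that("per-tooth detection metrics count label-aware outcomes", {
  gt <- dplyr::bind_rows(box_det(1L, c(0, 0, 0), fdi = 11L),
                         box_det(2L, c(10, 0, 0), fdi = 21L),
                         box_det(3L, c(20, 0, 0), fdi = 38L))
  # perfect detection and labels
  dm <- detection_metrics(match_detections(gt, gt), labels_of(gt), labels_of(gt))
  per <- dm[!is.na(dm$code), ]
  expect_true(all(per$precision == 1 & per$recall == 1))
  expect_true(all(per$mean_box_iou == 1))
  # one missed tooth of code 38
  pred2 <- gt[1:2, ]
  dm2 <- detection_metrics(match_detections(pred2, gt), labels_of(pred2),
                           labels_of(gt))
  per2 <- dm2[!is.na(dm2$code), ]
  expect_equal(per2$recall[per2$code == 38L], 0)
  expect_equal(per2$recall[per2$code == 11L], 1)
  # one spurious extra detection labeled 18
  pred3 <- dplyr::bind_rows(gt, box_det(4L, c(40, 0, 0), fdi = 18L))
  dm3 <- detection_metrics(match_detections(pred3, gt), labels_of(pred3),
                           labels_of(gt))
  nonmiss3 <- dm3[!is.na(dm3$code), ]
  expect_equal(nonmiss3$precision[nonmiss3$code == 18L], 0)   # tp 0, fp 1
  expect_equal(dm3$fp[is.na(dm3$code)], 1)
  # per-code tp + fn equals the ground-truth instance count of that code
  gt_counts <- c("11" = 1, "18" = 0, "21" = 1, "38" = 1)
  per3 <- dm3[!is.na(dm3$code), ]
  expect_equal(per3$tp + per3$fn, unname(gt_counts[as.character(per3$code)]))
})

test_that("numbering accuracy and confusion matrices reconcile", {
  tpl <- default_template("upper")
  gt <- generate_scene(tpl, simulation_config(seed = 8, points_per_tooth = 10L,
                                              gingiva_points = 0L))$scene$detections
  matching <- match_detections(gt, gt)
  # all labels correct: diagonal confusion, accuracy 1
  ev <- labeling_accuracy(matching, labels_of(gt), labels_of(gt))
  expect_true(all(ev$per_fdi$accuracy == 1))
  conf <- ev$confusion$upper
  expect_equal(sum(diag(conf[1:16, 1:16])), 16)
  expect_equal(sum(conf) - sum(diag(conf)), 0)
  # all labels shifted one arch slot: zero accuracy, superdiagonal band
  shift <- labels_of(gt)
  shifted_codes <- fdi_from_arch("upper", (fdi_arch_index(shift$fdi) + 1L) %% 16L)
  shift$fdi <- shifted_codes
  ev2 <- labeling_accuracy(matching, shift, labels_of(gt))
  expect_true(all(ev2$per_fdi$accuracy == 0))
  conf2 <- ev2$confusion$upper
  expect_equal(sum(diag(conf2[1:16, 1:16])), 0)
  # actual at arch k predicted at arch k+1
  for (k in 1:15)
    expect_equal(conf2[as.character(fdi_from_arch("upper", k - 1L)),
                       as.character(fdi_from_arch("upper", k))], 1L)
  # half of code-37 instances labeled 36 over two scans worth of instances
  gtl <- tibble::tibble(detection_id = 1:2, fdi = c(37L, 37L))
  prl <- tibble::tibble(detection_id = 1:2, fdi = c(37L, 36L))
  boxes <- dplyr::bind_rows(box_det(1L, c(0, 0, 0), fdi = 37L),
                            box_det(2L, c(10, 0, 0), fdi = 37L))
  ev3 <- labeling_accuracy(match_detections(boxes, boxes), prl, gtl)
  expect_equal(ev3$per_fdi$accuracy[ev3$per_fdi$code == 37L], 0.5)
  # row sums of code rows equal ground-truth instance counts
  expect_equal(unname(rowSums(ev3$confusion$lower)[as.character(37)]), 2)
})

test_that("metrics are invariant under instance order permutation", {
  tpl <- default_template("lower")
  gen <- generate_scene(tpl, simulation_config(seed = 21, points_per_tooth = 30L))
  sim <- simulate_detector(gen, simulation_config(seed = 22,
                                                  com_jitter_sigma = 0.5,
                                                  miss_rate = 0.1))
  pr <- template_prior(tpl)
  labs <- tidy(label_teeth(sim$scene, pr))
  rep1 <- evaluate_scene(sim$scene, gen$scene, labs)
  det <- sim$scene$detections
  withr::with_seed(1, det2 <- det[sample(nrow(det)), ])
  sc2 <- build_scene(det2, jaw_hint = sim$scene$jaw_hint)
  rep2 <- evaluate_scene(sc2, gen$scene, labs)
  expect_equal(rep1$labeling$per_fdi, rep2$labeling$per_fdi)
  expect_equal(rep1$labeling$confusion, rep2$labeling$confusion)
  d1 <- dplyr::arrange(rep1$detection, code)
  d2 <- dplyr::arrange(rep2$detection, code)
  expect_equal(d1, d2)
})
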