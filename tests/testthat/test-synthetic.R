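test_that("the default templates are plausible arches", {
  for (jaw in c("upper", "lower")) {
    tpl <- default_template(jaw)
    expect_equal(nrow(tpl$slots), 16)
    expect_equal(tpl$slots$code, fdi_jaw_codes(jaw))
    # slot x strictly increasing along the arch
    expect_true(all(diff(tpl$slots$x) > 0))
    # central incisors sit closer together than the first molars
    pos <- function(code) unlist(tpl$slots[tpl$slots$code == code, c("x", "y", "z")])
    if (jaw == "upper") {
      expect_lt(sqrt(sum((pos(11L) - pos(21L))^2)),
                sqrt(sum((pos(16L) - pos(26L))^2)))
    } else {
      expect_lt(sqrt(sum((pos(41L) - pos(31L))^2)),
                sqrt(sum((pos(46L) - pos(36L))^2)))
    }
    # molars wider than incisors
    sz <- tpl$tooth_sizes
    expect_gt(sz$md[sz$code %% 10 == 6][1], sz$md[sz$code %% 10 == 2][1])
    expect_true(all(sz$md > 0 & sz$bl > 0 & sz$h > 0))
  }
})

test_that("noiseless generation puts COMs exactly on the slots", {
  tpl <- default_template("upper")
  gen <- generate_scene(tpl, simulation_config(seed = 1))
  det <- gen$scene$detections
  expect_equal(nrow(det), 16)
  ord <- match(tpl$slots$code, det$fdi)
  expect_equal(det$x[ord], tpl$slots$x, tolerance = 1e-12)
  expect_equal(det$y[ord], tpl$slots$y, tolerance = 1e-12)
  expect_equal(det$z[ord], tpl$slots$z, tolerance = 1e-12)
  # the labeled cloud has both classes and matching instances
  expect_setequal(unique(gen$cloud$class), c(0L, 1L))
  expect_equal(sum(gen$cloud$class == 1L), 16 * 300)
})

test_that("missing teeth are excluded and bounded", {
  tpl <- default_template("upper")
  gen <- generate_scene(tpl, simulation_config(seed = 2, missing_codes = 16L))
  expect_equal(nrow(gen$scene$detections), 15)
  expect_false(16L %in% gen$scene$detections$fdi)
  # a count samples preferentially but deterministically
  gen3 <- generate_scene(tpl, simulation_config(seed = 3, missing_codes = 3L))
  expect_equal(nrow(gen3$scene$detections), 13)
  expect_error(generate_scene(tpl, simulation_config(
    seed = 1, missing_codes = fdi_jaw_codes("upper"))), "all teeth")
})

test_that("generation is bit-identical under one seed", {
  tpl <- default_template("lower")
  cfg <- simulation_config(seed = 9, missing_codes = 2L, com_jitter_sigma = 0)
  g1 <- generate_scene(tpl, cfg)
  g2 <- generate_scene(tpl, cfg)
  expect_identical(g1$scene$detections, g2$scene$detections)
  expect_identical(g1$cloud, g2$cloud)
  s1 <- simulate_detector(g1, simulation_config(seed = 4, com_jitter_sigma = 1,
                                                miss_rate = 0.2,
                                                false_positive_rate = 0.2))
  s2 <- simulate_detector(g2, simulation_config(seed = 4, com_jitter_sigma = 1,
                                                miss_rate = 0.2,
                                                false_positive_rate = 0.2))
  expect_identical(s1$scene$detections, s2$scene$detections)
  expect_identical(s1$correspondence, s2$correspondence)
})

test_that("a zero-noise detector reproduces the truth", {
  tpl <- default_template("upper")
  gen <- generate_scene(tpl, simulation_config(seed = 5))
  sim <- simulate_detector(gen, simulation_config(seed = 6))
  expect_equal(nrow(sim$scene$detections), 16)
  expect_equal(sim$scene$detections$x, gen$scene$detections$x)
  expect_equal(sim$correspondence$truth_id, gen$scene$detections$detection_id)
  expect_equal(nrow(sim$missed), 0)
  # miss everything
  sim0 <- simulate_detector(gen, simulation_config(seed = 6, miss_rate = 1))
  expect_null(sim0$scene)
  expect_equal(nrow(sim0$missed), 16)
  expect_equal(nrow(sim0$correspondence), 0)
})

test_that("COM jitter has the configured per-axis scale", {
  tpl <- default_template("upper")
  gen <- generate_scene(tpl, simulation_config(seed = 30, points_per_tooth = 5L,
                                               gingiva_points = 0L))
  disp <- matrix(NA_real_, 0, 3)
  for (s in 1:200) {
    sim <- simulate_detector(gen, simulation_config(seed = s,
                                                    com_jitter_sigma = 0.3))
    d <- sim$scene$detections
    truth <- gen$scene$detections[match(sim$correspondence$truth_id,
                                        gen$scene$detections$detection_id), ]
    disp <- rbind(disp, cbind(d$x - truth$x, d$y - truth$y, d$z - truth$z))
  }
  rms <- sqrt(colMeans(disp^2))
  expect_true(all(abs(rms - 0.3) / 0.3 < 0.05))
})

test_that("mask flips concentrate at the cluster boundary", {
  tpl <- default_template("upper")
  gen <- generate_scene(tpl, simulation_config(seed = 12, gingiva_points = 0L))
  sim <- simulate_detector(gen, simulation_config(seed = 13,
                                                  mask_flip_rate = 0.1))
  d <- sim$scene$detections
  for (i in seq_len(nrow(d))) {
    mask <- d$mask[[i]]
    expect_equal(sum(!mask), round(0.1 * length(mask)))
    pts <- d$points[[i]]
    com <- colMeans(pts[mask, , drop = FALSE])
    r_flipped <- sqrt(rowSums(sweep(pts[!mask, , drop = FALSE], 2, com)^2))
    r_kept <- sqrt(rowSums(sweep(pts[mask, , drop = FALSE], 2, com)^2))
    expect_gt(min(r_flipped), stats::median(r_kept))
  }
})

test_that("spurious detections appear between slots at the configured rate", {
  tpl <- default_template("lower")
  gen <- generate_scene(tpl, simulation_config(seed = 14, points_per_tooth = 20L,
                                               gingiva_points = 0L))
  n_fp <- sapply(1:100, function(s) {
    sim <- simulate_detector(gen, simulation_config(seed = s,
                                                    false_positive_rate = 0.1))
    sum(is.na(sim$correspondence$truth_id))
  })
  # binomial(16, 0.1) mean 1.6; Monte-Carlo mean over 100 runs is close
  expect_gt(mean(n_fp), 1.0)
  expect_lt(mean(n_fp), 2.2)
})

test_that("the analytic template prior equals the estimated noiseless prior", {
  tpl <- default_template("upper")
  ana <- template_prior(tpl)
  scenes <- lapply(1:10, function(s)
    generate_scene(tpl, simulation_config(seed = s, points_per_tooth = 10L,
                                          gingiva_points = 0L))$scene)
  est <- estimate_distance_prior(scenes)
  idx <- as.character(fdi_jaw_codes("upper"))
  expect_equal(ana$d[idx, idx], est$d[idx, idx], tolerance = 1e-9)
  expect_true(all(diag(ana$d) == 0))
  expect_equal(ana$d, t(ana$d))
  # combining both jaws fills both blocks
  both <- template_prior(list(default_template("upper"),
                              default_template("lower")))
  expect_false(anyNA(both$d[idx, idx]))
  idx_l <- as.character(fdi_jaw_codes("lower"))
  expect_false(anyNA(both$d[idx_l, idx_l]))
})

test_that("labeling accuracy degrades monotonically with COM jitter", {
  tpl <- default_template("upper")
  pr <- template_prior(tpl)
  acc_at <- function(sigma, n = 40) {
    mean(sapply(seq_len(n), function(s) {
      gen <- generate_scene(tpl, simulation_config(seed = 5000L + s,
                                                   points_per_tooth = 5L,
                                                   gingiva_points = 0L))
      sim <- simulate_detector(gen, simulation_config(seed = 9000L + s,
                                                      com_jitter_sigma = sigma))
      labs <- tidy(label_teeth(sim$scene, pr))
      mean(labs$fdi == sim$correspondence$truth_fdi)
    }))
  }
  accs <- vapply(c(0, 0.3, 1, 3), acc_at, numeric(1))
  expect_equal(accs[1], 1)
  # non-increasing up to 1 percentage point of Monte-Carlo slack
  expect_true(all(diff(accs) <= 0.01))
  expect_lt(accs[4], accs[1])
})
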