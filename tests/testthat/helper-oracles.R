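# Independent literal transcriptions of the penalty formulas, written as
# plain double loops straight from their printed definitions. These stay
# deliberately naive: they are the oracles the vectorized implementations
# are checked against and must not share code with them.

oracle_f11 <- function(E) {
  total <- 0
  for (c in seq_len(ncol(E))) {
    s <- 0
    for (n in seq_len(nrow(E))) s <- s + E[n, c]
    total <- total + max(s - 1, 0)
  }
  unname(total)
}

oracle_f12 <- function(E, coms, watershed_z) {
  codes <- as.integer(colnames(E))
  upper <- which(codes %/% 10 <= 2)
  lower <- which(codes %/% 10 >= 3)
  total <- 0
  for (n in seq_len(nrow(E))) {
    for (c in upper) total <- total + E[n, c] * (coms[n, 3] < watershed_z)
    for (c in lower) total <- total + E[n, c] * (watershed_z < coms[n, 3])
  }
  unname(total)
}

oracle_f13 <- function(E) {
  total <- 0
  for (n in seq_len(nrow(E))) total <- total + max(1 - sum(E[n, ]), 0)
  unname(total)
}

oracle_f1 <- function(E, coms, watershed_z, lambda12 = 0.1, lambda13 = 0.01) {
  oracle_f11(E) + lambda12 * oracle_f12(E, coms, watershed_z) +
    lambda13 * oracle_f13(E)
}

# geometric (arch) ordering key of a code: 0..15 within each jaw
oracle_arch_key <- function(code) {
  q <- code %/% 10; p <- code %% 10
  if (q %in% c(1, 4)) 8 - p else 7 + p
}

oracle_f2 <- function(E, coms) {
  codes <- as.integer(colnames(E))
  total <- 0
  for (jawset in list(which(codes %/% 10 <= 2), which(codes %/% 10 >= 3))) {
    for (n1 in seq_len(nrow(E))) for (n2 in seq_len(nrow(E))) {
      for (c1 in jawset) {
        if (E[n1, c1] != 1) next
        for (c2 in jawset) {
          if (E[n2, c2] != 1) next
          total <- total + xor(coms[n1, 1] > coms[n2, 1],
                               oracle_arch_key(codes[c1]) > oracle_arch_key(codes[c2]))
        }
      }
    }
  }
  unname(total)
}

oracle_f3 <- function(E, coms, D) {
  codes <- as.integer(colnames(E))
  total <- 0
  for (jawset in list(which(codes %/% 10 <= 2), which(codes %/% 10 >= 3))) {
    for (n1 in seq_len(nrow(E))) for (n2 in seq_len(nrow(E))) {
      if (n1 == n2) next
      for (c1 in jawset) {
        if (E[n1, c1] != 1) next
        for (c2 in jawset) {
          if (E[n2, c2] != 1) next
          dd <- sqrt(sum((coms[n1, ] - coms[n2, ])^2))
          prior <- D[as.character(codes[c1]), as.character(codes[c2])]
          if (!is.na(prior)) total <- total + (dd - prior)^2
        }
      }
    }
  }
  unname(total)
}

# random row-sum-<=1 assignment matrix over n detections
random_assignment <- function(n, p_assigned = 0.8) {
  codes <- sample(c(NA_integer_, dentalabel::fdi_codes()), n, replace = TRUE,
                  prob = c(1 - p_assigned, rep(p_assigned / 32, 32)))
  dentalabel::assignment_from_codes(codes)
}

# random small scene: one jaw, COMs scattered around template slot positions
random_small_scene <- function(n_per_jaw, jaw = "upper", sd = 2,
                               template = dentalabel::default_template(jaw)) {
  slots <- template$slots
  take <- sort(sample(16, n_per_jaw))
  coms <- cbind(slots$x[take], slots$y[take], slots$z[take]) +
    matrix(stats::rnorm(3 * n_per_jaw, 0, sd), ncol = 3)
  det <- tibble::tibble(detection_id = seq_len(n_per_jaw),
                        x = coms[, 1], y = coms[, 2], z = coms[, 3],
                        fdi = slots$code[take])
  dentalabel::build_scene(det, jaw_hint = jaw)
}

# exhaustive minimum of f2 over all permutations of the used codes (per jaw)
oracle_min_f2_permutations <- function(E, coms) {
  codes <- dentalabel::assignment_codes(E)
  assigned <- which(!is.na(codes))
  jaws <- ifelse(codes[assigned] %/% 10 <= 2, "upper", "lower")
  best <- Inf
  per_jaw <- split(assigned, jaws)
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  jaw_perm_sets <- lapply(per_jaw, function(rows) perms_of(codes[rows]))
  combos <- expand.grid(lapply(jaw_perm_sets, seq_along))
  for (r in seq_len(nrow(combos))) {
    cand <- codes
    for (j in seq_along(per_jaw)) {
      rows <- per_jaw[[j]]
      cand[rows] <- jaw_perm_sets[[j]][[combos[r, j]]]
    }
    best <- min(best, oracle_pair_inversions(cand, coms))
  }
  best
}

# ordered-pair inversion count straight from the indicator definition,
# one term per ordered same-jaw pair of assigned detections
oracle_pair_inversions <- function(cand, coms) {
  total <- 0
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (is.na(cand[i]) || is.na(cand[j])) next
    same_jaw <- (cand[i] %/% 10 <= 2) == (cand[j] %/% 10 <= 2)
    if (!same_jaw) next
    total <- total + xor(coms[i, 1] > coms[j, 1],
                         oracle_arch_key(cand[i]) > oracle_arch_key(cand[j]))
  }
  unname(total)
}

# exhaustive minimum of f3 over order-preserving placements into 16 slots
oracle_min_f3_placements <- function(scene, prior) {
  det <- scene$detections
  jaw <- scene$jaw_hint
  stopifnot(!is.null(jaw), jaw %in% c("upper", "lower"))
  ord <- order(det$x, det$y, det$z, det$detection_id)
  coms <- cbind(det$x, det$y, det$z)[ord, , drop = FALSE]
  m <- nrow(coms)
  jaw_codes <- if (jaw == "upper") c(18:11, 21:28) else c(48:41, 31:38)
  dmat <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    dmat[i, j] <- sqrt(sum((coms[i, ] - coms[j, ])^2))
  best <- Inf
  combos <- utils::combn(16, m)
  for (k in seq_len(ncol(combos))) {
    cand <- as.character(jaw_codes[combos[, k]])
    pen <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      D <- prior$d[cand[i], cand[j]]
      if (!is.na(D)) pen <- pen + (dmat[i, j] - D)^2
    }
    best <- min(best, pen)
  }
  best
}

# brute-force per-cell componentwise max for grid pooling
oracle_grid_max <- function(cloud, cell_size, feat_cols) {
  origin <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  span <- c(max(cloud$x), max(cloud$y), max(cloud$z)) - origin
  dims <- pmax(ceiling(span / cell_size), 1)
  out <- array(-Inf, dim = c(dims, length(feat_cols)))
  for (i in seq_len(nrow(cloud))) {
    ci <- pmin(floor((c(cloud$x[i], cloud$y[i], cloud$z[i]) - origin) /
                       cell_size), dims - 1) + 1
    for (k in seq_along(feat_cols))
      out[ci[1], ci[2], ci[3], k] <- max(out[ci[1], ci[2], ci[3], k],
                                         cloud[[feat_cols[k]]][i])
  }
  out[is.infinite(out)] <- 0  # empty cells hold the fill value
  out
}

# brute-force confusion counts for binary masks
oracle_confusion <- function(pred, gt) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1
    else if (pred[i] && !gt[i]) fp <- fp + 1
    else if (!pred[i] && gt[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# enumerate all one-to-one matchings to maximize total IoU (small inputs)
oracle_best_matching_iou <- function(iou) {
  np <- nrow(iou); ng <- ncol(iou)
  best <- 0
  assign_rec <- function(i, used, total) {
    if (i > np) { best <<- max(best, total); return() }
    assign_rec(i + 1, used, total)  # leave row i unmatched
    for (j in seq_len(ng)) if (!used[j]) {
      used[j] <- TRUE
      assign_rec(i + 1, used, total + iou[i, j])
      used[j] <- FALSE
    }
  }
  assign_rec(1, rep(FALSE, ng), 0)
  best
}
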