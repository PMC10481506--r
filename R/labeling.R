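#' Penalty weights for the stage-1 objective
#'
#' The stage-1 objective is `f1 = f11 + lambda12 * f12 + lambda13 * f13`:
#' duplicated codes (f11) dominate, wrong-jaw assignments (f12) cost
#' `lambda12` each, unassigned detections (f13) cost `lambda13` each. The
#' defaults 0.1 and 0.01 order the three concerns strictly: never duplicate
#' a code to fix a jaw, never cross a jaw to avoid leaving a detection
#' unassigned.
#'
#' @param lambda12 weight of the wrong-jaw count (default 0.1).
#' @param lambda13 weight of the unassigned count (default 0.01).
#' @return a `penalty_weights` list.
#' @export
penalty_weights <- function(lambda12 = 0.1, lambda13 = 0.01) {
  stopifnot(lambda12 >= 0, lambda13 >= 0)
  structure(list(lambda12 = lambda12, lambda13 = lambda13),
            class = "penalty_weights")
}

#' Create an empty assignment matrix
#'
#' An assignment matrix is binary N x 32: `E[n, c] = 1` means detection `n`
#' carries the FDI code of column `c` (column order [fdi_codes()]). Each row
#' has at most one 1: a detection holds at most one code.
#'
#' @param n number of detections (rows).
#' @return an N x 32 integer matrix of zeros with code column names.
#' @export
assignment_matrix <- function(n) {
  matrix(0L, nrow = n, ncol = 32,
         dimnames = list(NULL, as.character(fdi_codes())))
}

#' Build an assignment matrix from a code vector
#'
#' @param codes integer vector of FDI codes, `NA` for unassigned rows.
#' @return an assignment matrix with one 1 per non-`NA` row.
#' @export
assignment_from_codes <- function(codes) {
  E <- assignment_matrix(length(codes))
  keep <- which(!is.na(codes))
  E[cbind(keep, fdi_col(codes[keep]))] <- 1L
  E
}

#' Extract the assigned code of each detection row
#'
#' @param E assignment matrix.
#' @return integer vector of FDI codes, `NA` for unassigned rows.
#' @export
assignment_codes <- function(E) {
  check_assignment(E)
  apply(E, 1, function(r) {
    j <- which(r == 1L)
    if (length(j) == 0) NA_integer_ else fdi_codes()[j]
  })
}

check_assignment <- function(E) {
  stopifnot(is.matrix(E), ncol(E) == 32, all(E %in% c(0L, 1L)))
  if (any(rowSums(E) > 1))
    stop("assignment matrix has a row with more than one code", call. = FALSE)
  invisible(E)
}

# jaw of each detection: the hint when given, else its watershed side
detection_jaws <- function(com_z, watershed_z, jaw_hint = NULL,
                           upper_is_up = TRUE) {
  if (!is.null(jaw_hint) && jaw_hint != "both")
    return(rep(jaw_hint, length(com_z)))
  up <- if (upper_is_up) com_z >= watershed_z else com_z < watershed_z
  ifelse(up, "upper", "lower")
}

#' Assignment penalties: duplicates, wrong jaw, unassigned
#'
#' The three terms of the stage-1 objective.
#' `penalty_f11` counts surplus uses of each FDI code,
#' `sum_c max(sum_n e_nc - 1, 0)`: 0 when every code is used at most once.
#' `penalty_f12` counts assignments on the wrong side of the axial
#' watershed: upper-jaw codes given to detections with COM z strictly below
#' `watershed_z` plus lower-jaw codes strictly above it (convention: upper
#' teeth sit at z >= watershed; flip with `upper_is_up = FALSE`). A
#' `jaw_hint` for single-jaw scans replaces the watershed side test.
#' `penalty_f13` counts unassigned detections, `sum_n max(1 - sum_c e_nc, 0)`.
#' `penalty_f1` is their weighted sum.
#'
#' @param E assignment matrix (N x 32, see [assignment_matrix()]).
#' @param coms N x 3 matrix of detection centers of mass (mm).
#' @param watershed_z axial watershed (scene COM z component).
#' @param jaw_hint optional `"upper"`/`"lower"`: all detections belong to
#'   that jaw regardless of the watershed.
#' @param upper_is_up logical axial orientation convention.
#' @param weights a [penalty_weights()].
#' @return a non-negative scalar.
#' @export
penalty_f11 <- function(E) {
  check_assignment(E)
  sum(pmax(colSums(E) - 1, 0))
}

#' @rdname penalty_f11
#' @export
penalty_f12 <- function(E, coms, watershed_z, jaw_hint = NULL,
                        upper_is_up = TRUE) {
  check_assignment(E)
  coms <- as_point_matrix(coms)
  stopifnot(nrow(coms) == nrow(E))
  code_jaw <- fdi_jaw(fdi_codes())
  det_jaw <- detection_jaws(coms[, 3], watershed_z, jaw_hint, upper_is_up)
  if (is.null(jaw_hint) || jaw_hint == "both") {
    # literal indicator form: strict inequalities against the watershed
    up_cols <- which(code_jaw == "upper")
    lo_cols <- which(code_jaw == "lower")
    below <- if (upper_is_up) coms[, 3] < watershed_z else coms[, 3] > watershed_z
    above <- if (upper_is_up) coms[, 3] > watershed_z else coms[, 3] < watershed_z
    sum(rowSums(E[, up_cols, drop = FALSE]) * below) +
      sum(rowSums(E[, lo_cols, drop = FALSE]) * above)
  } else {
    wrong <- outer(det_jaw, code_jaw, "!=")
    sum(E[wrong])
  }
}

#' @rdname penalty_f11
#' @export
penalty_f13 <- function(E) {
  check_assignment(E)
  sum(pmax(1 - rowSums(E), 0))
}

#' @rdname penalty_f11
#' @export
penalty_f1 <- function(E, coms, watershed_z, weights = penalty_weights(),
                       jaw_hint = NULL, upper_is_up = TRUE) {
  penalty_f11(E) +
    weights$lambda12 * penalty_f12(E, coms, watershed_z, jaw_hint, upper_is_up) +
    weights$lambda13 * penalty_f13(E)
}

# per-jaw index: arch order (geometric, default) or raw FDI numerals
code_order_key <- function(codes, code_order = c("arch", "numeral")) {
  code_order <- match.arg(code_order)
  if (code_order == "arch") fdi_arch_index(codes) else codes
}

#' Ordering penalty: left-right inversions of assigned codes
#'
#' Within each jaw, the x component of the COMs must grow with the code's
#' position along the arch. `penalty_f2` is the double sum over ordered
#' pairs of same-jaw assigned detections of the exclusive-or indicator
#' `xor(COM_x(n1) > COM_x(n2), key(c1) > key(c2))`; each unordered inversion
#' therefore contributes 2. By default codes are compared by their geometric
#' `arch_index` (raw FDI numerals reverse direction at the midline; set
#' `code_order = "numeral"` to compare raw codes instead).
#'
#' @inheritParams penalty_f11
#' @param code_order `"arch"` (default) or `"numeral"`.
#' @return a non-negative even integer.
#' @export
penalty_f2 <- function(E, coms, code_order = c("arch", "numeral")) {
  check_assignment(E)
  coms <- as_point_matrix(coms)
  codes <- assignment_codes(E)
  total <- 0L
  for (jaw in c("upper", "lower")) {
    rows <- which(!is.na(codes) & fdi_jaw(ifelse(is.na(codes), 11L, codes)) == jaw)
    if (length(rows) < 2) next
    x <- coms[rows, 1]
    k <- code_order_key(codes[rows], code_order)
    total <- total + sum(xor(outer(x, x, ">"), outer(k, k, ">")))
  }
  as.integer(total)
}

#' Distance-prior penalty
#'
#' For every ordered pair of same-jaw assigned detections, the squared
#' difference between the Euclidean distance of their COMs and the prior
#' mean distance `D[c1, c2]` of their assigned codes. Both jaws contribute.
#' The difference is squared by default so the penalty is non-negative and
#' smooth; `exponent = "abs"` uses the absolute difference instead.
#'
#' @inheritParams penalty_f11
#' @param prior a [distance_prior()].
#' @param exponent `"square"` (default) or `"abs"`.
#' @param on_missing `"error"` (default): a missing prior entry for a used
#'   same-jaw code pair is a configuration error naming the pair;
#'   `"skip"`: such pairs are skipped with a warning.
#' @return a non-negative scalar.
#' @export
penalty_f3 <- function(E, coms, prior, exponent = c("square", "abs"),
                       on_missing = c("error", "skip")) {
  check_assignment(E)
  exponent <- match.arg(exponent)
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(prior, "distance_prior"))
  coms <- as_point_matrix(coms)
  codes <- assignment_codes(E)
  total <- 0
  skipped <- character(0)
  for (jaw in c("upper", "lower")) {
    rows <- which(!is.na(codes) & fdi_jaw(ifelse(is.na(codes), 11L, codes)) == jaw)
    if (length(rows) < 2) next
    dm <- as.matrix(stats::dist(coms[rows, , drop = FALSE]))
    Dsub <- prior$d[as.character(codes[rows]), as.character(codes[rows]),
                    drop = FALSE]
    off <- row(Dsub) != col(Dsub)
    miss <- off & is.na(Dsub)
    if (any(miss)) {
      pairs <- unique(apply(which(miss, arr.ind = TRUE), 1, function(ij)
        paste(sort(codes[rows][ij]), collapse = "-")))
      if (on_missing == "error")
        stop("penalty_f3: missing prior entry for code pair(s) ",
             paste(pairs, collapse = ", "), call. = FALSE)
      skipped <- c(skipped, pairs)
    }
    diffs <- (dm - Dsub)[off & !is.na(Dsub)]
    total <- total + if (exponent == "square") sum(diffs^2) else sum(abs(diffs))
  }
  if (length(skipped))
    warning("penalty_f3: skipped pairs with no prior entry: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  total
}

# detections of a scene as plain pieces used by the stages
scene_pieces <- function(scene) {
  stopifnot(inherits(scene, "arch_scene"))
  d <- scene$detections
  list(coms = as_point_matrix(d[, c("x", "y", "z")]),
       ids = d$detection_id,
       watershed_z = scene$watershed_z,
       jaw_hint = scene$jaw_hint,
       upper_is_up = scene$upper_is_up)
}

# deterministic processing order: increasing COM x, ties by y, z, then id
x_order <- function(coms, ids) order(coms[, 1], coms[, 2], coms[, 3], ids)

#' Stage 1: greedy assignment minimizing f1
#'
#' Processes detections in order of increasing COM x. Each detection is
#' assigned the lowest-arch-index free code of its jaw (the watershed side
#' of its COM, or the scene's `jaw_hint`); when the jaw's 16 codes are
#' exhausted the detection is left unassigned — a duplicate would cost 1
#' (f11) against `lambda13` for a blank row. The result never duplicates a
#' code while free codes remain and is locally optimal for `f1` under
#' single-assignment changes.
#'
#' @param scene an [build_scene()] arch scene.
#' @param weights a [penalty_weights()].
#' @return an assignment matrix `E1`.
#' @export
stage1_greedy <- function(scene, weights = penalty_weights()) {
  p <- scene_pieces(scene)
  n <- nrow(p$coms)
  jaws <- detection_jaws(p$coms[, 3], p$watershed_z, p$jaw_hint, p$upper_is_up)
  free <- list(upper = fdi_jaw_codes("upper"), lower = fdi_jaw_codes("lower"))
  codes <- rep(NA_integer_, n)
  for (i in x_order(p$coms, p$ids)) {
    jaw <- jaws[i]
    if (length(free[[jaw]]) > 0) {
      codes[i] <- free[[jaw]][1]          # lowest arch index still free
      free[[jaw]] <- free[[jaw]][-1]
    }                                     # else unassigned: cheapest move
  }
  assignment_from_codes(codes)
}

#' Stage 2: sort assigned codes along the arch
#'
#' Keeps, within each jaw, exactly the detections and the multiset of codes
#' assigned by stage 1, but redistributes the codes so that COM x order and
#' arch order agree: detections sorted by COM x receive that jaw's used
#' codes in increasing arch index. This attains the global minimum of the
#' inversion count `f2` over all permutations of the used codes (0 whenever
#' the codes are distinct).
#'
#' @param E1 stage-1 assignment matrix.
#' @param scene the scene `E1` was computed for.
#' @param code_order passed to the ordering key, see [penalty_f2()].
#' @return an assignment matrix `E2` with `penalty_f2(E2, ...) == 0` for
#'   duplicate-free inputs.
#' @export
stage2_sort <- function(E1, scene, code_order = "arch") {
  check_assignment(E1)
  p <- scene_pieces(scene)
  codes <- assignment_codes(E1)
  out <- codes
  for (jaw in c("upper", "lower")) {
    rows <- which(!is.na(codes) & fdi_jaw(ifelse(is.na(codes), 11L, codes)) == jaw)
    if (length(rows) < 2) next
    rows_sorted <- rows[x_order(p$coms[rows, , drop = FALSE], p$ids[rows])]
    # duplicates (possible only with zeroed weights) sort adjacently
    codes_sorted <- codes[rows][order(code_order_key(codes[rows], code_order),
                                      codes[rows])]
    out[rows_sorted] <- codes_sorted
  }
  assignment_from_codes(out)
}

#' Stage 3: optimal slot placement against the distance prior
#'
#' Retains the sorted left-to-right order of each jaw's detections but
#' re-decides *which* 16 arch slots they occupy, allowing blank slots for
#' missing teeth. All order-preserving placements of the `m` detections into
#' the jaw's 16 slots (`choose(16, m)`, at most 12870) are enumerated
#' exhaustively and the one minimizing the distance-prior penalty `f3` is
#' kept; ties go to the lexicographically smallest slot vector. The
#' inversion-free property of stage 2 is preserved by construction.
#'
#' @param E2 stage-2 assignment matrix (inversion-free per jaw).
#' @param scene the scene.
#' @param prior a [distance_prior()] covering the same-jaw code pairs.
#' @param exponent,on_missing passed to [penalty_f3()]; placements are
#'   scored with `on_missing = "skip"` semantics when `"skip"` is chosen.
#' @return an assignment matrix `E3`.
#' @export
stage3_slots <- function(E2, scene, prior, exponent = "square",
                         on_missing = "error") {
  check_assignment(E2)
  stopifnot(inherits(prior, "distance_prior"))
  p <- scene_pieces(scene)
  codes <- assignment_codes(E2)
  out <- codes
  for (jaw in c("upper", "lower")) {
    rows <- which(!is.na(codes) & fdi_jaw(ifelse(is.na(codes), 11L, codes)) == jaw)
    m <- length(rows)
    if (m == 0) next
    if (m > 16) stop("stage3_slots: more than 16 assigned detections in one jaw",
                     call. = FALSE)
    rows_sorted <- rows[x_order(p$coms[rows, , drop = FALSE], p$ids[rows])]
    jaw_codes <- fdi_jaw_codes(jaw)
    dm <- as.matrix(stats::dist(p$coms[rows_sorted, , drop = FALSE]))
    Djaw <- prior$d[as.character(jaw_codes), as.character(jaw_codes)]
    if (on_missing == "error" && anyNA(Djaw[row(Djaw) != col(Djaw)]) && m >= 2) {
      # only an error if a candidate placement actually needs a missing entry;
      # since all placements are scanned, any off-diagonal NA can be needed
      bad <- which(is.na(Djaw) & row(Djaw) != col(Djaw), arr.ind = TRUE)
      pairs <- unique(apply(bad, 1, function(ij)
        paste(sort(jaw_codes[ij]), collapse = "-")))
      stop("stage3_slots: prior is missing same-jaw entries: ",
           paste(pairs, collapse = ", "), call. = FALSE)
    }
    combos <- utils::combn(16L, m)
    best <- NULL; best_pen <- Inf
    for (k in seq_len(ncol(combos))) {
      slots <- combos[, k]
      Dsub <- Djaw[slots, slots, drop = FALSE]
      diffs <- dm - Dsub
      off <- row(Dsub) != col(Dsub) & !is.na(Dsub)
      pen <- if (exponent == "square") sum(diffs[off]^2) else sum(abs(diffs[off]))
      if (pen < best_pen - 1e-12) { best_pen <- pen; best <- slots }
    }
    out[rows_sorted] <- jaw_codes[best]
  }
  assignment_from_codes(out)
}

#' Label the teeth of a scene with FDI codes
#'
#' Runs the three refinement stages — greedy jaw-consistent assignment
#' (stage 1), left-right sorting (stage 2), optimal slot placement against
#' the distance prior (stage 3) — and returns the assignments of every
#' stage together with their penalties. Deterministic given its inputs.
#'
#' @param scene an arch scene ([build_scene()] or a generated scene).
#' @param prior a [distance_prior()].
#' @param weights a [penalty_weights()].
#' @param code_order,exponent,on_missing tuning knobs, see [penalty_f2()] /
#'   [penalty_f3()].
#' @return a `labeling_result`: list with `labels` (tibble `detection_id`,
#'   `fdi`), matrices `E1`, `E2`, `E3`, and `penalties` (tibble of f1, f2,
#'   f3 evaluated at every stage). Use [tidy()] / [glance()] to extract
#'   tables.
#' @examples
#' tpl <- default_template("upper")
#' sc <- generate_scene(tpl, simulation_config(seed = 7))$scene
#' res <- label_teeth(sc, template_prior(tpl))
#' head(tidy(res))
#' @export
label_teeth <- function(scene, prior, weights = penalty_weights(),
                        code_order = "arch", exponent = "square",
                        on_missing = "error") {
  stopifnot(inherits(scene, "arch_scene"))
  p <- scene_pieces(scene)
  E1 <- stage1_greedy(scene, weights)
  E2 <- stage2_sort(E1, scene, code_order)
  E3 <- stage3_slots(E2, scene, prior, exponent, on_missing)
  pen <- function(E) tibble::tibble(
    f1 = penalty_f1(E, p$coms, p$watershed_z, weights, p$jaw_hint, p$upper_is_up),
    f2 = penalty_f2(E, p$coms, code_order),
    f3 = penalty_f3(E, p$coms, prior, exponent, on_missing = "skip"))
  penalties <- dplyr::bind_rows(
    dplyr::mutate(pen(E1), stage = "E1"),
    dplyr::mutate(pen(E2), stage = "E2"),
    dplyr::mutate(pen(E3), stage = "E3"))[, c("stage", "f1", "f2", "f3")]
  structure(list(
    labels = tibble::tibble(detection_id = p$ids, fdi = assignment_codes(E3)),
    E1 = E1, E2 = E2, E3 = E3,
    penalties = penalties,
    weights = weights), class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  n <- nrow(x$labels)
  cat("<labeling_result> ", sum(!is.na(x$labels$fdi)), "/", n,
      " detections assigned\n", sep = "")
  print(x$penalties)
  invisible(x)
}

#' Exhaustive lexicographic labeling oracle
#'
#' Verification oracle for the staged heuristic on small scenes: explores
#' every assignment with row sums at most 1 (each detection takes one of
#' the 16 codes of its watershed-side jaw, or none) and returns one
#' minimizing `(f1, f2, f3)` lexicographically. Branches are cut only with
#' exact lower bounds (partial duplicate count plus `lambda13` times the
#' partial unassigned count for f1; the partial inversion count for f2), so
#' no lexicographic optimum can be pruned away. Ties resolve to the
#' smallest arch-index vector over detections in COM-x order, unassigned
#' ranking last.
#'
#' @inheritParams label_teeth
#' @param max_n refuse jaws with more detections than this (default 8):
#'   the search space grows combinatorially.
#' @return an assignment matrix.
#' @export
brute_force_label <- function(scene, prior, weights = penalty_weights(),
                              max_n = 8, code_order = "arch",
                              exponent = "square") {
  p <- scene_pieces(scene)
  jaws <- detection_jaws(p$coms[, 3], p$watershed_z, p$jaw_hint, p$upper_is_up)
  codes_out <- rep(NA_integer_, nrow(p$coms))
  for (jaw in c("upper", "lower")) {
    rows <- which(jaws == jaw)
    m <- length(rows)
    if (m == 0) next
    if (m > max_n)
      stop("brute_force_label: ", m, " detections in the ", jaw,
           " jaw exceed max_n = ", max_n, call. = FALSE)
    rows_sorted <- rows[x_order(p$coms[rows, , drop = FALSE], p$ids[rows])]
    codes_out[rows_sorted] <-
      brute_force_jaw(p$coms[rows_sorted, , drop = FALSE], jaw, prior,
                      weights, code_order, exponent)
  }
  assignment_from_codes(codes_out)
}

# exact DFS over one jaw's detections (already in COM-x order);
# choice per detection: arch slots 1..16 in order, then unassigned
brute_force_jaw <- function(coms, jaw, prior, weights, code_order, exponent) {
  m <- nrow(coms)
  jaw_codes <- fdi_jaw_codes(jaw)
  keys <- code_order_key(jaw_codes, code_order)
  dm <- as.matrix(stats::dist(coms))
  Djaw <- prior$d[as.character(jaw_codes), as.character(jaw_codes)]
  best <- list(f = c(Inf, Inf, Inf), sel = NULL)
  lex_less <- function(a, b) {
    for (i in 1:3) {
      if (a[i] < b[i] - 1e-12) return(TRUE)
      if (a[i] > b[i] + 1e-12) return(FALSE)
    }
    FALSE
  }
  recurse <- function(i, sel, dup, unas, inv) {
    # sel: slot index 1..16 or NA per detection handled so far
    f1_lb <- dup + weights$lambda13 * unas
    if (f1_lb > best$f[1] + 1e-12) return()
    if (abs(f1_lb - best$f[1]) <= 1e-12 && inv > best$f[2] + 1e-12) return()
    if (i > m) {
      f3 <- 0
      assigned <- which(!is.na(sel))
      if (length(assigned) >= 2) {
        Dsub <- Djaw[sel[assigned], sel[assigned], drop = FALSE]
        diffs <- dm[assigned, assigned, drop = FALSE] - Dsub
        off <- row(Dsub) != col(Dsub) & !is.na(Dsub)
        f3 <- if (exponent == "square") sum(diffs[off]^2) else sum(abs(diffs[off]))
      }
      f <- c(f1_lb, inv, f3)
      if (lex_less(f, best$f)) best <<- list(f = f, sel = sel)
      return()
    }
    for (s in seq_len(16L)) {
      new_dup <- dup + as.integer(any(sel == s, na.rm = TRUE))  # one more surplus use
      prev <- which(!is.na(sel[seq_len(i - 1)]))
      # detections come in increasing x; an earlier detection with a larger
      # key is an inversion (counted once per ordered pair = twice); an
      # exact x tie contributes exactly one ordered-pair term
      tie <- coms[prev, 1] == coms[i, 1]
      new_inv <- inv + sum(tie) +
        2L * sum(keys[sel[prev[!tie]]] > keys[s])
      sel[i] <- s
      recurse(i + 1L, sel, new_dup, unas, new_inv)
      sel[i] <- NA_integer_
    }
    recurse(i + 1L, sel, dup, unas + 1L, inv)
  }
  recurse(1L, rep(NA_integer_, m), 0, 0L, 0L)
  jaw_codes[best$sel]
}
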