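#' FDI two-digit codes for the permanent dentition
#'
#' The FDI (Federation Dentaire Internationale) notation identifies each of
#' the 32 permanent teeth with a two-digit code: the first digit is the
#' quadrant (1 upper right, 2 upper left, 3 lower left, 4 lower right), the
#' second the position from central incisor (1) to third molar (8).
#'
#' Geometrically the codes of one jaw form a single left-to-right sequence
#' along the dental arch; `arch_index` is that geometric position, 0 to 15:
#' upper jaw 18, 17, ..., 11, 21, ..., 28 and lower jaw 48, 47, ..., 41,
#' 31, ..., 38. Raw numeric comparison of codes is *not* monotone along the
#' arch (it reverses at the midline), which is why ordering penalties in this
#' package compare `arch_index` instead.
#'
#' @return `fdi_codes()` returns the integer vector of the 32 codes in
#'   column order used by assignment matrices (11..18, 21..28, 31..38,
#'   41..48). `fdi_table()` returns a tibble with one row per code and
#'   columns `code`, `quadrant`, `position`, `jaw` (`"upper"`/`"lower"`),
#'   `arch_index` (0-15 within jaw) and `type` (incisor/canine/premolar/
#'   molar).
#' @examples
#' fdi_table()
#' @export
fdi_codes <- function() {
  as.integer(c(11:18, 21:28, 31:38, 41:48))
}

#' @rdname fdi_codes
#' @export
fdi_table <- function() {
  code <- fdi_codes()
  quadrant <- code %/% 10L
  position <- code %% 10L
  jaw <- ifelse(quadrant <= 2L, "upper", "lower")
  # arch order runs right to left for the patient: quadrant 1 (and 4)
  # descend 8..1, then quadrant 2 (and 3) ascend 1..8
  arch_index <- ifelse(quadrant %in% c(1L, 4L), 8L - position, 7L + position)
  type <- dplyr::case_when(
    position <= 2L ~ "incisor",
    position == 3L ~ "canine",
    position <= 5L ~ "premolar",
    TRUE ~ "molar"
  )
  tibble::tibble(code = code, quadrant = quadrant, position = position,
                 jaw = jaw, arch_index = as.integer(arch_index), type = type)
}

#' Convert between FDI codes and (jaw, arch index)
#'
#' @param code integer vector of FDI codes.
#' @param jaw `"upper"` or `"lower"` (recycled).
#' @param arch_index integer vector, 0-15.
#' @return `fdi_jaw()` and `fdi_arch_index()` return the jaw / arch index of
#'   each code; `fdi_from_arch()` the code at a given jaw and arch position.
#' @export
fdi_jaw <- function(code) {
  stopifnot(all(code %in% fdi_codes()))
  ifelse(code %/% 10L <= 2L, "upper", "lower")
}

#' @rdname fdi_jaw
#' @export
fdi_arch_index <- function(code) {
  tab <- fdi_table()
  tab$arch_index[match(code, tab$code)]
}

#' @rdname fdi_jaw
#' @export
fdi_from_arch <- function(jaw, arch_index) {
  tab <- fdi_table()
  key <- paste(jaw, arch_index)
  tab$code[match(key, paste(tab$jaw, tab$arch_index))]
}

# column index (1..32) of a code in an assignment matrix
fdi_col <- function(code) match(code, fdi_codes())

#' @rdname fdi_jaw
#' @description `fdi_jaw_codes()` lists one jaw's 16 codes in arch order
#'   (arch_index 0 to 15).
#' @export
fdi_jaw_codes <- function(jaw) {
  tab <- fdi_table()
  tab <- tab[tab$jaw == jaw, ]
  tab$code[order(tab$arch_index)]
}
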