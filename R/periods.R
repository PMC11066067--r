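#' Geological periods
#'
#' The default table follows the standard geologic timescale at the level used
#' for Precambrian microbial evolution (eons/eras down to the Phanerozoic
#' eras), e.g. the Paleoarchean spans 3.6-3.2 Ga.  Boundary ages belong to the
#' younger period, so 3.2 Ga maps to the Mesoarchean.
#'
#' @return `default_periods()` returns a tibble with columns `period`,
#'   `older_Ga` and `younger_Ga`, ordered from youngest to oldest.
#' @examples
#' assign_geological_period(3.4)
#' @export
default_periods <- function() {
  tibble(
    period = c(
      "Cenozoic", "Mesozoic", "Paleozoic",
      "Neoproterozoic", "Mesoproterozoic", "Paleoproterozoic",
      "Neoarchean", "Mesoarchean", "Paleoarchean", "Eoarchean", "Hadean"
    ),
    older_Ga = c(0.066, 0.252, 0.541, 1.0, 1.6, 2.5, 2.8, 3.2, 3.6, 4.0, 4.6),
    younger_Ga = c(0, 0.066, 0.252, 0.541, 1.0, 1.6, 2.5, 2.8, 3.2, 3.6, 4.0)
  )
}

#' @rdname default_periods
#' @param path Path of a 3-column TSV (`period`, `older_Ga`, `younger_Ga`).
#' @export
read_period_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("period", "older_Ga", "younger_Ga") %in% names(tb))) {
    abort("A period table needs columns: period, older_Ga, younger_Ga.")
  }
  tb <- dplyr::arrange(tb, .data$older_Ga)
  validate_period_table(tb)
  tb
}

validate_period_table <- function(periods) {
  if (any(periods$older_Ga <= periods$younger_Ga)) {
    abort("Each period's older bound must exceed its younger bound.")
  }
  o <- order(periods$older_Ga)
  if (any(abs(periods$older_Ga[o][-nrow(periods)] -
              periods$younger_Ga[o][-1]) > 1e-9)) {
    abort("Period intervals must be contiguous and non-overlapping.")
  }
  invisible(periods)
}

#' @rdname default_periods
#' @param age Numeric vector of ages in Ga.
#' @param periods A period table (default [default_periods()]).
#' @return `assign_geological_period()` returns the period name(s) containing
#'   `age`; ties at a boundary resolve toward the present (younger period).
#' @export
assign_geological_period <- function(age, periods = default_periods()) {
  validate_period_table(periods)
  periods <- dplyr::arrange(periods, .data$older_Ga)
  oldest <- max(periods$older_Ga)
  vapply(age, function(a) {
    if (is.na(a) || a < 0 || a > oldest) {
      abort(sprintf("Age %.6g Ga is outside the period table range [0, %.6g].", a, oldest))
    }
    periods$period[which(periods$older_Ga >= a)[1]]
  }, character(1))
}
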