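#' The seven mixture classes
#'
#' Composition patterns of the simulated corpus, in the fixed gas order
#' (methane, acetone, water): the ternary mixture, the three binary
#' mixtures, and the three single gases.
#'
#' @return character vector `c("MAW","MA","MW","AW","M","A","W")`.
#' @export
mixture_classes <- function() c("MAW", "MA", "MW", "AW", "M", "A", "W")

#' Presence mask of a mixture class
#'
#' @param class one of [mixture_classes()].
#' @return integer vector of 3 presence flags (methane, acetone, water).
#' @export
class_mask <- function(class) {
  masks <- list(MAW = c(1L, 1L, 1L), MA = c(1L, 1L, 0L), MW = c(1L, 0L, 1L),
                AW = c(0L, 1L, 1L), M = c(1L, 0L, 0L), A = c(0L, 1L, 0L),
                W = c(0L, 0L, 1L))
  m <- masks[[class]]
  if (is.null(m)) stop("class_mask: unknown mixture class '", class, "'")
  m
}

# ci pattern (e.g. "101") -> class name, "none" for all-absent
.pattern_to_class <- function(ci) {
  key <- paste(ci, collapse = "")
  switch(key,
         "111" = "MAW", "110" = "MA", "101" = "MW", "011" = "AW",
         "100" = "M", "010" = "A", "001" = "W", "000" = "none",
         stop("unrecognised presence pattern ", key))
}

#' Default per-gas concentration ranges
#'
#' Uniform sampling ranges (ppm) applied when a gas is present: 0--50 for the
#' two trace gases and 1000--2000 for water vapour (normal indoor humidity
#' over the long path). Absent gases are exactly 0.
#'
#' @return list with elements `methane`, `acetone`, `water`, each `c(lo, hi)`.
#' @export
concentration_ranges <- function() {
  list(methane = c(0, 50), acetone = c(0, 50), water = c(1000, 2000))
}

#' Draw a ground-truth label for one mixture class
#'
#' Present gases get a uniform concentration draw inside their range; absent
#' gases get concentration 0 and presence flag 0. Uses the current RNG
#' state (seed outside for reproducibility).
#'
#' @param class one of [mixture_classes()].
#' @param ranges per-gas ranges, see [concentration_ranges()].
#' @return list with `ci` (3 presence flags) and `cr` (3 concentrations ppm).
#' @export
sample_concentrations <- function(class, ranges = concentration_ranges()) {
  ci <- class_mask(class)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  cr <- ifelse(ci == 1L, stats::runif(3, lo, hi), 0)
  list(ci = ci, cr = as.numeric(cr))
}
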