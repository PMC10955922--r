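#' Read / write two-column spectrum text
#'
#' Measured or exported spectra travel as plain text with columns
#' (wavenumber cm^-1, absorbance), whitespace- or comma-separated, ascending
#' wavenumber, optional header.
#'
#' @param path file path.
#' @return `read_spectrum`: data frame with `wavenumber` and `absorbance`.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,;[:space:]]+")[[1]][1])))
  tab <- utils::read.table(path, header = has_header,
                           sep = if (grepl(",", first)) "," else "",
                           comment.char = "#")
  out <- data.frame(wavenumber = tab[[1]], absorbance = tab[[2]])
  if (any(diff(out$wavenumber) <= 0)) {
    stop("read_spectrum: wavenumbers must be strictly ascending in ", path)
  }
  out
}

#' @rdname read_spectrum
#' @param wavenumber,absorbance vectors to write.
#' @return `write_spectrum`: `path` invisibly.
#' @export
write_spectrum <- function(path, wavenumber, absorbance) {
  stopifnot(length(wavenumber) == length(absorbance))
  utils::write.table(data.frame(wavenumber = wavenumber,
                                absorbance = absorbance),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a measured spectrum onto the model grid
#'
#' Linear interpolation; the spectrum must span the grid (no extrapolation).
#'
#' @param spectrum data frame from [read_spectrum()].
#' @param grid target [spectral_grid()].
#' @return absorbance vector of grid length.
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  lo <- min(spectrum$wavenumber); hi <- max(spectrum$wavenumber)
  if (grid$start < lo || grid$end > hi) {
    stop(sprintf("resample_spectrum: spectrum %.6g..%.6g cm^-1 does not span grid %.6g..%.6g cm^-1",
                 lo, hi, grid$start, grid$end))
  }
  stats::approx(spectrum$wavenumber, spectrum$absorbance, xout = grid$nu)$y
}

#' Derive a per-stage seed from the global seed
#'
#' Each pipeline stage draws from its own seed, derived deterministically
#' from the global seed and the stage name, so stages can be re-run
#' independently yet reproducibly.
#'
#' @param seed global integer seed.
#' @param stage stage name string.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Run manifest: written before a CLI stage runs and finalised after.
write_manifest <- function(path, stage, config, seed, outputs = character(),
                           status = "running") {
  cfg_file <- tempfile()
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(stage = stage, status = status,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("gasblendr")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = as.list(outputs))
  unlink(cfg_file)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
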