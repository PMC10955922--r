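#' Absorption line list
#'
#' Container for the spectroscopic line parameters of one gas. `lines` is a
#' data frame with one row per transition and columns
#' `center` (cm^-1), `intensity` (cm^-1 / (molecule cm^-2) at the 296 K
#' reference), `air_hwhm` and `self_hwhm` (cm^-1/atm), `lower_state_energy`
#' (cm^-1), `temp_exponent` (dimensionless) and `pressure_shift` (cm^-1/atm).
#' Rows are stored sorted by `center`. The lower-state energy and temperature
#' exponent are retained for future non-reference-temperature evaluation even
#' though the 296 K path only uses the broadening exponent.
#'
#' @param gas_id identifier string, e.g. "CH4".
#' @param lines data frame of line parameters (see Details).
#' @param molar_mass molar mass in g/mol (sets the Doppler width).
#' @return An object of class `line_list`.
#' @export
line_list <- function(gas_id, lines, molar_mass) {
  req <- c("center", "intensity", "air_hwhm", "self_hwhm",
           "lower_state_energy", "temp_exponent", "pressure_shift")
  missing_cols <- setdiff(req, names(lines))
  if (length(missing_cols)) {
    stop("line_list: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  lines <- as.data.frame(lines)[req]
  if (nrow(lines)) {
    if (any(lines$intensity < 0)) stop("line_list: intensities must be >= 0")
    if (any(lines$air_hwhm < 0 | lines$self_hwhm < 0)) {
      stop("line_list: broadening half widths must be >= 0")
    }
    lines <- lines[order(lines$center), , drop = FALSE]
    rownames(lines) <- NULL
  }
  stopifnot(is.numeric(molar_mass), molar_mass > 0)
  structure(list(gas_id = as.character(gas_id), lines = lines,
                 molar_mass = molar_mass),
            class = "line_list")
}

#' @export
print.line_list <- function(x, ...) {
  cat(sprintf("<line_list> %s: %d lines, molar mass %.4g g/mol\n",
              x$gas_id, nrow(x$lines), x$molar_mass))
  invisible(x)
}

# Molar masses (g/mol) of the HITRAN molecule ids this package reads most.
.hitran_molar_mass <- c("1" = 18.010565, "6" = 16.031300)
.hitran_gas_name <- c("1" = "H2O", "6" = "CH4")

#' Read a HITRAN 160-character fixed-width line list
#'
#' Parses the classic `.par` record layout: molecule id (cols 1-2),
#' isotopologue (3), transition wavenumber (4-15), line intensity (16-25),
#' Einstein A (26-35, unused), air-broadened HWHM (36-40), self-broadened
#' HWHM (41-45), lower-state energy (46-55), temperature exponent (56-59) and
#' air pressure shift (60-67). Remaining columns are ignored.
#'
#' @param path file path.
#' @param molecule optional HITRAN molecule id to keep (e.g. 6 for CH4).
#' @param isotopologue optional isotopologue id to keep.
#' @param gas_id identifier for the resulting list; defaults to the HITRAN
#'   name when the molecule id is known.
#' @param molar_mass molar mass g/mol; defaults from the molecule id for
#'   H2O (1) and CH4 (6), otherwise required.
#' @return a [line_list()].
#' @export
read_hitran_par <- function(path, molecule = NULL, isotopologue = NULL,
                            gas_id = NULL, molar_mass = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nchar(txt) >= 67]
  if (!length(txt)) stop("read_hitran_par: no 160-character records in ", path)
  f <- function(a, b) substr(txt, a, b)
  rec <- data.frame(
    molecule = as.integer(f(1, 2)),
    iso = suppressWarnings(as.integer(f(3, 3))),
    center = as.numeric(f(4, 15)),
    intensity = as.numeric(f(16, 25)),
    air_hwhm = as.numeric(f(36, 40)),
    self_hwhm = as.numeric(f(41, 45)),
    lower_state_energy = as.numeric(f(46, 55)),
    temp_exponent = as.numeric(f(56, 59)),
    pressure_shift = as.numeric(f(60, 67)))
  if (!is.null(molecule)) rec <- rec[rec$molecule == molecule, , drop = FALSE]
  if (!is.null(isotopologue)) rec <- rec[rec$iso == isotopologue, , drop = FALSE]
  mol <- if (!is.null(molecule)) molecule else unique(rec$molecule)[1]
  if (is.null(molar_mass)) {
    molar_mass <- .hitran_molar_mass[as.character(mol)]
    if (is.na(molar_mass)) {
      stop("read_hitran_par: supply 'molar_mass' for HITRAN molecule id ", mol)
    }
  }
  if (is.null(gas_id)) {
    gas_id <- .hitran_gas_name[as.character(mol)]
    if (is.na(gas_id)) gas_id <- paste0("hitran_", mol)
  }
  line_list(gas_id, rec[, -(1:2)], molar_mass = unname(molar_mass))
}

#' Composite absorption cross-section table
#'
#' PNNL-style table of absorbance per (ppm m) versus wavenumber for a gas
#' whose band structure is too dense to resolve line by line (here acetone).
#' Small negative values are baseline artifacts of the measured composite;
#' they are clipped to zero on ingest into a unit spectrum.
#'
#' @param wavenumbers strictly ascending axis, cm^-1.
#' @param values absorbance per (ppm m), finite.
#' @param gas_id identifier string.
#' @return An object of class `cross_section_table`.
#' @export
cross_section_table <- function(wavenumbers, values, gas_id = "xsec") {
  stopifnot(length(wavenumbers) == length(values), length(values) >= 2)
  if (any(!is.finite(wavenumbers)) || any(!is.finite(values))) {
    stop("cross_section_table: non-finite entries")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("cross_section_table: wavenumbers must be strictly ascending")
  }
  structure(list(gas_id = as.character(gas_id),
                 wavenumbers = as.numeric(wavenumbers),
                 values = as.numeric(values)),
            class = "cross_section_table")
}

#' @export
print.cross_section_table <- function(x, ...) {
  cat(sprintf("<cross_section_table> %s: %d nodes, %.6g .. %.6g cm^-1\n",
              x$gas_id, length(x$values), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Read a two-column cross-section table
#'
#' Whitespace- or comma-separated text with columns (wavenumber cm^-1,
#' absorbance per ppm m); an optional single header line is skipped when the
#' first field is not numeric.
#'
#' @param path file path.
#' @param gas_id identifier for the table.
#' @return a [cross_section_table()].
#' @export
read_cross_section <- function(path, gas_id = "xsec") {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,;[:space:]]+")[[1]][1])))
  tab <- utils::read.table(path, header = has_header,
                           sep = if (grepl(",", first)) "," else "",
                           comment.char = "#")
  cross_section_table(tab[[1]], tab[[2]], gas_id = gas_id)
}
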