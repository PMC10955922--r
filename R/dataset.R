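#' Generate the labelled training corpus
#'
#' Draws `m` blended samples across the seven mixture classes: for each
#' sample a class-consistent concentration label is drawn, the noise-free
#' mixture spectrum is formed from the unit spectra, and the four
#' perturbation channels are applied. The 6-digit label matrix `Y` holds the
#' three presence flags followed by the three concentrations (ppm).
#' Generation is a pure function of the arguments: a fixed seed reproduces
#' the corpus bit for bit.
#'
#' If `cfg$noise_sigma` is `NULL` it is resolved here so that the peak
#' absorbance of the third (high-concentration, water-like) gas at the
#' midpoint of its range has an SNR of about 150, the realistic figure for
#' the strongest absorber in a multipass-cell system.
#'
#' @param m total sample count.
#' @param grid a [spectral_grid()].
#' @param unit_spectra list of 3 [unit_absorbance()] objects in gas order
#'   (methane, acetone, water).
#' @param class_allocation named or ordered integer vector of per-class
#'   counts over [mixture_classes()], summing to `m`; default splits `m`
#'   as evenly as possible (exactly `m/7` per class when divisible, as in
#'   the 17500 = 7 x 2500 reference corpus).
#' @param cfg a [perturbation_config()].
#' @param seed integer seed.
#' @param ranges per-gas concentration ranges, see [concentration_ranges()].
#' @return object of class `blended_dataset`: list with `X` (m x n_points
#'   absorbance matrix), `Y` (m x 6 label matrix, columns CI1..CI3,
#'   CR1..CR3), `class` (character m), `grid`, `cfg` (with resolved
#'   `noise_sigma`), `seed`.
#' @export
generate_dataset <- function(m, grid, unit_spectra,
                             class_allocation = NULL,
                             cfg = perturbation_config(), seed = 1,
                             ranges = concentration_ranges()) {
  stopifnot(inherits(grid, "spectral_grid"), length(unit_spectra) == 3)
  classes <- mixture_classes()
  if (is.null(class_allocation)) {
    base <- m %/% 7L
    class_allocation <- rep(base, 7L)
    extra <- m - base * 7L
    if (extra > 0) class_allocation[seq_len(extra)] <-
        class_allocation[seq_len(extra)] + 1L
  }
  if (length(class_allocation) != 7L || sum(class_allocation) != m) {
    stop("generate_dataset: class_allocation must have 7 counts summing to m (",
         m, "); got sum ", sum(class_allocation))
  }
  U <- vapply(unit_spectra, function(u) {
    stopifnot(inherits(u, "unit_absorbance"),
              u$grid$n_points == grid$n_points)
    u$values
  }, numeric(grid$n_points))
  if (is.null(cfg$noise_sigma)) {
    mid_w <- mean(ranges$water)
    cfg$noise_sigma <- max(U[, 3]) * mid_w / 150
  }
  set.seed(seed)
  cls <- rep(classes, class_allocation)
  X <- matrix(0, nrow = m, ncol = grid$n_points)
  Y <- matrix(0, nrow = m, ncol = 6,
              dimnames = list(NULL, c("CI1", "CI2", "CI3",
                                      "CR1", "CR2", "CR3")))
  for (j in seq_len(m)) {
    lab <- sample_concentrations(cls[j], ranges = ranges)
    base <- drop(U %*% lab$cr)
    X[j, ] <- apply_perturbations(base, cfg, grid)
    Y[j, ] <- c(lab$ci, lab$cr)
  }
  structure(list(X = X, Y = Y, class = cls, grid = grid, cfg = cfg,
                 seed = seed, format_version = "1.0"),
            class = "blended_dataset")
}

#' @export
print.blended_dataset <- function(x, ...) {
  cat(sprintf("<blended_dataset> %d samples x %d points, classes: %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s=%d", names(table(x$class)), table(x$class)),
                    collapse = " ")))
  invisible(x)
}

#' Holdout train/test split
#'
#' Shuffled disjoint split covering `1:m`, with `round(m * ratio)` test
#' samples (the 9:1 protocol at the default ratio).
#'
#' @param m dataset size.
#' @param ratio test fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_holdout <- function(m, ratio = 0.1, seed = 1) {
  stopifnot(m >= 2, ratio > 0, ratio < 1)
  set.seed(seed)
  perm <- sample.int(m)
  n_test <- max(1L, round(m * ratio))
  list(train = sort(perm[-seq_len(n_test)]),
       test = sort(perm[seq_len(n_test)]))
}

#' k-fold partition of an index set
#'
#' Shuffles the indices and deals them into `k` pairwise-disjoint folds whose
#' sizes differ by at most 1.
#'
#' @param indices integer vector to partition (e.g. the train split).
#' @param k number of folds, `2 <= k <= length(indices)`.
#' @param seed integer seed.
#' @return list of `k` integer vectors.
#' @export
kfold <- function(indices, k = 10, seed = 1) {
  n <- length(indices)
  if (k < 2 || k > n) {
    stop("kfold: need 2 <= k <= length(indices); got k = ", k, ", n = ", n)
  }
  set.seed(seed)
  shuffled <- sample(indices)
  unname(split(shuffled, rep_len(seq_len(k), n)))
}

#' Write / read the HDF5 dataset container
#'
#' Stores `X`, `Y` and the class labels together with the grid, the
#' perturbation configuration (as JSON), the seed and a format version, so a
#' corpus round-trips losslessly.
#'
#' @param ds a `blended_dataset`.
#' @param path output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "blended_dataset"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ds$X, path, "X")
  rhdf5::h5write(ds$Y, path, "Y")
  rhdf5::h5write(match(ds$class, mixture_classes()), path, "class")
  meta <- list(grid_start = ds$grid$start, grid_end = ds$grid$end,
               grid_n = ds$grid$n_points, seed = ds$seed,
               format_version = ds$format_version,
               cfg_json = as.character(jsonlite::toJSON(unclass(ds$cfg),
                                                        auto_unbox = TRUE,
                                                        digits = NA)))
  rhdf5::h5write(meta, path, "meta")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- rhdf5::h5read(path, "meta")
  major <- sub("\\..*$", "", as.character(meta$format_version))
  if (major != "1") {
    stop("read_dataset: unsupported dataset format_version ",
         meta$format_version)
  }
  cfg <- jsonlite::fromJSON(as.character(meta$cfg_json))
  cfg <- do.call(perturbation_config, cfg[names(cfg) %in%
                                            names(formals(perturbation_config))])
  Y <- rhdf5::h5read(path, "Y")
  colnames(Y) <- c("CI1", "CI2", "CI3", "CR1", "CR2", "CR3")
  out <- structure(
    list(X = rhdf5::h5read(path, "X"), Y = Y,
         class = mixture_classes()[as.integer(rhdf5::h5read(path, "class"))],
         grid = spectral_grid(as.numeric(meta$grid_start),
                              as.numeric(meta$grid_end),
                              as.integer(meta$grid_n)),
         cfg = cfg, seed = as.integer(meta$seed),
         format_version = as.character(meta$format_version)),
    class = "blended_dataset")
  rhdf5::h5closeAll()
  out
}

#' Export a dataset as a CSV pair
#'
#' Writes `<prefix>_X.csv` (spectra, one row per sample) and
#' `<prefix>_Y.csv` (labels plus class) for interoperability.
#'
#' @param ds a `blended_dataset`.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_dataset_csv <- function(ds, prefix) {
  stopifnot(inherits(ds, "blended_dataset"))
  px <- paste0(prefix, "_X.csv")
  py <- paste0(prefix, "_Y.csv")
  utils::write.table(ds$X, px, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(data.frame(ds$Y, class = ds$class,
                              check.names = FALSE),
                   py, row.names = FALSE)
  invisible(c(px, py))
}
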