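#' Activation map over the last hidden layer
#'
#' For target output neurons `n`, the map is
#' `M_x = sum_n W[x, n] * a_L[x]`: the last-hidden activation weighted by
#' the output weights that connect each hidden unit to the targeted outputs.
#' Targets index the six output neurons (1--3 presence heads, 4--6
#' concentration heads); the default attributes all six, summed, with
#' per-output maps available by passing a subset. Attribution is on the
#' pre-activation output scores, which are linear in the last-hidden
#' activation.
#'
#' @param state a `sam_state`.
#' @param spectrum absorbance vector of input width.
#' @param targets subset of `1:6`, non-empty.
#' @return numeric vector `M` over the last hidden layer's units.
#' @export
activation_map <- function(state, spectrum, targets = 1:6) {
  stopifnot(inherits(state, "sam_state"))
  targets <- check_targets(targets)
  fw <- eval_forward(state, spectrum)
  n_layers <- length(state$W)
  W_out <- state$W[[n_layers]]                 # last-hidden x 6
  a_last <- drop(fw$a_last_raw)
  drop(rowSums(W_out[, targets, drop = FALSE]) * a_last)
}

check_targets <- function(targets) {
  targets <- unique(as.integer(targets))
  if (!length(targets) || any(is.na(targets)) ||
      any(targets < 1) || any(targets > 6)) {
    stop("targets must be a non-empty subset of 1:6")
  }
  targets
}

eval_forward <- function(state, spectrum) {
  if (length(spectrum) != state$cfg$input_width) {
    stop("spectrum length ", length(spectrum), " != input width ",
         state$cfg$input_width)
  }
  fw <- sam_forward_batch(state, matrix(as.numeric(spectrum), nrow = 1),
                          train = FALSE)
  state$cache$fw <- fw
  fw
}

#' Guided backpropagation gradient over the input
#'
#' Gradient of the summed target output scores with respect to the input
#' spectrum, with the guided rule applied at every ReLU: the backward signal
#' is zeroed wherever the forward pre-activation was non-positive or the
#' upstream gradient negative, keeping only input directions that positively
#' drive the targeted outputs. Defined only for ReLU hidden activations;
#' for other activations use [plain_gradient()].
#'
#' @inheritParams activation_map
#' @return numeric gradient vector on the input grid.
#' @export
guided_backprop <- function(state, spectrum, targets = 1:6) {
  stopifnot(inherits(state, "sam_state"))
  if (state$cfg$hidden_activation != "relu") {
    stop("guided_backprop: guided rule is defined for ReLU activations ",
         "only (configured: ", state$cfg$hidden_activation,
         "); use plain_gradient() as the fallback")
  }
  input_gradient(state, spectrum, targets, guided = TRUE)
}

#' Plain input gradient
#'
#' Ordinary gradient of the summed target output scores with respect to the
#' input spectrum (no guided masking); valid for any hidden activation and
#' the finite-difference-checkable baseline of [guided_backprop()]. The two
#' agree when every pre-activation and backward signal is positive.
#'
#' @inheritParams activation_map
#' @return numeric gradient vector on the input grid.
#' @export
plain_gradient <- function(state, spectrum, targets = 1:6) {
  stopifnot(inherits(state, "sam_state"))
  input_gradient(state, spectrum, targets, guided = FALSE)
}

input_gradient <- function(state, spectrum, targets, guided) {
  targets <- check_targets(targets)
  fw <- eval_forward(state, spectrum)
  n_layers <- length(state$W)
  e <- numeric(6); e[targets] <- 1
  dA <- drop(state$W[[n_layers]] %*% e)        # into last hidden activation
  for (l in rev(seq_len(n_layers - 1))) {
    gz <- drop(.activation_grad(matrix(fw$z[[l]], nrow = 1),
                                state$cfg$hidden_activation))
    dZ <- dA * gz
    if (guided) dZ[dZ < 0] <- 0
    dA <- drop(state$W[[l]] %*% dZ)
  }
  dA
}

#' Fuse an activation map with input gradients
#'
#' The activation map lives on the hidden-unit index axis (default 211
#' units) while the gradients live on the spectral grid (default 3321
#' points); `M` is linearly interpolated onto the grid (uniform stretch,
#' endpoints preserved) and multiplied element-wise with `g_b`. Optionally
#' the fused map is rectified (negative part dropped) for rendering.
#'
#' @param M activation map vector (any length >= 2).
#' @param g_b gradient vector on the grid.
#' @param grid the [spectral_grid()].
#' @param rectify keep only the positive part of the fused map.
#' @return list with `g_a` (fused map) and `M_interp` (interpolated map),
#'   both of grid length.
#' @export
fuse_gam <- function(M, g_b, grid, rectify = FALSE) {
  stopifnot(inherits(grid, "spectral_grid"), length(g_b) == grid$n_points,
            length(M) >= 2)
  M_interp <- stats::approx(seq(0, 1, length.out = length(M)), M,
                            xout = seq(0, 1, length.out = grid$n_points))$y
  g_a <- g_b * M_interp
  if (rectify) g_a <- pmax(g_a, 0)
  list(g_a = g_a, M_interp = M_interp)
}

#' Gradient activation map of a prediction
#'
#' End-to-end attribution for one spectrum: the activation map `M` over the
#' last hidden layer, the guided input gradients `g_b` (plain gradients,
#' with a warning, when the hidden activation is not ReLU) and their fusion
#' `g_a` on the spectral grid. High `|g_a|` marks the spectral regions that
#' drive the targeted outputs.
#'
#' @inheritParams activation_map
#' @param grid the [spectral_grid()] the spectrum lives on.
#' @param rectify rectify the fused map (rendering choice; the raw signed
#'   map is the default).
#' @return object of class `gam_result`: `M`, `g_b`, `g_a`, `M_interp`,
#'   `targets`, `grid`.
#' @export
gam <- function(state, spectrum, grid, targets = 1:6, rectify = FALSE) {
  targets <- check_targets(targets)
  M <- activation_map(state, spectrum, targets)
  g_b <- if (state$cfg$hidden_activation == "relu") {
    guided_backprop(state, spectrum, targets)
  } else {
    warning("gam: hidden activation is not ReLU; using plain gradients")
    plain_gradient(state, spectrum, targets)
  }
  fused <- fuse_gam(M, g_b, grid, rectify = rectify)
  structure(list(M = M, g_b = g_b, g_a = fused$g_a,
                 M_interp = fused$M_interp, targets = targets, grid = grid),
            class = "gam_result")
}

#' @export
print.gam_result <- function(x, ...) {
  cat(sprintf("<gam_result> targets {%s}; |M| = %d, grid %d points, max |g_a| = %.4g\n",
              paste(x$targets, collapse = ","), length(x$M),
              x$grid$n_points, max(abs(x$g_a))))
  invisible(x)
}

#' Export a GAM as three-column text plus JSON metadata
#'
#' Writes `(wavenumber, g_a, M_interp)` rows to `path` and a small JSON
#' sidecar `<path>.json` with the targets and grid.
#'
#' @param x a `gam_result`.
#' @param path output text path.
#' @return `path` invisibly.
#' @export
write_gam <- function(x, path) {
  stopifnot(inherits(x, "gam_result"))
  utils::write.table(data.frame(wavenumber = x$grid$nu, g_a = x$g_a,
                                M_interp = x$M_interp),
                     path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(targets = x$targets,
                            grid = list(start = x$grid$start,
                                        end = x$grid$end,
                                        n_points = x$grid$n_points)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
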