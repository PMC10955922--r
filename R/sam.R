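#' Network architecture configuration
#'
#' The spectral analysis network is a fully connected multilayer perceptron
#' mapping one absorbance spectrum to six outputs: three presence
#' probabilities (sigmoid heads, "CI") and three concentration regressors
#' (linear heads, "CR"). The default architecture is
#' 3321-196-74-211-6 with dropout 0.2 between the last hidden layer and the
#' output layer. Concentration targets are trained per-gas max-normalised
#' (`cr_scale`), because the gases span two orders of magnitude in ppm; the
#' scaling is inverted at prediction time. Set `cr_scale = c(1,1,1)` to
#' train on raw ppm.
#'
#' @param input_width spectrum length (grid points).
#' @param hidden_widths hidden layer sizes.
#' @param dropout dropout rate before the output layer, in `[0, 1)`.
#' @param hidden_activation `"relu"` (default; required for guided
#'   backpropagation), `"tanh"` or `"identity"`.
#' @param cr_scale per-gas normalisation constants (ppm) for the three
#'   concentration outputs.
#' @return An object of class `sam_config`.
#' @export
sam_config <- function(input_width = 3321, hidden_widths = c(196, 74, 211),
                       dropout = 0.2, hidden_activation = "relu",
                       cr_scale = c(50, 50, 2000)) {
  stopifnot(input_width >= 1, length(hidden_widths) >= 1,
            all(hidden_widths >= 1), dropout >= 0, dropout < 1,
            length(cr_scale) == 3, all(cr_scale > 0))
  hidden_activation <- match.arg(hidden_activation,
                                 c("relu", "tanh", "identity"))
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 output_width = 6L, n_gases = 3L,
                 dropout = dropout, hidden_activation = hidden_activation,
                 cr_scale = cr_scale),
            class = "sam_config")
}

#' Training configuration
#'
#' Defaults are the reference training recipe: batch 256, 500 epochs,
#' learning rate 0.01, Adam with beta1 = 0.5 and beta2 = 0.999, and
#' concentration-loss weight lambda = 100 (the identification task converges
#' much faster than the regression task; the weight keeps both in play).
#'
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param learning_rate Adam step size (the initial rate under a schedule).
#' @param adam_beta1,adam_beta2 Adam moment decay constants.
#' @param lambda_con weight of the concentration (MSE) loss term.
#' @param lr_schedule `"constant"`, or `"cosine_tail"` (constant for the
#'   first half of training, cosine decay to 0 over the second half) —
#'   useful in short-budget runs, where constant-rate Adam stalls at a
#'   noise floor proportional to the step size.
#' @param init weight initialisation: `"uniform"` (fan-in-scaled uniform)
#'   or `"spectral"` (first layer set to whitened principal-component
#'   loadings of the training spectra with a positive bias shift, deeper
#'   layers orthogonal, output layer zero). Spectral initialisation starts
#'   the network as a well-conditioned near-linear map of standardised PC
#'   scores; with few optimiser steps it converges much faster on
#'   absorbance inputs, whose nonnegative, strongly correlated channels
#'   condition fan-in random features poorly.
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 256, epochs = 500,
                         learning_rate = 0.01, adam_beta1 = 0.5,
                         adam_beta2 = 0.999, lambda_con = 100,
                         lr_schedule = c("constant", "cosine_tail"),
                         init = c("uniform", "spectral"), seed = 1) {
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate > 0,
            adam_beta1 >= 0, adam_beta1 < 1, adam_beta2 >= 0, adam_beta2 < 1,
            lambda_con >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 lambda_con = lambda_con,
                 lr_schedule = match.arg(lr_schedule),
                 init = match.arg(init), seed = as.integer(seed)),
            class = "train_config")
}

# Spectral-whitening initialisation: layer 1 holds sign-paired whitened PC
# loadings (preactivation = standardised PC score + bias_shift, so ReLU
# units start active over most of the data), hidden layers are scaled
# orthogonal with the same positive bias shift, and the output layer starts
# at zero. Uses the current RNG state.
spectral_init <- function(state, X, bias_shift = 1) {
  h1 <- ncol(state$W[[1]])
  rank_max <- min(h1, ncol(X), nrow(X) - 1)
  pc <- stats::prcomp(X, center = TRUE, rank. = rank_max)
  npc <- ncol(pc$rotation)
  sdv <- pmax(pc$sdev[seq_len(npc)], 1e-8)
  R <- sweep(pc$rotation, 2, sdv, "/")
  mu <- colMeans(X)
  for (j in seq_len(h1)) {
    k <- ((j - 1) %% npc) + 1
    s <- if (j > npc) -1 else 1
    state$W[[1]][, j] <- s * R[, k]
    state$b[[1]][j] <- -s * sum(mu * R[, k]) + bias_shift
  }
  n_layers <- length(state$W)
  if (n_layers > 2) {
    for (l in 2:(n_layers - 1)) {
      d_in <- nrow(state$W[[l]]); d_out <- ncol(state$W[[l]])
      Q <- if (d_in >= d_out) {
        qr.Q(qr(matrix(stats::rnorm(d_in * d_out), d_in)))[, seq_len(d_out),
                                                           drop = FALSE]
      } else {
        t(qr.Q(qr(matrix(stats::rnorm(d_in * d_out), d_out)))[, seq_len(d_in),
                                                              drop = FALSE])
      }
      state$W[[l]] <- Q * 2 * sqrt(2 / d_in)
      state$b[[l]] <- rep(bias_shift, d_out)
    }
  }
  state$W[[n_layers]] <- state$W[[n_layers]] * 0
  state$b[[n_layers]] <- state$b[[n_layers]] * 0
  state
}

.activation <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), tanh = tanh(z), identity = z)
}
.activation_grad <- function(z, kind) {
  # ReLU subgradient at 0 is taken as 0
  switch(kind, relu = (z > 0) * 1, tanh = 1 - tanh(z)^2,
         identity = array(1, dim = dim(z)))
}
.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialise network state
#'
#' Weights and biases are drawn uniformly on
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` (fan-in scaling), seeded.
#'
#' @param cfg a [sam_config()].
#' @param seed integer seed.
#' @return object of class `sam_state`: layer weight matrices `W` (each
#'   `fan_in x fan_out`), bias vectors `b`, the config, an empty training
#'   history and a cache environment for the last forward pass.
#' @export
sam_init <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sam_config"))
  widths <- c(cfg$input_width, cfg$hidden_widths, cfg$output_width)
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(widths) - 1)) {
    lim <- 1 / sqrt(widths[l])
    W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1], -lim, lim),
                     nrow = widths[l])
    b[[l]] <- stats::runif(widths[l + 1], -lim, lim)
  }
  structure(list(cfg = cfg, W = W, b = b,
                 history = data.frame(epoch = integer(), obj = numeric(),
                                      iden = numeric(), con = numeric()),
                 train_cfg = NULL, format_version = "1.0",
                 cache = new.env(parent = emptyenv())),
            class = "sam_state")
}

#' @export
print.sam_state <- function(x, ...) {
  widths <- c(x$cfg$input_width, x$cfg$hidden_widths, x$cfg$output_width)
  cat(sprintf("<sam_state> %s, %s, %d epochs trained\n",
              paste(widths, collapse = "-"), x$cfg$hidden_activation,
              nrow(x$history)))
  invisible(x)
}

# Batch forward pass. X is batch x input_width. In training mode a dropout
# mask (inverted dropout) is applied to the last hidden activation.
sam_forward_batch <- function(state, X, train = FALSE) {
  cfg <- state$cfg
  n_hidden <- length(cfg$hidden_widths)
  a <- list(X)            # a[[1]] = input
  z <- list()
  for (l in seq_len(n_hidden)) {
    z[[l]] <- addbias(a[[l]] %*% state$W[[l]], state$b[[l]])
    a[[l + 1]] <- .activation(z[[l]], cfg$hidden_activation)
  }
  drop_mask <- NULL
  a_last <- a[[n_hidden + 1]]
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix(stats::rbinom(length(a_last), 1, keep) / keep,
                        nrow = nrow(a_last))
    a_last <- a_last * drop_mask
  }
  lo <- n_hidden + 1
  z_out <- addbias(a_last %*% state$W[[lo]], state$b[[lo]])
  list(a = a, z = z, a_last_raw = a[[n_hidden + 1]], a_last = a_last,
       drop_mask = drop_mask, z_out = z_out,
       ci_prob = .sigmoid(z_out[, 1:3, drop = FALSE]),
       cr_scaled = z_out[, 4:6, drop = FALSE])
}

addbias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Forward pass on one spectrum
#'
#' Deterministic evaluation-mode pass (dropout off). The last hidden
#' activation and the pre-activation trace are cached in `state$cache` for
#' the attribution operations.
#'
#' @param state a [sam_init()] / [sam_train()] state.
#' @param spectrum absorbance vector of length `cfg$input_width`.
#' @return object of class `sam_prediction`: `ci_prob` (3 presence
#'   probabilities), `cr_raw` (3 concentrations, ppm, unclipped), `cr_gated`
#'   (gated concentrations, see [predict_gated()]).
#' @export
sam_forward <- function(state, spectrum) {
  stopifnot(inherits(state, "sam_state"))
  if (length(spectrum) != state$cfg$input_width) {
    stop("sam_forward: spectrum length ", length(spectrum),
         " != input width ", state$cfg$input_width)
  }
  fw <- sam_forward_batch(state, matrix(as.numeric(spectrum), nrow = 1),
                          train = FALSE)
  state$cache$fw <- fw
  state$cache$spectrum <- as.numeric(spectrum)
  cr_raw <- drop(fw$cr_scaled) * state$cfg$cr_scale
  p <- drop(fw$ci_prob)
  structure(list(ci_prob = p, cr_raw = cr_raw,
                 cr_gated = gate_concentrations(p, cr_raw)),
            class = "sam_prediction")
}

#' @export
print.sam_prediction <- function(x, ...) {
  cat(sprintf("<sam_prediction> ci_prob = (%s), cr_gated ppm = (%s)\n",
              paste(sprintf("%.3f", x$ci_prob), collapse = ", "),
              paste(sprintf("%.4g", x$cr_gated), collapse = ", ")))
  invisible(x)
}

# The gating rule: a concentration is reported only when its presence
# probability strictly exceeds 0.5; otherwise it is forced to 0. Reported
# concentrations are clipped at 0.
gate_concentrations <- function(ci_prob, cr_raw) {
  ifelse(ci_prob > 0.5, pmax(cr_raw, 0), 0)
}

#' Confidence-gated prediction
#'
#' Runs the forward pass and applies the gating rule: gas `i`'s
#' concentration is reported only when its presence probability exceeds 0.5
#' (strictly; a probability of exactly 0.5 gates to absent), otherwise the
#' reported concentration is 0 regardless of the regressor output. Gating
#' removes the ambiguity of near-zero regression outputs: a zero means
#' "absent", not "small".
#'
#' @param state a `sam_state`.
#' @param spectrum absorbance vector of input width.
#' @return a `sam_prediction` (see [sam_forward()]); `cr_gated` carries the
#'   gated concentrations in ppm.
#' @export
predict_gated <- function(state, spectrum) {
  sam_forward(state, spectrum)
}

#' Joint identification + regression loss
#'
#' `L_obj = L_iden + lambda * L_con`, where `L_iden` is the mean binary
#' cross-entropy over the `m x 3` presence flags (probabilities clamped to
#' `[eps, 1-eps]`) and `L_con` the mean squared error over the `m x 3`
#' (scaled) concentrations, absent gases included with target 0.
#'
#' @param ci_prob m x 3 predicted presence probabilities.
#' @param cr_pred m x 3 predicted (scaled) concentrations.
#' @param ci_true m x 3 binary presence flags.
#' @param cr_true m x 3 (scaled) concentration targets.
#' @param lambda_con weight of the concentration term.
#' @param eps clamping constant for the cross-entropy.
#' @return list with `obj`, `iden`, `con` (all `>= 0`).
#' @export
sam_loss <- function(ci_prob, cr_pred, ci_true, cr_true,
                     lambda_con = 100, eps = 1e-7) {
  if (any(!is.finite(ci_prob)) || any(!is.finite(cr_pred)) ||
      any(!is.finite(ci_true)) || any(!is.finite(cr_true))) {
    stop("sam_loss: non-finite inputs")
  }
  p <- pmin(pmax(ci_prob, eps), 1 - eps)
  iden <- -mean(ci_true * log(p) + (1 - ci_true) * log(1 - p))
  con <- mean((cr_true - cr_pred)^2)
  list(obj = iden + lambda_con * con, iden = iden, con = con)
}

#' Train the network with Adam
#'
#' Minibatch Adam on the joint loss. Reproducible given the seed in
#' `train_cfg` (initialisation, shuffling and dropout all draw from it).
#' With `epochs = 0` the initialised, untrained state is returned with an
#' empty history.
#'
#' @param X m x input_width spectra matrix.
#' @param Y m x 6 label matrix (CI1..CI3, CR1..CR3; concentrations in ppm).
#' @param cfg a [sam_config()].
#' @param train_cfg a [train_config()].
#' @param log_file optional path; per-epoch JSON lines
#'   (`epoch, obj, iden, con, seconds`) are appended there.
#' @param verbose print per-epoch losses.
#' @return a trained `sam_state` with `history` (one row per epoch).
#' @export
sam_train <- function(X, Y, cfg = sam_config(), train_cfg = train_config(),
                      log_file = NULL, verbose = FALSE) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), ncol(Y) == 6,
            ncol(X) == cfg$input_width, nrow(X) >= 1,
            inherits(train_cfg, "train_config"))
  m <- nrow(X)
  G <- Y[, 1:3, drop = FALSE]
  Cs <- sweep(Y[, 4:6, drop = FALSE], 2, cfg$cr_scale, "/")
  state <- sam_init(cfg, seed = train_cfg$seed)
  if (identical(train_cfg$init, "spectral")) {
    state <- spectral_init(state, X)
  }
  state$train_cfg <- train_cfg
  if (train_cfg$epochs == 0) return(state)
  n_layers <- length(state$W)
  mW <- lapply(state$W, function(w) w * 0)
  vW <- lapply(state$W, function(w) w * 0)
  mb <- lapply(state$b, function(x) x * 0)
  vb <- lapply(state$b, function(x) x * 0)
  b1 <- train_cfg$adam_beta1; b2 <- train_cfg$adam_beta2
  lr0 <- train_cfg$learning_rate; lam <- train_cfg$lambda_con
  adam_eps <- 1e-8
  t_step <- 0
  hist <- matrix(NA_real_, nrow = train_cfg$epochs, ncol = 3)
  t0 <- Sys.time()
  for (epoch in seq_len(train_cfg$epochs)) {
    frac <- (epoch - 1) / train_cfg$epochs
    lr <- if (identical(train_cfg$lr_schedule, "cosine_tail") && frac >= 0.5) {
      lr0 * 0.5 * (1 + cos(pi * (frac - 0.5) / 0.5))
    } else {
      lr0
    }
    perm <- sample.int(m)
    starts <- seq(1, m, by = train_cfg$batch_size)
    ep_loss <- c(0, 0, 0); ep_n <- 0
    for (s in starts) {
      idx <- perm[s:min(s + train_cfg$batch_size - 1, m)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      fw <- sam_forward_batch(state, Xb, train = TRUE)
      P <- fw$ci_prob
      Ch <- fw$cr_scaled
      ls <- sam_loss(P, Ch, G[idx, , drop = FALSE], Cs[idx, , drop = FALSE],
                     lambda_con = lam)
      if (!is.finite(ls$obj)) {
        stop("sam_train: training diverged (non-finite loss) at epoch ",
             epoch)
      }
      ep_loss <- ep_loss + B * c(ls$obj, ls$iden, ls$con); ep_n <- ep_n + B
      # output-layer gradient: BCE-through-sigmoid for CI, weighted MSE for CR
      dZo <- cbind((P - G[idx, , drop = FALSE]) / (B * 3),
                   lam * 2 * (Ch - Cs[idx, , drop = FALSE]) / (B * 3))
      gW <- vector("list", n_layers); gb <- vector("list", n_layers)
      gW[[n_layers]] <- crossprod(fw$a_last, dZo)
      gb[[n_layers]] <- colSums(dZo)
      dA <- tcrossprod(dZo, state$W[[n_layers]])
      if (!is.null(fw$drop_mask)) dA <- dA * fw$drop_mask
      for (l in rev(seq_len(n_layers - 1))) {
        dZ <- dA * .activation_grad(fw$z[[l]], cfg$hidden_activation)
        gW[[l]] <- crossprod(fw$a[[l]], dZ)
        gb[[l]] <- colSums(dZ)
        if (l > 1) dA <- tcrossprod(dZ, state$W[[l]])
      }
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (l in seq_len(n_layers)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        state$W[[l]] <- state$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + adam_eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        state$b[[l]] <- state$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + adam_eps)
      }
    }
    hist[epoch, ] <- ep_loss / ep_n
    if (verbose) {
      cat(sprintf("epoch %4d  obj %.5g  iden %.5g  con %.5g\n",
                  epoch, hist[epoch, 1], hist[epoch, 2], hist[epoch, 3]))
    }
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(list(epoch = epoch, obj = hist[epoch, 1],
                                iden = hist[epoch, 2], con = hist[epoch, 3],
                                seconds = as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs"))),
                           auto_unbox = TRUE, digits = NA),
          "\n", file = log_file, append = TRUE, sep = "")
    }
  }
  state$history <- data.frame(epoch = seq_len(train_cfg$epochs),
                              obj = hist[, 1], iden = hist[, 2],
                              con = hist[, 3])
  state
}

#' Batch gated predictions
#'
#' Evaluation-mode forward pass over a spectra matrix, returning presence
#' probabilities, gated concentrations and binary presence calls.
#'
#' @param state a `sam_state`.
#' @param X m x input_width spectra matrix.
#' @return list with `ci_prob` (m x 3), `ci` (m x 3 binary, probability
#'   > 0.5), `cr_raw`, `cr_gated` (m x 3 ppm).
#' @export
sam_predict <- function(state, X) {
  stopifnot(is.matrix(X), ncol(X) == state$cfg$input_width)
  fw <- sam_forward_batch(state, X, train = FALSE)
  cr_raw <- sweep(fw$cr_scaled, 2, state$cfg$cr_scale, "*")
  gated <- (fw$ci_prob > 0.5) * pmax(cr_raw, 0)
  list(ci_prob = fw$ci_prob, ci = (fw$ci_prob > 0.5) * 1L,
       cr_raw = cr_raw, cr_gated = gated)
}

#' Save / load a checkpoint
#'
#' The checkpoint is a single RDS container holding the weights, biases,
#' configs, training history and a format version; the round trip is
#' bit-exact on weights. A JSON snapshot of the configuration is embedded
#' for inspection outside R.
#'
#' @param state a `sam_state`.
#' @param path checkpoint path.
#' @return `path` invisibly; `sam_load` returns the restored `sam_state`.
#' @export
sam_save <- function(state, path) {
  stopifnot(inherits(state, "sam_state"))
  payload <- list(format_version = state$format_version,
                  cfg = state$cfg, train_cfg = state$train_cfg,
                  W = state$W, b = state$b, history = state$history,
                  cfg_json = as.character(jsonlite::toJSON(
                    list(cfg = unclass(state$cfg),
                         train_cfg = if (!is.null(state$train_cfg))
                           unclass(state$train_cfg)),
                    auto_unbox = TRUE, digits = NA)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname sam_save
#' @export
sam_load <- function(path) {
  payload <- readRDS(path)
  major <- sub("\\..*$", "", as.character(payload$format_version))
  if (major != "1") {
    stop("sam_load: unsupported checkpoint format_version ",
         payload$format_version)
  }
  structure(list(cfg = payload$cfg, W = payload$W, b = payload$b,
                 history = payload$history, train_cfg = payload$train_cfg,
                 format_version = payload$format_version,
                 cache = new.env(parent = emptyenv())),
            class = "sam_state")
}

#' Seeded random search over hyperparameters
#'
#' A deliberately simple stand-in for a full hyperparameter optimisation:
#' draws `n_draws` random combinations of hidden widths, learning rate and
#' batch size, trains each briefly and reports the final objective.
#'
#' @param X,Y training data as in [sam_train()].
#' @param n_draws number of random configurations.
#' @param epochs training epochs per draw.
#' @param seed integer seed.
#' @return data frame of configurations and final losses, sorted by `obj`.
#' @export
random_search_hyperparams <- function(X, Y, n_draws = 5, epochs = 20,
                                      seed = 1) {
  set.seed(seed)
  draws <- data.frame(
    h1 = sample(32:256, n_draws, replace = TRUE),
    h2 = sample(16:128, n_draws, replace = TRUE),
    h3 = sample(32:256, n_draws, replace = TRUE),
    lr = 10^stats::runif(n_draws, -3, -1.5),
    batch = sample(c(64L, 128L, 256L), n_draws, replace = TRUE))
  draws$obj <- NA_real_
  for (i in seq_len(n_draws)) {
    cfg <- sam_config(input_width = ncol(X),
                      hidden_widths = c(draws$h1[i], draws$h2[i], draws$h3[i]))
    tc <- train_config(batch_size = draws$batch[i], epochs = epochs,
                       learning_rate = draws$lr[i], seed = seed + i)
    st <- sam_train(X, Y, cfg, tc)
    draws$obj[i] <- utils::tail(st$history$obj, 1)
  }
  draws[order(draws$obj), ]
}
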