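#' Exact match ratio
#'
#' Fraction of samples whose full 3-flag composition prediction matches the
#' truth exactly (a partially correct composition counts as wrong).
#'
#' @param true_ci,pred_ci m x 3 binary matrices of presence flags.
#' @return fraction in `[0, 1]`.
#' @export
emr <- function(true_ci, pred_ci) {
  check_binary_pair(true_ci, pred_ci)
  mean(rowSums(true_ci != pred_ci) == 0)
}

#' Hamming accuracy
#'
#' Fraction of individual presence flags predicted correctly over all
#' samples and gases; always at least the exact match ratio.
#'
#' @inheritParams emr
#' @return fraction in `[0, 1]`.
#' @export
ha <- function(true_ci, pred_ci) {
  check_binary_pair(true_ci, pred_ci)
  mean(true_ci == pred_ci)
}

check_binary_pair <- function(true_ci, pred_ci) {
  if (!is.matrix(true_ci) || !is.matrix(pred_ci) ||
      !all(dim(true_ci) == dim(pred_ci))) {
    stop("presence matrices must be matrices of equal dimensions")
  }
  if (!all(true_ci %in% c(0, 1)) || !all(pred_ci %in% c(0, 1))) {
    stop("presence matrices must be binary")
  }
  invisible(TRUE)
}

#' Composition confusion matrix
#'
#' Maps each sample's presence pattern to its mixture class and tabulates
#' true class against predicted class. Predictions may declare no gas at
#' all, so the 7 classes are extended by a "none" bucket. Rows of the
#' normalised matrix sum to 1 for observed classes (all-zero otherwise).
#'
#' @inheritParams emr
#' @return object of class `composition_confusion`: list with `counts` and
#'   row-normalised `proportions` (8 x 8 matrices over
#'   `c(mixture_classes(), "none")`).
#' @export
composition_confusion <- function(true_ci, pred_ci) {
  check_binary_pair(true_ci, pred_ci)
  lv <- c(mixture_classes(), "none")
  tc <- apply(true_ci, 1, .pattern_to_class)
  pc <- apply(pred_ci, 1, .pattern_to_class)
  counts <- table(factor(tc, levels = lv), factor(pc, levels = lv))
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  rs <- rowSums(counts)
  prop <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, proportions = prop),
            class = "composition_confusion")
}

#' @export
print.composition_confusion <- function(x, digits = 2, ...) {
  cat("<composition_confusion> row-normalised proportions:\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Write a confusion matrix as labelled CSV
#' @param x a `composition_confusion`.
#' @param path output path.
#' @param what `"proportions"` (default) or `"counts"`.
#' @return `path` invisibly.
#' @export
write_confusion_csv <- function(x, path, what = c("proportions", "counts")) {
  what <- match.arg(what)
  utils::write.csv(as.data.frame(x[[what]]), path, row.names = TRUE)
  invisible(path)
}

#' Concentration-regression metrics
#'
#' Per-gas coefficient of determination
#' `R2 = 1 - sum((c - chat)^2) / sum((c - mean(c))^2)`, mean absolute error
#' (ppm), and mean relative error. Relative errors are computed only over
#' samples where the gas is truly present with `c > 0` (relative error is
#' undefined at zero truth; absent-gas behaviour is judged by the
#' identification metrics instead). `R2` for a gas whose true values have
#' zero variance is reported as `NA` with a warning.
#'
#' @param true_c,pred_c m x 3 concentration matrices, ppm.
#' @param gas_names names for the three columns of the report.
#' @return object of class `regression_metrics`: data frame `per_gas` with
#'   columns `gas`, `r2`, `mae`, `mre`, `n_present`, plus matrices `ae`
#'   (absolute errors) and `re` (relative errors, `NA` where truth is 0).
#' @export
regression_metrics <- function(true_c, pred_c,
                               gas_names = c("methane", "acetone", "water")) {
  if (!is.matrix(true_c) || !is.matrix(pred_c) ||
      !all(dim(true_c) == dim(pred_c))) {
    stop("regression_metrics: concentration matrices must match in shape")
  }
  ngas <- ncol(true_c)
  ae <- abs(true_c - pred_c)
  re <- ae / ifelse(true_c > 0, true_c, NA_real_)
  per_gas <- data.frame(gas = gas_names[seq_len(ngas)],
                        r2 = NA_real_, mae = NA_real_, mre = NA_real_,
                        n_present = NA_integer_)
  for (i in seq_len(ngas)) {
    ct <- true_c[, i]; cp <- pred_c[, i]
    ss_tot <- sum((ct - mean(ct))^2)
    if (ss_tot == 0) {
      warning("regression_metrics: zero variance in true values for gas ",
              gas_names[i], "; R2 undefined")
    } else {
      per_gas$r2[i] <- 1 - sum((ct - cp)^2) / ss_tot
    }
    per_gas$mae[i] <- mean(ae[, i])
    present <- ct > 0
    per_gas$n_present[i] <- sum(present)
    per_gas$mre[i] <- if (any(present)) mean(re[present, i]) else NA_real_
  }
  structure(list(per_gas = per_gas, ae = ae, re = re),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat("<regression_metrics>\n")
  print(x$per_gas, row.names = FALSE)
  invisible(x)
}

#' Full evaluation of a trained model on a labelled set
#'
#' Gated predictions are scored with the identification metrics (EMR, HA,
#' composition confusion) and the regression metrics on the gated
#' concentrations.
#'
#' @param state a trained `sam_state`.
#' @param X m x input_width spectra.
#' @param Y m x 6 labels (CI then CR in ppm).
#' @return object of class `metrics_report`: list with `emr`, `ha`,
#'   `confusion`, `regression`.
#' @export
evaluate_model <- function(state, X, Y) {
  stopifnot(ncol(Y) == 6)
  pr <- sam_predict(state, X)
  true_ci <- Y[, 1:3, drop = FALSE]
  structure(list(emr = emr(true_ci, pr$ci), ha = ha(true_ci, pr$ci),
                 confusion = composition_confusion(true_ci, pr$ci),
                 regression = regression_metrics(Y[, 4:6, drop = FALSE],
                                                 pr$cr_gated)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> EMR = %.4f, HA = %.4f\n", x$emr, x$ha))
  print(x$regression)
  invisible(x)
}

#' Serialise a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(emr = report$emr, ha = report$ha,
         per_gas = report$regression$per_gas,
         confusion_proportions = report$confusion$proportions),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
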