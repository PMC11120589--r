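#' Yoon's connection-weight relative importance
#'
#' Signed relative importance of each input of a trained perceptron,
#' computed from the products of input-to-hidden and hidden-to-output
#' weights: `RI_i = sum_k(w_ik * w_k) / sum_i |sum_k(w_ik * w_k)| * 100`.
#' Biases are excluded; only connection weights enter. The absolute
#' importances sum to 100% per output by construction. Weights are taken
#' on the normalized scale on which the network was trained.
#'
#' @param model an [mlp_model()] or an `od_ann_fit`.
#' @return Named numeric vector of signed percentages over the inputs.
#' @examples
#' m <- mlp_model(W1 = matrix(c(2, -1, 1), nrow = 1), B1 = 0, W2 = 3, B2 = 0)
#' yoon_ri(m)  # 50, -25, 25
#' @export
yoon_ri <- function(model) {
  if (inherits(model, "od_ann_fit")) model <- model$model
  stopifnot(inherits(model, "mlp_model"))
  inner <- drop(model$W2 %*% model$W1)  # sum over hidden units per input
  denom <- sum(abs(inner))
  if (denom == 0) stop("all connection-weight products are zero; relative importance undefined")
  ri <- 100 * inner / denom
  names(ri) <- colnames(model$W1) %||% od_factor_names()[seq_along(ri)]
  ri
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative-importance matrix over trained models
#'
#' @param fits an `od_ann_search` (list of fits).
#' @return Matrix, inputs x responses, of signed percentages.
#' @export
ri_matrix <- function(fits) {
  vapply(fits, yoon_ri, numeric(3))
}

#' Goodness-of-fit report
#'
#' Computes the model-validation suite on observed/predicted pairs:
#' reduced chi-square `sum((e)^2) / (N - n_params)`, `RMSE`, mean bias
#' error `MBE`, mean percentage error `MPE`, sum of squared errors `SSE`,
#' average absolute relative deviation `AARD`, and
#' `r2 = 1 - SSE / sum((obs - mean(obs))^2)`, plus moments of the
#' residuals `obs - pred` (mean, sd, variance, skewness, excess
#' kurtosis; plain moment estimators without small-sample bias
#' correction). `MPE` is implemented exactly as conventionally printed,
#' `100/N * sum(|e| / pred)`, which coincides with `AARD` whenever all
#' predictions are positive; both are reported.
#'
#' @param observed,predicted numeric vectors of equal length `N >= 2`.
#' @param n_params parameter count in the chi-square denominator; for a
#'   3-H-1 perceptron this is `5H + 1`.
#' @return One-row data frame of class `"od_gof"`.
#' @examples
#' gof_report(c(1, 2, 3), c(1, 1, 1), n_params = 1)
#' @export
gof_report <- function(observed, predicted, n_params = 0L) {
  N <- length(observed)
  if (length(predicted) != N) stop("observed and predicted differ in length")
  if (N < 2L) stop("need at least 2 records")
  e <- observed - predicted
  sse <- sum(e^2)
  chi_sq <- NA_real_
  if (n_params >= N) {
    warning("n_params >= N; reduced chi-square undefined")
  } else {
    chi_sq <- sse / (N - n_params)
  }
  mpe <- aard <- NA_real_
  if (any(predicted == 0)) {
    warning("zero predicted value(s); MPE and AARD undefined")
  } else {
    mpe <- 100 / N * sum(abs(e) / predicted)
    aard <- 100 / N * sum(abs(e / predicted))
  }
  data.frame(
    chi_sq = chi_sq,
    RMSE = sqrt(sse / N),
    MBE = mean(e),
    MPE = mpe,
    SSE = sse,
    AARD = aard,
    r2 = 1 - sse / sum((observed - mean(observed))^2),
    skewness = e1071::skewness(e, type = 1),
    kurtosis = e1071::kurtosis(e, type = 1),
    mean = mean(e),
    stdev = stats::sd(e),
    variance = stats::var(e),
    N = N,
    n_params = n_params
  ) -> out
  class(out) <- c("od_gof", "data.frame")
  out
}

#' Fit report across trained response models
#'
#' Evaluates every trained model on all runs of the design table and
#' stacks one [gof_report()] row per response, using each model's free
#' parameter count (`5H + 1`) in the chi-square denominator.
#'
#' @param fits an `od_ann_search`.
#' @param table the `od_design` table the models were trained on.
#' @return Data frame, one row per response.
#' @export
fit_report <- function(fits, table) {
  facs <- as.matrix(as.data.frame(table)[, od_factor_names()])
  rows <- lapply(fits, function(f) {
    pred <- mlp_forward(f$model, facs)
    g <- gof_report(table[[f$response]], pred, n_params = 5L * f$H + 1L)
    cbind(response = f$response, g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
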