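#' @name activations
#' @title Activation functions available to the perceptron models
#' @description Hidden and output layers can use `identity`, `logistic`
#'   (sigmoid), `tanh` or `exponential` transfer functions. Derivatives
#'   are expressed in terms of the activation value for the backprop
#'   gradient.
#' @keywords internal
NULL

.activations <- list(
  identity    = list(f = function(z) z,              df = function(a) rep(1, length(a))),
  logistic    = list(f = function(z) 1 / (1 + exp(-z)), df = function(a) a * (1 - a)),
  tanh        = list(f = function(z) tanh(z),        df = function(a) 1 - a^2),
  exponential = list(f = function(z) exp(z),         df = function(a) a)
)

.get_activation <- function(id) {
  if (!id %in% names(.activations)) {
    stop("unknown activation '", id, "'; use one of: ",
         paste(names(.activations), collapse = ", "))
  }
  .activations[[id]]
}

#' Min-max bounds of a training matrix
#'
#' @param X numeric matrix or data frame (columns are variables).
#' @return List with `min` and `max` named vectors.
#' @export
minmax_bounds <- function(X) {
  X <- as.matrix(X)
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  degenerate <- colnames(X)[maxs == mins]
  if (length(degenerate) > 0L) {
    stop("min-max bounds degenerate (max = min) for column(s): ",
         paste(degenerate, collapse = ", "))
  }
  list(min = mins, max = maxs)
}

#' Min-max normalization
#'
#' Maps each column to `(x - min) / (max - min)` using bounds computed
#' from training data. Values outside the training bounds map outside
#' `[0, 1]` and raise a warning.
#'
#' @param X matrix (or vector treated as one column).
#' @param bounds a [minmax_bounds()] list.
#' @return Matrix of the same shape.
#' @export
minmax_normalize <- function(X, bounds) {
  X <- as.matrix(X)
  out <- sweep(sweep(X, 2L, bounds$min), 2L, bounds$max - bounds$min, "/")
  if (any(out < 0 | out > 1)) {
    warning("value(s) outside the training bounds mapped outside [0, 1]")
  }
  out
}

#' Invert a min-max normalization
#'
#' @param X normalized matrix.
#' @param bounds the bounds used to normalize.
#' @return Matrix on the original scale.
#' @export
minmax_denormalize <- function(X, bounds) {
  X <- as.matrix(X)
  sweep(sweep(X, 2L, bounds$max - bounds$min, "*"), 2L, bounds$min, "+")
}

#' Construct a multilayer-perceptron response model
#'
#' A 3-H-1 feedforward network: `y = f_out(W2 %*% f_hid(W1 %*% x + B1) + B2)`,
#' operating on min-max normalized inputs and output when bounds are
#' attached.
#'
#' @param W1 hidden weight matrix, `H x n_inputs`.
#' @param B1 hidden bias vector, length `H`.
#' @param W2 output weight vector (or `1 x H` matrix).
#' @param B2 output bias (scalar).
#' @param f_hidden,f_output activation ids (see `.activations`).
#' @param bounds_in,bounds_out optional [minmax_bounds()] for the inputs
#'   and the response; when `NULL` the model works on the normalized scale.
#' @return List of class `"mlp_model"`.
#' @export
mlp_model <- function(W1, B1, W2, B2, f_hidden = "tanh", f_output = "identity",
                      bounds_in = NULL, bounds_out = NULL) {
  W1 <- as.matrix(W1)
  W2 <- as.numeric(W2)
  H <- nrow(W1)
  if (H < 1L) stop("need at least one hidden neuron")
  if (length(B1) != H || length(W2) != H) {
    stop("dimension mismatch: W1 has ", H, " hidden rows but B1/W2 have ",
         length(B1), "/", length(W2), " entries")
  }
  .get_activation(f_hidden); .get_activation(f_output)
  structure(list(W1 = W1, B1 = as.numeric(B1), W2 = W2, B2 = as.numeric(B2)[1],
                 f_hidden = f_hidden, f_output = f_output,
                 H = H, bounds_in = bounds_in, bounds_out = bounds_out),
            class = "mlp_model")
}

# Forward pass on the normalized scale. X is n x p.
.mlp_eval <- function(model, X) {
  fh <- .get_activation(model$f_hidden)
  fo <- .get_activation(model$f_output)
  A <- fh$f(sweep(X %*% t(model$W1), 2L, model$B1, "+"))
  drop(fo$f(A %*% model$W2 + model$B2))
}

#' Predict a response with a perceptron model
#'
#' Normalizes the factor settings with the model's input bounds, runs the
#' layer composition `f_out(W2 %*% f_hid(W1 %*% x + B1) + B2)` and
#' denormalizes the output. Models without bounds operate directly on the
#' normalized scale.
#'
#' @param model an [mlp_model()].
#' @param x numeric vector of factor settings, or a matrix/data frame with
#'   one row per prediction.
#' @return Predicted response value(s).
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  X <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(X) != ncol(model$W1)) {
    stop("dimension mismatch: model expects ", ncol(model$W1),
         " inputs, got ", ncol(X))
  }
  if (!is.null(model$bounds_in)) X <- suppressWarnings(minmax_normalize(X, model$bounds_in))
  y <- .mlp_eval(model, X)
  if (!is.null(model$bounds_out)) {
    y <- drop(minmax_denormalize(matrix(y, ncol = 1L), model$bounds_out))
  }
  y
}

#' Training configuration for the perceptron models
#'
#' @param hidden integer vector of hidden-layer sizes searched.
#' @param restarts random restarts per topology (seeded).
#' @param maxit BFGS iteration cap per restart.
#' @param fractions train/test/validation split fractions (sum to 1).
#' @param seed integer seed governing the split and every restart.
#' @param f_hidden,f_output activation ids used for training.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(hidden = 3:10, restarts = 50L, maxit = 200L,
                         fractions = c(0.6, 0.2, 0.2), seed = 42L,
                         f_hidden = "tanh", f_output = "identity") {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (restarts < 1L) stop("need at least one restart")
  if (any(hidden < 1L)) stop("hidden sizes must be >= 1")
  structure(list(hidden = as.integer(hidden), restarts = as.integer(restarts),
                 maxit = as.integer(maxit), fractions = fractions,
                 seed = as.integer(seed), f_hidden = f_hidden,
                 f_output = f_output, error = "sos"),
            class = "train_config")
}

# Deterministic split sizes: round train and test, remainder validates.
split_sizes <- function(n, fractions) {
  n_train <- round(fractions[1] * n)
  n_test <- round(fractions[2] * n)
  c(train = n_train, test = n_test, validation = n - n_train - n_test)
}

# pack/unpack the parameter vector for optim
.unpack <- function(par, H, p) {
  list(W1 = matrix(par[seq_len(H * p)], nrow = H),
       B1 = par[H * p + seq_len(H)],
       W2 = par[H * p + H + seq_len(H)],
       B2 = par[H * p + 2 * H + 1L])
}

# SOS loss and analytic gradient on normalized data
.mlp_loss <- function(par, X, y, H, fh, fo) {
  w <- .unpack(par, H, ncol(X))
  Z1 <- sweep(X %*% t(w$W1), 2L, w$B1, "+")
  A <- fh$f(Z1)
  yhat <- drop(fo$f(A %*% w$W2 + w$B2))
  if (!all(is.finite(yhat))) return(1e12)
  sum((yhat - y)^2)
}

.mlp_grad <- function(par, X, y, H, fh, fo) {
  w <- .unpack(par, H, ncol(X))
  Z1 <- sweep(X %*% t(w$W1), 2L, w$B1, "+")
  A <- fh$f(Z1)
  yhat <- drop(fo$f(A %*% w$W2 + w$B2))
  if (!all(is.finite(yhat))) return(rep(0, length(par)))
  d <- 2 * (yhat - y) * fo$df(yhat)
  dA <- outer(d, w$W2) * fh$df(A)
  g <- c(as.vector(t(dA) %*% X), colSums(dA), drop(t(A) %*% d), sum(d))
  if (!all(is.finite(g))) rep(0, length(par)) else g
}

#' Train a perceptron model for one response
#'
#' Splits the runs into training/test/validation sets by a seeded
#' shuffle, min-max normalizes factors and response on the training rows
#' only, and for each hidden-layer size and each seeded random restart
#' minimizes the training sum-of-squares by BFGS. The model with the
#' highest test-split r-squared is retained; the validation split is
#' reported but never used for selection. Restarts whose loss is
#' non-finite are discarded and counted.
#'
#' @param table an `od_design` table.
#' @param response name of the response column to model.
#' @param cfg a [train_config()].
#' @return List of class `"od_ann_fit"`: the best `mlp_model`, selected
#'   `H`, per-split `r2` and `sos` (original response scale), BFGS
#'   iteration count, split indices, and the number of discarded restarts.
#' @export
train_response <- function(table, response, cfg = train_config()) {
  if (!response %in% names(table)) stop("unknown response column: ", response)
  facs <- od_factor_names()
  X_raw <- as.matrix(as.data.frame(table)[, facs])
  y_raw <- table[[response]]
  n <- nrow(X_raw)
  sizes <- split_sizes(n, cfg$fractions)
  if (sizes["train"] < 5L) stop("need at least 5 training rows after the split")

  set.seed(cfg$seed)
  ord <- sample.int(n)
  idx <- list(train = ord[seq_len(sizes["train"])],
              test = ord[sizes["train"] + seq_len(sizes["test"])],
              validation = ord[sizes["train"] + sizes["test"] +
                                 seq_len(sizes["validation"])])

  b_in <- minmax_bounds(X_raw[idx$train, , drop = FALSE])
  b_out <- minmax_bounds(matrix(y_raw[idx$train], ncol = 1L,
                                dimnames = list(NULL, response)))
  Xn <- suppressWarnings(minmax_normalize(X_raw, b_in))
  yn <- drop(suppressWarnings(minmax_normalize(matrix(y_raw, ncol = 1L,
                                                      dimnames = list(NULL, response)),
                                               b_out)))
  fh <- .get_activation(cfg$f_hidden)
  fo <- .get_activation(cfg$f_output)
  Xtr <- Xn[idx$train, , drop = FALSE]
  ytr <- yn[idx$train]

  best <- NULL
  discarded <- 0L
  for (H in cfg$hidden) {
    npar <- 5L * H + 1L
    for (r in seq_len(cfg$restarts)) {
      par0 <- stats::runif(npar, -0.5, 0.5)
      fit <- tryCatch(
        stats::optim(par0, .mlp_loss, .mlp_grad, X = Xtr, y = ytr, H = H,
                     fh = fh, fo = fo, method = "BFGS",
                     control = list(maxit = cfg$maxit, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) {
        discarded <- discarded + 1L
        next
      }
      w <- .unpack(fit$par, H, ncol(Xn))
      model <- mlp_model(w$W1, w$B1, w$W2, w$B2, cfg$f_hidden, cfg$f_output,
                         bounds_in = b_in, bounds_out = b_out)
      pred <- mlp_forward(model, X_raw)
      r2_test <- .r_squared(y_raw[idx$test], pred[idx$test])
      if (is.null(best) || isTRUE(r2_test > best$r2[["test"]]) ||
          (isTRUE(r2_test == best$r2[["test"]]) && fit$value < best$train_loss)) {
        best <- list(
          response = response, model = model, H = H,
          r2 = vapply(idx, function(i) .r_squared(y_raw[i], pred[i]), numeric(1)),
          sos = vapply(idx, function(i) sum((y_raw[i] - pred[i])^2), numeric(1)),
          iterations = unname(fit$counts["gradient"]),
          train_loss = fit$value, split = idx)
      }
    }
  }
  if (is.null(best)) stop("all restarts diverged for response ", response)
  best$discarded <- discarded
  best$config <- cfg
  class(best) <- "od_ann_fit"
  best
}

# r^2 = 1 - SSE/SStot; NA when the split has no variance (e.g. 1 row)
.r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' @export
print.od_ann_fit <- function(x, ...) {
  cat(sprintf("MLP 3-%d-1 for %s (%s/%s): r2 train %.3f, test %.3f, validation %.3f\n",
              x$H, x$response, x$model$f_hidden, x$model$f_output,
              x$r2[["train"]], x$r2[["test"]], x$r2[["validation"]]))
  invisible(x)
}

#' Topology search across responses
#'
#' Runs [train_response()] for each requested response, deriving a
#' distinct seed per response from `cfg$seed` so results are reproducible
#' yet independent across responses.
#'
#' @param table an `od_design` table.
#' @param responses character vector of response columns.
#' @param cfg a [train_config()].
#' @return List of class `"od_ann_search"` of `od_ann_fit` objects,
#'   named by response.
#' @export
topology_search <- function(table, responses = od_response_names(),
                            cfg = train_config()) {
  fits <- lapply(seq_along(responses), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 1000L * i
    train_response(table, responses[i], cfg_i)
  })
  names(fits) <- responses
  class(fits) <- "od_ann_search"
  fits
}

#' Summarize a topology search as a performance table
#'
#' @param object an `od_ann_search`.
#' @param ... unused.
#' @return Data frame with one row per response: network name
#'   (`MLP 3-H-1`), r-squared and SOS per split, iteration count and
#'   activations.
#' @export
summary.od_ann_search <- function(object, ...) {
  rows <- lapply(object, function(f) {
    data.frame(response = f$response, net = sprintf("MLP 3-%d-1", f$H),
               r2_train = f$r2[["train"]], r2_test = f$r2[["test"]],
               r2_validation = f$r2[["validation"]],
               sos_train = f$sos[["train"]], sos_test = f$sos[["test"]],
               sos_validation = f$sos[["validation"]],
               iterations = f$iterations,
               hidden_activation = f$model$f_hidden,
               output_activation = f$model$f_output)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize trained models to JSON
#'
#' @param fits an `od_ann_search` (or list of `od_ann_fit`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
models_to_json <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    m <- f$model
    list(response = f$response, H = f$H,
         W1 = m$W1, B1 = m$B1, W2 = m$W2, B2 = m$B2,
         f_hidden = m$f_hidden, f_output = m$f_output,
         bounds_in = m$bounds_in, bounds_out = m$bounds_out,
         r2 = as.list(f$r2), sos = as.list(f$sos))
  })
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
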