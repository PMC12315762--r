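# Pluggable single-predictor regressors behind a fit/predict contract.

#' Regressor contract
#'
#' A regressor is a list with fields `label`, `fit(x, y) -> model`, and
#' `predict(model, x) -> yhat`. Implementations must be deterministic given
#' their configuration. Built-ins: [regressor_ols()] (default) and
#' [regressor_svr()].
#'
#' @param label short identifier.
#' @param fit function of training activation `x` and behavior `y`.
#' @param predict function of the fitted model and test activation.
#' @return A `decodr_regressor` list.
#' @export
new_regressor <- function(label, fit, predict) {
  structure(list(label = label, fit = fit, predict = predict),
            class = "decodr_regressor")
}

#' Ordinary least-squares simple regression decoder
#'
#' Closed-form simple regression of behavior on activation:
#' `slope = cov(x, y) / var(x)`, `intercept = mean(y) - slope * mean(x)`.
#' Training activation with zero variance signals a degenerate fit (the cell
#' becomes missing downstream).
#'
#' @return A `decodr_regressor`.
#' @export
regressor_ols <- function() {
  new_regressor(
    "ols",
    fit = function(x, y) {
      co <- fit_linear_decoder(x, y)
      list(intercept = co[[1]], slope = co[[2]])
    },
    predict = function(model, x) model$intercept + model$slope * x
  )
}

#' Epsilon-insensitive support vector regression decoder
#'
#' Wraps `e1071::svm` (eps-regression). Defaults: linear kernel, `cost = 1`,
#' `epsilon = 0.1`, predictors scaled. A linear kernel keeps the fitted
#' relationship comparable to the simple linear decoder, which is the point
#' of the comparison: on strongly linear data the two decoders should agree
#' closely.
#'
#' @param kernel,cost,epsilon,scale passed to `e1071::svm`.
#' @return A `decodr_regressor`.
#' @export
regressor_svr <- function(kernel = "linear", cost = 1, epsilon = 0.1,
                          scale = TRUE) {
  new_regressor(
    "svr",
    fit = function(x, y) {
      e1071::svm(x = matrix(x, ncol = 1), y = y, type = "eps-regression",
                 kernel = kernel, cost = cost, epsilon = epsilon,
                 scale = scale)
    },
    predict = function(model, x) {
      as.numeric(predict(model, matrix(x, ncol = 1)))
    }
  )
}

#' Fit the simple linear decoder
#'
#' @param x_train activation values (>= 3, nonzero variance).
#' @param y_train behavior values.
#' @return Named numeric `c(intercept, slope)`; `NA`s if `x_train` has zero
#'   variance (degenerate fit).
#' @export
#' @examples
#' fit_linear_decoder(c(0, 1, 2), c(1, 3, 5))
fit_linear_decoder <- function(x_train, y_train) {
  if (length(x_train) < 3)
    abort("need >= 3 training trials", class = "decodr_validation_error")
  vx <- var(x_train)
  if (!is.finite(vx) || vx == 0)
    return(c(intercept = NA_real_, slope = NA_real_))
  slope <- stats::cov(x_train, y_train) / vx
  c(intercept = mean(y_train) - slope * mean(x_train), slope = slope)
}
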