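#' Regression evaluation metrics
#'
#' The five indicators used to judge every learner: coefficient of
#' determination \eqn{R^2}, mean square error, mean absolute error,
#' mean absolute percentage error (as a fraction, not x100), and the
#' explained variance score \eqn{EVS = 1 - Var(y - \hat y)/Var(y)}.
#' \eqn{R^2} and EVS coincide whenever the residuals have zero mean.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return named list of class `metric_set` with `r2`, `mse`, `mae`,
#'   `mape`, `evs`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop_input("need two equal-length vectors of >= 2 values")
  if (sd(y_true) == 0)
    stop_input("r2/evs undefined: y_true is constant")
  if (any(y_true == 0))
    stop_input("mape undefined: y_true contains zero")
  res <- y_true - y_pred
  ss_tot <- sum((y_true - mean(y_true))^2)
  structure(list(
    r2 = 1 - sum(res^2) / ss_tot,
    mse = mean(res^2),
    mae = mean(abs(res)),
    mape = mean(abs(res / y_true)),
    evs = 1 - var(res) / var(y_true)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 %.4f | MSE %.5f | MAE %.4f | MAPE %.4f | EVS %.4f\n",
              x$r2, x$mse, x$mae, x$mape, x$evs))
  invisible(x)
}
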