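# Recursive one-step and multi-step forecasting with change-stream
# bookkeeping and inverse standardization.

.forecast_result <- function(std, orig, horizon, origin, variant,
                             taxon_ids) {
  dimnames(std) <- dimnames(orig) <- list(taxon_ids,
                                          paste0("step_", seq_len(horizon)))
  structure(list(horizon = horizon, standardized = std, original = orig,
                 origin = origin, variant = variant,
                 taxon_ids = taxon_ids),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("forecast_result (%s): %d taxa, %d step(s) ahead\n",
              x$variant, nrow(x$original), x$horizon))
  print(utils::head(x$original, 5))
  if (nrow(x$original) > 5) cat("...\n")
  invisible(x)
}

.check_window <- function(fit, window, standardizer) {
  cfg <- fit$model$config
  if (!is.matrix(window)) window <- as.matrix(window)
  if (nrow(window) != cfg$n_taxa)
    .stopf("window has %d taxa but the model was trained on %d",
           nrow(window), cfg$n_taxa)
  if (ncol(window) != cfg$window)
    .stopf("window has %d time steps but the model expects %d",
           ncol(window), cfg$window)
  if (!is.null(rownames(window)) && !is.null(standardizer$taxon_ids) &&
      !identical(unname(rownames(window)), unname(standardizer$taxon_ids)))
    .stopf("window taxa do not match the training taxa (order included)")
  window
}

# one forward pass on a single standardized window (D x W), first head step
.std_one_step <- function(fit, wstd) {
  D <- nrow(wstd); W <- ncol(wstd)
  xa <- array(0, c(1L, D, W)); xa[1L, , ] <- wstd
  xc <- array(0, c(1L, D, W)); xc[1L, , ] <- make_change_stream(wstd)
  pred <- .model_forward(fit$model, xa, xc, fit$ahat,
                         keep_cache = FALSE)$pred
  pred[1L, , 1L]
}

#' One-step forecast from a recent window
#'
#' Standardizes the window with the model's stored parameters, rebuilds
#' the change stream, runs the forward pass, and maps the prediction back
#' to the original abundance scale.
#'
#' @param fit a [train_variant()] \code{trained_model}.
#' @param window recent observations, taxa x window, on the original
#'   scale, taxon order as in training.
#' @param standardizer the [fit_standardizer()] used at training time.
#' @param origin optional time index of the last observed column.
#' @return a \code{forecast_result} with horizon 1.
#' @export
predict_one_step <- function(fit, window, standardizer, origin = NA) {
  stopifnot(inherits(fit, "trained_model"))
  window <- .check_window(fit, window, standardizer)
  wstd <- apply_standardizer(window, standardizer)
  p_std <- .std_one_step(fit, wstd)
  .forecast_result(matrix(p_std, ncol = 1),
                   matrix(inverse_transform(matrix(p_std, ncol = 1),
                                            standardizer), ncol = 1),
                   horizon = 1L, origin = origin,
                   variant = fit$model$variant,
                   taxon_ids = standardizer$taxon_ids)
}

#' Recursive multi-step forecast
#'
#' Iterates the one-step forecast: each predicted step is appended to the
#' standardized window (dropping the oldest step) and the change stream is
#' rebuilt so the appended delta always equals the difference of
#' consecutive window values. Horizon 8 reproduces the eight-step
#' protocol.
#'
#' @param fit a [train_variant()] \code{trained_model}.
#' @param window recent observations, taxa x window, original scale.
#' @param h number of steps ahead (>= 1).
#' @param standardizer the training [fit_standardizer()].
#' @param origin optional time index of the last observed column.
#' @return a \code{forecast_result} with horizon \code{h}.
#' @export
predict_multi_step <- function(fit, window, h, standardizer, origin = NA) {
  stopifnot(inherits(fit, "trained_model"))
  h <- .check_count(h, "h", min = 1L)
  window <- .check_window(fit, window, standardizer)
  wstd <- apply_standardizer(window, standardizer)
  D <- nrow(wstd)
  preds <- matrix(0, D, h)
  for (s in seq_len(h)) {
    preds[, s] <- .std_one_step(fit, wstd)
    wstd <- cbind(wstd[, -1, drop = FALSE], preds[, s])
  }
  .forecast_result(preds, inverse_transform(preds, standardizer),
                   horizon = h, origin = origin,
                   variant = fit$model$variant,
                   taxon_ids = standardizer$taxon_ids)
}

#' Write a forecast as TSV
#'
#' Long format: taxon, origin_time, step, predicted_standardized,
#' predicted_original.
#'
#' @param forecast a \code{forecast_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_forecast <- function(forecast, path) {
  stopifnot(inherits(forecast, "forecast_result"))
  df <- data.frame(
    taxon = rep(forecast$taxon_ids, forecast$horizon),
    origin_time = forecast$origin,
    step = rep(seq_len(forecast$horizon), each = nrow(forecast$original)),
    predicted_standardized = as.vector(forecast$standardized),
    predicted_original = as.vector(forecast$original),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
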