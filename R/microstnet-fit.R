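# The user-facing modelling interface: fit the whole pipeline (network,
# standardization, windows, training) from an abundance table and expose
# the usual S3 methods.

#' Fit a spatio-temporal forecaster to an abundance time series
#'
#' End-to-end fit: removes all-zero taxa, builds the taxon-taxon
#' co-occurrence network (Spearman rho, permutation p-values,
#' Benjamini-Hochberg correction at \code{alpha}) on the training segment,
#' Z-score standardizes with training-only parameters, slices the series
#' into sliding windows with an abundance stream and a first-difference
#' change stream, splits windows chronologically, and trains the requested
#' variant with best-validation-MAE checkpointing.
#'
#' @param x an [abundance_table()] or a taxa x time numeric matrix on the
#'   original abundance scale (columns in temporal order).
#' @param variant "microstnet" (two streams + recurrent branch, default),
#'   "stgcn2s" (two streams only) or "lstm" (recurrent branch only).
#' @param window input window length W (default 8).
#' @param horizon head horizon H (default 1; multi-step forecasts recurse).
#' @param train_fraction chronological window split (default 0.8; use 0.7
#'   for a 7:3 split).
#' @param network optional precomputed \code{cooccurrence_network} (or a
#'   normalized adjacency matrix); built from the training segment when
#'   NULL. Ignored by the lstm variant.
#' @param n_perm,alpha permutation count and significance level for the
#'   network (defaults 1000 and 0.05).
#' @param epochs,lr,batch_size training settings (defaults 50, 1e-3, 32).
#' @param channels,kernel,n_blocks,lstm_layers,lstm_hidden architecture
#'   settings; see [model_config()].
#' @param seed single seed fanned out to the network permutations, weight
#'   initialisation and batch shuffling.
#' @param verbose print per-epoch progress.
#' @return object of class \code{microstnet}: list with \code{fit} (the
#'   \code{trained_model}), \code{standardizer}, \code{network},
#'   \code{dataset}, \code{split}, \code{series}, \code{call}.
#' @seealso [predict.microstnet()], [ablation_run()], [simulate_series()]
#' @examples
#' \donttest{
#' spec <- simulator_spec(n_taxa = 6, n_steps = 80, noise_sd = 0.2, seed = 7)
#' series <- simulate_series(spec)
#' fit <- microstnet(series, epochs = 3, n_perm = 50, seed = 7)
#' predict(fit, h = 3)
#' }
#' @export
microstnet <- function(x, variant = c("microstnet", "stgcn2s", "lstm"),
                       window = 8, horizon = 1, train_fraction = 0.8,
                       network = NULL, n_perm = 1000, alpha = 0.05,
                       epochs = 50, lr = 1e-3, batch_size = 32,
                       channels = 16, kernel = 3, n_blocks = 2,
                       lstm_layers = 5, lstm_hidden = window, seed = 1,
                       verbose = FALSE) {
  variant <- match.arg(variant)
  cl <- match.call()
  if (inherits(x, "abundance_table")) {
    x <- drop_zero_features(x)
    series <- x$values
  } else {
    series <- as.matrix(x)
    if (is.null(rownames(series)))
      rownames(series) <- paste0("taxon_", seq_len(nrow(series)))
    keep <- rowSums(series != 0) > 0
    if (!any(keep)) .stopf("all taxa are identically zero")
    series <- series[keep, , drop = FALSE]
  }
  D <- nrow(series); Tn <- ncol(series)
  window <- .check_count(window, "window", min = 2L)
  horizon <- .check_count(horizon, "horizon", min = 1L)
  if (Tn < window + horizon + 2L)
    .stopf("series too short (T = %d) for window %d + horizon %d",
           Tn, window, horizon)
  seeds <- .fan_seed(seed, 3L)

  n_windows <- Tn - window - horizon + 1L
  split <- split_series(n_windows, train_fraction = train_fraction)
  # columns touched by training windows (inputs and targets) only
  train_cols <- seq_len(max(split$train) + window + horizon - 1L)

  standardizer <- fit_standardizer(series[, train_cols, drop = FALSE],
                                   taxon_ids = rownames(series))

  if (variant == "lstm") {
    net <- NULL
    ahat <- diag(D)
  } else if (is.null(network)) {
    net <- build_cooccurrence(series[, train_cols, drop = FALSE],
                              n_perm = n_perm, alpha = alpha,
                              seed = seeds[1])
    ahat <- net$normalized_adjacency
  } else if (inherits(network, "cooccurrence_network")) {
    net <- network
    ahat <- net$normalized_adjacency
  } else {
    net <- NULL
    ahat <- as.matrix(network)
    if (!all(dim(ahat) == D))
      .stopf("'network' adjacency must be %d x %d", D, D)
  }

  std_series <- apply_standardizer(series, standardizer)
  dataset <- make_windows(std_series, window = window, horizon = horizon)
  config <- model_config(n_taxa = D, window = window, horizon = horizon,
                         channels = channels, kernel = kernel,
                         n_blocks = n_blocks, lstm_layers = lstm_layers,
                         lstm_hidden = lstm_hidden, seed = seeds[2])
  fit <- train_variant(variant, dataset, split, ahat = ahat,
                       config = config, epochs = epochs, lr = lr,
                       batch_size = batch_size, seed = seeds[3],
                       verbose = verbose)
  structure(list(fit = fit, standardizer = standardizer, network = net,
                 dataset = dataset, split = split, series = series,
                 variant = variant, seed = seed, call = cl),
            class = "microstnet")
}

#' @export
print.microstnet <- function(x, ...) {
  cfg <- x$fit$model$config
  cat("Spatio-temporal microbial forecaster\n")
  cat(sprintf("  variant: %s   taxa: %d   window: %d   horizon: %d\n",
              x$variant, cfg$n_taxa, cfg$window, cfg$horizon))
  if (!is.null(x$network))
    cat(sprintf("  co-occurrence network: %d significant edges\n",
                x$network$n_edges))
  cat(sprintf("  best validation MAE %.5f (epoch %d of %d)\n",
              x$fit$best_val_mae, x$fit$best_epoch, nrow(x$fit$history)))
  invisible(x)
}

#' @export
summary.microstnet <- function(object, ...) {
  ev <- evaluate_model(object$fit, object$dataset, idx = object$split$eval,
                       standardizer = object$standardizer)
  out <- list(variant = object$variant,
              n_taxa = object$fit$model$config$n_taxa,
              n_train = length(object$split$train),
              n_eval = length(object$split$eval),
              n_parameters = n_params(object$fit$model),
              n_edges = if (!is.null(object$network))
                object$network$n_edges else NA_integer_,
              best_epoch = object$fit$best_epoch,
              evaluation = ev)
  class(out) <- "summary.microstnet"
  out
}

#' @export
print.summary.microstnet <- function(x, ...) {
  cat(sprintf("variant %s: %d taxa, %d training / %d validation windows, %d parameters\n",
              x$variant, x$n_taxa, x$n_train, x$n_eval, x$n_parameters))
  if (!is.na(x$n_edges)) cat(sprintf("network edges: %d\n", x$n_edges))
  cat(sprintf("validation MAE %.5f (standardized), %.5f (original scale)\n",
              x$evaluation$mae, x$evaluation$mae_original))
  cat(sprintf("validation sMAPE %.2f%% (standardized)\n", x$evaluation$smape))
  invisible(x)
}

#' Forecast future abundances from a fitted model
#'
#' Recursive forecast from the last observed window (or a supplied one),
#' returned on both the standardized and the original scale.
#'
#' @param object a [microstnet()] fit.
#' @param newdata optional taxa x window matrix of recent observations on
#'   the original scale; defaults to the final window of the fitted
#'   series.
#' @param h steps ahead (default 1).
#' @param ... unused.
#' @return a \code{forecast_result}.
#' @export
predict.microstnet <- function(object, newdata = NULL, h = 1, ...) {
  W <- object$fit$model$config$window
  if (is.null(newdata)) {
    Tn <- ncol(object$series)
    newdata <- object$series[, (Tn - W + 1L):Tn, drop = FALSE]
    origin <- Tn
  } else origin <- NA
  predict_multi_step(object$fit, newdata, h = h,
                     standardizer = object$standardizer, origin = origin)
}

#' @export
coef.microstnet <- function(object, ...) object$fit$model$params

#' One-step validation residuals on the original abundance scale
#'
#' @param object a [microstnet()] fit.
#' @param ... unused.
#' @return matrix windows x taxa of (observed - predicted) first-horizon
#'   residuals.
#' @export
residuals.microstnet <- function(object, ...) {
  ev <- .subset_tensor(object$dataset, object$split$eval)
  pred <- .predict_batch(object$fit$model, ev, object$fit$ahat)
  res_std <- ev$targets[, , 1L] - pred[, , 1L]
  sweep(res_std, 2L, object$standardizer$sds, `*`)
}

#' @export
fitted.microstnet <- function(object, ...) {
  ev <- .subset_tensor(object$dataset, object$split$eval)
  pred <- .predict_batch(object$fit$model, ev, object$fit$ahat)
  std <- pred[, , 1L]
  sweep(sweep(std, 2L, object$standardizer$sds, `*`), 2L,
        object$standardizer$means, `+`)
}

#' Plot the training history
#'
#' Training loss and validation MAE per epoch, with the selected best
#' epoch marked.
#'
#' @param x a [microstnet()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.microstnet <- function(x, ...) {
  h <- x$fit$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_mae), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MAE (standardized)", ...)
  graphics::abline(v = x$fit$best_epoch, lty = 3)
  graphics::legend("topright", c("training loss", "validation MAE"),
                   lty = 1, col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
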