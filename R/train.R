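# Training (Adam on mean-absolute-error loss, best-validation-MAE
# checkpointing), forecast metrics, evaluation and the three-way ablation.

#' Mean absolute error
#'
#' @param y,yhat equal-length numeric vectors (or arrays), m >= 1.
#' @return non-negative number \eqn{\frac{1}{m}\sum |y_i - \hat y_i|}.
#' @examples mae(c(1, 2), c(2, 4))  # 1.5
#' @export
mae <- function(y, yhat) {
  if (length(y) == 0L) .stopf("empty input")
  if (length(y) != length(yhat)) .stopf("'y' and 'yhat' lengths differ")
  mean(abs(y - yhat))
}

#' Symmetric mean absolute percentage error
#'
#' \eqn{\frac{100}{m}\sum \frac{|y_i - \hat y_i|}{(|y_i| + |\hat y_i|)/2}},
#' bounded term-wise by 200. A term with \eqn{y_i = \hat y_i = 0}
#' contributes 0 (the 0/0 case is read as a perfect prediction).
#'
#' @param y,yhat equal-length numeric vectors.
#' @return percentage in [0, 200].
#' @export
smape <- function(y, yhat) {
  if (length(y) == 0L) .stopf("empty input")
  if (length(y) != length(yhat)) .stopf("'y' and 'yhat' lengths differ")
  num <- abs(y - yhat)
  den <- (abs(y) + abs(yhat)) / 2
  terms <- ifelse(den == 0, 0, num / den)
  mean(terms) * 100
}

# --- Adam over the nested parameter list ----------------------------------

.zeros_like <- function(g) {
  if (is.list(g)) lapply(g, .zeros_like)
  else if (is.numeric(g)) g * 0
  else g
}

# walk grads (which mirror the numeric part of params) and update in place
.adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  if (is.list(g)) {
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      r <- .adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    if (is.null(names(g))) {
      for (i in seq_along(g)) {
        r <- .adam_update(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
    }
    return(list(p = p, m = m, v = v))
  }
  if (!is.numeric(g)) return(list(p = p, m = m, v = v))
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

.subset_tensor <- function(dataset, idx) {
  list(windows = dataset$windows[idx, , , drop = FALSE],
       changes = dataset$changes[idx, , , drop = FALSE],
       targets = dataset$targets[idx, , , drop = FALSE])
}

.predict_batch <- function(model, part, ahat) {
  .model_forward(model, part$windows, part$changes, ahat,
                 keep_cache = FALSE)$pred
}

#' Train a model variant
#'
#' Minimises mean-absolute-error loss (the selection metric of the
#' protocol; a squared loss would mismatch model selection) with Adam,
#' evaluates validation MAE on the standardized scale after every epoch,
#' and returns the weights of the best epoch, not the last.
#'
#' @param variant "microstnet", "stgcn2s" or "lstm".
#' @param dataset a [make_windows()] \code{series_tensor} on the
#'   standardized scale.
#' @param split list with \code{train} and \code{eval} window indices,
#'   e.g. from [split_series()].
#' @param ahat normalized adjacency matrix for the graph blocks.
#' @param config a [model_config()]; built from the data dimensions when
#'   NULL.
#' @param epochs training epochs (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param seed seed for weight init and batch shuffling.
#' @param verbose print per-epoch progress.
#' @return object of class \code{trained_model}: list with \code{model}
#'   (best weights), \code{history} (data frame epoch / train_loss /
#'   val_mae), \code{best_epoch}, \code{best_val_mae}, \code{ahat},
#'   \code{seed}.
#' @export
train_variant <- function(variant, dataset, split, ahat = NULL,
                          config = NULL, epochs = 50, lr = 1e-3,
                          batch_size = 32, seed = 1, verbose = FALSE) {
  variant <- match.arg(variant, .VARIANTS)
  stopifnot(inherits(dataset, "series_tensor"))
  epochs <- .check_count(epochs, "epochs", min = 1L)
  batch_size <- .check_count(batch_size, "batch_size", min = 1L)
  .check_scalar_number(lr, "lr", min = 1e-12)
  if (!length(split$train) || !length(split$eval))
    .stopf("empty train or eval split")
  D <- dim(dataset$windows)[2]; W <- dim(dataset$windows)[3]
  H <- dim(dataset$targets)[3]
  if (is.null(config))
    config <- model_config(n_taxa = D, window = W, horizon = H, seed = seed)
  config$seed <- as.integer(seed)  # the training seed governs init too
  if (is.null(ahat)) ahat <- diag(D)
  tr <- .subset_tensor(dataset, split$train)
  ev <- .subset_tensor(dataset, split$eval)
  n_tr <- length(split$train)

  model <- build_variant(variant, config)
  mstate <- NULL; vstate <- NULL; step <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mae = numeric(0))
  best <- list(val = Inf, epoch = NA_integer_, params = model$params)

  .with_seed(seed, for (ep in seq_len(epochs)) {
    ord <- sample.int(n_tr)
    losses <- numeric(0)
    for (start in seq(1L, n_tr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_tr)]
      bt <- .subset_tensor(tr, idx)
      fw <- .model_forward(model, bt$windows, bt$changes, ahat,
                           keep_cache = TRUE)
      resid <- fw$pred - bt$targets
      loss <- mean(abs(resid))
      if (!is.finite(loss))
        .stopf("NaN/Inf loss at epoch %d (lr too high or bad inputs?)", ep)
      losses <- c(losses, loss)
      dpred <- sign(resid) / length(resid)
      grads <- .model_backward(model, dpred, ahat, fw$cache)
      if (is.null(mstate)) {
        mstate <- .zeros_like(grads); vstate <- .zeros_like(grads)
      }
      step <- step + 1L
      upd <- .adam_update(model$params, grads, mstate, vstate, lr, step)
      model$params <- upd$p; mstate <- upd$m; vstate <- upd$v
    }
    val_pred <- .predict_batch(model, ev, ahat)
    val_mae <- mae(ev$targets, val_pred)
    history[ep, ] <- list(ep, mean(losses), val_mae)
    if (val_mae < best$val)
      best <- list(val = val_mae, epoch = ep, params = model$params)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val MAE %.5f", ep,
                      mean(losses), val_mae))
  })

  model$params <- best$params
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, best_val_mae = best$val,
                 ahat = ahat, seed = as.integer(seed)),
            class = "trained_model")
}

#' Evaluate a trained model on a windowed dataset
#'
#' Computes MAE and sMAPE per horizon step and pooled, on the standardized
#' scale; when a standardizer is supplied, also on the original abundance
#' scale.
#'
#' @param fit a [train_variant()] \code{trained_model} (or an
#'   \code{stnet_model} plus \code{ahat}).
#' @param dataset a standardized \code{series_tensor}.
#' @param idx window indices to evaluate (default: all).
#' @param standardizer optional [fit_standardizer()] for original-scale
#'   metrics.
#' @return list with \code{mae}, \code{smape} (pooled), \code{per_horizon}
#'   data frame, and (if a standardizer is given) \code{mae_original},
#'   \code{smape_original}.
#' @export
evaluate_model <- function(fit, dataset, idx = NULL, standardizer = NULL) {
  stopifnot(inherits(fit, "trained_model"))
  part <- if (is.null(idx)) dataset else .subset_tensor(dataset, idx)
  pred <- .predict_batch(fit$model, part, fit$ahat)
  y <- part$targets
  H <- dim(y)[3]
  per_h <- data.frame(
    horizon = seq_len(H),
    mae = vapply(seq_len(H), function(h) mae(y[, , h], pred[, , h]),
                 numeric(1)),
    smape = vapply(seq_len(H), function(h) smape(y[, , h], pred[, , h]),
                   numeric(1)))
  out <- list(mae = mae(y, pred), smape = smape(y, pred),
              per_horizon = per_h, n_windows = dim(y)[1])
  if (!is.null(standardizer)) {
    D <- dim(y)[2]
    to_orig <- function(a) {
      m <- matrix(aperm(a, c(2, 1, 3)), D)   # taxa rows
      m <- inverse_transform(m, standardizer)
      aperm(array(m, c(D, dim(a)[1], H)), c(2, 1, 3))
    }
    yo <- to_orig(y); po <- to_orig(pred)
    out$mae_original <- mae(yo, po)
    out$smape_original <- smape(yo, po)
  }
  out
}

#' Three-model ablation
#'
#' Trains the full model, the two-stream graph model without the recurrent
#' branch, and the recurrent-only model on identical train/validation
#' windows for each seed, and reports the best validation MAE per run plus
#' per-variant mean and sd.
#'
#' @param dataset a standardized \code{series_tensor}.
#' @param split shared train/eval indices.
#' @param ahat normalized adjacency.
#' @param seeds integer vector of training seeds (>= 1 seed).
#' @param config shared [model_config()] (optional).
#' @param epochs,lr,batch_size training settings passed to
#'   [train_variant()].
#' @param dataset_name label used in the output table.
#' @return object of class \code{ablation_result}: list with \code{runs}
#'   (data frame dataset / algorithm / seed / mae / best_epoch) and
#'   \code{summary} (data frame dataset / algorithm / mean_mae / sd_mae).
#' @export
ablation_run <- function(dataset, split, ahat = NULL, seeds = 1:3,
                         config = NULL, epochs = 50, lr = 1e-3,
                         batch_size = 32, dataset_name = "synthetic") {
  if (!length(seeds)) .stopf("need at least one seed")
  runs <- list()
  for (sd_i in seeds) {
    for (variant in .VARIANTS) {
      fit <- train_variant(variant, dataset, split, ahat = ahat,
                           config = config, epochs = epochs, lr = lr,
                           batch_size = batch_size, seed = sd_i)
      runs[[length(runs) + 1L]] <- data.frame(
        dataset = dataset_name, algorithm = variant, seed = sd_i,
        mae = fit$best_val_mae, best_epoch = fit$best_epoch,
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$algorithm), function(d)
    data.frame(dataset = d$dataset[1], algorithm = d$algorithm[1],
               mean_mae = mean(d$mae),
               sd_mae = if (nrow(d) > 1) stats::sd(d$mae) else NA_real_,
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$mean_mae), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg), class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("ablation over", length(unique(x$runs$seed)), "seed(s):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
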