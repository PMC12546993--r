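# Plain-text model checkpoints. Doubles are stored as %.17g strings so a
# save -> load round trip is bit-exact.

.CHECKPOINT_FORMAT <- "microstnet-checkpoint-1"

.encode_tree <- function(x) {
  if (is.list(x)) return(lapply(x, .encode_tree))
  if (is.numeric(x))
    return(list(`.num` = list(dim = if (is.null(dim(x))) length(x)
                              else dim(x),
                              data = sprintf("%.17g", as.vector(x)))))
  x
}

.decode_tree <- function(x) {
  if (is.list(x) && identical(names(x), ".num")) {
    v <- as.numeric(x$`.num`$data)
    d <- unlist(x$`.num`$dim)
    if (length(d) > 1L) dim(v) <- d
    return(v)
  }
  if (is.list(x)) return(lapply(x, .decode_tree))
  if (is.character(x) && length(x) == 1L) return(x)
  x
}

#' Save a trained model to a plain-text checkpoint
#'
#' Single JSON file holding a format tag, the configuration, the variant,
#' all weights (full precision), the standardizer, the normalized
#' adjacency used at training time, and the training history.
#'
#' @param fit a [train_variant()] \code{trained_model}.
#' @param path output path (.json).
#' @param standardizer the training [fit_standardizer()].
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(fit, path, standardizer = NULL) {
  stopifnot(inherits(fit, "trained_model"))
  cfg <- fit$model$config
  obj <- list(
    format = .CHECKPOINT_FORMAT,
    variant = fit$model$variant,
    config = unclass(cfg),
    params = .encode_tree(fit$model$params),
    ahat = .encode_tree(fit$ahat),
    taxon_ids = if (!is.null(standardizer)) standardizer$taxon_ids,
    standardizer = if (!is.null(standardizer))
      list(means = sprintf("%.17g", standardizer$means),
           sds = sprintf("%.17g", standardizer$sds)),
    history = list(epoch = fit$history$epoch,
                   train_loss = sprintf("%.17g", fit$history$train_loss),
                   val_mae = sprintf("%.17g", fit$history$val_mae)),
    best_epoch = fit$best_epoch,
    best_val_mae = sprintf("%.17g", fit$best_val_mae),
    seed = fit$seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint path.
#' @return list with \code{fit} (a \code{trained_model}) and
#'   \code{standardizer} (or NULL).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) .stopf("checkpoint not found: %s", path)
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, .CHECKPOINT_FORMAT))
    .stopf("unrecognized checkpoint format: %s", obj$format %||% "<none>")
  cfg <- obj$config
  config <- model_config(n_taxa = cfg$n_taxa, window = cfg$window,
                         horizon = cfg$horizon, channels = cfg$channels,
                         kernel = cfg$kernel, n_blocks = cfg$n_blocks,
                         lstm_layers = cfg$lstm_layers,
                         lstm_hidden = cfg$lstm_hidden,
                         lstm_on_change = isTRUE(cfg$lstm_on_change),
                         seed = cfg$seed)
  model <- structure(list(variant = obj$variant, config = config,
                          params = .decode_tree(obj$params)),
                     class = "stnet_model")
  ahat <- .decode_tree(obj$ahat)
  history <- data.frame(epoch = unlist(obj$history$epoch),
                        train_loss = as.numeric(unlist(obj$history$train_loss)),
                        val_mae = as.numeric(unlist(obj$history$val_mae)))
  fit <- structure(list(model = model, history = history,
                        best_epoch = obj$best_epoch,
                        best_val_mae = as.numeric(obj$best_val_mae),
                        ahat = ahat, seed = obj$seed),
                   class = "trained_model")
  standardizer <- NULL
  if (!is.null(obj$standardizer)) {
    standardizer <- structure(
      list(means = as.numeric(unlist(obj$standardizer$means)),
           sds = as.numeric(unlist(obj$standardizer$sds)),
           taxon_ids = unlist(obj$taxon_ids)),
      class = "standardizer")
  }
  list(fit = fit, standardizer = standardizer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
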