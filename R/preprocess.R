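# Standardization, change stream, windowing, chronological splitting.

#' Fit per-taxon Z-score parameters
#'
#' Computes the per-taxon mean and population standard deviation (divisor
#' \eqn{n}) on training data only. A zero standard deviation (constant taxon)
#' is substituted by 1 so that standardizing maps the taxon to all zeros
#' instead of NaN.
#'
#' @param train_values numeric matrix, taxa x samples (>= 2 samples).
#' @param taxon_ids optional taxon identifiers; defaults to row names.
#' @return an object of class \code{standardizer}: list with \code{means},
#'   \code{sds}, \code{taxon_ids}.
#' @examples
#' fit_standardizer(matrix(c(1, 2, 3), 1, 3))  # mean 2, sd sqrt(2/3)
#' @export
fit_standardizer <- function(train_values, taxon_ids = rownames(train_values)) {
  if (!is.matrix(train_values) || !is.numeric(train_values))
    .stopf("'train_values' must be a numeric matrix (taxa x samples)")
  n <- ncol(train_values)
  if (n < 2L) .stopf("need at least 2 samples to fit a standardizer")
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(nrow(train_values)))
  mu <- rowMeans(train_values)
  sds <- sqrt(rowMeans((train_values - mu)^2))  # population sd, divisor n
  sds[sds == 0] <- 1
  structure(list(means = unname(mu), sds = unname(sds),
                 taxon_ids = taxon_ids),
            class = "standardizer")
}

.check_standardizer <- function(values, params) {
  stopifnot(inherits(params, "standardizer"))
  if (nrow(values) != length(params$means))
    .stopf("taxon count mismatch: %d rows vs %d standardizer entries",
           nrow(values), length(params$means))
  if (!is.null(rownames(values)) &&
      !identical(unname(rownames(values)), unname(params$taxon_ids)))
    .stopf("taxon order does not match the standardizer")
}

#' Standardize abundances with fitted parameters
#'
#' @param values numeric matrix, taxa x samples, taxon order matching
#'   \code{params}.
#' @param params a [fit_standardizer()] object.
#' @return matrix of \eqn{(x - \mu_i)/\sigma_i}.
#' @export
apply_standardizer <- function(values, params) {
  .check_standardizer(values, params)
  (values - params$means) / params$sds
}

#' Map standardized values back to the original abundance scale
#'
#' Inverse of [apply_standardizer()]: \eqn{x \sigma_i + \mu_i} per taxon row.
#'
#' @param values standardized matrix, taxa x anything.
#' @param params a [fit_standardizer()] object.
#' @return matrix on the original scale.
#' @export
inverse_transform <- function(values, params) {
  .check_standardizer(values, params)
  values * params$sds + params$means
}

#' First-difference change stream of a multivariate series
#'
#' \eqn{\Delta_{t} = x_t - x_{t-1}} for \eqn{t \ge 2}, with the first column
#' zero-padded so the change stream has the same shape as the abundance
#' stream.
#'
#' @param series numeric matrix, taxa x time (>= 2 time steps).
#' @return matrix of the same shape.
#' @export
make_change_stream <- function(series) {
  if (!is.matrix(series)) series <- as.matrix(series)
  Tn <- ncol(series)
  if (Tn < 2L) .stopf("change stream needs at least 2 time steps")
  cbind(matrix(0, nrow(series), 1),
        series[, -1, drop = FALSE] - series[, -Tn, drop = FALSE])
}

#' Slice a series into sliding input windows and forecast targets
#'
#' Window \eqn{n} (stride 1) covers time columns \eqn{[n, n+W)}; its target
#' covers \eqn{[n+W, n+W+H)}, so no target index ever appears in its own
#' input. The change stream is rebuilt inside each window (zero first
#' column), matching what is available at prediction time.
#'
#' @param series taxa x time matrix (any scale; standardize first for model
#'   input).
#' @param window input width W.
#' @param horizon target width H (default 1).
#' @return an object of class \code{series_tensor}: list with
#'   \code{windows} (N x D x W), \code{changes} (N x D x W),
#'   \code{targets} (N x D x H), \code{origins} (first time index of each
#'   window), and \code{scale} (copied from the \code{scale} argument).
#' @param scale label recorded on the result ("standardized" or "original").
#' @export
make_windows <- function(series, window, horizon = 1, scale = "standardized") {
  if (!is.matrix(series)) series <- as.matrix(series)
  window <- .check_count(window, "window", min = 2L)
  horizon <- .check_count(horizon, "horizon", min = 1L)
  D <- nrow(series); Tn <- ncol(series)
  if (Tn < window + horizon)
    .stopf("series too short: T = %d < window + horizon = %d", Tn,
           window + horizon)
  if (any(!is.finite(series))) .stopf("series contains non-finite values")
  N <- Tn - window - horizon + 1L
  windows <- array(0, c(N, D, window))
  changes <- array(0, c(N, D, window))
  targets <- array(0, c(N, D, horizon))
  for (n in seq_len(N)) {
    w <- series[, n:(n + window - 1L), drop = FALSE]
    windows[n, , ] <- w
    changes[n, , ] <- make_change_stream(w)
    targets[n, , ] <- series[, (n + window):(n + window + horizon - 1L)]
  }
  structure(list(windows = windows, changes = changes, targets = targets,
                 origins = seq_len(N), taxon_ids = rownames(series),
                 scale = scale),
            class = "series_tensor")
}

#' Split window indices into training and evaluation sets
#'
#' Chronological mode (the default) assigns the first
#' \code{floor(train_fraction * n_items)} items to training and the rest to
#' evaluation, preserving temporal order; random mode shuffles with the
#' seed. Both the 80/20 and the 7:3 conventions are supported through
#' \code{train_fraction}.
#'
#' @param n_items number of items (windows) to split.
#' @param train_fraction fraction in (0, 1), default 0.8.
#' @param mode "chronological" (default) or "random".
#' @param seed RNG seed for random mode.
#' @return list with integer vectors \code{train} and \code{eval}.
#' @export
split_series <- function(n_items, train_fraction = 0.8,
                         mode = c("chronological", "random"), seed = NULL) {
  n_items <- .check_count(n_items, "n_items", min = 2L)
  .check_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1)
    .stopf("'train_fraction' must be strictly inside (0, 1)")
  mode <- match.arg(mode)
  n_train <- floor(train_fraction * n_items)
  n_train <- max(1L, min(n_items - 1L, n_train))
  if (mode == "chronological") {
    list(train = seq_len(n_train), eval = (n_train + 1L):n_items)
  } else {
    perm <- .with_seed(seed, sample.int(n_items))
    list(train = sort(perm[seq_len(n_train)]),
         eval = sort(perm[(n_train + 1L):n_items]))
  }
}
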