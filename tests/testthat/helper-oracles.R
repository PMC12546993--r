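# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths.

# textbook Benjamini-Hochberg step-up, coded directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# tie-free Spearman shortcut: 1 - 6 sum(d^2) / (n (n^2 - 1))
spearman_shortcut <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force two-sided permutation p-value over all n! permutations
perm_pvalue_oracle <- function(x, y) {
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rho <- function(a, b) stats::cor(rank(a), rank(b))
  obs <- abs(rho(x, y))
  hits <- vapply(all_perms(seq_along(y)),
                 function(p) abs(rho(x, y[p])) >= obs - 1e-12, logical(1))
  mean(hits)
}

# brute-force causal convolution: conv[t] = sum_cin sum_j W[c,cin,j] x[t-j+1]
conv_oracle <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[3]; c2 <- dim(W)[1]
  out <- array(0, c(d[1], c2, d[3], d[4]))
  for (bb in seq_len(d[1])) for (cc in seq_len(c2))
    for (nn in seq_len(d[3])) for (tt in seq_len(d[4])) {
      acc <- b[cc]
      for (ci in seq_len(d[2])) for (j in seq_len(k)) {
        src <- tt - j + 1L
        if (src >= 1L) acc <- acc + W[cc, ci, j] * x[bb, ci, nn, src]
      }
      out[bb, cc, nn, tt] <- acc
    }
  out
}

# brute-force graph contraction: lfs[b,c,i,t] = sum_j Ahat[i,j] x[b,c,j,t]
contract_oracle <- function(x, ahat) {
  d <- dim(x)
  out <- array(0, d)
  for (bb in seq_len(d[1])) for (cc in seq_len(d[2]))
    for (ii in seq_len(d[3])) for (tt in seq_len(d[4]))
      out[bb, cc, ii, tt] <- sum(ahat[ii, ] * x[bb, cc, , tt])
  out
}

# small abundance table with taxonomy
toy_table <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 0, 4,
                1, 1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("otu1", "otu2", "otu3"),
                              paste0("s", 1:4)))
  abundance_table(m, taxonomy = c(
    "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Streptococcaceae;g__Streptococcus",
    "k__Bacteria;p__Actinobacteria;c__Actinomycetia;o__Micrococcales;f__Micrococcaceae;g__Rothia",
    "k__Bacteria;p__Actinobacteria;c__Actinomycetia;o__Micrococcales;f__Micrococcaceae;g__Rothia"))
}

# shared tiny training problem: deterministic, quickly learnable
tiny_zero_noise_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- simulator_spec(n_taxa = 6, n_steps = 160, noise_sd = 0, seed = 3)
    series <- simulate_series(spec)
    std <- fit_standardizer(series)
    ds <- make_windows(apply_standardizer(series, std), window = 8,
                       horizon = 1)
    sp <- split_series(dim(ds$windows)[1], 0.8)
    cfg <- model_config(6, 8, channels = 8, n_blocks = 1)
    fit <- train_variant("microstnet", ds, sp,
                         ahat = normalize_adjacency(spec$graph),
                         config = cfg, epochs = 40, lr = 3e-4,
                         batch_size = 128, seed = 1)
    cache <<- list(spec = spec, series = series, std = std, ds = ds,
                   sp = sp, fit = fit)
    cache
  }
})
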