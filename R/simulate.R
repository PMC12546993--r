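# Graph-coupled VAR(1) simulator: ground-truth interaction graph, linear
# first-order dynamics with Gaussian noise, closed-form optimal one-step
# MAE, and an optional multinomial count-table layer mimicking 16S OTU
# tables.

#' Random sparse signed interaction graph
#'
#' Each unordered pair becomes an edge with probability \code{density};
#' edge weights are drawn uniformly from \eqn{[-1, -0.3] \cup [0.3, 1]}
#' (never near zero, so edges matter) and mirrored. Zero diagonal.
#'
#' @param D number of taxa.
#' @param density edge probability in [0, 1].
#' @param seed RNG seed.
#' @return D x D symmetric signed matrix with zero diagonal.
#' @export
generate_graph <- function(D, density, seed = NULL) {
  D <- .check_count(D, "D", min = 1L)
  .check_scalar_number(density, "density", min = 0, max = 1)
  A <- matrix(0, D, D)
  if (D > 1L) {
    up <- which(upper.tri(A))
    .with_seed(seed, {
      present <- stats::runif(length(up)) < density
      mag <- stats::runif(length(up), 0.3, 1)
      sgn <- sample(c(-1, 1), length(up), replace = TRUE)
      A[up] <- ifelse(present, sgn * mag, 0)
    })
    A <- A + t(A)
  }
  A
}

#' Specify a graph-coupled VAR(1) simulator
#'
#' Dynamics: \eqn{x_t = c + \Phi x_{t-1} + \epsilon_t} with transition
#' matrix \eqn{\Phi = \rho_{self} I + \gamma A} and i.i.d. Gaussian noise
#' of standard deviation \code{noise_sd} per taxon. The intercept \eqn{c}
#' is chosen as \eqn{(I - \Phi)\mu} so the stationary mean equals
#' \code{baseline}. Stationarity (spectral radius of \eqn{\Phi} below 1)
#' is required; reduce \code{gamma} or \code{rho_self} otherwise.
#'
#' Defaults emulate a daily genus-level series: 20 taxa, 300 days, moderate
#' day-to-day persistence (0.6), sparse signed couplings and noise of 0.3
#' abundance units.
#'
#' @param n_taxa number of taxa D.
#' @param n_steps number of retained time steps T.
#' @param graph optional D x D symmetric signed interaction matrix;
#'   generated by [generate_graph()] when NULL.
#' @param density edge density used when generating the graph.
#' @param rho_self diagonal self-persistence.
#' @param gamma coupling scale applied to the graph.
#' @param noise_sd Gaussian innovation standard deviation (>= 0).
#' @param baseline stationary mean, recycled to length D.
#' @param seed RNG seed controlling the graph and the noise.
#' @param count_depth optional sequencing depth for
#'   [emulate_count_table()].
#' @return object of class \code{simulator_spec}.
#' @export
simulator_spec <- function(n_taxa = 20, n_steps = 300, graph = NULL,
                           density = 0.15, rho_self = 0.6, gamma = 0.12,
                           noise_sd = 0.3, baseline = 10, seed = 1,
                           count_depth = NULL) {
  n_taxa <- .check_count(n_taxa, "n_taxa", min = 2L)
  n_steps <- .check_count(n_steps, "n_steps", min = 3L)
  .check_scalar_number(noise_sd, "noise_sd", min = 0)
  seeds <- .fan_seed(seed, 2L)
  if (is.null(graph)) graph <- generate_graph(n_taxa, density, seed = seeds[1])
  if (!is.matrix(graph) || nrow(graph) != n_taxa || ncol(graph) != n_taxa)
    .stopf("'graph' must be a %d x %d matrix", n_taxa, n_taxa)
  phi <- diag(rho_self, n_taxa) + gamma * graph
  radius <- max(Mod(eigen(phi, only.values = TRUE)$values))
  if (radius >= 1)
    .stopf("unstable dynamics: spectral radius %.3f >= 1; lower gamma or rho_self",
           radius)
  baseline <- rep_len(baseline, n_taxa)
  structure(list(n_taxa = n_taxa, n_steps = n_steps, graph = graph,
                 rho_self = rho_self, gamma = gamma, phi = phi,
                 noise_sd = noise_sd, baseline = baseline,
                 intercept = as.vector((diag(n_taxa) - phi) %*% baseline),
                 spectral_radius = radius, seed = seed,
                 noise_seed = seeds[2], count_depth = count_depth),
            class = "simulator_spec")
}

#' Simulate a graph-coupled abundance series
#'
#' Runs the VAR(1) recursion from the stationary mean, discards a 100-step
#' burn-in, and returns the taxa x time matrix together with the
#' ground-truth transition matrix.
#'
#' @param spec a [simulator_spec()].
#' @return matrix D x T with attributes \code{phi} (transition matrix) and
#'   \code{spec}; rows named \code{taxon_1..D}, columns \code{t1..tT}.
#' @export
simulate_series <- function(spec) {
  stopifnot(inherits(spec, "simulator_spec"))
  D <- spec$n_taxa; Tn <- spec$n_steps; burn <- 100L
  total <- Tn + burn
  eps <- .with_seed(spec$noise_seed, {
    if (spec$noise_sd > 0)
      matrix(stats::rnorm(D * total, sd = spec$noise_sd), D, total)
    else matrix(0, D, total)
  })
  x <- matrix(0, D, total)
  prev <- spec$baseline
  for (t in seq_len(total)) {
    prev <- spec$intercept + spec$phi %*% prev + eps[, t]
    x[, t] <- prev
  }
  out <- x[, (burn + 1L):total, drop = FALSE]
  dimnames(out) <- list(paste0("taxon_", seq_len(D)), paste0("t", seq_len(Tn)))
  attr(out, "phi") <- spec$phi
  attr(out, "spec") <- spec
  out
}

#' MAE of the best possible one-step forecast
#'
#' The conditional mean is the optimal predictor; its residual is the
#' Gaussian innovation, whose expected absolute value is
#' \eqn{\sigma \sqrt{2/\pi}}. Used as the yardstick for trained models.
#'
#' @param spec a [simulator_spec()].
#' @return non-negative number.
#' @export
optimal_one_step_mae <- function(spec) {
  stopifnot(inherits(spec, "simulator_spec"))
  spec$noise_sd * sqrt(2 / pi)
}

#' Sample a synthetic 16S-style count table from a simulated series
#'
#' Each time point's abundances are softmax-normalized into proportions and
#' a multinomial of size \code{count_depth} is drawn, producing an integer
#' OTU-like table. Synthetic taxonomy strings spanning four phyla
#' (\code{p__P1..P4}) are attached so phylum-level summaries are testable.
#'
#' @param series taxa x time numeric matrix (e.g. [simulate_series()]).
#' @param count_depth reads per sample (>= 1).
#' @param seed RNG seed.
#' @param temperature softmax scale; larger values flatten proportions.
#' @return an [abundance_table()] of integer counts with taxonomy.
#' @export
emulate_count_table <- function(series, count_depth, seed = NULL,
                                temperature = 2) {
  if (!is.matrix(series)) series <- as.matrix(series)
  count_depth <- .check_count(count_depth, "count_depth", min = 1L)
  .check_scalar_number(temperature, "temperature", min = 1e-8)
  D <- nrow(series); Tn <- ncol(series)
  counts <- .with_seed(seed, {
    sapply(seq_len(Tn), function(t) {
      z <- series[, t] / temperature
      z <- z - max(z)
      p <- exp(z) / sum(exp(z))
      stats::rmultinom(1, count_depth, p)[, 1]
    })
  })
  rownames(counts) <- if (!is.null(rownames(series))) rownames(series)
                      else paste0("taxon_", seq_len(D))
  colnames(counts) <- if (!is.null(colnames(series))) colnames(series)
                      else paste0("t", seq_len(Tn))
  phyla <- paste0("P", ((seq_len(D) - 1L) %% 4L) + 1L)
  taxonomy <- sprintf(
    "k__Bacteria;p__%s;c__C%s;o__O%s;f__F%d;g__G%d",
    phyla, phyla, phyla, seq_len(D), seq_len(D))
  abundance_table(counts, taxonomy = taxonomy)
}

#' Phylum labels of a synthetic count table
#'
#' @param table an [abundance_table()] with taxonomy.
#' @return character vector of phylum labels (the \code{p__} field).
#' @export
phylum_labels <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$taxonomy)) .stopf("table has no taxonomy")
  vapply(.split_taxonomy(table$taxonomy), function(p) {
    hit <- grep("^p__", p, value = TRUE)
    if (length(hit) && nchar(hit[1]) > 3L) sub("^p__", "", hit[1])
    else NA_character_
  }, character(1))
}
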