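# Taxon-taxon co-occurrence networks: Spearman rho, permutation p-values,
# Benjamini-Hochberg correction, significance thresholding, and the
# symmetrically normalized adjacency used by the spatial graph blocks.

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive their average rank). If
#' either vector is constant the correlation is undefined; 0 is returned
#' with attribute \code{degenerate = TRUE}.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return correlation in [-1, 1]; attribute \code{degenerate} flags
#'   constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) .stopf("'x' and 'y' must have equal length")
  if (length(x) < 3L) .stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  structure(stats::cor(x, y, method = "spearman"), degenerate = FALSE)
}

# all permutations of 1..n as an n! x n matrix (n <= 7)
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# centered, norm-1 mid-ranks; NULL if constant
.rank_scores <- function(x) {
  r <- rank(x)
  r <- r - mean(r)
  s <- sqrt(sum(r^2))
  if (s == 0) return(NULL)
  r / s
}

#' Permutation p-value for a Spearman correlation
#'
#' Two-sided test of independence: the fraction of permutations of \code{y}
#' whose |rho| reaches the observed |rho|. Monte Carlo mode (default) uses
#' the add-one estimator \eqn{(1 + k)/(1 + n_{perm})}, which can never
#' return 0; exhaustive mode enumerates all \eqn{n!} permutations (n <= 7)
#' and returns the exact proportion (the identity permutation counts, so
#' p >= 1/n!).
#'
#' @param x,y numeric vectors, length n >= 3.
#' @param n_perm number of Monte Carlo permutations (default 1000).
#' @param seed RNG seed (Monte Carlo mode).
#' @param mode "montecarlo" or "exhaustive".
#' @return p-value in (0, 1] with attributes \code{rho} and
#'   \code{degenerate}. Constant input gives p = 1, flagged.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000, seed = NULL,
                               mode = c("montecarlo", "exhaustive")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) .stopf("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 observations")
  rx <- .rank_scores(x); ry <- .rank_scores(y)
  if (is.null(rx) || is.null(ry))
    return(structure(1, rho = 0, degenerate = TRUE))
  rho_obs <- sum(rx * ry)
  if (mode == "exhaustive") {
    if (n > 7L) .stopf("exhaustive mode supports n <= 7 (got %d)", n)
    perms <- .all_permutations(n)
    rho_perm <- apply(perms, 1L, function(p) sum(rx * ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
  } else {
    n_perm <- .check_count(n_perm, "n_perm", min = 1L)
    k <- .with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        r <- sum(rx * ry[sample.int(n)])
        if (abs(r) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
      }
      hits
    })
    p <- (1 + k) / (1 + n_perm)
  }
  structure(p, rho = rho_obs, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control (via [stats::p.adjust()]): sort
#' ascending, scale \eqn{p_{(i)} m / i}, enforce monotonicity from the
#' largest rank down, cap at 1, return in the original order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)))
    .stopf("p-values must be finite numbers")
  if (any(pvals < 0 | pvals > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Threshold a correlation matrix into a signed co-occurrence network
#'
#' Keeps the signed Spearman weight wherever the adjusted p-value is at
#' most \code{alpha} (edges with adjusted p strictly greater than
#' \code{alpha} are removed, so p = alpha exactly is retained); the
#' diagonal is forced to zero. Also computes the normalized adjacency via
#' [normalize_adjacency()].
#'
#' @param rho D x D symmetric Spearman matrix (unit diagonal).
#' @param padj D x D symmetric adjusted p-value matrix.
#' @param alpha significance level (default 0.05).
#' @param taxon_ids optional taxon names; defaults to \code{rownames(rho)}.
#' @param pvals optional raw p-value matrix, carried through for export.
#' @return object of class \code{cooccurrence_network}: list with
#'   \code{taxon_ids}, \code{rho}, \code{pvals}, \code{padj},
#'   \code{adjacency}, \code{normalized_adjacency}, \code{n_edges},
#'   \code{empty} (flag: no surviving edge).
#' @export
build_network <- function(rho, padj, alpha = 0.05,
                          taxon_ids = rownames(rho), pvals = NULL) {
  if (!isTRUE(all.equal(rho, t(rho), tolerance = 1e-8)))
    .stopf("'rho' must be symmetric")
  if (!isTRUE(all.equal(padj, t(padj), tolerance = 1e-8)))
    .stopf("'padj' must be symmetric")
  if (!all(dim(rho) == dim(padj))) .stopf("'rho' and 'padj' shapes differ")
  .check_scalar_number(alpha, "alpha", min = 0, max = 1)
  D <- nrow(rho)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(D))
  adjacency <- ifelse(padj > alpha, 0, rho)
  diag(adjacency) <- 0
  dimnames(adjacency) <- list(taxon_ids, taxon_ids)
  n_edges <- sum(adjacency[upper.tri(adjacency)] != 0)
  if (n_edges == 0L)
    warning("co-occurrence network has no significant edges", call. = FALSE)
  structure(list(taxon_ids = taxon_ids, rho = rho, pvals = pvals,
                 padj = padj, adjacency = adjacency,
                 normalized_adjacency = normalize_adjacency(adjacency),
                 n_edges = n_edges, empty = n_edges == 0L),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d taxa, %d edges\n",
              length(x$taxon_ids), x$n_edges))
  invisible(x)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' \eqn{\hat A = D^{-1/2} (|A| + I) D^{-1/2}} where \eqn{|A|} is the
#' element-wise absolute value of the signed adjacency, \eqn{I} adds
#' self-loops and \eqn{D} is the diagonal degree matrix of \eqn{|A| + I}.
#' Absolute values are taken because the graph blocks need non-negative
#' aggregation weights while the exported network keeps edge signs.
#'
#' @param adjacency D x D symmetric matrix with zero diagonal.
#' @return symmetric non-negative matrix \eqn{\hat A}.
#' @export
normalize_adjacency <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    .stopf("'adjacency' must be a square matrix")
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-8)))
    .stopf("'adjacency' must be symmetric")
  a <- abs(adjacency)
  diag(a) <- diag(a) + 1
  dinv <- 1 / sqrt(rowSums(a))
  ahat <- a * tcrossprod(dinv)
  dimnames(ahat) <- dimnames(adjacency)
  ahat
}

#' Summarise a network by phylum
#'
#' Counts connected nodes, edges, nodes per phylum, and splits edges into
#' internal associations (both endpoints in the same phylum) and external
#' associations (endpoints in different phyla).
#'
#' @param net a [build_network()] object.
#' @param phylum_labels character vector of phylum labels, one per taxon in
#'   network order.
#' @return list with \code{n_nodes}, \code{n_edges},
#'   \code{nodes_per_phylum}, \code{internal_edges}, \code{external_edges}.
#' @export
network_summary <- function(net, phylum_labels) {
  stopifnot(inherits(net, "cooccurrence_network"))
  D <- length(net$taxon_ids)
  if (length(phylum_labels) != D || any(is.na(phylum_labels)))
    .stopf("'phylum_labels' must label every taxon")
  A <- net$adjacency
  deg <- rowSums(A != 0)
  up <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  internal <- sum(phylum_labels[up[, 1]] == phylum_labels[up[, 2]])
  connected <- deg > 0
  list(n_nodes = sum(connected),
       n_edges = nrow(up),
       nodes_per_phylum = if (any(connected))
         table(phylum_labels[connected]) else table(character(0)),
       internal_edges = internal,
       external_edges = nrow(up) - internal)
}

#' Build a co-occurrence network from an abundance table
#'
#' Composition of the network pipeline: pairwise Spearman rho over taxa,
#' two-sided permutation p-values (one shared set of seeded permutations,
#' reused across pairs), Benjamini-Hochberg correction applied to the
#' D(D-1)/2 unique pair p-values and mirrored, thresholding at
#' \code{alpha}, and symmetric normalization.
#'
#' @param table an [abundance_table()] or taxa x samples numeric matrix
#'   (>= 2 taxa, >= 3 samples).
#' @param n_perm Monte Carlo permutations (default 1000).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param mode "montecarlo" (default) or "exhaustive" (n <= 7 samples).
#' @return a \code{cooccurrence_network}; see [build_network()].
#' @export
build_cooccurrence <- function(table, n_perm = 1000, alpha = 0.05, seed = 1,
                               mode = c("montecarlo", "exhaustive")) {
  mode <- match.arg(mode)
  vals <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  D <- nrow(vals); n <- ncol(vals)
  if (D < 2L) .stopf("need at least 2 taxa")
  if (n < 3L) .stopf("need at least 3 samples")
  taxon_ids <- rownames(vals)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(D))

  scores <- lapply(seq_len(D), function(i) .rank_scores(vals[i, ]))
  degenerate <- vapply(scores, is.null, logical(1))
  R <- matrix(0, n, D)
  for (i in which(!degenerate)) R[, i] <- scores[[i]]

  rho <- crossprod(R)             # unit diagonal for non-degenerate rows
  diag(rho) <- 1
  pmat <- matrix(1, D, D); diag(pmat) <- 0

  if (mode == "exhaustive") {
    if (n > 7L) .stopf("exhaustive mode supports n <= 7 samples (got %d)", n)
    perms <- .all_permutations(n)
  } else {
    n_perm <- .check_count(n_perm, "n_perm", min = 1L)
    perms <- .with_seed(seed, {
      t(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)))
    })
  }
  # one shared permutation set for every pair keeps the run reproducible
  # and lets each pair's null correlations come from a single matrix product
  for (i in seq_len(D - 1L)) {
    if (degenerate[i]) next
    Ri_perm <- matrix(R[, i][t(perms)], nrow = n)   # n x n_perm
    for (j in (i + 1L):D) {
      if (degenerate[j]) next
      rho_null <- as.vector(crossprod(R[, j], Ri_perm))
      hits <- sum(abs(rho_null) >= abs(rho[i, j]) - 1e-12)
      p <- if (mode == "exhaustive") hits / nrow(perms)
           else (1 + hits) / (1 + nrow(perms))
      pmat[i, j] <- pmat[j, i] <- p
    }
  }

  up <- upper.tri(pmat)
  padj_vec <- bh_adjust(pmat[up])
  padj <- matrix(0, D, D)
  padj[up] <- padj_vec
  padj <- padj + t(padj)
  dimnames(rho) <- dimnames(pmat) <- dimnames(padj) <-
    list(taxon_ids, taxon_ids)
  build_network(rho, padj, alpha = alpha, taxon_ids = taxon_ids,
                pvals = pmat)
}

#' Export a network edge list as TSV
#'
#' One row per surviving edge: \code{taxon_a}, \code{taxon_b}, \code{rho},
#' \code{pval}, \code{padj}; suitable for Cytoscape/Gephi import.
#'
#' @param net a \code{cooccurrence_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_edge_list <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  up <- which(upper.tri(net$adjacency) & net$adjacency != 0, arr.ind = TRUE)
  df <- data.frame(
    taxon_a = net$taxon_ids[up[, 1]],
    taxon_b = net$taxon_ids[up[, 2]],
    rho = net$rho[up],
    pval = if (is.null(net$pvals)) NA_real_ else net$pvals[up],
    padj = net$padj[up],
    stringsAsFactors = FALSE)
  df <- df[order(df$taxon_a, df$taxon_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
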