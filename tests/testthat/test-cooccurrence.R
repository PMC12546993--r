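# Spearman correlation, permutation tests, BH correction, thresholding,
# adjacency normalization and network summaries.

test_that("spearman_rho matches the tie-free shortcut formula", {
  expect_equal(as.numeric(spearman_rho(1:3, c(10, 20, 30))), 1)
  expect_equal(as.numeric(spearman_rho(1:3, c(3, 2, 1))), -1)
  expect_equal(as.numeric(spearman_rho(1:4, c(3, 1, 4, 2))), 0)

  set.seed(2)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    x <- sample(1000, n); y <- sample(1000, n)   # tie-free
    expect_equal(as.numeric(spearman_rho(x, y)),
                 spearman_shortcut(x, y), tolerance = 1e-12)
  }

  flagged <- spearman_rho(c(2, 2, 2), c(1, 2, 3))
  expect_equal(as.numeric(flagged), 0)
  expect_true(attr(flagged, "degenerate"))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("exhaustive permutation p-values equal brute-force enumeration", {
  p3 <- permutation_pvalue(1:3, c(5, 7, 9), mode = "exhaustive")
  expect_equal(as.numeric(p3), 2 / 6)  # identity + reversal reach |rho| = 1

  set.seed(8)
  for (n in 4:6) {
    x <- sample(100, n); y <- sample(100, n)
    expect_equal(as.numeric(permutation_pvalue(x, y, mode = "exhaustive")),
                 perm_pvalue_oracle(x, y))
  }
})

test_that("Monte Carlo permutation p-values are seeded and add-one", {
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 7, 1, 8, 2.8, 1.8)
  p1 <- permutation_pvalue(x, y, n_perm = 200, seed = 42)
  p2 <- permutation_pvalue(x, y, n_perm = 200, seed = 42)
  expect_identical(p1, p2)
  expect_gt(as.numeric(p1), 0)
  expect_lte(as.numeric(p1), 1)
  # add-one estimator: p is (1 + k)/(1 + n_perm), so never below 1/(n+1)
  expect_gte(as.numeric(p1), 1 / 201)

  pc <- permutation_pvalue(x, rep(1, 6), n_perm = 50, seed = 1)
  expect_equal(as.numeric(pc), 1)
  expect_true(attr(pc, "degenerate"))
})

test_that("bh_adjust reproduces the textbook step-up on random inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)

  set.seed(13)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # order equivariance
  p <- runif(15); perm <- sample(15)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.2, 1.3)), "0, 1")
})

test_that("thresholding removes padj > alpha but keeps the boundary", {
  rho <- matrix(c(1, 0.8, -0.5,
                  0.8, 1, 0.3,
                  -0.5, 0.3, 1), 3, 3)
  padj <- matrix(c(0, 0.05, 0.06,
                   0.05, 0, 0.01,
                   0.06, 0.01, 0), 3, 3)
  net <- build_network(rho, padj, alpha = 0.05)
  expect_equal(net$adjacency[1, 2], 0.8)    # padj = alpha retained
  expect_equal(net$adjacency[1, 3], 0)      # padj > alpha removed
  expect_equal(net$adjacency[2, 3], 0.3)
  expect_equal(unname(diag(net$adjacency)), rep(0, 3))
  expect_equal(net$n_edges, 2L)

  expect_warning(
    empty <- build_network(rho, matrix(1, 3, 3) - diag(3), alpha = 0.05),
    "no significant")
  expect_true(empty$empty)
  expect_error(build_network(rho, padj[, 3:1]), "symmetric")
})

test_that("adjacency normalization is the symmetric self-loop form", {
  expect_equal(normalize_adjacency(matrix(0, 2, 2)), diag(2))
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(a), matrix(0.5, 2, 2))

  set.seed(21)
  w <- matrix(rnorm(36), 6, 6); w <- w + t(w); diag(w) <- 0
  ahat <- normalize_adjacency(w)
  expect_equal(ahat, t(ahat))
  expect_true(all(ahat >= 0))
  expect_true(all(is.finite(ahat)))

  # ring graph with unit weights: regular, so constant row sums
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- 1; ring[j, i] <- 1 }
  rs <- rowSums(normalize_adjacency(ring))
  expect_equal(rs, rep(rs[1], 6))
})

test_that("network summaries split internal and external associations", {
  rho <- matrix(1, 3, 3); diag(rho) <- 1
  padj <- matrix(0, 3, 3)
  net <- build_network(rho, padj, taxon_ids = c("A", "B", "C"))
  s <- network_summary(net, c("P1", "P1", "P2"))
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$internal_edges, 1L)   # A-B
  expect_equal(s$external_edges, 2L)   # A-C, B-C

  expect_warning(empty <- build_network(diag(3) * 0 + diag(3),
                                        matrix(1, 3, 3) - diag(3)))
  se <- network_summary(empty, c("P1", "P1", "P2"))
  expect_equal(se$n_edges, 0L)
  expect_equal(se$n_nodes, 0L)

  set.seed(31)
  for (rep in 1:5) {
    D <- 8
    rho <- matrix(runif(D * D, -1, 1), D, D); rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    padj <- matrix(runif(D * D), D, D); padj <- (padj + t(padj)) / 2
    diag(padj) <- 0
    suppressWarnings(net <- build_network(rho, padj, alpha = 0.4))
    lab <- sample(c("P1", "P2", "P3"), D, replace = TRUE)
    s <- network_summary(net, lab)
    expect_equal(s$internal_edges + s$external_edges, s$n_edges)
  }
})

test_that("build_cooccurrence tests each pair once and is reproducible", {
  set.seed(3)
  m <- matrix(rnorm(5 * 20), 5, 20)
  n1 <- suppressWarnings(build_cooccurrence(m, n_perm = 99, seed = 7))
  n2 <- suppressWarnings(build_cooccurrence(m, n_perm = 99, seed = 7))
  expect_identical(n1, n2)
  expect_equal(n1$rho, t(n1$rho))
  expect_equal(diag(n1$rho), rep(1, 5), ignore_attr = TRUE)
  # D(D-1)/2 unique p-values mirrored
  expect_equal(n1$pvals, t(n1$pvals))
  expect_equal(sum(upper.tri(n1$pvals)), choose(5, 2))
  expect_true(all(n1$padj[upper.tri(n1$padj)] >=
                    n1$pvals[upper.tri(n1$pvals)] - 1e-12))
})

test_that("a perfectly correlated pair is the only exhaustive-mode edge", {
  set.seed(14)
  x <- sample(100, 7)
  m <- rbind(a = x, b = 2 * x + 3, c = sample(100, 7))
  net <- build_cooccurrence(m, mode = "exhaustive", alpha = 0.05)
  edges <- which(net$adjacency != 0 & upper.tri(net$adjacency),
                 arr.ind = TRUE)
  expect_equal(nrow(edges), 1L)
  expect_equal(unname(edges[1, ]), c(1L, 2L))
  expect_equal(net$adjacency[1, 2], 1)
})

test_that("a strongly coupled taxon pair survives the full pipeline", {
  g <- matrix(0, 3, 3); g[1, 2] <- g[2, 1] <- 1
  spec <- simulator_spec(n_taxa = 3, n_steps = 60, graph = g,
                         rho_self = 0.4, gamma = 0.45, noise_sd = 0.3,
                         seed = 6)
  series <- simulate_series(spec)
  net <- build_cooccurrence(series, n_perm = 999, seed = 2)
  expect_true(net$adjacency[1, 2] != 0)
  expect_gt(net$adjacency[1, 2], 0)   # mutualistic pair: positive sign
})
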