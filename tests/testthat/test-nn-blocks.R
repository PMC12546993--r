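# Block algebra, gradients, equivariance, variant contracts and
# checkpoint serialization.

make_cfg <- function(...) {
  defaults <- list(n_taxa = 3, window = 5, horizon = 2, channels = 2,
                   kernel = 2, n_blocks = 1, lstm_layers = 2,
                   lstm_hidden = 3, seed = 11)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

rand_ahat <- function(D, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(D * D), D, D); a <- (a + t(a)) / 2; diag(a) <- 0
  normalize_adjacency(a)
}

test_that("temporal block matches the causal convolution oracle", {
  # identity kernel (k = 1, weight 1, linear path) is a passthrough
  set.seed(1)
  x <- array(rnorm(2 * 1 * 3 * 6), c(2, 1, 3, 6))
  p_id <- list(W = array(1, c(1, 1, 1)), b = 0, activation = "linear")
  expect_equal(temporal_block_forward(x, p_id), x)

  # zero weights, bias beta, linear path: constant output
  p_b <- list(W = array(0, c(1, 1, 2)), b = 0.7, activation = "linear")
  expect_equal(temporal_block_forward(x, p_b),
               array(0.7, dim(x)))

  # k = 2, weights [1, 1]: sliding pair sums with left zero pad
  x3 <- array(0, c(1, 1, 1, 3)); x3[1, 1, 1, ] <- c(1, 2, 3)
  p_s <- list(W = array(1, c(1, 1, 2)), b = 0, activation = "linear")
  expect_equal(as.vector(temporal_block_forward(x3, p_s)), c(1, 3, 5))

  # random kernels vs the brute-force oracle
  set.seed(2)
  for (rep in 1:5) {
    d <- c(sample(1:3, 1), sample(1:3, 1), sample(2:4, 1), sample(3:7, 1))
    k <- sample(1:3, 1); c2 <- sample(1:4, 1)
    x <- array(rnorm(prod(d)), d)
    W <- array(rnorm(c2 * d[2] * k), c(c2, d[2], k))
    b <- rnorm(c2)
    got <- temporal_block_forward(x, list(W = W, b = b,
                                          activation = "linear"))
    expect_equal(got, conv_oracle(x, W, b), tolerance = 1e-10)
  }

  # gated activation: linear path times sigmoid of the gate path
  xg <- array(rnorm(1 * 1 * 2 * 4), c(1, 1, 2, 4))
  Wg <- array(rnorm(2 * 1 * 1), c(2, 1, 1)); bg <- rnorm(2)
  pre <- conv_oracle(xg, Wg, bg)
  glu <- temporal_block_forward(xg, list(W = Wg, b = bg,
                                         activation = "glu"))
  expect_equal(glu,
               pre[, 1, , , drop = FALSE] *
                 (1 / (1 + exp(-pre[, 2, , , drop = FALSE]))),
               tolerance = 1e-12)
})

test_that("spatial block contracts the node axis like the double loop", {
  D <- 3
  x <- array(abs(rnorm(2 * 2 * D * 4)), c(2, 2, D, 4))
  id_mix <- list(M = diag(2), b = c(0, 0))

  # identity adjacency and identity mix: passthrough (inputs positive)
  expect_equal(spatial_block_forward(x, diag(D), id_mix), x)

  # two-node average
  x2 <- array(0, c(1, 1, 2, 1)); x2[1, 1, , 1] <- c(1, 3)
  got <- spatial_block_forward(x2, matrix(0.5, 2, 2),
                               list(M = matrix(1), b = 0))
  expect_equal(as.vector(got), c(2, 2))

  # row-stochastic adjacency keeps node-constant inputs constant
  xc <- array(rep(abs(rnorm(2 * 2 * 4)), each = 1), c(2, 2, 1, 4))
  xc <- array(xc[, , rep(1, D), , drop = FALSE], c(2, 2, D, 4))
  rs <- matrix(1 / D, D, D)
  outc <- spatial_block_forward(xc, rs, id_mix)
  expect_equal(outc[, , 1, ], outc[, , D, ])

  # random tensors vs the double-loop oracle (linear mix, positive input)
  set.seed(6)
  for (rep in 1:5) {
    d <- c(2, sample(1:3, 1), sample(2:4, 1), sample(2:5, 1))
    x <- array(abs(rnorm(prod(d))) + 0.1, d)
    ahat <- rand_ahat(d[3], seed = rep)
    got <- spatial_block_forward(x, ahat,
                                 list(M = diag(d[2]), b = rep(0, d[2])))
    expect_equal(got, contract_oracle(x, ahat), tolerance = 1e-10)
  }
})

test_that("recurrent branch is a bounded deterministic fixed point at zero", {
  cfg <- make_cfg()
  model <- build_variant("lstm", cfg)
  zero_layers <- lapply(model$params$lstm, function(l)
    list(Wx = l$Wx * 0, Wh = l$Wh * 0, b = l$b * 0))
  x0 <- array(0, c(2, 3, 5))
  expect_equal(recurrent_branch_forward(x0, zero_layers),
               matrix(0, 6, 3))

  set.seed(3)
  x <- array(rnorm(2 * 3 * 5, sd = 3), c(2, 3, 5))
  h1 <- recurrent_branch_forward(x, model$params$lstm)
  h2 <- recurrent_branch_forward(x, model$params$lstm)
  expect_identical(h1, h2)
  expect_true(all(abs(h1) < 1))
})

test_that("analytic gradients match central finite differences everywhere", {
  cfg <- make_cfg()
  ns <- asNamespace("microstnet")
  set.seed(42)
  B <- 2
  xa <- array(rnorm(B * 3 * 5), c(B, 3, 5))
  xc <- array(rnorm(B * 3 * 5), c(B, 3, 5))
  y <- array(rnorm(B * 3 * 2), c(B, 3, 2))
  ahat <- rand_ahat(3, seed = 9)
  loss_of <- function(model) {
    pred <- ns$.model_forward(model, xa, xc, ahat)$pred
    mean(abs(pred - y))
  }
  for (variant in c("lstm", "stgcn2s", "microstnet")) {
    model <- build_variant(variant, cfg)
    fw <- ns$.model_forward(model, xa, xc, ahat, keep_cache = TRUE)
    dpred <- sign(fw$pred - y) / length(y)
    grads <- ns$.model_backward(model, dpred, ahat, fw$cache)

    flat_g <- unlist(grads)
    expect_true(all(is.finite(flat_g)))
    eps <- 1e-6
    # walk each numeric leaf, probing a few entries
    check_leaf <- function(path, g) {
      if (is.list(g)) {
        ix <- if (is.null(names(g))) seq_along(g) else names(g)
        for (i in ix) if (!is.null(g[[i]]))
          check_leaf(c(path, i), g[[i]])
        return(invisible())
      }
      if (!is.numeric(g)) return(invisible())
      for (e in sample(length(g), min(3L, length(g)))) {
        perturb <- function(delta) {
          m2 <- model
          node <- m2$params
          # descend and rebuild with the perturbed entry
          setval <- function(node, depth) {
            key <- path[depth]
            key <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
            if (depth == length(path)) {
              node[[key]][e] <- node[[key]][e] + delta
            } else {
              node[[key]] <- setval(node[[key]], depth + 1)
            }
            node
          }
          m2$params <- setval(m2$params, 1)
          m2
        }
        gnum <- (loss_of(perturb(eps)) - loss_of(perturb(-eps))) / (2 * eps)
        rel <- abs(gnum - g[e]) / max(1e-6, abs(gnum) + abs(g[e]))
        expect_lt(rel, 1e-3)
      }
    }
    check_leaf(character(0), grads)
  }
})

test_that("full forward is node-permutation equivariant", {
  cfg <- make_cfg(n_taxa = 4)
  ahat <- rand_ahat(4, seed = 5)
  set.seed(10)
  xa <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  xc <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  perm <- c(3, 1, 4, 2)
  for (variant in c("microstnet", "stgcn2s", "lstm")) {
    model <- build_variant(variant, cfg)
    base <- microstnet_forward(model, xa, xc, ahat)
    permuted <- microstnet_forward(model,
                                   xa[, perm, , drop = FALSE],
                                   xc[, perm, , drop = FALSE],
                                   ahat[perm, perm])
    expect_equal(permuted, base[, perm, , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("forward passes are pure and variant shapes agree", {
  cfg <- make_cfg()
  ahat <- rand_ahat(3)
  set.seed(20)
  xa <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  xc <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  for (variant in c("microstnet", "stgcn2s", "lstm")) {
    model <- build_variant(variant, cfg)
    p1 <- microstnet_forward(model, xa, xc, ahat)
    p2 <- microstnet_forward(model, xa, xc, ahat)
    expect_identical(p1, p2)
    expect_equal(dim(p1), c(4, 3, 2))
  }
  expect_error(build_variant("nope", cfg), "arg")
})

test_that("the recurrent-only variant never reads the adjacency", {
  cfg <- make_cfg()
  model <- build_variant("lstm", cfg)
  set.seed(30)
  xa <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  a1 <- rand_ahat(3, seed = 1)
  a2 <- rand_ahat(3, seed = 2)
  expect_identical(microstnet_forward(model, xa, ahat = a1),
                   microstnet_forward(model, xa, ahat = a2))
})

test_that("parameter counts are strictly ordered across variants", {
  cfg <- model_config(n_taxa = 10, window = 8, channels = 16, kernel = 3,
                      n_blocks = 2, lstm_layers = 5)
  n_l <- n_params(build_variant("lstm", cfg))
  n_s <- n_params(build_variant("stgcn2s", cfg))
  n_m <- n_params(build_variant("microstnet", cfg))
  expect_lt(n_l, n_s)
  expect_lt(n_s, n_m)
  # the full model adds exactly the recurrent branch plus the wider head
  cfg_names <- names(build_variant("microstnet", cfg)$params)
  expect_setequal(setdiff(cfg_names,
                          names(build_variant("stgcn2s", cfg)$params)),
                  "lstm")
})

test_that("checkpoints round-trip bit-exactly through JSON", {
  cfg <- make_cfg()
  ds_fake <- structure(list(
    windows = array(rnorm(6 * 3 * 5), c(6, 3, 5)),
    changes = array(rnorm(6 * 3 * 5), c(6, 3, 5)),
    targets = array(rnorm(6 * 3 * 2), c(6, 3, 2)),
    scale = "standardized"), class = "series_tensor")
  fit <- train_variant("microstnet", ds_fake,
                       list(train = 1:4, eval = 5:6),
                       ahat = rand_ahat(3), config = cfg, epochs = 2,
                       lr = 1e-3, batch_size = 2, seed = 7)
  std <- fit_standardizer(matrix(rnorm(9), 3, 3),
                          taxon_ids = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path, standardizer = std)
  back <- load_checkpoint(path)
  expect_identical(back$fit$model$params, fit$model$params)
  expect_identical(back$standardizer$means, std$means)
  expect_identical(back$standardizer$sds, std$sds)
  expect_identical(back$fit$ahat, unname(fit$ahat))
  set.seed(50)
  xa <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  expect_identical(microstnet_forward(back$fit$model, xa, ahat = back$fit$ahat),
                   microstnet_forward(fit$model, xa, ahat = fit$ahat))
})
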