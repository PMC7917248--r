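# Architecture contracts, the triplet loss, and gradient correctness.

test_that("the shape chain follows the architecture", {
  cfg <- model_config(seed = 3)
  params <- init_params(cfg)
  # drug tunnel: 1024 -> 256/64/256
  expect_identical(dim(params$mlp[[1]]$W), c(1024L, 256L))
  expect_identical(dim(params$mlp[[2]]$W), c(256L, 64L))
  expect_identical(dim(params$mlp[[3]]$W), c(64L, 256L))
  fp <- matrix(rbinom(1024, 1, 0.1), 1)
  ed <- drug_encoder(fp, params, cfg)
  expect_identical(dim(ed), c(1L, 256L))
  # protein tunnel: 1000 x 26 -> 32
  enc <- encode_protein("MKVLANNNPQRS")
  ep <- protein_encoder(enc, params, cfg)
  expect_identical(dim(ep), c(1L, 32L))
  # shared space: both project to 256; concatenation feeds the 1024-wide head
  expect_identical(ncol(project_shared(ed, params, cfg, "drug")), 256L)
  expect_identical(ncol(project_shared(ep, params, cfg, "protein")), 256L)
  expect_identical(dim(params$fc[[1]]$W), c(512L, 1024L))
  expect_error(drug_encoder(matrix(0, 1, 100), params, cfg), "does not match")
})

test_that("encoders collapse to zero under zero weights and biases", {
  cfg <- tiny_config(dropout_rates = c(0, 0))
  params <- init_params(cfg)
  zero <- rapply(params, function(x) x * 0, how = "replace")
  fp <- matrix(rbinom(32, 1, 0.5), 1)
  expect_true(all(drug_encoder(fp, zero, cfg) == 0))
  enc <- encode_protein("MKVL", max_len = cfg$max_len)
  expect_true(all(protein_encoder(enc, zero, cfg) == 0))
  # zero-weight head with bias b predicts b for every pair
  b <- 2.5
  zero$fc[[length(zero$fc)]]$b <- b
  pd <- matrix(rnorm(10), 1)
  pp <- matrix(rnorm(10), 1)
  expect_equal(predict_affinity(pd, pp, zero, cfg), b)
})

test_that("an identity-initialized square projection is the identity map", {
  cfg <- tiny_config(shared_dim = 12L, mlp_widths = c(32L, 16L, 8L, 12L))
  params <- init_params(cfg)
  params$proj_drug$W <- diag(12)
  params$proj_drug$b <- numeric(12)
  v <- rnorm(12)
  expect_equal(as.numeric(project_shared(v, params, cfg, "drug")), v)
})

test_that("padding rows beyond every receptive field do not change the protein encoding", {
  cfg <- tiny_config()
  params <- init_params(cfg)
  enc <- encode_protein("MKVLHH", max_len = cfg$max_len)
  out1 <- protein_encoder(enc, params, cfg)
  # scrambling all-zero tail rows leaves an all-zero tail -> same output
  m2 <- unclass(enc)[c(1:20, sample(21:40)), ]
  out2 <- tripletDTA:::conv_forward(matrix(as.numeric(m2), nrow(m2)), 1L, cfg, params)$out
  expect_equal(out1, out2)
})

test_that("triplet loss matches hand evaluation and its degenerate cases", {
  expect_equal(triplet_loss(c(0, 0), c(0, 0), c(1, 0), margin = 1), 0)
  expect_equal(triplet_loss(c(0, 0), c(3, 0), c(1, 0), margin = 1), 9)
  v <- rnorm(8)
  expect_equal(triplet_loss(v, v, v, margin = 1), 1)   # distances cancel
  expect_equal(triplet_loss(v, v, v, margin = 0.3), 0.3)
  expect_error(triplet_loss(c(0, 0), c(0, 0, 0), c(1, 0)), "share")
  expect_error(triplet_loss(v, v, v, margin = 0), "margin")
})

test_that("triplet loss depends on distances only and is never negative", {
  set.seed(7)
  brute <- function(a, p, n, m) max(sum((a - p)^2) - sum((a - n)^2) + m, 0)
  for (i in 1:50) {
    a <- rnorm(5); p <- rnorm(5); n <- rnorm(5)
    m <- runif(1, 0.1, 3)
    l <- triplet_loss(a, p, n, m)
    expect_gte(l, 0)
    expect_equal(l, brute(a, p, n, m), tolerance = 1e-12)
    # invariance under a common rigid rotation
    Q <- qr.Q(qr(matrix(rnorm(25), 5)))
    expect_equal(triplet_loss(drop(Q %*% a), drop(Q %*% p), drop(Q %*% n), m),
                 l, tolerance = 1e-9)
    # zero whenever the negative is margin-further than the positive
    if (sum((a - n)^2) >= sum((a - p)^2) + m) expect_identical(l, 0)
  }
})

test_that("combined loss reduces to MSE without triplets and dominates it otherwise", {
  y <- c(5, 6, 7); yh <- c(5.5, 6, 6)
  expect_equal(combined_loss(y, yh, triplet_weight = 0), mse(y, yh))
  expect_equal(combined_loss(y, yh, anchors = NULL), mse(y, yh))
  A <- matrix(rnorm(12), 3); P <- matrix(rnorm(12), 3); N <- matrix(rnorm(12), 3)
  expect_gte(combined_loss(y, yh, A, P, N, margin = 1, triplet_weight = 2),
             mse(y, yh))
})

test_that("backpropagated gradients match finite differences on a tiny model", {
  set.seed(42)
  cfg <- model_config(
    mlp_widths = c(16L, 8L, 6L), cnn_filters = c(4L, 5L),
    cnn_kernel_lengths = c(3L, 4L), shared_dim = 6L, fc_widths = c(7L, 5L),
    dropout_rates = c(0, 0), max_len = 20L, margin = 1, triplet_weight = 1,
    seed = 11L
  )
  params <- init_params(cfg)
  # jitter away from the exact-zero ReLU kinks of freshly initialized biases
  theta <- tripletDTA:::flatten_params(params)
  theta <- theta + runif(length(theta), -0.05, 0.05)
  params <- tripletDTA:::unflatten_params(theta, params)
  data <- list(
    fps = matrix(rbinom(5 * 16, 1, 0.4), 5, 16),
    prot_stack = lapply(1:3, function(i) {
      m <- matrix(0, 20, 26)
      m[cbind(1:15, sample(1:26, 15, TRUE))] <- 1
      m
    })
  )
  batch <- data.frame(
    drug_index = c(1, 2, 3, 4, 5, 1), protein_index = c(1, 2, 3, 1, 2, 3),
    neg_index = c(2, 3, 4, 5, 1, 3), pkd = runif(6, 4, 8),
    label = c("positive", "negative", "positive", "positive", "negative", "positive")
  )
  res <- tripletDTA:::batch_loss_grads(params, batch, data, cfg, train = FALSE)
  g <- tripletDTA:::flatten_params(res$grads)
  f <- function(th) {
    tripletDTA:::batch_loss_grads(tripletDTA:::unflatten_params(th, params),
                                  batch, data, cfg,
                                  train = FALSE, with_grads = FALSE)$loss
  }
  idx <- sort(sample(length(theta), 200))
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, 0)
  rel <- abs(num - g[idx]) / pmax(1, abs(num) + abs(g[idx]))
  expect_lt(max(rel), 1e-4)
  # every block of the network receives gradient signal somewhere
  expect_true(all(vapply(res$grads, function(b) any(abs(unlist(b)) > 0), TRUE)))
})

test_that("inference is deterministic: repeated predictions agree exactly", {
  cfg <- tiny_config()
  params <- init_params(cfg)
  pd <- matrix(rnorm(3 * cfg$shared_dim), 3)
  pp <- matrix(rnorm(3 * cfg$shared_dim), 3)
  p1 <- predict_affinity(pd, pp, params, cfg)
  expect_identical(p1, predict_affinity(pd, pp, params, cfg))
  expect_true(all(is.finite(p1)))
})
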