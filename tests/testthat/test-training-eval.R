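# Metrics and the training loop.

test_that("concordance index handles perfect, reversed and tied orderings", {
  expect_identical(concordance_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(concordance_index(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 3, 2)), 2 / 3)
  # constant predictor: every comparable pair is a prediction tie
  expect_equal(concordance_index(c(1, 2, 3, 4), rep(0, 4)), 0.5)
  expect_error(concordance_index(c(1, 1, 1), c(1, 2, 3)), "tied")
  expect_error(concordance_index(1, 1), "length")
})

test_that("concordance index agrees with the brute-force oracle, ties included", {
  set.seed(31)
  for (n in c(5, 40, 200)) {
    y <- sample(1:8, n, replace = TRUE)            # truth ties (excluded pairs)
    p <- round(rnorm(n), 1)                         # prediction ties (0.5 credit)
    if (length(unique(y)) < 2) y[1] <- y[1] + 1
    expect_equal(concordance_index(y, p), ci_bruteforce(y, p), tolerance = 1e-12)
  }
})

test_that("concordance index agrees with the survival-analysis implementation", {
  skip_if_not_installed("survival")
  set.seed(8)
  y <- rnorm(150)
  p <- y + rnorm(150, sd = 2)
  expect_equal(concordance_index(y, p),
               survival::concordance(y ~ p)$concordance,
               tolerance = 1e-10)
})

test_that("random predictions hover at chance level", {
  set.seed(13)
  y <- rnorm(60)
  cis <- vapply(1:40, function(i) concordance_index(y, sample(y)), 0)
  expect_lt(abs(mean(cis) - 0.5), 0.05)
})

test_that("mse matches hand computations and validates lengths", {
  expect_identical(mse(c(1, 2), c(1, 2)), 0)
  expect_identical(mse(c(0, 0), c(1, 1)), 1)
  expect_identical(mse(c(0, 2), c(1, 5)), 5)
  expect_error(mse(1:3, 1:2), "equal length")
})

test_that("training runs, records history, and returns the best checkpoint", {
  ds <- tiny_dataset(10, 4, seed = 5)
  cfg <- tiny_config(epochs = 4L, seed = 2L)
  m <- train(ds, cfg)
  h <- m$history
  expect_identical(nrow(h), 4L)
  expect_true(all(is.finite(h$train_loss)))
  expect_identical(m$best_epoch, which.min(h$val_mse))
  expect_identical(attr(h, "seed"), 2L)
  # the combined loss decreases on a learnable planted signal
  expect_lt(h$train_loss[4], h$train_loss[1])
})

test_that("training is reproducible and the triplet term changes the optimum", {
  ds <- tiny_dataset(10, 4, seed = 6)
  cfg <- tiny_config(epochs = 2L, seed = 9L)
  m1 <- train(ds, cfg)
  m2 <- train(ds, cfg)
  expect_identical(as.data.frame(m1$history), as.data.frame(m2$history))
  expect_identical(m1$params, m2$params)
  # lambda = 0 and lambda = 1 reach different parameters on the same data/seed
  m0 <- train(ds, tiny_config(epochs = 2L, seed = 9L, triplet_weight = 0))
  expect_false(identical(m0$params, m1$params))
  expect_false(isTRUE(all.equal(m0$history$train_loss, m1$history$train_loss)))
})

test_that("evaluation is invariant to record order and exact for an oracle predictor", {
  ds <- tiny_dataset(8, 3, seed = 12)
  cfg <- tiny_config(epochs = 1L, seed = 4L)
  m <- train(ds, cfg)
  recs <- as_affinity_records(ds)
  ev1 <- evaluate(m, recs)
  perm <- sample(nrow(recs))
  ev2 <- evaluate(m, recs[perm, ])
  expect_equal(ev1$mse, ev2$mse, tolerance = 1e-12)
  expect_equal(ev1$ci, ev2$ci, tolerance = 1e-12)
  # a perfect oracle gives (0, 1)
  expect_identical(mse(recs$pkd, recs$pkd), 0)
  expect_identical(concordance_index(recs$pkd, recs$pkd), 1)
})

test_that("checkpoints round-trip through save and load", {
  ds <- tiny_dataset(8, 3, seed = 3)
  cfg <- tiny_config(epochs = 1L, seed = 5L)
  m <- train(ds, cfg)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.rds", "metadata.json",
                                               "history.tsv")))))
  m2 <- load_model(dir)
  expect_equal(m2$params, m$params, tolerance = 1e-15)
  expect_identical(unclass(m2$config), unclass(m$config))
  recs <- as_affinity_records(ds)[1:5, ]
  expect_equal(predict_records(m2, recs), predict_records(m, recs),
               tolerance = 1e-12)
})
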