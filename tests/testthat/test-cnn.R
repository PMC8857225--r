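# CNN architecture, training behaviour and prediction contracts.

test_that("shape report reproduces the conv/pool cascade down to 1x1x64", {
  m <- build_model(cnn_config(), seed = 1)
  rep <- m$layer_shape_report
  expect_equal(rep$output_shape[rep$layer == "conv1"], "128x128x12")
  cascade <- rep$output_shape[grepl("^(conv|pool)", rep$layer)]
  expect_equal(cascade,
               c("128x128x12", "64x64x12", "32x32x16", "16x16x16",
                 "8x8x32", "4x4x32", "2x2x64", "1x1x64"))
  expect_equal(rep$output_shape[rep$layer == "flatten"], "64")
})

test_that("parameter count matches the per-layer hand formula", {
  # conv: (k*k*c_in + 1)*c_out; dense: (n_in + 1)*n_out
  hand <- (3 * 3 * 3 + 1) * 12 + (3 * 3 * 12 + 1) * 16 +
    (3 * 3 * 16 + 1) * 32 + (3 * 3 * 32 + 1) * 64 +
    (64 + 1) * 512 + (512 + 1) * 128 + (128 + 1) * 1
  m <- build_model(cnn_config(), seed = 1)
  expect_equal(m$parameter_count, hand)
  expect_equal(hand, 124289L)
  # and the count is derived from the actually allocated arrays
  alloc <- sum(unlist(lapply(m$weights$conv, lengths))) +
    sum(unlist(lapply(m$weights$dense, lengths)))
  expect_equal(m$parameter_count, alloc)
})

test_that("input sizes not reducible to 1x1 are rejected", {
  expect_error(build_model(cnn_config(input_size = 100L)), "1x1")
  expect_error(build_model(cnn_config(input_size = 96L)), "1x1")
})

test_that("invalid training configurations are rejected", {
  expect_error(cnn_config(filters = c(12, 16, 32)), "filters")
  expect_error(cnn_config(filters = c(12, 12, 32, 64)), "filters")
  expect_error(cnn_config(decision_threshold = 1), "decision_threshold")
})

test_that("training runs the configured epochs and is seed-deterministic", {
  d <- easy60()
  xs <- d$x[, , , 1:24]; ys <- d$labels[1:24]
  cfg <- cnn_config(epochs = 4L)
  f1 <- ischemia_cnn(xs, ys, config = cfg, seed = 7)
  f2 <- ischemia_cnn(xs, ys, config = cfg, seed = 7)
  expect_equal(nrow(f1$history), 4L)
  expect_equal(f1$history$loss, f2$history$loss)
  px <- d$x[, , , 25:40]
  expect_identical(predict(f1, px), predict(f2, px))
  expect_identical(predict(f1, px, type = "prob"),
                   predict(f2, px, type = "prob"))
  # a different seed gives a different trajectory
  f3 <- ischemia_cnn(xs, ys, config = cfg, seed = 8)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("training refuses a single-class training set", {
  d <- easy60()
  neg <- which(d$labels == 0)[1:6]
  expect_error(ischemia_cnn(d$x[, , , neg], d$labels[neg],
                            config = cnn_config(epochs = 1L)),
               "single label class")
})

test_that("training loss decreases and fits an easy training set", {
  ef <- easy_fit()
  d <- easy150()
  h <- ef$fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  tr_i <- ef$idx(ef$split$train_ids)
  train_acc <- mean(predict(ef$fit, d$x[, , , tr_i]) == d$labels[tr_i])
  expect_gte(train_acc, 0.95)
})

test_that("validation history tracks a held-out set", {
  d <- easy60()
  fit <- ischemia_cnn(d$x[, , , 1:24], d$labels[1:24],
                      d$x[, , , 25:36], d$labels[25:36],
                      config = cnn_config(epochs = 3L), seed = 2)
  expect_false(anyNA(fit$history$val_loss))
  expect_false(anyNA(fit$history$val_metric))
  expect_true(all(fit$history$val_metric >= 0 & fit$history$val_metric <= 1))
})

test_that("prediction applies a strict > threshold with ties to 0", {
  d <- easy60()
  m <- build_model(cnn_config(), seed = 5)   # untrained is fine here
  px <- d$x[, , , 1:6]
  p <- suppressWarnings(predict(m, px, type = "prob"))
  # threshold exactly at a returned probability: that case must predict 0
  lab <- suppressWarnings(predict(m, px, threshold = p[2]))
  expect_equal(lab[2], 0L)
  expect_equal(lab, as.integer(p > p[2]))
  # just below the probability it flips to 1
  lab2 <- suppressWarnings(predict(m, px, threshold = p[2] - 1e-9))
  expect_equal(lab2[2], 1L)
})

test_that("batch prediction equals one-by-one prediction", {
  d <- easy60()
  m <- build_model(cnn_config(), seed = 9)
  px <- d$x[, , , 1:5]
  batch <- suppressWarnings(predict(m, px, type = "prob"))
  single <- vapply(1:5, function(i)
    suppressWarnings(predict(m, px[, , , i], type = "prob")), 0)
  expect_identical(batch, single)
})

test_that("mismatched image shapes are rejected at prediction", {
  m <- build_model(cnn_config(), seed = 1)
  expect_error(suppressWarnings(predict(m, array(0, c(128, 128, 3, 2)))),
               "does not match")
})

test_that("class weighting raises sensitivity on an imbalanced set", {
  # heavy imbalance, overlapping classes; compare weighted (1:3) vs
  # unweighted training at equal epochs over 10 seeds
  cfg <- synth_config(n_cases = 40, ischemic_fraction = 0.2,
                      normal_mbf_range = c(2.4, 3.2),
                      defect_mbf_range = c(1.6, 2.2),
                      noise_sd = 0.2, borderline_fraction = 0.2, seed = 21)
  ds <- synth_dataset(cfg)
  x <- ds$images / 255
  cfg_w <- cnn_config(epochs = 12L)
  cfg_u <- cnn_config(epochs = 12L, class_weights = c(1, 1))
  sen <- function(fit) {
    p <- predict(fit, x)
    sum(p == 1 & ds$labels == 1) / sum(ds$labels == 1)
  }
  sens <- t(vapply(1:10, function(s) {
    c(w = sen(ischemia_cnn(x, ds$labels, config = cfg_w, seed = 100 + s)),
      u = sen(ischemia_cnn(x, ds$labels, config = cfg_u, seed = 100 + s)))
  }, c(w = 0, u = 0)))
  expect_gt(mean(sens[, "w"]), mean(sens[, "u"]))
})
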