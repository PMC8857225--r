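# Confusion counts, metrics, aggregation, net benefit, Cohen's kappa.

test_that("confusion counts match exhaustive enumeration on small vectors", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pred <- sample(0:1, n, replace = TRUE)
    ref <- sample(0:1, n, replace = TRUE)
    cc <- confusion(pred, ref)
    brute <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (i in seq_len(n)) {
      cell <- if (ref[i] == 1 && pred[i] == 1) "TP"
      else if (ref[i] == 0 && pred[i] == 0) "TN"
      else if (ref[i] == 0 && pred[i] == 1) "FP"
      else "FN"
      brute[cell] <- brute[cell] + 1
    }
    expect_equal(c(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN), brute)
    expect_equal(cc$TP + cc$FN, sum(ref == 1))
    expect_equal(cc$TN + cc$FP, sum(ref == 0))
  }
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(confusion(c(0, 2), c(0, 1)), "binary")
})

test_that("a perfect classifier scores 1 on every metric", {
  ref <- c(1, 1, 0, 0, 1)
  m <- compute_metrics(confusion(ref, ref))
  expect_equal(unname(unclass(m)), rep(1, 6))
})

test_that("metrics from label vectors equal metrics from counts", {
  set.seed(17)
  for (rep in 1:10) {
    pred <- sample(0:1, 30, replace = TRUE)
    ref <- sample(0:1, 30, replace = TRUE)
    cc <- confusion(pred, ref)
    m <- compute_metrics(cc)
    # direct computation from the vectors, bypassing confusion()
    sen <- sum(pred == 1 & ref == 1) / sum(ref == 1)
    spe <- sum(pred == 0 & ref == 0) / sum(ref == 0)
    expect_equal(unname(m["ACC"]), mean(pred == ref))
    expect_equal(unname(m["SEN"]), sen)
    expect_equal(unname(m["SPE"]), spe)
    expect_equal(unname(m["AUC"]), (sen + spe) / 2)
  }
})

test_that("zero denominators give the undefined sentinel, not zero", {
  m <- compute_metrics(confusion(c(0, 0, 0), c(0, 0, 0)))
  expect_true(is.na(m["SEN"]))
  expect_true(is.na(m["PRE"]))
  expect_equal(unname(m["SPE"]), 1)
  expect_equal(unname(m["ACC"]), 1)
})

test_that("aggregation reproduces hand-sorted median and IQR", {
  acc <- c(0.80, 0.70, 0.90, 0.85, 0.75)
  agg <- aggregate_runs(data.frame(ACC = acc))
  expect_equal(agg$median, 0.80)
  expect_equal(agg$IQR, 0.85 - 0.75)  # type-7 quartiles on 5 points
  # identical runs collapse to IQR 0
  agg0 <- aggregate_runs(data.frame(ACC = rep(0.8261, 7),
                                    SPE = rep(0.9615, 7)))
  expect_equal(agg0$IQR, c(0, 0))
  # permutation invariance
  expect_equal(aggregate_runs(data.frame(ACC = rev(acc))), agg)
})

test_that("net benefit follows TP/N - FP/N * pt/(1-pt)", {
  cc <- confusion_counts(TP = 15, TN = 25, FP = 1, FN = 5)
  dc <- decision_curve(cc, grid = c(0, 0.25, 0.5, 0.75))
  expect_equal(dc$net_benefit[1], 15 / 46)
  expect_equal(dc$net_benefit[3], (15 - 1) / 46)
  expect_equal(dc$net_benefit[2], 15 / 46 - (1 / 46) * (0.25 / 0.75))
  # strictly decreasing whenever FP > 0
  expect_true(all(diff(dc$net_benefit) < 0))
  # FP = 0: constant TP/N over the whole grid
  flat <- decision_curve(confusion_counts(10, 30, 0, 6))
  expect_equal(unique(flat$net_benefit), 10 / 46)
  expect_error(decision_curve(cc, grid = c(0, 1)), "\\[0, 1\\)")
})

test_that("kappa matches the hand-computed agreement arithmetic", {
  # agreement table [[10,2],[3,31]]
  a <- rep(c(1, 1, 0, 0), c(10, 2, 3, 31))
  b <- rep(c(1, 0, 1, 0), c(10, 2, 3, 31))
  k <- cohen_kappa(a, b)
  po <- (10 + 31) / 46
  pe <- (12 * 13 + 34 * 33) / 46^2
  expect_equal(k$po, po)
  expect_equal(k$pe, pe)
  expect_equal(k$kappa, (po - pe) / (1 - pe))
})

test_that("kappa is 1 for identical mixed-class raters and NA when degenerate", {
  v <- c(1, 0, 1, 1, 0)
  expect_equal(cohen_kappa(v, v)$kappa, 1.0)
  k <- cohen_kappa(rep(1, 5), rep(1, 5))
  expect_true(is.na(k$kappa))
  expect_match(k$note, "constant")
})

test_that("kappa is symmetric and invariant under a simultaneous label flip", {
  set.seed(7)
  for (rep in 1:10) {
    a <- sample(0:1, 20, replace = TRUE)
    b <- sample(0:1, 20, replace = TRUE)
    k1 <- cohen_kappa(a, b)$kappa
    expect_equal(k1, cohen_kappa(b, a)$kappa)
    expect_equal(k1, cohen_kappa(1 - a, 1 - b)$kappa)
  }
})

test_that("category agreement scores full TN/FP agreement as kappa 1", {
  # two raters agreeing exactly on which subjects are TN and FP, while two
  # positives flip between TP and FN
  a <- rep(c("TP", "FN", "FN", "TN", "FP"), c(13, 2, 5, 25, 1))
  b <- rep(c("TP", "TP", "FN", "TN", "FP"), c(13, 2, 5, 25, 1))
  res <- category_agreement(a, b)
  expect_equal(res$kappa[res$category == "TN"], 1.0)
  expect_equal(res$kappa[res$category == "FP"], 1.0)
  expect_lt(res$kappa[res$category == "TP"], 1.0)
  expect_lt(res$kappa[res$category == "ischemic"], 1.0)
})

test_that("per-run ensemble metrics line up with per-row confusion", {
  preds <- rbind(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L))
  ens <- fake_ensemble(preds, reference = c(1L, 0L, 0L, 0L))
  em <- ensemble_metrics(ens)
  expect_equal(nrow(em), 2)
  expect_equal(em$TP, c(1L, 1L))
  expect_equal(em$FP, c(1L, 1L))
  expect_equal(em$ACC, c(3 / 4, 3 / 4))
})
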