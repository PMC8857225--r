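# Clinical-threshold comparator: truth-based and image-based rules.

test_that("the threshold rule is strict at 2.3 ml/g/min", {
  lay <- territory_layout()
  n <- nrow(lay$segments)
  normal <- rep(3.0, n)
  expect_equal(classify_by_threshold(normal, layout = lay), 0L)
  at <- normal; at[10] <- 2.3
  expect_equal(classify_by_threshold(at, layout = lay), 0L)   # exactly at: normal
  below <- normal; below[10] <- 2.29
  expect_equal(classify_by_threshold(below, layout = lay), 1L)
})

test_that("min_defect_segments demands an angularly contiguous run", {
  lay <- territory_layout()
  n <- nrow(lay$segments)
  rule2 <- clinical_rule(min_defect_segments = 2)
  seg <- lay$segments
  ring1 <- which(seg$ring == 1)
  # two adjacent sub-threshold sectors: ischemic under the 2-segment rule
  v <- rep(3.0, n); v[ring1[c(4, 5)]] <- 1.5
  expect_equal(classify_by_threshold(v, rule2, lay), 1L)
  # two separated sectors: not contiguous
  v2 <- rep(3.0, n); v2[ring1[c(4, 8)]] <- 1.5
  expect_equal(classify_by_threshold(v2, rule2, lay), 0L)
  # wrap-around contiguity across the 0-degree boundary
  v3 <- rep(3.0, n); v3[ring1[c(1, 12)]] <- 1.5
  expect_equal(classify_by_threshold(v3, rule2, lay), 1L)
})

test_that("the truth-based rule reproduces generator labels exactly", {
  cfg <- synth_config(n_cases = 80, seed = 9)
  seeds <- polarcnn:::with_seed(cfg$seed,
                                sample.int(.Machine$integer.max, 80))
  for (s in seeds[1:80]) {
    case <- sample_case(cfg, s)
    expect_identical(classify_by_threshold(case), case$label)
  }
})

test_that("losslessly rendered cases classify like their truth", {
  lay <- territory_layout()
  n <- nrow(lay$segments)
  normal <- rep(3.0, n)
  img <- render_polar_map(normal, lay, size = 256)
  expect_equal(classify_image_by_threshold(img, lay), 0L)
  # one territory dropped to 1.5: clearly ischemic from the image alone
  v <- normal
  v[lay$segments$territory == "LCx"] <- 1.5
  img2 <- render_polar_map(v, lay, size = 256)
  expect_equal(classify_image_by_threshold(img2, lay), 1L)
})

test_that("overlay markings do not disturb image-based classification", {
  lay <- territory_layout()
  v <- rep(3.0, nrow(lay$segments))
  v[lay$segments$territory == "RCA"] <- 1.2
  img <- render_polar_map(v, lay, size = 256, overlays = TRUE)
  expect_equal(classify_image_by_threshold(img, lay), 1L)
})

test_that("an unrecognized palette raises an error", {
  grey <- array(0.5, c(128, 128, 3))
  expect_error(classify_image_by_threshold(grey), "palette")
})

test_that("JPEG-95 image classification agrees with truth on clear-margin cases", {
  # cases whose extreme MBF keeps >= 0.1 ml/g/min clear of the threshold;
  # the generator can clip normal minima exactly onto the threshold, so
  # zero-margin draws are excluded before the comparison
  cfg <- synth_config(n_cases = 240, normal_mbf_range = c(2.45, 3.4),
                      defect_mbf_range = c(0.8, 2.15),
                      noise_sd = 0.1, borderline_fraction = 0, seed = 33)
  ds <- synth_dataset(cfg)
  margin <- vapply(ds$truth, function(tr) {
    mn <- min(tr$values)
    if (mn < 2.3) 2.3 - mn else mn - 2.3
  }, 0)
  keep <- which(margin >= 0.1)[1:200]
  expect_false(anyNA(keep))
  dir <- withr::local_tempdir()
  agree <- vapply(keep, function(i) {
    f <- file.path(dir, "case.jpg")
    polarcnn:::write_rgb(ds$images[, , , i], f, quality = 95)
    classify_image_by_threshold(polarcnn:::read_rgb(f)) ==
      classify_by_threshold(ds$truth[[i]])
  }, TRUE)
  expect_gte(mean(agree), 0.99)
})

test_that("truth-table classification matches the per-case rule", {
  ds <- synth_dataset(synth_config(n_cases = 12, seed = 44), render_size = 64)
  res <- classify_truth(ds)
  expect_equal(res$label, ds$labels)
  # and through the exported CSV sidecar
  dir <- withr::local_tempdir()
  export_dataset(ds, dir)
  truth <- read.csv(file.path(dir, "truth.csv"))
  res2 <- classify_truth(truth)
  expect_equal(res2$label[match(ds$case_ids, res2$case_id)], ds$labels)
})
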