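# Synthetic polar-map generator: sampling, rendering, export.

test_that("configuration invariants are enforced with named errors", {
  expect_error(synth_config(defect_mbf_range = c(1, 2.5)), "defect_mbf_range")
  expect_error(synth_config(normal_mbf_range = c(2.0, 3.0)), "normal_mbf_range")
  expect_error(synth_config(ischemic_fraction = 1.2), "ischemic_fraction")
  expect_error(synth_config(ischemia_threshold = 4), "ischemia_threshold")
  expect_error(synth_config(borderline_fraction = -0.1), "borderline_fraction")
})

test_that("zero ischemic fraction yields only label-0 cases", {
  cfg <- synth_config(n_cases = 30, ischemic_fraction = 0, seed = 5)
  labs <- vapply(1:30, function(i) sample_case(cfg, i)$label, 0L)
  expect_true(all(labs == 0))
})

test_that("ischemic cases dip below the threshold; normals never do", {
  cfg <- synth_config(n_cases = 50, ischemic_fraction = 0.5, seed = 8)
  for (i in 1:50) {
    case <- sample_case(cfg, i * 13L)
    if (case$label == 1) {
      expect_lt(min(case$values), 2.3)
      expect_gt(length(case$defect_segments), 0)
      # defect is a contiguous angular arc: sectors form one circular run
      seg <- case$layout$segments[case$defect_segments, ]
      for (r in unique(seg$ring)) {
        secs <- sort(seg$sector[seg$ring == r])
        n <- case$layout$n_sectors
        flags <- rep(FALSE, n); flags[secs] <- TRUE
        runs <- rle(c(flags, flags))
        expect_equal(max(runs$lengths[runs$values]), length(secs))
      }
    } else {
      expect_gte(min(case$values), 2.3)
    }
    expect_true(all(case$values >= 0))
    expect_equal(case$label, as.integer(min(case$values) < 2.3))
  }
})

test_that("sampling is deterministic in (config, case_seed)", {
  cfg <- synth_config(seed = 3)
  a <- sample_case(cfg, 99L)
  b <- sample_case(cfg, 99L)
  expect_identical(a$values, b$values)
  expect_identical(a$label, b$label)
})

test_that("a uniform MBF field renders as one interior color plus black", {
  lay <- territory_layout()
  vals <- rep(3.0, nrow(lay$segments))
  img <- render_polar_map(vals, lay, size = 96)
  cols <- unique(matrix(img, ncol = 3), MARGIN = 1)
  expect_equal(nrow(cols), 2)
  expect_true(any(rowSums(cols) == 0))  # black background present
  # corner pixels are outside the disc -> black
  expect_equal(unname(img[1, 1, ]), c(0, 0, 0))
})

test_that("rendered color is clipped at the display maximum", {
  lay <- territory_layout()
  a <- render_polar_map(rep(3.5, nrow(lay$segments)), lay, size = 64)
  b <- render_polar_map(rep(5.0, nrow(lay$segments)), lay, size = 64)
  expect_identical(a, b)
})

test_that("rendering rejects an empty segment grid", {
  expect_error(render_polar_map(numeric(0), territory_layout(), size = 64),
               "empty segment grid")
})

test_that("interior pixel colors follow the rainbow LUT of the local segment", {
  lay <- territory_layout()
  vals <- seq(0.2, 3.4, length.out = nrow(lay$segments))
  img <- render_polar_map(vals, lay, size = 128, blend_deg = 0)
  # sample one interior pixel per ring-1 segment centre
  seg <- lay$segments
  mid <- seg[seg$ring == 1, ]
  for (k in seq_len(nrow(mid))) {
    th <- (mid$ang_lo[k] + mid$ang_hi[k]) / 2 * pi / 180
    r <- (mid$rad_lo[k] + mid$rad_hi[k]) / 2
    x <- r * sin(th); y <- r * cos(th)
    col <- round((x + 1) / 2 * 128 + 0.5); row <- round((1 - y) / 2 * 128 + 0.5)
    got <- img[row, col, ] / 255
    want <- as.numeric(mbf_to_rgb(vals[mid$segment_id[k]]))
    expect_lt(max(abs(got - want)), 2 / 255)
  }
})

test_that("the dataset is a pure function of its configuration", {
  cfg <- synth_config(n_cases = 4, seed = 17)
  a <- synth_dataset(cfg, render_size = 64)
  b <- synth_dataset(cfg, render_size = 64)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
})

test_that("realized class balance stays within binomial 99% bounds", {
  cfg <- synth_config(n_cases = 120, ischemic_fraction = 0.4, seed = 23)
  seeds <- polarcnn:::with_seed(cfg$seed,
                                sample.int(.Machine$integer.max, 120))
  labs <- vapply(seeds, function(s) sample_case(cfg, s)$label, 0L)
  bounds <- qbinom(c(0.005, 0.995), 120, 0.4)
  expect_gte(sum(labs), bounds[1])
  expect_lte(sum(labs), bounds[2])
})

test_that("export writes JPEGs, label sidecars, truth and manifest", {
  dir <- withr::local_tempdir()
  ds <- synth_dataset(synth_config(n_cases = 10, seed = 31), render_size = 96)
  manifest <- export_dataset(ds, dir, jpeg_quality = 95)
  expect_equal(nrow(manifest), 10)
  expect_length(list.files(dir, pattern = "\\.jpg$"), 10)
  expect_length(list.files(dir, pattern = "\\.txt$"), 10)
  # label sidecar content round-trips, ischemic cases hold exactly "1"
  for (i in seq_len(10)) {
    lab_path <- file.path(dir, manifest$label_file[i])
    expect_identical(readLines(lab_path), as.character(ds$labels[i]))
    expect_equal(read_label(lab_path), ds$labels[i])
  }
  # truth sidecar reproduces the generated segmental MBF
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 10 * nrow(ds$layout$segments))
  one <- truth[truth$case_id == ds$case_ids[3], ]
  expect_equal(one$mbf[order(one$segment_id)], unname(ds$truth[[3]]$values))
  # label consistency is assertable from the persisted truth alone
  mins <- tapply(truth$mbf, truth$case_id, min)
  expect_equal(unname(as.integer(mins[ds$case_ids] < 2.3)), ds$labels)
})

test_that("territory layout partitions the bullseye", {
  lay <- territory_layout()
  seg <- lay$segments
  expect_setequal(unique(seg$territory), c("apex", "LAD", "LCx", "RCA"))
  # angular spans partition [0, 360) within each ring
  for (r in unique(seg$ring)) {
    sr <- seg[seg$ring == r, ]
    sr <- sr[order(sr$ang_lo), ]
    expect_equal(sr$ang_lo[1], 0)
    expect_equal(sr$ang_hi[nrow(sr)], 360)
    if (nrow(sr) > 1) expect_equal(sr$ang_lo[-1], sr$ang_hi[-nrow(sr)])
  }
  # radial spans partition (apex_radius, 1] over the annulus rings
  ann <- unique(seg[seg$ring > 0, c("ring", "rad_lo", "rad_hi")])
  ann <- ann[order(ann$ring), ]
  expect_equal(ann$rad_lo[1], lay$apex_radius)
  expect_equal(ann$rad_hi[nrow(ann)], 1)
  expect_equal(ann$rad_lo[-1], ann$rad_hi[-nrow(ann)])
  # every outer-ring territory is one of the coronary arteries
  expect_setequal(unique(seg$territory[seg$ring > 0]), c("LAD", "LCx", "RCA"))
})
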