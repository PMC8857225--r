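# Shared fixtures, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Well-separated classes: defect MBF <= 2.0, normal >= 2.8 (easy to learn).
easy_config <- function(n_cases, seed, ischemic_fraction = 0.45) {
  synth_config(n_cases = n_cases, ischemic_fraction = ischemic_fraction,
               normal_mbf_range = c(2.8, 3.4),
               defect_mbf_range = c(0.8, 2.0),
               noise_sd = 0.15, borderline_fraction = 0, seed = seed)
}

# 150 easy cases rendered at 256, with images scaled to [0, 1].
easy150 <- function() fixture("easy150", function() {
  ds <- synth_dataset(easy_config(150, seed = 411))
  list(x = ds$images / 255, labels = ds$labels, case_ids = ds$case_ids,
       truth = ds$truth, dataset = ds)
})

# 60 easy cases for the scaled-down stability protocol.
easy60 <- function() fixture("easy60", function() {
  ds <- synth_dataset(easy_config(60, seed = 611))
  list(x = ds$images / 255, labels = ds$labels, case_ids = ds$case_ids,
       dataset = ds)
})

# One canonical full-length training run on the easy 150-case split,
# shared between the CNN unit tests and the end-to-end recoverability check.
easy_fit <- function() fixture("easy_fit", function() {
  d <- easy150()
  sp <- split_dataset(d$case_ids, seed = 5)
  idx <- function(ids) match(ids, d$case_ids)
  fit <- ischemia_cnn(d$x[, , , idx(sp$train_ids)],
                      d$labels[idx(sp$train_ids)],
                      d$x[, , , idx(sp$val_ids)],
                      d$labels[idx(sp$val_ids)],
                      config = cnn_config(), seed = 3)
  list(fit = fit, split = sp, idx = idx)
})

# Hand-built run ensemble (bypasses training) for category-assignment rules.
fake_ensemble <- function(predictions, reference) {
  structure(list(predictions = predictions, reference_labels = reference,
                 run_seeds = seq_len(nrow(predictions)),
                 histories = NULL,
                 test_ids = colnames(predictions)),
            class = "run_ensemble")
}
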