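#' Repeated-training stability protocol
#'
#' Trains the CNN from scratch `n_runs` times, varying only the seed (run
#' i uses `base_seed + i`), and predicts the frozen hold-out test set after
#' each run. Train/validation membership stays fixed by default; set
#' `resample_split = TRUE` to re-draw the train/validation partition each
#' run from the run seed (the test set always stays frozen).
#'
#' @param dataset A `polarmap_dataset` ([synth_dataset()]) or a list with
#'   `x` (`size x size x 3 x n` array in `[0, 1]`), `labels`, `case_ids`.
#'   `polarmap_dataset` images are preprocessed automatically.
#' @param split A [split_dataset()] result over the dataset's case ids.
#' @param config A [cnn_config()].
#' @param n_runs Number of repeated runs; default 100.
#' @param base_seed Base seed; run i uses `base_seed + i`.
#' @param resample_split Re-draw train/validation membership per run.
#' @return An object of class `run_ensemble`: list with `predictions`
#'   (`n_runs x n_test` 0/1 matrix, columns named by test case id),
#'   `reference_labels`, `run_seeds` and `histories`.
#' @export
run_protocol <- function(dataset, split, config = cnn_config(),
                         n_runs = 100L, base_seed = 0L,
                         resample_split = FALSE) {
  stopifnot(inherits(split, "split_spec"), n_runs >= 1)
  ds <- as_training_data(dataset, config$input_size)
  idx <- function(ids) match(ids, ds$case_ids)
  test_i <- idx(split$test_ids)
  if (anyNA(test_i)) stop("split test ids not found in dataset")
  test_x <- ds$x[, , , test_i, drop = FALSE]
  ref <- ds$labels[test_i]
  preds <- matrix(NA_integer_, n_runs, length(test_i),
                  dimnames = list(NULL, split$test_ids))
  run_seeds <- base_seed + seq_len(n_runs)
  histories <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    pool_split <- split
    if (resample_split) {
      pool <- c(split$train_ids, split$val_ids)
      n_train <- length(split$train_ids)
      pool_split$train_ids <- with_seed(run_seeds[r] * 2L + 1L,
                                        sort(sample(pool, n_train)))
      pool_split$val_ids <- sort(setdiff(pool, pool_split$train_ids))
    }
    tr_i <- idx(pool_split$train_ids)
    va_i <- idx(pool_split$val_ids)
    fit <- try(ischemia_cnn(ds$x[, , , tr_i, drop = FALSE], ds$labels[tr_i],
                            ds$x[, , , va_i, drop = FALSE], ds$labels[va_i],
                            config = config, seed = run_seeds[r]),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("protocol aborted at run ", r, ": ", attr(fit, "condition")$message)
    preds[r, ] <- predict(fit, test_x)
    histories[[r]] <- fit$history
  }
  structure(list(predictions = preds, reference_labels = ref,
                 run_seeds = run_seeds, histories = histories,
                 test_ids = split$test_ids),
            class = "run_ensemble")
}

# Accept either a polarmap_dataset (raw 0-255 renders) or a prepared list.
as_training_data <- function(dataset, input_size) {
  if (inherits(dataset, "polarmap_dataset")) {
    d <- dim(dataset$images)
    n <- d[4]
    x <- array(0, dim = c(input_size, input_size, 3, n))
    for (i in seq_len(n))
      x[, , , i] <- preprocess(dataset$images[, , , i], input_size)
    list(x = x, labels = dataset$labels, case_ids = dataset$case_ids)
  } else {
    stopifnot(is.list(dataset), !is.null(dataset$x), !is.null(dataset$labels))
    dataset
  }
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("Run ensemble: %d runs x %d test subjects\n",
              nrow(x$predictions), ncol(x$predictions)))
  acc <- rowMeans(sweep(x$predictions, 2, x$reference_labels, "==") * 1)
  cat(sprintf("  per-run accuracy: median %.4f (IQR %.4f)\n",
              median(acc), stats::IQR(acc)))
  invisible(x)
}

#' Majority-vote confusion-category assignment
#'
#' Assigns each test subject to the confusion-matrix category (TP, TN, FP,
#' FN) it falls into in strictly more than `threshold_count` of the runs;
#' subjects with no category above the threshold stay `"unassigned"`. With
#' the defaults (100 runs, threshold 50) this is the "over 50 times out of
#' 100 runs" rule; an exact 50/50 split is unassigned.
#'
#' @param ensemble A [run_protocol()] result.
#' @param threshold_count Strict lower bound on the category count;
#'   defaults to half the number of runs.
#' @return An object of class `category_assignment`: data frame with
#'   `case_id`, `reference`, counts of the two reachable categories, and
#'   `category`.
#' @export
assign_categories <- function(ensemble,
                              threshold_count = nrow(ensemble$predictions) / 2) {
  stopifnot(inherits(ensemble, "run_ensemble"),
            nrow(ensemble$predictions) >= 1)
  preds <- ensemble$predictions
  ref <- ensemble$reference_labels
  n_sub <- ncol(preds)
  cat_of <- function(pred, truth) {
    if (truth == 1) ifelse(pred == 1, "TP", "FN")
    else ifelse(pred == 1, "FP", "TN")
  }
  rows <- lapply(seq_len(n_sub), function(j) {
    cats <- cat_of(preds[, j], ref[j])
    tab <- table(factor(cats, levels = c("TP", "TN", "FP", "FN")))
    top <- names(tab)[which.max(tab)]
    assigned <- if (max(tab) > threshold_count) top else "unassigned"
    data.frame(case_id = colnames(preds)[j], reference = ref[j],
               n_tp = tab[["TP"]], n_tn = tab[["TN"]],
               n_fp = tab[["FP"]], n_fn = tab[["FN"]],
               category = assigned)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("category_assignment", "data.frame"))
}
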