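#' Configuration for resampled model evaluation
#'
#' The validation protocol: `n_iterations` independent random splits into a
#' training fraction and a held-out test fraction (default 1000 x 75/25),
#' with every metric reported as the mean over iterations and the R-squared
#' uncertainty as a 95% percentile interval of the per-iteration values.
#' Classification splits are stratified by age group by default so no
#' training fold loses a class under the imbalance typical of pooled public
#' data. A bootstrap mode (train drawn with replacement, out-of-bag test) is
#' available behind `bootstrap = TRUE`.
#'
#' @param task `"regression"` (predict age) or `"classification"` (predict
#'   Young/Middle/Old).
#' @param n_iterations Number of resampling iterations (default 1000).
#' @param train_fraction Fraction of samples used for training (default 0.75).
#' @param seed Integer seed driving all splits and seeded model internals.
#' @param model Model name or custom contract, see [age_model()].
#' @param stratify Stratify splits by age group; defaults to `TRUE` for
#'   classification, `FALSE` for regression.
#' @param bootstrap Draw the training set with replacement instead of
#'   partitioning.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(task = c("regression", "classification"),
                        n_iterations = 1000, train_fraction = 0.75,
                        seed = 1, model = "xgboost",
                        stratify = NULL, bootstrap = FALSE) {
  task <- match.arg(task)
  check_positive_int(n_iterations, "n_iterations")
  check_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_fraction", "must be strictly between 0 and 1")
  }
  structure(list(task = task, n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 model = model,
                 stratify = stratify %||% (task == "classification"),
                 bootstrap = isTRUE(bootstrap)),
            class = "eval_config")
}

#' Draw one train/test split
#'
#' Partitions `1:n_samples` into a training set of size
#' `round(train_fraction * n_samples)` and the complementary test set, using
#' the current RNG state. With `strata`, training slots are allocated across
#' strata by largest remainder so every non-empty stratum keeps at least one
#' training sample; allocation failures are retried and raised after 100
#' attempts. With `bootstrap = TRUE` the training set is drawn with
#' replacement and the test set is the out-of-bag remainder.
#'
#' @param n_samples Number of samples (>= 4).
#' @param train_fraction Training fraction in (0, 1).
#' @param strata Optional factor of length `n_samples` (age groups).
#' @param bootstrap Sample the training set with replacement.
#' @return List with integer vectors `train` and `test`; without bootstrap
#'   they are disjoint and exhaustive.
#' @export
resample_split <- function(n_samples, train_fraction = 0.75, strata = NULL,
                           bootstrap = FALSE) {
  if (n_samples < 4) stop_validation("resampling needs at least 4 samples")
  n_train <- round(train_fraction * n_samples)
  if (n_train < 1 || n_train >= n_samples) {
    stop_validation("train fraction leaves an empty train or test set")
  }
  if (bootstrap) {
    train <- sort(sample.int(n_samples, n_train, replace = TRUE))
    return(list(train = train, test = setdiff(seq_len(n_samples), unique(train))))
  }
  if (is.null(strata)) {
    train <- sort(sample.int(n_samples, n_train))
    return(list(train = train, test = setdiff(seq_len(n_samples), train)))
  }
  strata <- as.factor(strata)
  if (length(strata) != n_samples) stop_validation("`strata` length must equal n_samples")
  for (attempt in seq_len(100)) {
    alloc <- allocate_stratified(table(droplevels(strata)), n_train)
    if (!is.null(alloc)) {
      train <- sort(unlist(lapply(names(alloc), function(lv) {
        idx <- which(strata == lv)
        if (alloc[[lv]] == length(idx)) idx else idx[sample.int(length(idx), alloc[[lv]])]
      }), use.names = FALSE))
      return(list(train = train, test = setdiff(seq_len(n_samples), train)))
    }
  }
  stop_validation("could not allocate a stratified split keeping every class in training")
}

# largest-remainder allocation of n_train over strata, >=1 per non-empty
# stratum and never the whole stratum unless unavoidable; NULL on failure
allocate_stratified <- function(counts, n_train) {
  k <- length(counts)
  if (n_train < k) return(NULL)
  exact <- n_train * counts / sum(counts)
  base <- pmax(1L, floor(exact))
  base <- pmin(base, as.integer(counts))
  rem <- n_train - sum(base)
  if (rem < 0) {
    for (i in order(base, decreasing = TRUE)) {
      if (rem == 0) break
      give <- min(base[i] - 1L, -rem)
      base[i] <- base[i] - give; rem <- rem + give
    }
  } else if (rem > 0) {
    room <- as.integer(counts) - base
    for (i in order(exact - floor(exact), decreasing = TRUE)) {
      if (rem == 0) break
      give <- min(room[i], rem)
      base[i] <- base[i] + give; rem <- rem - give
    }
  }
  if (rem != 0 || any(base < 1)) return(NULL)
  as.list(setNames(as.integer(base), names(counts)))
}

#' Resampled age regression for a gene feature set
#'
#' For each iteration: draw a fresh train/test split, fit the model on the
#' training samples' log-CPM features, predict the held-out samples' ages,
#' and score R-squared (relative to the test-set mean; negative values are
#' possible and meaningful), mean squared error, and mean and median
#' absolute error. Iterations whose test set is degenerate (fewer than two
#' samples, or constant test ages) are skipped and counted.
#'
#' @param ds A [count_dataset()] (already expression-filtered).
#' @param factors Normalization factors from [norm_factors()]; features are
#'   the corresponding log-CPM values, computed once globally.
#' @param feature_set Character vector of gene ids to use as features.
#' @param cfg An [eval_config()] with `task = "regression"`.
#' @return An object of class `age_eval` carrying the per-iteration metric
#'   tibble (see [tidy.age_eval()]) and summary statistics (see
#'   [glance.age_eval()]).
#' @export
evaluate_regression <- function(ds, factors, feature_set,
                                cfg = eval_config("regression")) {
  stopifnot(cfg$task == "regression")
  run_harness(ds, factors, feature_set, cfg)
}

#' Resampled age-group classification for a gene feature set
#'
#' As [evaluate_regression()], but the target is the Young/Middle/Old age
#' group, metrics are accuracy and macro-averaged F1, precision and recall,
#' and a 3x3 confusion matrix (rows = true group) is accumulated over
#' iterations and reported as its mean.
#'
#' @inheritParams evaluate_regression
#' @param cfg An [eval_config()] with `task = "classification"`.
#' @return An `age_eval` object; its `confusion` element is the mean
#'   confusion matrix.
#' @export
evaluate_classification <- function(ds, factors, feature_set,
                                    cfg = eval_config("classification")) {
  stopifnot(cfg$task == "classification")
  run_harness(ds, factors, feature_set, cfg)
}

run_harness <- function(ds, factors, feature_set, cfg) {
  stopifnot(inherits(ds, "count_dataset"))
  unknown <- setdiff(feature_set, gene_ids(ds))
  if (length(unknown) > 0) {
    stop_validation(paste0("feature gene(s) absent from dataset: ",
                           paste(head(unknown, 5), collapse = ", ")))
  }
  nm <- log_cpm(ds, factors)
  x <- t(nm$values[feature_set, , drop = FALSE])
  classify <- cfg$task == "classification"
  y <- if (classify) sample_age_groups(ds) else ds$samples$age
  if (!classify && length(unique(y)) < 2) stop_validation("need >=2 distinct ages")
  strata <- if (cfg$stratify) sample_age_groups(ds) else NULL
  model <- age_model(cfg$model, cfg$task)
  n <- nrow(x)

  set.seed(cfg$seed)
  iter_seeds <- sample.int(2^31 - 1, cfg$n_iterations)
  rows <- vector("list", cfg$n_iterations)
  confusion <- matrix(0, 3, 3, dimnames = list(true = levels(sample_age_groups(ds)),
                                               predicted = levels(sample_age_groups(ds))))
  n_skipped <- 0L

  for (i in seq_len(cfg$n_iterations)) {
    set.seed(iter_seeds[i])
    split <- resample_split(n, cfg$train_fraction, strata = strata,
                            bootstrap = cfg$bootstrap)
    y_test <- y[split$test]
    degenerate <- length(split$test) < 2 ||
      (!classify && sd(as.numeric(y_test)) == 0)
    if (degenerate) { n_skipped <- n_skipped + 1L; next }
    state <- model$fit(x[split$train, , drop = FALSE],
                       if (classify) droplevels(y[split$train]) else y[split$train])
    pred <- model$predict(state, x[split$test, , drop = FALSE])
    split_hash <- rlang::hash(split)
    if (classify) {
      pred <- factor(as.character(pred), levels = levels(y))
      cm <- table(true = y_test, predicted = pred)
      confusion <- confusion + cm
      m <- macro_metrics(cm)
      rows[[i]] <- tibble(iteration = i, accuracy = m["accuracy"],
                          f1 = m["f1"], precision = m["precision"],
                          recall = m["recall"], n_test = length(split$test),
                          split_hash = split_hash)
    } else {
      err <- as.numeric(pred) - y_test
      ss_tot <- sum((y_test - mean(y_test))^2)
      rows[[i]] <- tibble(iteration = i, r2 = 1 - sum(err^2) / ss_tot,
                          mse = mean(err^2), mean_ae = mean(abs(err)),
                          median_ae = median(abs(err)),
                          n_test = length(split$test), split_hash = split_hash)
    }
  }
  iters <- bind_rows(rows)
  n_done <- nrow(iters)
  structure(list(task = cfg$task, iterations = iters, config = cfg,
                 n_features = length(feature_set), n_samples = n,
                 n_skipped = n_skipped,
                 confusion = if (classify && n_done > 0) confusion / n_done),
            class = "age_eval")
}

# macro-averaged classification metrics from one confusion matrix;
# classes never predicted contribute precision 0 (zero-division convention)
macro_metrics <- function(cm) {
  cm <- as.matrix(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) == 0, 0, tp / colSums(cm))
  rec <- ifelse(rowSums(cm) == 0, NA_real_, tp / rowSums(cm))
  rec_m <- mean(rec, na.rm = TRUE)
  f1 <- ifelse(prec + rec == 0 | is.na(rec), 0, 2 * prec * rec / (prec + rec))
  present <- !is.na(rec)
  c(accuracy = sum(tp) / sum(cm), precision = mean(prec[present]),
    recall = rec_m, f1 = mean(f1[present]))
}

#' @export
print.age_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<age_eval> %s, %d features, %d iterations (%d skipped)\n",
              x$task, x$n_features, nrow(x$iterations), x$n_skipped))
  print(g)
  invisible(x)
}

#' Per-iteration metrics of a resampled evaluation
#'
#' @param x An `age_eval` object.
#' @param ... Unused.
#' @return A tibble with one row per completed iteration.
#' @export
tidy.age_eval <- function(x, ...) x$iterations

#' One-row summary of a resampled evaluation
#'
#' Means of each stored per-iteration metric, plus for regression the 95%
#' percentile interval of the R-squared values (2.5th and 97.5th
#' percentiles across iterations).
#'
#' @param x An `age_eval` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.age_eval <- function(x, ...) {
  it <- x$iterations
  if (x$task == "regression") {
    tibble(mean_r2 = mean(it$r2), mean_mse = mean(it$mse),
           mean_mean_ae = mean(it$mean_ae), mean_median_ae = mean(it$median_ae),
           r2_ci_low = quantile(it$r2, 0.025, names = FALSE),
           r2_ci_high = quantile(it$r2, 0.975, names = FALSE),
           n_iterations = nrow(it), n_skipped = x$n_skipped)
  } else {
    tibble(mean_accuracy = mean(it$accuracy), mean_f1 = mean(it$f1),
           mean_precision = mean(it$precision), mean_recall = mean(it$recall),
           n_iterations = nrow(it), n_skipped = x$n_skipped)
  }
}

#' Evaluate several feature sets under identical splits
#'
#' Runs the harness once per named gene list with the same seed, so every
#' row is built from the same sequence of train/test splits and rows are
#' directly comparable (the paired design is verifiable through the stored
#' split hashes). This is how "all genes vs top-k vs conserved set" tables
#' are produced.
#'
#' @param ds,factors,cfg As in [evaluate_regression()].
#' @param sets Named list of gene-id character vectors.
#' @return A tibble with one row per feature set: the [glance.age_eval()]
#'   summary plus `feature_set` and `n_genes`. The underlying `age_eval`
#'   objects are attached as the `evals` attribute.
#' @export
compare_feature_sets <- function(ds, factors, sets, cfg) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  evals <- lapply(sets, function(fs) run_harness(ds, factors, fs, cfg))
  out <- purrr::imap(evals, function(ev, nm) {
    dplyr::bind_cols(tibble(feature_set = nm, n_genes = ev$n_features), glance(ev))
  })
  out <- bind_rows(out)
  attr(out, "evals") <- evals
  out
}
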