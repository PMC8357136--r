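eval_fixture <- function(seed = 1, n = 40, n_genes = 30) {
  set.seed(seed)
  ages <- round(runif(n, 5, 90))
  base <- matrix(rnbinom(n_genes * n, mu = 200, size = 8), n_genes, n)
  # plant a clean age signal in the first third of the genes
  for (g in seq_len(n_genes %/% 3)) {
    base[g, ] <- rpois(n, 50 + 4 * ages)
  }
  dimnames(base) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n)))
  tiny_dataset(base, ages = ages,
               study = rep(c("st1", "st2"), length.out = n))
}

test_that("splits partition samples at the requested fraction, reproducibly", {
  set.seed(1)
  sp <- resample_split(8, 0.75)
  expect_equal(length(sp$train), 6)
  expect_equal(length(sp$test), 2)
  expect_equal(sort(c(sp$train, sp$test)), 1:8)

  set.seed(99); a <- resample_split(40, 0.75)
  set.seed(99); b <- resample_split(40, 0.75)
  set.seed(100); c <- resample_split(40, 0.75)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(resample_split(3, 0.75), "at least 4")
})

test_that("every sample is held out about a quarter of the time", {
  n <- 40; iters <- 1000
  freq <- numeric(n)
  set.seed(7)
  for (i in seq_len(iters)) {
    held_out <- resample_split(n, 0.75)$test
    freq[held_out] <- freq[held_out] + 1
  }
  p <- freq / iters
  se <- sqrt(0.25 * 0.75 / iters)  # 5-sigma slack
  expect_true(all(abs(p - 0.25) < 5 * se))
})

test_that("stratified splits keep every age group in training", {
  strata <- factor(rep(c("Young", "Middle", "Old"), c(30, 4, 6)))
  set.seed(3)
  for (i in 1:50) {
    sp <- resample_split(40, 0.75, strata = strata)
    expect_equal(length(sp$train), 30)
    expect_setequal(as.character(unique(strata[sp$train])),
                    c("Young", "Middle", "Old"))
  }
})

test_that("bootstrap mode draws training samples with replacement", {
  set.seed(11)
  reps <- replicate(50, {
    sp <- resample_split(20, 0.75, bootstrap = TRUE)
    c(dup = anyDuplicated(sp$train) > 0,
      disjoint = length(intersect(unique(sp$train), sp$test)) == 0)
  })
  expect_true(any(reps["dup", ]))
  expect_true(all(reps["disjoint", ]))
})

test_that("an oracle regressor scores R2 = 1 and zero error every iteration", {
  ds <- eval_fixture()
  fac <- norm_factors(ds, "none")
  cfg <- eval_config("regression", n_iterations = 20, seed = 5,
                     model = oracle_regressor(ds$samples$age, sample_ids(ds)))
  rep <- evaluate_regression(ds, fac, gene_ids(ds), cfg)
  it <- tidy(rep)
  expect_true(all(it$r2 == 1))
  expect_true(all(it$median_ae == 0))
})

test_that("a train-mean regressor has non-positive mean R2", {
  ds <- eval_fixture()
  cfg <- eval_config("regression", n_iterations = 200, seed = 6,
                     model = train_mean_regressor)
  rep <- evaluate_regression(ds, norm_factors(ds, "none"), gene_ids(ds), cfg)
  expect_lte(glance(rep)$mean_r2, 0)
})

test_that("summaries are exact arithmetic means and percentile CIs of stored iterations", {
  ds <- eval_fixture()
  cfg <- eval_config("regression", n_iterations = 50, seed = 2)
  rep <- evaluate_regression(ds, norm_factors(ds, "none"),
                             gene_ids(ds)[1:10], cfg)
  it <- tidy(rep); g <- glance(rep)
  expect_identical(g$mean_r2, mean(it$r2))
  expect_identical(g$mean_mse, mean(it$mse))
  expect_identical(g$mean_median_ae, mean(it$median_ae))
  expect_identical(g$r2_ci_low, quantile(it$r2, 0.025, names = FALSE))
  expect_identical(g$r2_ci_high, quantile(it$r2, 0.975, names = FALSE))
  expect_gte(g$r2_ci_low, min(it$r2))
  expect_lte(g$r2_ci_high, max(it$r2))
  expect_lte(g$r2_ci_low, g$r2_ci_high)
})

test_that("the harness is deterministic given the config seed", {
  ds <- eval_fixture()
  cfg <- eval_config("regression", n_iterations = 10, seed = 42)
  r1 <- evaluate_regression(ds, norm_factors(ds, "none"), gene_ids(ds)[1:8], cfg)
  r2 <- evaluate_regression(ds, norm_factors(ds, "none"), gene_ids(ds)[1:8], cfg)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("an oracle classifier is perfect and its mean confusion matrix diagonal", {
  ds <- eval_fixture()
  groups <- sample_age_groups(ds)
  cfg <- eval_config("classification", n_iterations = 25, seed = 8,
                     model = oracle_classifier(groups, sample_ids(ds)))
  rep <- evaluate_classification(ds, norm_factors(ds, "none"), gene_ids(ds), cfg)
  it <- tidy(rep)
  expect_true(all(it$accuracy == 1))
  expect_true(all(it$f1 == 1))
  cm <- rep$confusion
  expect_equal(sum(cm) - sum(diag(cm)), 0)
})

test_that("majority-class accuracy sits near the largest class share", {
  ds <- eval_fixture(seed = 3, n = 48)
  cfg <- eval_config("classification", n_iterations = 200, seed = 9,
                     model = "majority_baseline")
  rep <- evaluate_classification(ds, norm_factors(ds, "none"), gene_ids(ds), cfg)
  share <- max(table(sample_age_groups(ds))) / ncol(ds$counts)
  expect_lt(abs(glance(rep)$mean_accuracy - share), 0.08)
})

test_that("confusion totals equal test-set sizes per iteration and on average", {
  ds <- eval_fixture()
  cfg <- eval_config("classification", n_iterations = 30, seed = 4)
  rep <- evaluate_classification(ds, norm_factors(ds, "none"),
                                 gene_ids(ds)[1:10], cfg)
  it <- tidy(rep)
  expect_equal(sum(rep$confusion), mean(it$n_test))
})

test_that("harness agrees with an independently coded evaluation loop", {
  ds <- eval_fixture(seed = 10)
  fac <- norm_factors(ds, "none")
  features <- gene_ids(ds)[1:12]
  cfg <- eval_config("regression", n_iterations = 40, seed = 123,
                     model = "linear")
  rep <- evaluate_regression(ds, fac, features, cfg)

  # independent loop: same seed protocol, naive lm formula interface
  nm <- log_cpm(ds, fac)
  x <- t(nm$values[features, ])
  y <- ds$samples$age
  set.seed(123)
  iter_seeds <- sample.int(2^31 - 1, 40)
  r2 <- numeric(40)
  for (i in 1:40) {
    set.seed(iter_seeds[i])
    train <- sort(sample.int(nrow(x), round(0.75 * nrow(x))))
    test <- setdiff(seq_len(nrow(x)), train)
    df <- as.data.frame(x)
    fit <- stats::lm(y[train] ~ ., data = df[train, ])
    pred <- predict(fit, newdata = df[test, ])
    r2[i] <- 1 - sum((pred - y[test])^2) / sum((y[test] - mean(y[test]))^2)
  }
  expect_equal(glance(rep)$mean_r2, mean(r2), tolerance = 1e-8)
})

test_that("compare_feature_sets pairs rows through identical split sequences", {
  ds <- eval_fixture()
  fac <- norm_factors(ds, "none")
  cfg <- eval_config("regression", n_iterations = 15, seed = 77, model = "linear")
  tab <- compare_feature_sets(ds, fac,
                              list(setA = gene_ids(ds)[1:10],
                                   also_setA = gene_ids(ds)[1:10],
                                   other = gene_ids(ds)[11:20]), cfg)
  expect_equal(tab$mean_r2[1], tab$mean_r2[2])
  evals <- attr(tab, "evals")
  h <- lapply(evals, function(e) tidy(e)$split_hash)
  expect_identical(h$setA, h$other)
})

test_that("unknown feature ids are refused by name", {
  ds <- eval_fixture()
  expect_error(evaluate_regression(ds, norm_factors(ds, "none"),
                                   c("g001", "nope"),
                                   eval_config("regression", n_iterations = 2)),
               "nope")
})

test_that("the R2 confidence interval narrows as iterations grow", {
  widths <- vapply(c(100, 1000), function(ni) {
    ws <- vapply(1:5, function(s) {
      ds <- eval_fixture(seed = s)
      cfg <- eval_config("regression", n_iterations = ni, seed = s,
                         model = "linear")
      g <- glance(evaluate_regression(ds, norm_factors(ds, "none"),
                                      gene_ids(ds)[1:10], cfg))
      g$r2_ci_high - g$r2_ci_low
    }, numeric(1))
    median(ws)
  }, numeric(1))
  expect_lte(widths[2], widths[1] * 1.15)
})
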