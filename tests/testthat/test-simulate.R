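test_that("identical configs give identical datasets, different seeds differ", {
  s1 <- simulate_dataset(small_sim_config(seed = 11))
  s2 <- simulate_dataset(small_sim_config(seed = 11))
  s3 <- simulate_dataset(small_sim_config(seed = 12))
  expect_identical(s1, s2)
  expect_false(identical(s1$dataset_a$counts, s3$dataset_a$counts))
})

test_that("no planted signal leaves correlations centred at zero and truth empty", {
  sim <- simulate_dataset(small_sim_config(seed = 5, n_conserved_pairs = 0,
                                           n_private_aging_a = 0,
                                           n_private_aging_b = 0,
                                           effect_size = 0))
  expect_equal(nrow(sim$truth), 0)
  nm <- log_cpm(sim$dataset_a, norm_factors(sim$dataset_a, "none"))
  r <- correlate_with_age(nm)$r
  expect_lt(abs(mean(r)), 0.05)
  # null correlations at n = 30 have sd ~ 1/sqrt(29); no real signal present
  expect_lt(mean(abs(r)), 0.2)
  expect_true(all(abs(r) < 0.8))
})

test_that("degenerate noise model gives Poisson counts at the baseline mean", {
  cfg <- small_sim_config(seed = 9, dispersion = 0, study_logsize_sd = 0,
                          sample_logsize_sd = 0, gene_study_sd = 0,
                          effect_size = 0, n_conserved_pairs = 0,
                          n_private_aging_a = 0, n_private_aging_b = 0,
                          baseline_logmean_range = c(5, 8))
  sim <- simulate_dataset(cfg)
  counts <- sim$dataset_a$counts
  # per-gene sample mean within ~4 SE of the (unknown but bounded) Poisson
  # mean; check via variance ~= mean, the Poisson signature
  ratio <- apply(counts, 1, var) / rowMeans(counts)
  expect_lt(abs(median(ratio) - 1), 0.15)
  # and mean counts live inside the configured baseline range (4 SE slack)
  se <- sqrt(rowMeans(counts) / ncol(counts))
  expect_true(all(rowMeans(counts) > 2^5 - 4 * se))
  expect_true(all(rowMeans(counts) < 2^8 + 4 * se))
})

test_that("overdispersion shows up as variance exceeding the mean", {
  sim <- simulate_dataset(small_sim_config(seed = 2, dispersion = 0.3,
                                           study_logsize_sd = 0,
                                           sample_logsize_sd = 0,
                                           gene_study_sd = 0))
  counts <- sim$dataset_a$counts
  high <- rowMeans(counts) > 50
  expect_gte(sum(high), 100)
  v <- apply(counts[high, ], 1, var)
  expect_gt(mean(v > rowMeans(counts[high, ])), 0.95)
})

test_that("median planted-gene |r| increases strictly with effect size", {
  med_r <- vapply(c(0.1, 0.3, 0.6), function(e) {
    per_seed <- vapply(1:20, function(s) {
      sim <- simulate_dataset(small_sim_config(seed = s, effect_size = e))
      nm <- log_cpm(sim$dataset_a, norm_factors(sim$dataset_a, "none"))
      tab <- correlate_with_age(nm)
      planted <- sim$truth$gene_id[sim$truth$species == "human"]
      median(tab$abs_r[tab$gene_id %in% planted])
    }, numeric(1))
    median(per_seed)
  }, numeric(1))
  expect_true(all(diff(med_r) > 0))
})

test_that("study depth regimes separate raw medians and TMM pulls them back", {
  sim <- simulate_dataset(small_sim_config(seed = 3, study_logsize_sd = 1))
  ds <- filter_expressed(sim$dataset_a)
  lmed <- tapply(seq_len(ncol(ds$counts)), ds$samples$study_id,
                 function(i) median(log2(ds$counts[, i] + 0.5)))
  expect_gt(max(lmed) - min(lmed), 0.5)
  raw <- study_effect_score(raw_log_counts(ds))
  tmm <- study_effect_score(log_cpm(ds, tmm_factors(ds)))
  expect_lt(tmm, raw)
})

test_that("planted slopes are half positive half negative and shared across species", {
  sim <- simulate_dataset(small_sim_config(seed = 7))
  cons <- sim$truth[sim$truth$role == "conserved", ]
  a <- cons[cons$species == "human", ]
  b <- cons[cons$species == "fly", ]
  expect_equal(sum(a$slope > 0), sum(a$slope < 0))
  expect_equal(sign(a$slope), sign(b$slope[match(a$partner, b$gene_id)]))
})

test_that("decoy ortholog rows never outscore true pairs", {
  sim <- simulate_dataset(small_sim_config(seed = 4, ortholog_noise = 0.6))
  cons <- sim$truth[sim$truth$role == "conserved" & sim$truth$species == "human", ]
  true_key <- paste(cons$gene_id, cons$partner)
  is_true <- paste(sim$orthologs$gene_id_a, sim$orthologs$gene_id_b) %in% true_key
  expect_gt(sum(!is_true), 0)  # decoys present
  expect_lt(max(sim$orthologs$score[!is_true]), min(sim$orthologs$score[is_true]))
})

test_that("fixtures round-trip bit-exactly and reject corrupted counts", {
  sim <- simulate_dataset(small_sim_config(seed = 6))
  dir <- withr::local_tempdir()
  files <- write_fixture(sim, dir)
  expect_true(all(file.exists(files)))
  back <- read_fixture(dir)
  expect_identical(back$dataset_a$counts, sim$dataset_a$counts)
  expect_identical(back$dataset_b$counts, sim$dataset_b$counts)
  expect_equal(as.data.frame(back$orthologs), as.data.frame(sim$orthologs))
  expect_equal(as.data.frame(back$truth), as.data.frame(sim$truth))

  # corrupt one count to a negative value -> ingest must refuse
  lines <- readLines(files["counts_a"])
  lines[2] <- sub("\t(\\d+)", "\t-5", lines[2])
  writeLines(lines, files["counts_a"])
  expect_error(read_count_dataset(files["counts_a"], files["meta_a"]),
               "non-negative")
})

test_that("invalid configurations are refused naming the field", {
  expect_error(sim_config(n_genes_a = 0), "n_genes_a")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_genes_a = 30, n_conserved_pairs = 20,
                          n_private_aging_a = 20), "n_private_aging_a")
  expect_error(sim_config(age_ranges_a = list(c(5, 1), c(1, 5), c(1, 5))),
               "age_ranges_a")
  expect_error(sim_config(ortholog_noise = 2), "ortholog_noise")
})
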