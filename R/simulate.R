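#' Configuration for the two-species multi-study count simulator
#'
#' Describes a pair of species-level RNA-seq compendia assembled from several
#' independent studies, the way public-archive aging datasets are: each study
#' has its own sequencing-depth regime and its own age window, and a planted
#' subset of ortholog pairs carries a monotone age trend in both species.
#' Defaults reproduce the study conditions the package's recovery experiments
#' use: 2000 genes per species, three studies of 20 samples each, 40
#' conserved pairs, log2 slope 0.5 per SD of age, NB dispersion 0.2.
#'
#' @param n_genes_a,n_genes_b Genes per species.
#' @param n_samples_per_study_a,n_samples_per_study_b Integer vector, one
#'   entry per study.
#' @param age_ranges_a,age_ranges_b List of `c(min, max)` age windows, one
#'   per study: continuous years for species A, integer days for species B.
#'   Defaults span young/middle/old unevenly across studies.
#' @param n_conserved_pairs Ortholog pairs age-associated in both species.
#' @param n_private_aging_a,n_private_aging_b Genes age-associated in one
#'   species only.
#' @param effect_size Slope of mean log2 expression per SD of (pooled,
#'   within-species standardized) age for planted genes; half the planted
#'   slopes are positive, half negative.
#' @param dispersion Negative-binomial dispersion phi >= 0 in the
#'   `variance = mu + phi * mu^2` parameterization; 0 gives Poisson counts.
#' @param study_logsize_sd SD of per-study log library-size offsets
#'   (sequencing-depth regimes; archives span >10x between studies).
#' @param sample_logsize_sd SD of per-sample log library-size noise around
#'   the study offset.
#' @param gene_study_sd SD of gene-by-study log2-fold batch noise.
#' @param baseline_logmean_range Uniform range for per-gene baseline log2
#'   mean expression.
#' @param ortholog_noise Fraction of the ortholog table made of decoy
#'   many-to-many rows (scores strictly below every true-pair score).
#' @param seed Integer RNG seed; identical configs give identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes_a = 2000, n_genes_b = 2000,
                       n_samples_per_study_a = c(20, 20, 20),
                       n_samples_per_study_b = c(20, 20, 20),
                       age_ranges_a = list(c(18, 55), c(25, 75), c(45, 90)),
                       age_ranges_b = list(c(1, 15), c(5, 40), c(20, 60)),
                       n_conserved_pairs = 40,
                       n_private_aging_a = 60, n_private_aging_b = 60,
                       effect_size = 0.5, dispersion = 0.2,
                       study_logsize_sd = 0.7, sample_logsize_sd = 0.2,
                       gene_study_sd = 0.1,
                       baseline_logmean_range = c(3, 9),
                       ortholog_noise = 0.5, seed = 1) {
  cfg <- list(
    n_genes_a = check_positive_int(n_genes_a, "n_genes_a"),
    n_genes_b = check_positive_int(n_genes_b, "n_genes_b"),
    n_samples_per_study_a = n_samples_per_study_a,
    n_samples_per_study_b = n_samples_per_study_b,
    age_ranges_a = age_ranges_a, age_ranges_b = age_ranges_b,
    n_conserved_pairs = n_conserved_pairs,
    n_private_aging_a = n_private_aging_a,
    n_private_aging_b = n_private_aging_b,
    effect_size = effect_size, dispersion = dispersion,
    study_logsize_sd = study_logsize_sd,
    sample_logsize_sd = sample_logsize_sd,
    gene_study_sd = gene_study_sd,
    baseline_logmean_range = baseline_logmean_range,
    ortholog_noise = ortholog_noise, seed = seed)

  for (sp in c("a", "b")) {
    ns <- cfg[[paste0("n_samples_per_study_", sp)]]
    ar <- cfg[[paste0("age_ranges_", sp)]]
    if (!is.numeric(ns) || length(ns) < 1 || any(ns < 1) || any(ns != round(ns))) {
      stop_config(paste0("n_samples_per_study_", sp), "must be positive integers, one per study")
    }
    if (!is.list(ar) || length(ar) != length(ns) ||
        !all(vapply(ar, function(r) length(r) == 2 && all(is.finite(r)) &&
                      r[1] > 0 && r[2] >= r[1], logical(1)))) {
      stop_config(paste0("age_ranges_", sp),
                  "must be a list of c(min, max) with 0 < min <= max, one per study")
    }
  }
  for (fld in c("n_conserved_pairs", "n_private_aging_a", "n_private_aging_b")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop_config(fld, "must be a single non-negative integer")
    }
    cfg[[fld]] <- as.integer(v)
  }
  if (cfg$n_conserved_pairs + cfg$n_private_aging_a > cfg$n_genes_a) {
    stop_config("n_private_aging_a", "planted genes exceed n_genes_a")
  }
  if (cfg$n_conserved_pairs + cfg$n_private_aging_b > cfg$n_genes_b) {
    stop_config("n_private_aging_b", "planted genes exceed n_genes_b")
  }
  check_scalar_number(cfg$effect_size, "effect_size")
  check_scalar_number(cfg$dispersion, "dispersion", lo = 0)
  check_scalar_number(cfg$study_logsize_sd, "study_logsize_sd", lo = 0)
  check_scalar_number(cfg$sample_logsize_sd, "sample_logsize_sd", lo = 0)
  check_scalar_number(cfg$gene_study_sd, "gene_study_sd", lo = 0)
  if (!is.numeric(cfg$baseline_logmean_range) || length(cfg$baseline_logmean_range) != 2 ||
      diff(cfg$baseline_logmean_range) < 0) {
    stop_config("baseline_logmean_range", "must be c(lo, hi) with lo <= hi")
  }
  check_scalar_number(cfg$ortholog_noise, "ortholog_noise", lo = 0, hi = 0.95)
  check_positive_int(abs(cfg$seed) + 1, "seed")  # any integer accepted
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Simulate a two-species multi-study count dataset with known truth
#'
#' For each species: sample ages uniformly within each study's age window
#' (integer days for species B); give each sample an expected library scale
#' `exp(study_offset + sample_noise)`; set each gene's log2 mean to
#' `baseline + slope * standardized_age + gene_x_study_effect` (ages are
#' standardized with the pooled within-species mean/SD so `effect_size`
#' means the same thing in years and in days); draw counts from a negative
#' binomial with that mean times the library scale and dispersion `phi`
#' (Poisson when `phi = 0`). Planted conserved pairs share the sign of their
#' slope across species. The ortholog table holds one high-score row per
#' conserved pair plus lower-score many-to-many decoy rows.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset_a`, `dataset_b` (each a
#'   [count_dataset()]), `orthologs` (tibble `gene_id_a`, `gene_id_b`,
#'   `score`) and `truth` (tibble `gene_id`, `species`, `role`, `slope`,
#'   `partner`): the ground-truth table of planted genes.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes_a = 200, n_genes_b = 200, seed = 7))
#' sim$dataset_a
#' head(sim$truth)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  slopes_pair <- planted_slopes(config$n_conserved_pairs, config$effect_size)
  sp_a <- simulate_species(config, "a", "HGENE", "human", "years", slopes_pair)
  sp_b <- simulate_species(config, "b", "FGENE", "fly", "days", slopes_pair)
  orth <- simulate_orthologs(config, sp_a$planted_ids, sp_b$planted_ids)

  truth <- bind_rows(sp_a$truth, sp_b$truth)
  pair_a <- sp_a$planted_ids$conserved
  pair_b <- sp_b$planted_ids$conserved
  truth$partner <- NA_character_
  truth$partner[match(pair_a, truth$gene_id)] <- pair_b
  truth$partner[match(pair_b, truth$gene_id)] <- pair_a

  list(dataset_a = sp_a$dataset, dataset_b = sp_b$dataset,
       orthologs = orth, truth = truth)
}

planted_slopes <- function(n, effect_size) {
  if (n == 0) return(numeric(0))
  effect_size * rep_len(c(1, -1), n)
}

simulate_species <- function(cfg, sp, prefix, species, unit, slopes_pair) {
  n_genes <- cfg[[paste0("n_genes_", sp)]]
  n_per <- cfg[[paste0("n_samples_per_study_", sp)]]
  ranges <- cfg[[paste0("age_ranges_", sp)]]
  n_studies <- length(n_per)
  n_samples <- sum(n_per)
  study <- rep(sprintf("study_%s%d", sp, seq_len(n_studies)), n_per)

  ages <- unlist(lapply(seq_len(n_studies), function(s) {
    a <- runif(n_per[s], ranges[[s]][1], ranges[[s]][2])
    if (unit == "days") a <- pmax(1, round(a))
    a
  }))
  z <- if (sd(ages) > 0) (ages - mean(ages)) / sd(ages) else ages * 0

  gene_id <- sprintf("%s%05d", prefix, seq_len(n_genes))
  n_cons <- cfg$n_conserved_pairs
  n_priv <- cfg[[paste0("n_private_aging_", sp)]]
  conserved <- gene_id[seq_len(n_cons)]
  private <- gene_id[n_cons + seq_len(n_priv)]
  slopes <- numeric(n_genes)
  slopes[seq_len(n_cons)] <- slopes_pair
  slopes[n_cons + seq_len(n_priv)] <- planted_slopes(n_priv, cfg$effect_size)

  lo <- cfg$baseline_logmean_range[1]; hi <- cfg$baseline_logmean_range[2]
  baseline <- runif(n_genes, lo, hi)
  # planted aging genes are drawn from the upper half of the baseline range:
  # an age trend is only observable in genes expressed above the detection
  # filter, so the planted truth must not hide below it
  n_planted <- n_cons + n_priv
  if (n_planted > 0) {
    baseline[seq_len(n_planted)] <- runif(n_planted, (lo + hi) / 2, hi)
  }
  study_off <- rnorm(n_studies, 0, cfg$study_logsize_sd)
  libscale <- exp(study_off[match(study, unique(study))] +
                    rnorm(n_samples, 0, cfg$sample_logsize_sd))
  batch <- matrix(rnorm(n_genes * n_studies, 0, cfg$gene_study_sd), n_genes, n_studies)

  log2mu <- outer(baseline, rep(1, n_samples)) +
    outer(slopes, z) + batch[, match(study, unique(study)), drop = FALSE]
  mu <- sweep(2^log2mu, 2, libscale, "*")
  counts <- if (cfg$dispersion == 0) {
    matrix(rpois(length(mu), lambda = mu), n_genes, n_samples)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion), n_genes, n_samples)
  }
  dimnames(counts) <- list(gene_id, sprintf("%s_s%03d", species, seq_len(n_samples)))

  samples <- tibble(sample_id = colnames(counts), study_id = study,
                    age = ages, age_unit = unit, species = species)
  truth <- tibble(gene_id = c(conserved, private), species = species,
                  role = rep(c("conserved", "private"), c(n_cons, n_priv)),
                  slope = slopes[seq_len(n_cons + n_priv)])
  list(dataset = count_dataset(counts, samples),
       planted_ids = list(conserved = conserved, private = private),
       truth = truth)
}

# true rows score in [10, 15]; decoys strictly below (in [1, 9]) so best-match
# recovery is testable while many-to-many resolution is still exercised
simulate_orthologs <- function(cfg, ids_a, ids_b) {
  n_true <- length(ids_a$conserved)
  true_rows <- tibble(gene_id_a = ids_a$conserved, gene_id_b = ids_b$conserved,
                      score = sample(10:15, n_true, replace = TRUE))
  n_decoy <- round(cfg$ortholog_noise / (1 - cfg$ortholog_noise) * max(n_true, 20))
  universe_a <- c(ids_a$conserved, ids_a$private)
  universe_b <- c(ids_b$conserved, ids_b$private)
  if (length(universe_a) == 0 || length(universe_b) == 0) n_decoy <- 0
  if (n_decoy > 0) {
    decoys <- tibble(
      gene_id_a = sample(universe_a, n_decoy, replace = TRUE),
      gene_id_b = sample(universe_b, n_decoy, replace = TRUE),
      score = sample(1:9, n_decoy, replace = TRUE))
    out <- bind_rows(true_rows, decoys)
  } else {
    out <- true_rows
  }
  out <- dplyr::distinct(out, .data$gene_id_a, .data$gene_id_b, .keep_all = TRUE)
  arrange(out, desc(.data$score), .data$gene_id_a, .data$gene_id_b)
}

#' Write or read a simulated fixture as tab-delimited files
#'
#' `write_fixture()` writes `counts_a.tsv`, `meta_a.tsv`, `counts_b.tsv`,
#' `meta_b.tsv`, `orthologs.tsv` and `truth.tsv` under `path` (UTF-8, Unix
#' newlines); `read_fixture()` reads them back through the validating
#' ingest path. The round trip is bit-exact.
#'
#' @param sim A [simulate_dataset()] result.
#' @param path Directory (created if absent).
#' @return `write_fixture()` returns the named file paths invisibly;
#'   `read_fixture()` returns a list shaped like [simulate_dataset()] output.
#' @export
write_fixture <- function(sim, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- c(counts_a = "counts_a.tsv", meta_a = "meta_a.tsv",
             counts_b = "counts_b.tsv", meta_b = "meta_b.tsv",
             orthologs = "orthologs.tsv", truth = "truth.tsv")
  files <- setNames(file.path(path, files), names(files))
  write_count_dataset(sim$dataset_a, files["counts_a"], files["meta_a"])
  write_count_dataset(sim$dataset_b, files["counts_b"], files["meta_b"])
  readr::write_tsv(sim$orthologs, files["orthologs"])
  readr::write_tsv(sim$truth, files["truth"])
  invisible(files)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  list(
    dataset_a = read_count_dataset(file.path(path, "counts_a.tsv"),
                                   file.path(path, "meta_a.tsv")),
    dataset_b = read_count_dataset(file.path(path, "counts_b.tsv"),
                                   file.path(path, "meta_b.tsv")),
    orthologs = read_ortholog_table(file.path(path, "orthologs.tsv")),
    truth = readr::read_tsv(file.path(path, "truth.tsv"),
                            show_col_types = FALSE, progress = FALSE))
}
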