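# Shared fixtures and independent oracles. Oracles are deliberately written
# in the most literal way possible (explicit loops, no shortcuts) so they
# stay independent of the package's vectorized implementations.

`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_dataset <- function(counts, ages = NULL, unit = "years", study = NULL) {
  n <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%03d", seq_len(n))
  meta <- tibble::tibble(
    sample_id = colnames(counts),
    study_id = study %||% rep("st1", n),
    age = ages %||% seq(20, 20 + 5 * (n - 1), by = 5),
    age_unit = unit, species = "testspecies")
  count_dataset(counts, meta)
}

random_nb_dataset <- function(n_genes, n_samples, seed, mu = 60, size = 5,
                              study = NULL) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              n_genes, n_samples)
  m[rowSums(m) == 0, 1] <- 1L  # no all-zero genes
  tiny_dataset(m, ages = runif(n_samples, 20, 80), study = study)
}

small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes_a = 300, n_genes_b = 300,
         n_samples_per_study_a = c(10, 10, 10),
         n_samples_per_study_b = c(10, 10, 10),
         n_conserved_pairs = 10, n_private_aging_a = 10,
         n_private_aging_b = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# --- oracle: per-gene expression filter by explicit recount -----------------
oracle_filter_keep <- function(counts, min_count, min_fraction) {
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    n_expressed <- 0
    for (s in seq_len(ncol(counts))) {
      if (counts[g, s] > min_count) n_expressed <- n_expressed + 1
    }
    keep[g] <- n_expressed >= ceiling(min_fraction * ncol(counts))
  }
  keep
}

# --- oracle: TMM straight from the formula, explicit sorts ------------------
oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  uq <- apply(cpm, 2, function(v) quantile(v, 0.75, names = FALSE))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    if (k == ref) { f[k] <- 1; next }
    yk <- counts[, k]; yr <- counts[, ref]
    ids <- rownames(counts)
    use <- which(yk > 0 & yr > 0)
    m <- a <- w <- numeric(length(use)); id <- character(length(use))
    for (j in seq_along(use)) {
      g <- use[j]
      m[j] <- log2((yk[g] / lib[k]) / (yr[g] / lib[ref]))
      a[j] <- 0.5 * log2((yk[g] / lib[k]) * (yr[g] / lib[ref]))
      w[j] <- (lib[k] - yk[g]) / (lib[k] * yk[g]) +
        (lib[ref] - yr[g]) / (lib[ref] * yr[g])
      id[j] <- ids[g]
    }
    n <- length(m)
    surv_tail <- function(key, trim) {
      ord <- order(key, id, method = "radix")
      ntrim <- floor(trim * n)
      surviving <- rep(FALSE, n)
      if (n - 2 * ntrim > 0) {
        for (pos in seq.int(ntrim + 1, n - ntrim)) surviving[ord[pos]] <- TRUE
      }
      surviving
    }
    keep <- surv_tail(m, logratio_trim) & surv_tail(a, abs_trim)
    num <- den <- 0
    for (j in which(keep)) {
      num <- num + m[j] / w[j]
      den <- den + 1 / w[j]
    }
    f[k] <- if (den == 0) 1 else 2^(num / den)
  }
  f / exp(mean(log(f)))
}

# --- oracle: RLE median-of-ratios --------------------------------------------
oracle_rle <- function(counts) {
  all_pos <- apply(counts, 1, function(row) all(row > 0))
  ref <- apply(counts[all_pos, , drop = FALSE], 1, function(row) exp(mean(log(row))))
  s <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    s[k] <- median(counts[all_pos, k] / ref)
  }
  f <- s / colSums(counts)
  unname(f / exp(mean(log(f))))
}

# --- oracle: two-pass Pearson correlation ------------------------------------
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sxx <- syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) 0 else unname(sxy / sqrt(sxx * syy))
}

# --- oracle: best match by repeated global-max extraction --------------------
oracle_best_match <- function(tbl) {
  tbl <- as.data.frame(tbl)
  kept <- tbl[0, ]
  while (nrow(tbl) > 0) {
    best <- order(-tbl$score, tbl$gene_id_a, tbl$gene_id_b)[1]
    kept <- rbind(kept, tbl[best, ])
    tbl <- tbl[tbl$gene_id_a != tbl$gene_id_a[best] &
                 tbl$gene_id_b != tbl$gene_id_b[best], ]
  }
  kept[order(kept$gene_id_a), ]
}

# model contracts used as harness probes
oracle_regressor <- function(ages, ids) {
  lookup <- setNames(ages, ids)
  list(fit = function(x, y) NULL,
       predict = function(state, x) unname(lookup[rownames(x)]))
}
train_mean_regressor <- list(
  fit = function(x, y) mean(y),
  predict = function(state, x) rep(state, nrow(x)))
oracle_classifier <- function(groups, ids) {
  lookup <- setNames(as.character(groups), ids)
  list(fit = function(x, y) levels(y),
       predict = function(state, x) factor(unname(lookup[rownames(x)]), levels = state))
}
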