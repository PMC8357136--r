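#' Library normalization factors
#'
#' `tmm_factors()` implements the trimmed mean of M-values estimator:
#' per-sample scaling factors are precision-weighted means of gene-wise
#' log2-fold-changes against a reference sample, after trimming the extremes
#' of both the log-ratio (M) and average-abundance (A) distributions.
#' `rle_factors()` implements the relative log expression (median-of-ratios)
#' estimator. `norm_factors()` dispatches by method name and is what the
#' pipeline calls; `method = "none"` gives unit factors (library-size-only
#' scaling).
#'
#' Factors are reported on a common convention: the effective library size of
#' sample *k* is `lib_size * factor`, and factors are rescaled so their
#' geometric mean is exactly 1. For RLE this means the raw median-of-ratios
#' size factor is divided by the library size before rescaling, which makes
#' TMM and RLE interchangeable downstream.
#'
#' @param ds A [count_dataset()].
#' @param logratio_trim Fraction trimmed from each tail of the M
#'   distribution (default 0.3).
#' @param abs_trim Fraction trimmed from each tail of the A distribution
#'   (default 0.05).
#' @param ref_sample Reference sample id; by default the sample whose
#'   upper quartile of counts-per-million is closest to the mean upper
#'   quartile across samples.
#'
#' @details Genes with a zero count in either the sample or the reference are
#' excluded from the M/A computation (the log-ratio is undefined there). The
#' number trimmed from each tail is `floor(trim_fraction * n_genes_retained)`
#' after a stable sort with ties broken by gene id, so results are identical
#' across platforms; a gene must survive both trims to contribute. The weight
#' of gene *g* is the inverse of its asymptotic log-ratio variance
#' `(N_k - y_gk)/(N_k y_gk) + (N_r - y_gr)/(N_r y_gr)`.
#'
#' @return A tibble of class `norm_factors` with columns `sample_id`,
#'   `lib_size`, `factor`, `method` (one row per sample, metadata order).
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 1))$dataset_a
#' tmm_factors(ds)
#' @export
tmm_factors <- function(ds, logratio_trim = 0.3, abs_trim = 0.05, ref_sample = NULL) {
  stopifnot(inherits(ds, "count_dataset"))
  y <- ds$counts
  if (ncol(y) < 2) stop_validation("TMM needs at least two samples")
  lib <- colSums(y)
  if (any(lib <= 0)) stop_validation("every sample needs a positive library size")
  check_scalar_number(logratio_trim, "logratio_trim", 0, 0.5)
  check_scalar_number(abs_trim, "abs_trim", 0, 0.5)

  cpm <- sweep(y, 2, lib, "/") * 1e6
  uq <- apply(cpm, 2, quantile, probs = 0.75, names = FALSE)
  ref <- if (is.null(ref_sample)) {
    colnames(y)[which.min(abs(uq - mean(uq)))]
  } else {
    if (!ref_sample %in% colnames(y)) stop_validation("unknown `ref_sample`")
    ref_sample
  }

  f <- vapply(colnames(y), function(k) {
    if (k == ref) return(1)
    tmm_pair_factor(y[, k], y[, ref], lib[k], lib[ref], rownames(y),
                    logratio_trim, abs_trim, sample_id = k)
  }, numeric(1))
  f <- f / geometric_mean(f)
  new_norm_factors(colnames(y), lib, f, "TMM")
}

# one sample vs reference; deterministic double trim then weighted mean of M
tmm_pair_factor <- function(yk, yr, nk, nr, ids, logratio_trim, abs_trim, sample_id) {
  pos <- yk > 0 & yr > 0
  if (!any(pos)) {
    stop_validation(paste0("sample `", sample_id,
                           "` shares no positively expressed gene with the reference"))
  }
  yk <- yk[pos]; yr <- yr[pos]; ids <- ids[pos]
  m <- log2((yk / nk) / (yr / nr))
  a <- 0.5 * log2((yk / nk) * (yr / nr))
  w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)

  n <- length(m)
  keep_tail <- function(key, trim) {
    ord <- order(key, ids, method = "radix")
    ntrim <- floor(trim * n)
    keep <- rep(FALSE, n)
    if (n - 2 * ntrim > 0) keep[ord[seq.int(ntrim + 1, n - ntrim)]] <- TRUE
    keep
  }
  keep <- keep_tail(m, logratio_trim) & keep_tail(a, abs_trim)
  if (!any(keep)) return(1)
  wt <- 1 / w[keep]
  # guard: a gene at half the library in both samples can give w = 0
  if (any(!is.finite(wt))) wt[!is.finite(wt)] <- max(wt[is.finite(wt)], 1)
  2^(sum(wt * m[keep]) / sum(wt))
}

#' @rdname tmm_factors
#' @export
rle_factors <- function(ds) {
  stopifnot(inherits(ds, "count_dataset"))
  y <- ds$counts
  lib <- colSums(y)
  if (any(lib <= 0)) stop_validation("every sample needs a positive library size")
  pos <- rowSums(y == 0) == 0
  if (!any(pos)) stop_validation("RLE needs at least one gene with positive counts in all samples")
  ref <- exp(rowMeans(log(y[pos, , drop = FALSE])))
  s <- apply(y[pos, , drop = FALSE], 2, function(col) median(col / ref))
  f <- s / lib
  f <- f / geometric_mean(f)
  new_norm_factors(colnames(y), lib, f, "RLE")
}

#' @rdname tmm_factors
#' @param method `"tmm"`, `"rle"` or `"none"`.
#' @param ... Passed to the method-specific estimator.
#' @export
norm_factors <- function(ds, method = c("tmm", "rle", "none"), ...) {
  method <- match.arg(method)
  switch(method,
         tmm  = tmm_factors(ds, ...),
         rle  = rle_factors(ds),
         none = new_norm_factors(colnames(ds$counts), colSums(ds$counts),
                                 rep(1, ncol(ds$counts)), "none"))
}

new_norm_factors <- function(sample_id, lib_size, factor, method) {
  out <- tibble(sample_id = sample_id, lib_size = unname(lib_size),
                factor = unname(factor), method = method)
  class(out) <- c("norm_factors", class(out))
  out
}

#' Log2 counts-per-million transformation
#'
#' Computes `log2((count + pseudocount) / (lib_size * factor) * 1e6)` for
#' every entry — normalized, log-scale expression used as features for
#' ranking and prediction. Monotone in the counts of each sample.
#'
#' @param ds A [count_dataset()].
#' @param factors A `norm_factors` tibble aligned to the dataset's samples
#'   (defaults to TMM factors).
#' @param pseudocount Added to every count before the log; default 0.5.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (genes x samples real matrix), `samples` (metadata tibble), `method`
#'   and `pseudocount`.
#' @export
log_cpm <- function(ds, factors = tmm_factors(ds), pseudocount = 0.5) {
  stopifnot(inherits(ds, "count_dataset"))
  check_scalar_number(pseudocount, "pseudocount", lo = 1e-12)
  if (!all(factors$sample_id == colnames(ds$counts))) {
    stop_validation("normalization factors do not align with the dataset's samples")
  }
  eff <- factors$lib_size * factors$factor
  vals <- log2(sweep(ds$counts + pseudocount, 2, eff, "/") * 1e6)
  structure(list(values = vals, samples = ds$samples,
                 method = factors$method[1], pseudocount = pseudocount),
            class = "normalized_matrix")
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d samples (log2-CPM, %s factors)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' @export
as_tibble.normalized_matrix <- function(x, ...) {
  tibble(gene_id = rownames(x$values)) |>
    dplyr::bind_cols(as_tibble(x$values))
}

#' Unnormalized log2 counts
#'
#' `log2(count + pseudocount)` with no library-size or factor scaling — the
#' "without normalization" baseline against which normalization methods are
#' judged for study-effect removal.
#'
#' @inheritParams log_cpm
#' @return A `normalized_matrix` with method tag `"raw"`.
#' @export
raw_log_counts <- function(ds, pseudocount = 0.5) {
  stopifnot(inherits(ds, "count_dataset"))
  check_scalar_number(pseudocount, "pseudocount", lo = 1e-12)
  structure(list(values = log2(ds$counts + pseudocount), samples = ds$samples,
                 method = "raw", pseudocount = pseudocount),
            class = "normalized_matrix")
}

#' Between-study separation of normalized expression
#'
#' A scalar summary of how far apart the studies' log-expression
#' distributions sit: the (population) variance, across studies, of each
#' study's mean log expression. Zero when all studies share the same mean;
#' successful normalization should shrink it relative to library-size-only
#' scaling.
#'
#' @param nm A [log_cpm()] result.
#' @param metadata Per-sample metadata (defaults to the metadata carried by
#'   `nm`); must contain `study_id` aligned with the matrix columns.
#' @return A single non-negative number.
#' @export
study_effect_score <- function(nm, metadata = nm$samples) {
  stopifnot(inherits(nm, "normalized_matrix"))
  study <- metadata$study_id
  if (length(unique(study)) < 2) stop_validation("study_effect_score needs >=2 studies")
  means <- vapply(split(seq_along(study), study),
                  function(idx) mean(nm$values[, idx]), numeric(1))
  pop_var(means)
}
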