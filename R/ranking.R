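#' Correlate every gene's expression with chronological age
#'
#' Pearson correlation of each gene's normalized log expression against the
#' samples' ages, the within-species ranking signal for aging-associated
#' genes. Genes whose expression is constant across samples get `r = 0` by
#' convention (their correlation is undefined). Spearman rank correlation is
#' available as an option.
#'
#' @param nm A [log_cpm()] result.
#' @param ages Numeric ages, one per sample (defaults to the metadata
#'   carried by `nm`); must not be constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble of class `age_correlation` with columns `gene_id`, `r`,
#'   `abs_r` and `rank` (1 = largest `|r|`, ties broken by gene id), sorted
#'   by rank — the shape of a per-species correlation table.
#' @export
correlate_with_age <- function(nm, ages = nm$samples$age,
                               method = c("pearson", "spearman")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  method <- match.arg(method)
  if (length(ages) != ncol(nm$values)) {
    stop_validation("`ages` length must equal the number of samples")
  }
  if (ncol(nm$values) < 3) stop_validation("correlation needs >=3 samples")
  if (sd(ages) == 0) stop_validation("ages are constant; correlation undefined")

  x <- if (method == "spearman") rank(ages) else ages
  vals <- nm$values
  if (method == "spearman") vals <- t(apply(vals, 1, rank))
  xc <- x - mean(x)
  vc <- vals - rowMeans(vals)
  num <- as.vector(vc %*% xc)
  den <- sqrt(rowSums(vc^2) * sum(xc^2))
  r <- ifelse(den == 0, 0, num / den)
  r <- pmin(1, pmax(-1, r))

  out <- tibble(gene_id = rownames(nm$values), r = r, abs_r = abs(r))
  out <- arrange(out, desc(.data$abs_r), .data$gene_id)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("age_correlation", class(out))
  out
}

#' Top-k genes by age correlation
#'
#' The first `k` genes of a correlation table under the chosen ranking key:
#' `|r|` by default (so both age-up and age-down genes qualify) or signed
#' `r`. Ties are broken by ascending gene id so the list is deterministic.
#'
#' @param tbl An [correlate_with_age()] table.
#' @param k List length (the classic choice is 1000); truncated to the
#'   number of genes with a warning if larger.
#' @param key `"absolute"` or `"signed"`.
#' @return Character vector of `k` gene ids in rank order.
#' @export
top_k <- function(tbl, k = 1000, key = c("absolute", "signed")) {
  key <- match.arg(key)
  check_positive_int(k, "k")
  if (k > nrow(tbl)) {
    warn(sprintf("k = %d exceeds the %d available genes; using all genes", k, nrow(tbl)))
    k <- nrow(tbl)
  }
  ord <- if (key == "absolute") {
    order(-tbl$abs_r, tbl$gene_id, method = "radix")
  } else {
    order(-tbl$r, tbl$gene_id, method = "radix")
  }
  tbl$gene_id[ord][seq_len(k)]
}
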