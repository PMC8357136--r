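#' Read and validate a scored ortholog table
#'
#' Tab-delimited three-column export (`gene_id_a`, `gene_id_b`, `score`) in
#' the shape of a DIOPT-style ortholog-prediction download: many-to-many
#' pairs, each scored by a non-negative confidence value. Duplicate (a, b)
#' pairs and non-finite scores are rejected.
#'
#' @param path Path to the tab-delimited table.
#' @return A tibble with columns `gene_id_a`, `gene_id_b`, `score`.
#' @export
read_ortholog_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_ortholog_table(tbl)
}

validate_ortholog_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  need <- c("gene_id_a", "gene_id_b", "score")
  if (!all(need %in% names(tbl))) {
    stop_validation("ortholog table needs columns gene_id_a, gene_id_b, score")
  }
  tbl <- tbl[need]
  if (anyDuplicated(tbl[c("gene_id_a", "gene_id_b")])) {
    stop_validation("ortholog table contains duplicate (gene_id_a, gene_id_b) pairs")
  }
  if (any(!is.finite(tbl$score)) || any(tbl$score < 0)) {
    stop_validation("ortholog scores must be finite and non-negative")
  }
  tbl
}

#' Resolve a many-to-many ortholog table to one-to-one best matches
#'
#' Greedy prioritization by score: rows are sorted by score descending (ties
#' broken lexicographically by `gene_id_a` then `gene_id_b`) and accepted in
#' order whenever neither gene is already matched — the highest-ranked
#' homolog for each gene is kept, leaving a one-to-one best-match map.
#' With all scores distinct this equals repeatedly extracting the global
#' maximum, and the result is invariant to input row order.
#'
#' @param tbl Ortholog tibble (`gene_id_a`, `gene_id_b`, `score`).
#' @return A tibble of class `best_match_map` with one row per retained
#'   pair, each gene id appearing at most once, sorted as accepted.
#' @examples
#' tbl <- tibble::tibble(gene_id_a = c("h1", "h1", "h2", "h2"),
#'                       gene_id_b = c("f1", "f2", "f1", "f2"),
#'                       score = c(10, 8, 9, 7))
#' resolve_best_match(tbl)  # h1-f1 (10), then h2-f2 (7)
#' @export
resolve_best_match <- function(tbl) {
  tbl <- validate_ortholog_table(tbl)
  if (nrow(tbl) == 0) {
    out <- tbl
  } else {
    ord <- order(-tbl$score, tbl$gene_id_a, tbl$gene_id_b, method = "radix")
    tbl <- tbl[ord, ]
    used_a <- character(0); used_b <- character(0)
    keep <- logical(nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      a <- tbl$gene_id_a[i]; b <- tbl$gene_id_b[i]
      if (!(a %in% used_a) && !(b %in% used_b)) {
        keep[i] <- TRUE
        used_a <- c(used_a, a); used_b <- c(used_b, b)
      }
    }
    out <- tbl[keep, ]
  }
  class(out) <- c("best_match_map", class(out))
  out
}

#' Intersect two species' top-ranked gene lists through the ortholog map
#'
#' The conserved age-associated gene set: best-match pairs whose species-A
#' member is in the species-A top list and whose species-B member is in the
#' species-B top list. Pairs are ordered by the better (smaller) of the two
#' within-species ranks, ties by `gene_id_a`, and carry both species'
#' correlation coefficients and the ortholog score.
#'
#' @param top_a,top_b Character vectors of top-ranked gene ids (in rank
#'   order) for each species.
#' @param map A [resolve_best_match()] result.
#' @param corr_a,corr_b The species' [correlate_with_age()] tables (used to
#'   attach `r` and ranks).
#' @return A tibble of class `conserved_gene_set` with columns `gene_id_a`,
#'   `gene_id_b`, `r_a`, `r_b`, `rank_a`, `rank_b`, `score`.
#' @export
intersect_conserved <- function(top_a, top_b, map, corr_a, corr_b) {
  hit <- map[map$gene_id_a %in% top_a & map$gene_id_b %in% top_b, ]
  hit <- as_tibble(hit)
  ra <- match(hit$gene_id_a, corr_a$gene_id)
  rb <- match(hit$gene_id_b, corr_b$gene_id)
  out <- tibble(gene_id_a = hit$gene_id_a, gene_id_b = hit$gene_id_b,
                r_a = corr_a$r[ra], r_b = corr_b$r[rb],
                rank_a = corr_a$rank[ra], rank_b = corr_b$rank[rb],
                score = hit$score)
  out <- arrange(out, pmin(.data$rank_a, .data$rank_b), .data$gene_id_a)
  class(out) <- c("conserved_gene_set", class(out))
  out
}
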