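#' Construct a validated count dataset
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' per-sample metadata. This is the container every downstream stage
#' (filtering, normalization, ranking, evaluation) consumes. Column order of
#' the matrix always equals the row order of `samples`.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Non-negative; fractional values are
#'   rejected unless `allow_noninteger = TRUE`, in which case they are
#'   floor-rounded (for quantifiers that emit expected counts).
#' @param samples Data frame with one row per sample: columns `sample_id`,
#'   `study_id`, `age` (positive), `age_unit` (`"years"` or `"days"`,
#'   constant within a dataset) and `species`; an optional `sex` column is
#'   carried through untouched.
#' @param allow_noninteger Accept real-valued counts and floor them.
#'
#' @return An object of class `count_dataset`: a list with elements `counts`
#'   (integer matrix) and `samples` (tibble).
#' @examples
#' m <- matrix(rpois(6, 20), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), study_id = "st1",
#'                    age = c(25, 70), age_unit = "years", species = "human")
#' ds <- count_dataset(m, meta)
#' dim(ds)
#' @export
count_dataset <- function(counts, samples, allow_noninteger = FALSE) {
  if (!is.matrix(counts)) stop_validation("`counts` must be a matrix")
  samples <- as_tibble(samples)
  required <- c("sample_id", "study_id", "age", "age_unit", "species")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("metadata is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("`counts` must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop_validation("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(counts))) stop_validation("duplicate sample ids in count matrix")
  if (anyDuplicated(samples$sample_id)) stop_validation("duplicate sample ids in metadata")

  absent <- setdiff(samples$sample_id, colnames(counts))
  if (length(absent) > 0) {
    stop_validation(paste0("sample(s) in metadata absent from count matrix: ",
                           paste(absent, collapse = ", ")))
  }
  extra <- setdiff(colnames(counts), samples$sample_id)
  if (length(extra) > 0) {
    stop_validation(paste0("sample(s) in count matrix absent from metadata: ",
                           paste(extra, collapse = ", ")))
  }
  # sample order follows the metadata
  counts <- counts[, samples$sample_id, drop = FALSE]

  if (any(!is.finite(counts))) stop_validation("counts contain non-finite values")
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (any(counts != round(counts))) {
    if (!allow_noninteger) {
      stop_validation("counts must be integers (use `allow_noninteger = TRUE` to floor expected counts)")
    }
    counts <- floor(counts)
  }
  storage.mode(counts) <- "integer"

  if (any(!is.finite(samples$age)) || any(samples$age <= 0)) {
    stop_validation("all ages must be positive and finite")
  }
  if (length(unique(samples$age_unit)) != 1L) {
    stop_validation("a dataset must use a single age unit")
  }
  if (!samples$age_unit[1] %in% c("years", "days")) {
    stop_validation(paste0("unknown age unit: ", samples$age_unit[1]))
  }

  structure(list(counts = counts, samples = samples), class = "count_dataset")
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d genes x %d samples (%s, ages in %s, %d studies)\n",
              nrow(x$counts), ncol(x$counts), x$samples$species[1],
              x$samples$age_unit[1], length(unique(x$samples$study_id))))
  invisible(x)
}

#' @export
as_tibble.count_dataset <- function(x, ...) {
  tibble(gene_id = rownames(x$counts)) |>
    dplyr::bind_cols(as_tibble(x$counts))
}

#' Gene and sample accessors
#' @param ds A `count_dataset`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(ds) rownames(ds$counts)

#' @rdname gene_ids
#' @export
sample_ids <- function(ds) colnames(ds$counts)

#' Read a count dataset from tab-delimited files
#'
#' The count matrix is tab-delimited with a header row of sample ids and
#' gene ids in the first column; the metadata file is tab-delimited with
#' columns `sample_id`, `study_id`, `age`, `age_unit`, `species`. Samples are
#' reordered to metadata order; every validation failure (dimension mismatch,
#' duplicate or missing ids, negative or fractional counts, unknown age unit)
#' raises a distinct error message.
#'
#' @param counts_path,metadata_path Paths to the two files.
#' @inheritParams count_dataset
#' @return A validated [count_dataset()].
#' @export
read_count_dataset <- function(counts_path, metadata_path, allow_noninteger = FALSE) {
  raw <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop_validation("count matrix needs a gene-id column plus >=1 sample")
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_validation("count matrix contains non-numeric entries")
  rownames(m) <- genes
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  count_dataset(m, meta, allow_noninteger = allow_noninteger)
}

#' Write a count dataset to tab-delimited files
#'
#' Inverse of [read_count_dataset()]; round-trips bit-exactly.
#'
#' @param ds A `count_dataset`.
#' @param counts_path,metadata_path Output paths (UTF-8, Unix newlines).
#' @return `ds`, invisibly.
#' @export
write_count_dataset <- function(ds, counts_path, metadata_path) {
  out <- as_tibble(ds)
  readr::write_tsv(out, counts_path)
  readr::write_tsv(ds$samples, metadata_path)
  invisible(ds)
}

#' Filter genes by minimum expression
#'
#' Keeps gene *g* iff its count exceeds `min_count` (strictly) in at least
#' `ceiling(min_fraction * n_samples)` samples — the "read values of greater
#' than 10 in at least 50% of the samples" rule applied to raw counts, ahead
#' of normalization. The sample set is unchanged and gene order is preserved,
#' so the operation is idempotent and commutes with sample permutations.
#'
#' @param ds A `count_dataset`.
#' @param min_count Count threshold; a gene needs counts strictly greater
#'   than this to be considered expressed in a sample. Default 10.
#' @param min_fraction Minimum fraction of samples in which the gene must be
#'   expressed. Default 0.5.
#' @return A `count_dataset` restricted to the passing genes. An empty result
#'   is returned with a warning, not an error.
#' @export
filter_expressed <- function(ds, min_count = 10, min_fraction = 0.5) {
  stopifnot(inherits(ds, "count_dataset"))
  check_scalar_number(min_count, "min_count", lo = 0)
  check_scalar_number(min_fraction, "min_fraction", lo = 0, hi = 1)
  need <- ceiling(min_fraction * ncol(ds$counts))
  keep <- rowSums(ds$counts > min_count) >= need
  if (!any(keep)) warn("no genes pass the expression filter")
  structure(list(counts = ds$counts[keep, , drop = FALSE], samples = ds$samples),
            class = "count_dataset")
}

#' Assign chronological age groups
#'
#' Maps ages to the three-group scheme used for classification. In years
#' (human): Young < 30, Middle 30-60 inclusive, Old > 60. In days (fly):
#' Young <= 10, Middle (10, 29], Old > 29 — day 10 sits in Young and the
#' Middle/Old boundary is drawn so that every positive age belongs to exactly
#' one group (see the methods vignette for the boundary rationale).
#'
#' @param age Numeric vector of positive ages.
#' @param unit `"years"` or `"days"`.
#' @return Factor with levels `Young`, `Middle`, `Old`.
#' @examples
#' assign_age_group(c(29, 30, 60, 61), "years")
#' assign_age_group(c(10, 29, 30), "days")
#' @export
assign_age_group <- function(age, unit) {
  unit <- match.arg(unit, c("years", "days"))
  if (any(!is.finite(age)) || any(age <= 0)) stop_validation("ages must be positive and finite")
  grp <- if (unit == "years") {
    ifelse(age < 30, "Young", ifelse(age <= 60, "Middle", "Old"))
  } else {
    ifelse(age <= 10, "Young", ifelse(age <= 29, "Middle", "Old"))
  }
  factor(grp, levels = c("Young", "Middle", "Old"))
}

#' Age groups for every sample of a dataset
#'
#' @param ds A `count_dataset`.
#' @return Factor of length `ncol(ds)` with levels Young/Middle/Old.
#' @export
sample_age_groups <- function(ds) {
  assign_age_group(ds$samples$age, ds$samples$age_unit[1])
}
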