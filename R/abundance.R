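#' Aggregate best-hit annotations into an abundance matrix
#'
#' Sums record hits per label at the chosen taxonomic rank (`domain`,
#' `phylum`, `class`, `order`, `family`, `genus`) or functional level
#' (`func_l1`..`func_l4`) and per sample. Records missing the label are
#' pooled into an `"unclassified"` row, so the matrix total always equals the
#' table's total hits.
#'
#' @param tab Best-hit classified annotation table, filtered in the matching
#'   profiling mode.
#' @param level Rank/level name (a column of the annotation dialect).
#' @param samples Optional character vector fixing the column order;
#'   defaults to order of first appearance.
#' @return An object of class `"abundance_matrix"`: a list with `counts`
#'   (features x samples numeric matrix), `level`, and `size_factors`
#'   (`NULL` until assigned).
#' @export
aggregate_counts <- function(tab, level, samples = NULL) {
  levels_ok <- c(tax_ranks(), func_levels())
  if (!level %in% levels_ok)
    stop("unknown level '", level, "'; expected one of: ",
         paste(levels_ok, collapse = ", "))
  validate_annotation_table(tab)
  lab <- tab[[level]]
  lab <- ifelse(is.na(lab), "unclassified", lab)
  if (is.null(samples)) samples <- unique(tab$sample_id)
  feats <- unique(lab)
  counts <- matrix(0, nrow = length(feats), ncol = length(samples),
                   dimnames = list(feats, samples))
  if (nrow(tab) > 0) {
    agg <- stats::aggregate(tab$hits,
                            by = list(feature = lab, sample = tab$sample_id),
                            FUN = sum)
    counts[cbind(agg$feature, agg$sample)] <- agg$x
  }
  structure(list(counts = counts, level = level, size_factors = NULL),
            class = "abundance_matrix")
}

as_abundance_counts <- function(x) {
  if (inherits(x, "abundance_matrix")) x$counts
  else if (is.matrix(x)) x
  else stop("expected an abundance_matrix or a matrix")
}

#' Median-of-ratios size factors
#'
#' The count-normalization constant per sample: a reference profile is the
#' per-feature geometric mean across samples over features with strictly
#' positive counts in every sample; each sample's factor is the median ratio
#' of its counts to the reference over those features. Factors are rescaled
#' to geometric mean 1 so they are comparable across runs.
#'
#' @param x An `abundance_matrix` or a counts matrix (features x samples).
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(x) {
  counts <- as_abundance_counts(x)
  if (ncol(counts) < 1) stop("need at least one sample")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no common features: no row has positive counts in all samples")
  sub <- counts[all_pos, , drop = FALSE]
  log_ref <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - log_ref)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Attach size factors to an abundance matrix
#'
#' @param x An `abundance_matrix`.
#' @return The matrix with `size_factors` filled in.
#' @export
estimate_size_factors <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  x$size_factors <- size_factors(x)
  x
}

#' Size-factor-normalized counts
#'
#' Divides each sample's counts by its size factor. Normalized values feed
#' ordination and heatmap outputs only; exact tests always consume the raw
#' integer counts.
#'
#' @param x An `abundance_matrix` (size factors estimated on demand).
#' @return An `abundance_matrix` with normalized (non-integer) counts.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  sf <- if (is.null(x$size_factors)) size_factors(x) else x$size_factors
  x$counts <- sweep(x$counts, 2, sf, "/")
  x$size_factors <- sf
  x
}

#' Convert to relative abundances
#'
#' Divides each sample column by its total so columns sum to 1. Proportions
#' are invariant to any per-column scaling applied beforehand (size-factor
#' normalization does not change them).
#'
#' @param x An `abundance_matrix` or counts matrix.
#' @return An `abundance_matrix` whose columns are proportions.
#' @export
to_relative <- function(x) {
  counts <- as_abundance_counts(x)
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("all-zero sample column")
  rel <- sweep(counts, 2, totals, "/")
  structure(list(counts = rel,
                 level = if (inherits(x, "abundance_matrix")) x$level else NA_character_,
                 size_factors = NULL),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples at level '", x$level, "'\n", sep = " ")
  if (!is.null(x$size_factors)) {
    cat("size factors:\n")
    print(round(x$size_factors, 4))
  }
  invisible(x)
}

#' Write an abundance matrix as TSV (+ companion JSON)
#'
#' First column holds the feature label, remaining columns the samples. A
#' companion `<path>.json` records the level and any size factors.
#'
#' @param x An `abundance_matrix`.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(level = x$level,
                            size_factors = as.list(x$size_factors)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV written by [write_abundance_matrix()].
#' @return An `abundance_matrix`.
#' @export
read_abundance_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(counts = counts,
                 level = if (!is.null(meta$level)) meta$level else NA_character_,
                 size_factors = if (!is.null(meta$size_factors))
                   unlist(meta$size_factors) else NULL),
            class = "abundance_matrix")
}
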