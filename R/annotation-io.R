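#' @title Annotation table dialect
#' @description Column order of the on-disk annotation-table dialect shared by
#'   all pipeline stages. One row per annotated feature (protein-coding region)
#'   per sample, carrying the hit count, alignment-quality fields, a six-rank
#'   taxonomic lineage and a four-level functional hierarchy whose leaf
#'   (`func_l4`) holds the EC/KEGG function identifier.
#' @keywords internal
annotation_columns <- function() {
  c("feature_id", "sample_id", "hits", "evalue", "identity_pct", "aln_len",
    "domain", "phylum", "class", "order", "family", "genus",
    "func_l1", "func_l2", "func_l3", "func_l4", "subject_id")
}

tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")
func_levels <- function() c("func_l1", "func_l2", "func_l3", "func_l4")

#' Annotation filter thresholds
#'
#' Defaults follow common shotgun-annotation practice: hits are retained when
#' the e-value is at most `evalue_max`, the alignment is at least
#' `aln_len_min` bp long, and the percent identity reaches the floor for the
#' profiling mode -- 60% for taxonomic and 80% for functional profiling.
#' `q_alpha` is the FDR level used to call features differential and
#' `eta2_min` the effect-size floor used when ranking ANOVA results.
#'
#' All comparisons are inclusive on the "keep" side (\code{<= evalue_max},
#' \code{>= aln_len_min}, \code{>= identity_min}).
#'
#' @param evalue_max Maximum e-value (default `1e-5`).
#' @param aln_len_min Minimum alignment length in bp (default 15).
#' @param identity_min_tax Identity floor (%) for taxonomic profiling (default 60).
#' @param identity_min_fun Identity floor (%) for functional profiling (default 80).
#' @param q_alpha Significance level on BH-adjusted q-values (default 0.05).
#' @param eta2_min Minimum eta-squared effect size (default 0.01).
#' @return A list of class `"threshold_config"`.
#' @export
threshold_config <- function(evalue_max = 1e-5, aln_len_min = 15L,
                             identity_min_tax = 60, identity_min_fun = 80,
                             q_alpha = 0.05, eta2_min = 0.01) {
  stopifnot(evalue_max > 0, aln_len_min >= 1,
            identity_min_tax >= 0, identity_min_tax <= 100,
            identity_min_fun >= 0, identity_min_fun <= 100,
            q_alpha > 0, q_alpha < 1, eta2_min >= 0, eta2_min <= 1)
  structure(list(evalue_max = evalue_max, aln_len_min = as.integer(aln_len_min),
                 identity_min_tax = identity_min_tax,
                 identity_min_fun = identity_min_fun,
                 q_alpha = q_alpha, eta2_min = eta2_min),
            class = "threshold_config")
}

validate_annotation_table <- function(tab, where = "annotation table") {
  miss <- setdiff(annotation_columns(), names(tab))
  if (length(miss) > 0)
    stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0)
      stop(where, ": ", what, " at row ", i[1],
           " (file line ", i[1] + 1L, ")")
  }
  bad_row(is.na(tab$hits) | tab$hits < 1 | tab$hits != floor(tab$hits),
          "hits must be an integer >= 1")
  bad_row(is.na(tab$evalue) | tab$evalue <= 0, "evalue must be > 0")
  bad_row(is.na(tab$identity_pct) | tab$identity_pct < 0 | tab$identity_pct > 100,
          "identity_pct must lie in [0, 100]")
  bad_row(is.na(tab$aln_len) | tab$aln_len < 1, "aln_len must be >= 1")
  # lineage prefix consistency: a missing rank implies all lower ranks missing
  ranks <- tax_ranks()
  for (j in seq_len(length(ranks) - 1)) {
    upper_missing <- is.na(tab[[ranks[j]]])
    lower_present <- !is.na(tab[[ranks[j + 1]]])
    bad_row(upper_missing & lower_present,
            paste0("lineage not prefix-consistent (", ranks[j + 1],
                   " present but ", ranks[j], " missing)"))
  }
  invisible(tab)
}

#' Read an annotation table
#'
#' Parses the tab-separated annotation-table dialect (header
#' `feature_id sample_id hits evalue identity_pct aln_len domain phylum class
#' order family genus func_l1..func_l4 subject_id`, `"NA"` = missing) into a
#' data frame, validating every row. Malformed rows (wrong column count,
#' non-positive hits, non-numeric e-value, prefix-inconsistent lineage) raise
#' an error naming the offending line.
#'
#' @param path Path to a TSV file in the annotation dialect.
#' @return A data frame with one row per annotation record, input order
#'   preserved.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != length(annotation_columns()))
  if (length(bad) > 0)
    stop("malformed row: expected ", length(annotation_columns()),
         " tab-separated fields, got ", nf[bad[1]], " at line ", bad[1])
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = "NA", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(names(tab), annotation_columns()))
    stop("header does not match the annotation-table dialect")
  for (col in c("evalue", "identity_pct")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    conv_fail <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(conv_fail) > 0)
      stop("non-numeric ", col, " at line ", conv_fail[1] + 1L)
    tab[[col]] <- v
  }
  for (col in c("hits", "aln_len")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    conv_fail <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(conv_fail) > 0)
      stop("non-numeric ", col, " at line ", conv_fail[1] + 1L)
    tab[[col]] <- as.integer(round(v))
  }
  validate_annotation_table(tab)
  rownames(tab) <- NULL
  tab
}

#' Write an annotation table
#'
#' Writes the dialect deterministically: fixed column order, input row order,
#' `"NA"` for missing values, tab separators, UTF-8. Two writes of the same
#' table are byte-identical, and `read_annotation_table()` recovers the table
#' field-for-field.
#'
#' @param tab Annotation table (data frame).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(tab, path) {
  validate_annotation_table(tab)
  out <- tab[, annotation_columns(), drop = FALSE]
  num_fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out$evalue <- num_fmt(out$evalue)
  out$identity_pct <- num_fmt(out$identity_pct)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Filter annotation records on alignment quality and domain
#'
#' Retains records with `evalue <= evalue_max`, `aln_len >= aln_len_min` and
#' `identity_pct >=` the identity floor of the chosen profiling mode (60% for
#' `"taxonomic"`, 80% for `"functional"` by default). Records whose domain is
#' not `"Bacteria"` are dropped as well (eukaryote, archaeon and virus hits are
#' excluded from profiling). Row order is preserved and no field values are
#' altered; filtering is idempotent.
#'
#' @param tab Annotation table.
#' @param thresholds A [threshold_config()].
#' @param mode `"taxonomic"` or `"functional"` -- selects the identity floor.
#' @return The filtered annotation table.
#' @seealso [annotation_summary()] for the pre-filter domain composition.
#' @export
apply_annotation_filters <- function(tab, thresholds = threshold_config(),
                                     mode = c("taxonomic", "functional")) {
  mode <- match.arg(mode)
  validate_annotation_table(tab)
  identity_min <- switch(mode,
                         taxonomic = thresholds$identity_min_tax,
                         functional = thresholds$identity_min_fun)
  keep <- tab$evalue <= thresholds$evalue_max &
    tab$aln_len >= thresholds$aln_len_min &
    tab$identity_pct >= identity_min &
    !is.na(tab$domain) & tab$domain == "Bacteria"
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domain composition of an annotation table
#'
#' Tallies hits by taxonomic domain before any filtering, so the percentage of
#' bacteria-domain features can be reported ahead of their removal (the
#' "Bacteria domain (%)" style summary of annotation runs).
#'
#' @param tab Annotation table.
#' @return A list with `by_domain` (named hit totals, missing domain counted as
#'   `"unclassified"`) and `pct_bacteria` (percent of hits annotated as
#'   Bacteria).
#' @export
annotation_summary <- function(tab) {
  validate_annotation_table(tab)
  dom <- ifelse(is.na(tab$domain), "unclassified", tab$domain)
  by_domain <- tapply(tab$hits, dom, sum)
  total <- sum(tab$hits)
  pct_bacteria <- if (total == 0) 0 else
    100 * sum(by_domain[names(by_domain) == "Bacteria"]) / total
  list(by_domain = by_domain, pct_bacteria = unname(pct_bacteria))
}

#' Best-hit classification
#'
#' Reduces an annotation table to exactly one record per
#' `(feature_id, sample_id)` pair: the record with the smallest e-value, ties
#' broken by largest identity, then longest alignment, then lexicographically
#' smallest `subject_id` -- a fully deterministic rule. Field values of the
#' surviving records are unchanged.
#'
#' @param tab Annotation table (typically already filtered).
#' @return Annotation table with one row per feature and sample, ordered by
#'   first appearance of each pair.
#' @export
best_hit_classification <- function(tab) {
  validate_annotation_table(tab)
  if (nrow(tab) == 0) return(tab)
  # order within each pair by the tie-break chain, then keep the first record
  ord <- order(tab$feature_id, tab$sample_id,
               tab$evalue, -tab$identity_pct, -tab$aln_len, tab$subject_id,
               method = "radix")
  sorted <- tab[ord, , drop = FALSE]
  key <- paste(sorted$feature_id, sorted$sample_id, sep = "\r")
  best <- sorted[!duplicated(key), , drop = FALSE]
  # restore first-appearance order of pairs
  key_in <- paste(tab$feature_id, tab$sample_id, sep = "\r")
  first_seen <- match(paste(best$feature_id, best$sample_id, sep = "\r"),
                      unique(key_in))
  out <- best[order(first_seen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read sample metadata
#'
#' @param path TSV with header `sample_id species sex`.
#' @return Data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "sex")
  if (!all(need %in% names(md)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md
}

#' Write sample metadata
#'
#' @param md Data frame with `sample_id`, `species`, `sex`.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md[, c("sample_id", "species", "sex")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
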