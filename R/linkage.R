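#' Link differential functions to the genera harboring them
#'
#' Builds the taxon-function edge set behind Sankey-style linkage plots:
#' one edge per (enzyme, genus, group) with `hits` summed over the
#' qualifying annotation records. A record qualifies when its `func_l4`
#' identifier is among the differential enzymes and it carries a resolved
#' genus on the same row (same feature) -- the join never crosses reads.
#' Records matching a differential enzyme but lacking a genus are counted in
#' a separate `unassigned` tally, not as edges. Optional group merging
#' (e.g. pooling two related species' samples into one label per sex) sums
#' hits across the merged samples.
#'
#' @param tab Best-hit classified annotation table (functional mode).
#' @param diff_enzymes Character vector of differential function ids
#'   (`func_l4` values); must be non-empty.
#' @param merge_groups Optional named character vector mapping
#'   `sample_id -> group label`; unmapped samples keep their own id.
#' @return A list of class `"linkage_edges"`: `edges` (data frame `enzyme`,
#'   `genus`, `group`, `hits`), `unassigned` (hit tally of genus-unresolved
#'   qualifying records).
#' @export
build_linkage_edges <- function(tab, diff_enzymes, merge_groups = NULL) {
  if (length(diff_enzymes) == 0) stop("diff_enzymes must be non-empty")
  validate_annotation_table(tab)
  sel <- !is.na(tab$func_l4) & tab$func_l4 %in% diff_enzymes
  sub <- tab[sel, , drop = FALSE]
  group <- sub$sample_id
  if (!is.null(merge_groups)) {
    mapped <- !is.na(match(group, names(merge_groups)))
    group[mapped] <- merge_groups[group[mapped]]
  }
  unresolved <- is.na(sub$genus)
  unassigned <- sum(sub$hits[unresolved])
  sub <- sub[!unresolved, , drop = FALSE]
  group <- group[!unresolved]
  if (nrow(sub) == 0) {
    warning("no qualifying genus-resolved records; empty edge set")
    edges <- data.frame(enzyme = character(0), genus = character(0),
                        group = character(0), hits = integer(0),
                        stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(sub$hits,
                            by = list(enzyme = sub$func_l4, genus = sub$genus,
                                      group = group),
                            FUN = sum)
    names(agg)[4] <- "hits"
    agg <- agg[order(agg$enzyme, agg$genus, agg$group), ]
    rownames(agg) <- NULL
    edges <- agg
  }
  structure(list(edges = edges, unassigned = unassigned),
            class = "linkage_edges")
}

as_edge_frame <- function(edges) {
  if (inherits(edges, "linkage_edges")) edges$edges
  else if (is.data.frame(edges)) {
    need <- c("enzyme", "genus", "group", "hits")
    if (!all(need %in% names(edges)))
      stop("edge frame needs columns: ", paste(need, collapse = ", "))
    edges
  } else stop("expected linkage_edges or a data frame of edges")
}

#' Enzyme-to-genus redundancy spectrum
#'
#' For each enzyme, counts the number of distinct genera harboring it
#' (pooled over all groups), and bins the enzymes into the redundancy bins
#' (1, 2--4, 5--10, >= 11 genera by default). The per-enzyme counts are
#' returned so any alternative binning can be recomputed.
#'
#' @param edges A [build_linkage_edges()] result or edge data frame.
#' @param bins Named list of `c(lower, upper)` genus-count bins
#'   (default [redundancy_bins()]).
#' @return A list of class `"redundancy_spectrum"`: `per_enzyme` (named
#'   genus counts), `fractions` (per-bin fraction of enzymes, summing to 1),
#'   `n_enzymes`.
#' @export
redundancy_spectrum <- function(edges, bins = redundancy_bins()) {
  ef <- as_edge_frame(edges)
  if (nrow(ef) == 0) stop("empty edge set")
  pairs <- unique(ef[, c("enzyme", "genus")])
  per_enzyme <- table(pairs$enzyme)
  per_enzyme <- stats::setNames(as.integer(per_enzyme), names(per_enzyme))
  fractions <- vapply(bins, function(b)
    mean(per_enzyme >= b[1] & per_enzyme <= b[2]), numeric(1))
  structure(list(per_enzyme = per_enzyme, fractions = fractions,
                 n_enzymes = length(per_enzyme)),
            class = "redundancy_spectrum")
}

#' @export
print.redundancy_spectrum <- function(x, ...) {
  cat("redundancy spectrum over", x$n_enzymes, "enzymes\n")
  print(round(100 * x$fractions, 1))
  invisible(x)
}

#' Genus contributions to the differential-function pool
#'
#' Per-genus totals over the linkage edges: hit share (% of all linkage
#' hits), number of distinct enzymes carried, and the per-group (e.g. sex)
#' hit split for mirror bar plots. The summary reports the cumulative share
#' of the `top_k` genera and the fraction of genera carrying exactly one
#' enzyme.
#'
#' @param edges A [build_linkage_edges()] result or edge data frame.
#' @param top_k Number of top genera for the cumulative share (default 5).
#' @return A list of class `"genus_contribution"`: `per_genus` (data frame
#'   `genus`, `hits`, `share_pct`, `n_enzymes`, one column per group),
#'   `top_k`, `top_k_share_pct`, `single_enzyme_fraction`.
#' @export
genus_contributions <- function(edges, top_k = 5) {
  ef <- as_edge_frame(edges)
  if (nrow(ef) == 0) stop("empty edge set")
  stopifnot(top_k >= 1)
  total_hits <- sum(ef$hits)
  hits_by_genus <- tapply(ef$hits, ef$genus, sum)
  enz_by_genus <- vapply(split(ef$enzyme, ef$genus),
                         function(e) length(unique(e)), integer(1))
  groups <- sort(unique(ef$group))
  split_mat <- vapply(groups, function(g) {
    v <- tapply(ef$hits[ef$group == g], ef$genus[ef$group == g], sum)
    out <- stats::setNames(numeric(length(hits_by_genus)), names(hits_by_genus))
    out[names(v)] <- v
    out
  }, numeric(length(hits_by_genus)))
  if (is.null(dim(split_mat)))
    split_mat <- matrix(split_mat, ncol = length(groups),
                        dimnames = list(names(hits_by_genus), groups))
  per_genus <- data.frame(genus = names(hits_by_genus),
                          hits = as.integer(hits_by_genus),
                          share_pct = 100 * as.numeric(hits_by_genus) / total_hits,
                          n_enzymes = enz_by_genus[names(hits_by_genus)],
                          split_mat[names(hits_by_genus), , drop = FALSE],
                          row.names = NULL, stringsAsFactors = FALSE,
                          check.names = FALSE)
  per_genus <- per_genus[order(-per_genus$share_pct, per_genus$genus), ]
  rownames(per_genus) <- NULL
  k <- min(top_k, nrow(per_genus))
  structure(list(per_genus = per_genus,
                 top_k = k,
                 top_k_share_pct = sum(per_genus$share_pct[seq_len(k)]),
                 single_enzyme_fraction = mean(per_genus$n_enzymes == 1)),
            class = "genus_contribution")
}

#' @export
print.genus_contribution <- function(x, ...) {
  cat(sprintf("genus contributions: top-%d share %.1f%%, %.1f%% of genera carry a single enzyme\n",
              x$top_k, x$top_k_share_pct, 100 * x$single_enzyme_fraction))
  print(utils::head(x$per_genus, x$top_k))
  invisible(x)
}

#' Dual-role partition of differential genera
#'
#' Splits the union of two genus sets -- genera with differential abundance
#' between groups ("differential taxonomic profiles") and genera providing
#' differentially abundant functions ("providers of differential
#' functions") -- into the three disjoint classes: taxonomic-only,
#' functional-only, and the dual-role overlap.
#'
#' @param diff_taxa_genera Character vector (may be empty).
#' @param provider_genera Character vector (may be empty).
#' @return A list of class `"dual_role_partition"`: `taxonomic_only`,
#'   `functional_only`, `overlap` (sorted character vectors).
#' @export
dual_role_partition <- function(diff_taxa_genera, provider_genera) {
  a <- unique(as.character(diff_taxa_genera))
  b <- unique(as.character(provider_genera))
  structure(list(taxonomic_only = sort(setdiff(a, b)),
                 functional_only = sort(setdiff(b, a)),
                 overlap = sort(intersect(a, b))),
            class = "dual_role_partition")
}

#' Write linkage outputs
#'
#' Emits the Sankey-ready edge list TSV (`enzyme genus group hits`), the
#' per-enzyme spectrum TSV (`enzyme n_genera`), and a summary JSON with
#' binned redundancy fractions, top-k share, single-enzyme fraction and the
#' unassigned tally.
#'
#' @param edges A [build_linkage_edges()] result.
#' @param dir Output directory (created if needed).
#' @param top_k Passed to [genus_contributions()].
#' @return `dir`, invisibly.
#' @export
write_linkage_outputs <- function(edges, dir, top_k = 5) {
  stopifnot(inherits(edges, "linkage_edges"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(edges$edges, file.path(dir, "linkage_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- redundancy_spectrum(edges)
  utils::write.table(data.frame(enzyme = names(spec$per_enzyme),
                                n_genera = spec$per_enzyme),
                     file.path(dir, "redundancy_spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  contrib <- genus_contributions(edges, top_k)
  utils::write.table(contrib$per_genus,
                     file.path(dir, "genus_contributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(binned_fractions = as.list(spec$fractions),
         n_enzymes = spec$n_enzymes,
         top_k = contrib$top_k,
         top_k_share_pct = contrib$top_k_share_pct,
         single_enzyme_fraction = contrib$single_enzyme_fraction,
         unassigned_hits = edges$unassigned),
    file.path(dir, "linkage_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
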