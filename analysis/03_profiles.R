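#!/usr/bin/env Rscript
# Annotation filtering, best-hit classification and abundance profiling:
# genus- and phylum-level taxonomic matrices (identity >= 60%) and
# functional matrices at category and enzyme level (identity >= 80%),
# with median-of-ratios size factors and relative abundances.

suppressMessages(library(taxfunlink))

out <- "results/synthetic"
ann <- read_annotation_table(file.path(out, "annotations.tsv"))

summ <- annotation_summary(ann)
cat(sprintf("%% of hits in Bacteria domain before filtering: %.1f\n",
            summ$pct_bacteria))

for (mode in c("taxonomic", "functional")) {
  filtered <- apply_annotation_filters(ann, mode = mode)
  cat(sprintf("%s mode: %d of %d records pass the thresholds\n",
              mode, nrow(filtered), nrow(ann)))
  tab <- best_hit_classification(filtered)
  levels <- if (mode == "taxonomic") c("genus", "phylum") else
    c("func_l1", "func_l4")
  for (lvl in levels) {
    m <- estimate_size_factors(aggregate_counts(tab, lvl))
    write_abundance_matrix(m, file.path(out, paste0("counts_", lvl, ".tsv")))
    write_abundance_matrix(to_relative(m),
                           file.path(out, paste0("relabund_", lvl, ".tsv")))
    cat(sprintf("  level %-8s: %3d features; size factors %s\n", lvl,
                nrow(m$counts),
                paste(round(m$size_factors, 3), collapse = " ")))
  }
  write_annotation_table(tab, file.path(out, paste0("besthit_", mode, ".tsv")))
}
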