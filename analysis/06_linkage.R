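#!/usr/bin/env Rscript
# Taxon-function linkage: link enzymes that differ between sexes to the
# genera harboring them, quantify the redundancy spectrum and per-genus
# contribution shares, and partition genera by taxonomic/functional role.

suppressMessages(library(taxfunlink))

out <- "results/synthetic"
md <- read_sample_metadata(file.path(out, "metadata.tsv"))
fun_tab <- read_annotation_table(file.path(out, "besthit_functional.tsv"))
th <- threshold_config()

# enzymes differential in any species (q < 0.05 from stage 05)
diff_enzymes <- unique(unlist(lapply(unique(md$species), function(sp) {
  res <- read.delim(file.path(out, sprintf("diff_func_l4_%s.tsv", sp)))
  res$feature[res$enriched_in != "none" & res$feature != "unclassified"]
})))
cat("differential enzymes across species:", length(diff_enzymes), "\n")

# merge the two samples of each sex across species 2 and 3 (the paired
# congeneric species), mirroring a merged-species linkage view
pair <- md[md$species %in% c("TickSp2", "TickSp3"), ]
merge_map <- setNames(paste0("Sp23.", pair$sex), pair$sample_id)

edges <- build_linkage_edges(fun_tab, diff_enzymes, merge_groups = merge_map)
write_linkage_outputs(edges, file.path(out, "linkage"))
spec <- redundancy_spectrum(edges)
contrib <- genus_contributions(edges, top_k = 5)
print(spec)
print(contrib)

# dual-role partition: differentially abundant genera vs function providers
diff_genera <- unique(unlist(lapply(unique(md$species), function(sp) {
  res <- read.delim(file.path(out, sprintf("diff_genus_%s.tsv", sp)))
  res$feature[res$enriched_in != "none" & res$feature != "unclassified"]
})))
part <- dual_role_partition(diff_genera, contrib$per_genus$genus)
jsonlite::write_json(unclass(part), file.path(out, "dual_role_partition.json"),
                     auto_unbox = FALSE, digits = NA)
cat(sprintf("dual-role overlap: %d genera; taxonomic-only: %d; functional-only: %d\n",
            length(part$overlap), length(part$taxonomic_only),
            length(part$functional_only)))
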