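#!/usr/bin/env Rscript
# Community structure of the genus-level profiles: rarefaction curves,
# alpha diversity (observed richness and Shannon), Venn partitions of shared
# genera, Bray-Curtis dissimilarities with ANOSIM by sex, and PCA.

suppressMessages(library(taxfunlink))

out <- "results/synthetic"
m <- read_abundance_matrix(file.path(out, "counts_genus.tsv"))
md <- read_sample_metadata(file.path(out, "metadata.tsv"))
counts <- m$counts[rownames(m$counts) != "unclassified", , drop = FALSE]

# rarefaction + alpha diversity
curves <- do.call(rbind, lapply(colnames(counts), function(s) {
  cbind(sample_id = s, rarefaction_curve(counts[, s]))
}))
write.table(curves, file.path(out, "rarefaction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
alpha <- data.frame(
  sample_id = colnames(counts),
  richness = colSums(counts > 0),
  shannon = apply(counts, 2, shannon_diversity))
write.table(alpha, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("alpha diversity:\n"); print(alpha, row.names = FALSE)

# shared genera between the sexes
genera_by_sex <- lapply(split(md$sample_id, md$sex), function(ids)
  rownames(counts)[rowSums(counts[, ids, drop = FALSE] > 0) > 0])
venn <- venn_partition(genera_by_sex)
write.table(venn, file.path(out, "venn_sex.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("genus sharing between sexes:\n"); print(venn, row.names = FALSE)

# dissimilarity, ANOSIM, ordination on relative abundances
rel <- to_relative(counts)
d <- bray_curtis_matrix(rel)
write.table(data.frame(sample_id = rownames(d), d),
            file.path(out, "bray_curtis_genus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sex <- md$sex[match(colnames(d), md$sample_id)]
an <- anosim(d, sex, n_perm = 999, seed = 1)
cat("ANOSIM (genus profiles, groups = sex): ")
print(an)

pca <- pca_ordination(rel)
scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     check.names = FALSE)
write.table(scores, file.path(out, "pca_scores_genus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCA: first axis explains %.1f%% of genus-profile variance\n",
            100 * pca$var_explained[1]))
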