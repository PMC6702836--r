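#!/usr/bin/env Rscript
# Read-level QC on the simulated FASTQ: dynamic-trim quality filtering
# (Phred floor 15, at most 5 bases below) and artificial-replicate removal,
# with before/after summary statistics in the style of a sequencing QC table.

suppressMessages(library(taxfunlink))

out <- "results/synthetic"
reads <- read_fastq(file.path(out, "reads.fastq"))
qc <- run_read_qc(reads, qc_params())

row_of <- function(s) data.frame(
  bp_count = s$bp_count, seq_count = s$seq_count,
  len_mean = round(s$len_mean, 1), len_sd = round(s$len_sd, 1),
  gc_mean = round(s$gc_mean, 1), gc_sd = round(s$gc_sd, 1))
summary_tab <- cbind(stage = c("upload", "post_qc"),
                     rbind(row_of(qc$summary_before), row_of(qc$summary_after)))
write.table(summary_tab, file.path(out, "qc_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fastq(qc$kept, file.path(out, "reads_qc.fastq"))

cat("reads in:", nrow(reads), "\n")
cat("removed by quality trimming:", qc$removed_quality, "\n")
cat("removed as artificial replicates:", qc$removed_duplicates, "\n")
print(summary_tab)
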