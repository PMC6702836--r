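# Small constructors shared across test files.

make_record <- function(feature_id = "f1", sample_id = "S1", hits = 1L,
                        evalue = 1e-10, identity_pct = 90, aln_len = 50L,
                        domain = "Bacteria", phylum = "P1", class = "C1",
                        order = "O1", family = "F1", genus = "G1",
                        func_l1 = "L1", func_l2 = "L2", func_l3 = "L3",
                        func_l4 = "1.1.1.1", subject_id = "subj1") {
  data.frame(feature_id = feature_id, sample_id = sample_id, hits = hits,
             evalue = evalue, identity_pct = identity_pct, aln_len = aln_len,
             domain = domain, phylum = phylum, class = class, order = order,
             family = family, genus = genus, func_l1 = func_l1,
             func_l2 = func_l2, func_l3 = func_l3, func_l4 = func_l4,
             subject_id = subject_id, stringsAsFactors = FALSE)
}

rand_annotation_table <- function(n, seed = 1, n_samples = 2, n_genera = 4) {
  set.seed(seed)
  genus <- sprintf("G%d", sample.int(n_genera, n, replace = TRUE))
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(feature_id = sprintf("f%04d", i),
                sample_id = sprintf("S%d", sample.int(n_samples, 1)),
                hits = sample.int(5, 1),
                evalue = 10^runif(1, -30, -6),
                identity_pct = round(runif(1, 80, 100), 1),
                aln_len = sample(20:120, 1),
                genus = genus[i],
                func_l4 = sprintf("%d.%d.%d.%d", sample.int(6, 1),
                                  sample.int(9, 1), sample.int(9, 1),
                                  sample.int(30, 1)),
                subject_id = sprintf("M5_%06d", sample.int(999999, 1)))
  }))
}

make_reads <- function(seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

# quality string from integer Phred values
qual_str <- function(phred) rawToChar(as.raw(phred + 33L))
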