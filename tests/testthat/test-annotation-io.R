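test_that("annotation tables round-trip and writes are byte-stable", {
  tab <- rbind(make_record(feature_id = "a", evalue = 1e-7),
               make_record(feature_id = "b", genus = NA_character_,
                           func_l4 = NA_character_, func_l1 = NA_character_,
                           func_l2 = NA_character_, func_l3 = NA_character_),
               make_record(feature_id = "c", identity_pct = 61.5))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tab, f1)
  write_annotation_table(tab, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_equal(read_annotation_table(f1), tab)
})

test_that("an empty table writes a header-only file", {
  tab <- make_record()[0, ]
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tab, tf)
  expect_length(readLines(tf), 1L)
  expect_identical(nrow(read_annotation_table(tf)), 0L)
})

test_that("malformed rows raise parse errors naming the line", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  good <- make_record()
  write_annotation_table(good, tf)
  lines <- readLines(tf)

  set_field <- function(line, col, value) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    f[match(col, annotation_columns())] <- value
    paste(f, collapse = "\t")
  }

  # negative hits
  writeLines(c(lines[1], set_field(lines[2], "hits", "-1")), tf)
  expect_error(read_annotation_table(tf), "hits.*line 2")

  # non-numeric evalue
  writeLines(c(lines[1], set_field(lines[2], "evalue", "oops")), tf)
  expect_error(read_annotation_table(tf), "evalue.*line 2")

  # wrong column count
  writeLines(c(lines[1], paste(lines[2], "extra", sep = "\t")), tf)
  expect_error(read_annotation_table(tf), "malformed row.*line 2")
})

test_that("missing genus is parsed as missing and counted separately", {
  tab <- rbind(make_record(feature_id = "f1"),
               make_record(feature_id = "f2"),
               make_record(feature_id = "f3"),
               make_record(feature_id = "f4", family = NA_character_,
                           genus = NA_character_),
               make_record(feature_id = "f5", family = NA_character_,
                           genus = NA_character_))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tab, tf)
  back <- read_annotation_table(tf)
  expect_identical(nrow(back), 5L)
  expect_identical(sum(!is.na(back$genus)), 3L)
})

test_that("prefix-inconsistent lineages are rejected", {
  bad <- make_record(family = NA_character_)  # genus present, family missing
  expect_error(validate_annotation_table(bad), "prefix-consistent")
})

test_that("filters apply the paper-default thresholds inclusively", {
  th <- threshold_config()
  base <- make_record(evalue = 1e-8, identity_pct = 90, aln_len = 30)

  # e-value cut-off 1e-5: 1e-4 removed, boundary kept
  expect_identical(nrow(apply_annotation_filters(
    transform(base, evalue = 1e-4), th, "taxonomic")), 0L)
  expect_identical(nrow(apply_annotation_filters(
    transform(base, evalue = 1e-5), th, "taxonomic")), 1L)

  # identity floors 60 (taxonomic) vs 80 (functional)
  mid <- transform(base, identity_pct = 70)
  expect_identical(nrow(apply_annotation_filters(mid, th, "taxonomic")), 1L)
  expect_identical(nrow(apply_annotation_filters(mid, th, "functional")), 0L)

  # alignment length 15 bp, inclusive boundary
  expect_identical(nrow(apply_annotation_filters(
    transform(base, aln_len = 14L), th, "taxonomic")), 0L)
  expect_identical(nrow(apply_annotation_filters(
    transform(base, aln_len = 15L), th, "taxonomic")), 1L)

  # non-bacterial domains removed
  euk <- make_record(domain = "Eukaryota", phylum = NA_character_,
                     class = NA_character_, order = NA_character_,
                     family = NA_character_, genus = NA_character_)
  expect_identical(nrow(apply_annotation_filters(euk, th, "taxonomic")), 0L)
})

test_that("filtering is idempotent and preserves surviving records", {
  tab <- rand_annotation_table(200, seed = 4)
  tab$evalue[1:30] <- 1e-3
  tab$domain[31:40] <- "Eukaryota"
  tab[31:40, c("phylum", "class", "order", "family", "genus")] <- NA
  once <- apply_annotation_filters(tab, mode = "functional")
  twice <- apply_annotation_filters(once, mode = "functional")
  expect_identical(once, twice)
  # surviving rows are untouched field-for-field
  expect_equal(once, tab[tab$evalue <= 1e-5 & tab$domain == "Bacteria", ],
               ignore_attr = TRUE)
})

test_that("annotation_summary reports pre-filter domain shares", {
  tab <- rbind(make_record(hits = 9L),
               make_record(domain = "Eukaryota", phylum = NA_character_,
                           class = NA_character_, order = NA_character_,
                           family = NA_character_, genus = NA_character_))
  s <- annotation_summary(tab)
  expect_equal(s$pct_bacteria, 90)
})

test_that("best-hit classification applies the deterministic tie-break chain", {
  # smallest e-value wins
  t1 <- rbind(make_record(evalue = 1e-10, subject_id = "x"),
              make_record(evalue = 1e-7, subject_id = "y"))
  expect_identical(best_hit_classification(t1)$subject_id, "x")

  # single record unchanged
  single <- make_record()
  expect_equal(best_hit_classification(single), single)

  # full tie except subject_id: lexicographically smallest survives
  t2 <- rbind(make_record(subject_id = "B"), make_record(subject_id = "A"))
  expect_identical(best_hit_classification(t2)$subject_id, "A")

  # intermediate ties: identity then alignment length
  t3 <- rbind(make_record(identity_pct = 85, subject_id = "p"),
              make_record(identity_pct = 95, subject_id = "q"))
  expect_identical(best_hit_classification(t3)$subject_id, "q")
  t4 <- rbind(make_record(aln_len = 40L, subject_id = "p"),
              make_record(aln_len = 80L, subject_id = "q"))
  expect_identical(best_hit_classification(t4)$subject_id, "q")
})

test_that("best-hit output has one record per feature-sample pair", {
  tab <- rand_annotation_table(300, seed = 6, n_samples = 3)
  tab$feature_id <- sprintf("f%03d", sample.int(80, nrow(tab), replace = TRUE))
  out <- best_hit_classification(tab)
  key_in <- unique(paste(tab$feature_id, tab$sample_id))
  expect_identical(nrow(out), length(key_in))
  expect_identical(anyDuplicated(paste(out$feature_id, out$sample_id)), 0L)
  # every surviving row is one of the input rows, unaltered
  expect_true(all(do.call(paste, out) %in% do.call(paste, tab)))
})
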