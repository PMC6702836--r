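linkage_table <- function() {
  rbind(make_record(feature_id = "r1", sample_id = "S1", hits = 2L,
                    genus = "A", func_l4 = "E1"),
        make_record(feature_id = "r2", sample_id = "S1", hits = 1L,
                    genus = "B", func_l4 = "E1"),
        make_record(feature_id = "r3", sample_id = "S1", hits = 1L,
                    genus = "A", func_l4 = "E2"))
}

test_that("edges join enzymes to genera on the same feature row", {
  le <- build_linkage_edges(linkage_table(), diff_enzymes = "E1")
  expect_identical(nrow(le$edges), 2L)
  expect_equal(le$edges$hits[le$edges$genus == "A"], 2)
  expect_equal(le$edges$hits[le$edges$genus == "B"], 1)
  expect_false("E2" %in% le$edges$enzyme)
  expect_identical(le$unassigned, 0L)
  expect_error(build_linkage_edges(linkage_table(), character(0)),
               "non-empty")
})

test_that("group merging sums hits and unresolved genera are tallied", {
  tab <- rbind(make_record(feature_id = "r1", sample_id = "IOf", hits = 2L,
                           genus = "A", func_l4 = "E1"),
               make_record(feature_id = "r2", sample_id = "IPf", hits = 3L,
                           genus = "A", func_l4 = "E1"),
               make_record(feature_id = "r3", sample_id = "IOf", hits = 4L,
                           family = NA_character_, genus = NA_character_,
                           func_l4 = "E1"))
  le <- build_linkage_edges(tab, "E1",
                            merge_groups = c(IOf = "Ix.f", IPf = "Ix.f"))
  expect_identical(nrow(le$edges), 1L)
  expect_equal(le$edges$hits, 5)
  expect_identical(le$edges$group, "Ix.f")
  expect_equal(le$unassigned, 4L)
  # conservation: edge hits + unassigned = qualifying record hits
  expect_equal(sum(le$edges$hits) + le$unassigned, sum(tab$hits))
})

test_that("redundancy spectrum bins distinct genera per enzyme", {
  edges <- data.frame(
    enzyme = c("E1", "E2", "E2", "E2", "E2", "E2"),
    genus = c("A", "A", "B", "C", "D", "E"),
    group = "G1", hits = 1, stringsAsFactors = FALSE)
  sp <- redundancy_spectrum(edges)
  expect_equal(unname(sp$fractions["single"]), 0.5)
  expect_equal(unname(sp$fractions["mid"]), 0.5)
  expect_equal(sum(sp$fractions), 1, tolerance = 1e-12)

  mono <- data.frame(enzyme = c("E1", "E2"), genus = c("A", "B"),
                     group = "G1", hits = 1)
  expect_equal(unname(redundancy_spectrum(mono)$fractions["single"]), 1)
  expect_error(redundancy_spectrum(mono[0, ]), "empty")
})

test_that("redundancy spectrum is invariant to group merging", {
  set.seed(25)
  edges <- data.frame(
    enzyme = sprintf("E%d", sample.int(6, 40, replace = TRUE)),
    genus = sprintf("G%d", sample.int(8, 40, replace = TRUE)),
    group = sample(c("IOf", "IOm", "IPf", "IPm"), 40, replace = TRUE),
    hits = sample.int(5, 40, replace = TRUE), stringsAsFactors = FALSE)
  merged <- edges
  merged$group <- sub("^I[OP]", "Ix.", merged$group)
  expect_equal(redundancy_spectrum(edges)$per_enzyme,
               redundancy_spectrum(merged)$per_enzyme)
})

test_that("genus contributions compute shares, splits and summaries", {
  edges <- data.frame(enzyme = c("E1", "E2", "E2"),
                      genus = c("A", "A", "B"),
                      group = c("f", "m", "f"),
                      hits = c(3, 1, 1), stringsAsFactors = FALSE)
  gcb <- genus_contributions(edges, top_k = 1)
  pg <- gcb$per_genus
  expect_equal(pg$share_pct[pg$genus == "A"], 80)
  expect_equal(pg$share_pct[pg$genus == "B"], 20)
  expect_equal(pg$n_enzymes[pg$genus == "A"], 2L, ignore_attr = TRUE)
  expect_equal(gcb$single_enzyme_fraction, 0.5)
  expect_equal(gcb$top_k_share_pct, 80)
  expect_equal(pg$f[pg$genus == "A"], 3)
  expect_equal(pg$m[pg$genus == "A"], 1)

  solo <- genus_contributions(edges[edges$genus == "A", ], top_k = 1)
  expect_equal(solo$top_k_share_pct, 100)
})

test_that("genus shares are invariant to scaling all hits", {
  set.seed(33)
  edges <- data.frame(
    enzyme = sprintf("E%d", sample.int(5, 30, replace = TRUE)),
    genus = sprintf("G%d", sample.int(6, 30, replace = TRUE)),
    group = sample(c("f", "m"), 30, replace = TRUE),
    hits = sample.int(9, 30, replace = TRUE), stringsAsFactors = FALSE)
  scaled <- edges
  scaled$hits <- scaled$hits * 7
  a <- genus_contributions(edges)
  b <- genus_contributions(scaled)
  expect_equal(a$per_genus$share_pct, b$per_genus$share_pct, tolerance = 1e-12)
  expect_equal(a$top_k_share_pct, b$top_k_share_pct, tolerance = 1e-12)
})

test_that("noiseless synthetic data recover the planted repertoire exactly", {
  cfg <- generator_config(n_species = 1, n_genera = 10, n_enzymes = 10,
                          spectrum_targets = c(single = 0.5, low = 0.5,
                                               mid = 0, high = 0),
                          n_diff_genera = 0, reads_per_sample = 5000,
                          p_unannotated_function = 0,
                          noise = noise_config(p_fail = 0), seed = 61)
  tr <- build_ground_truth(cfg)
  sim <- simulate_annotation_tables(tr)
  bh <- best_hit_classification(
    apply_annotation_filters(sim$annotations, mode = "functional"))
  le <- build_linkage_edges(bh, diff_enzymes = tr$enzyme_catalog)
  # observed incidence equals the planted repertoire restricted to sampled
  # genus-enzyme pairs; at this depth every pair is sampled
  obs <- unique(le$edges[, c("enzyme", "genus")])
  inc <- matrix(FALSE, nrow = nrow(tr$repertoire), ncol = ncol(tr$repertoire),
                dimnames = dimnames(tr$repertoire))
  inc[cbind(obs$genus, obs$enzyme)] <- TRUE
  expect_identical(inc, tr$repertoire)
  # and the binned spectrum equals the integral targets exactly
  sp <- redundancy_spectrum(le)
  expect_equal(unname(sp$fractions),
               unname(cfg$spectrum_targets[names(redundancy_bins())]),
               tolerance = 1e-12)
  # conservation through the join
  qualifying <- bh[!is.na(bh$func_l4), ]
  expect_equal(sum(le$edges$hits) + le$unassigned, sum(qualifying$hits))
})

test_that("dual-role partition is a disjoint cover of the union", {
  p <- dual_role_partition(c("A", "B", "C"), c("B", "D"))
  expect_identical(p$overlap, "B")
  expect_identical(p$taxonomic_only, c("A", "C"))
  expect_identical(p$functional_only, "D")

  same <- dual_role_partition(c("X", "Y"), c("Y", "X"))
  expect_length(same$taxonomic_only, 0)
  expect_length(same$functional_only, 0)

  set.seed(44)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    pr <- dual_role_partition(a, b)
    parts <- c(pr$taxonomic_only, pr$functional_only, pr$overlap)
    expect_identical(anyDuplicated(parts), 0L)
    expect_setequal(parts, union(a, b))
  }
})

test_that("linkage outputs are written as loadable tables", {
  le <- build_linkage_edges(linkage_table(), c("E1", "E2"))
  dir <- withr::local_tempdir()
  write_linkage_outputs(le, dir)
  edges_back <- read.delim(file.path(dir, "linkage_edges.tsv"))
  expect_equal(sum(edges_back$hits), sum(le$edges$hits))
  summ <- jsonlite::read_json(file.path(dir, "linkage_summary.json"))
  expect_equal(summ$n_enzymes, 2L)
})
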