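test_that("expected rarefaction richness matches enumeration on tiny cases", {
  # counts [2,2], depth 1: each draw sees exactly one taxon
  expect_equal(rarefaction_expected(c(2, 2), 1), 1)
  # counts [3,1], depth 2: enumeration over all C(4,2)=6 subsets gives 1.5
  expect_equal(rarefaction_expected(c(3, 1), 2), 1.5)
  # depth = total: observed richness exactly
  expect_equal(rarefaction_expected(c(5, 3, 2), 10), 3)
  expect_equal(rarefaction_expected(c(5, 3, 2), 0), 0)
  expect_error(rarefaction_expected(c(2, 2), 5), "depth")
})

test_that("expected rarefaction matches Monte-Carlo subsampling", {
  counts <- c(12, 7, 3, 1, 1, 25, 4)
  depth <- 15
  set.seed(99)
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(10000, length(unique(sample(pool, depth))))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefaction_expected(counts, depth) - mean(draws)), 3 * se)
})

test_that("rarefaction agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  counts <- c(40, 11, 6, 2, 1, 90)
  for (d in c(5, 25, 80))
    expect_equal(rarefaction_expected(counts, d),
                 as.numeric(vegan::rarefy(counts, d)), tolerance = 1e-9)
})

test_that("Shannon diversity matches hand arithmetic and vegan", {
  expect_equal(shannon_diversity(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_diversity(c(5)), 0)
  p <- c(3, 1) / 4
  expect_equal(shannon_diversity(c(3, 1)), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon_diversity(c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  v <- c(9, 4, 1, 7, 2)
  expect_equal(shannon_diversity(v), unname(vegan::diversity(v)),
               tolerance = 1e-12)
})

test_that("Bray-Curtis dissimilarity follows its closed form", {
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 3), c(2, 3)), 0)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(14)
  m <- matrix(rpois(40, 12), nrow = 8)
  ours <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("ANOSIM hits its boundary values", {
  # two tight clusters far apart: all between > all within -> R = 1
  coords <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(coords))
  res <- anosim(d, c("a", "a", "a", "b", "b", "b"), n_perm = 999, seed = 1)
  expect_equal(res$R, 1)
  expect_true(res$exhaustive)  # C(6,3) = 20 assignments <= 999
  # the observed labelling and its mirror both reach R = 1
  expect_equal(res$p, 2 / 20)

  # all distances equal: mid-ranks equalize, R = 0
  d0 <- matrix(1, 4, 4) - diag(4)
  res0 <- anosim(d0, c("a", "a", "b", "b"), n_perm = 999, seed = 1)
  expect_equal(res0$R, 0)

  expect_error(anosim(d0, c("a", "b", "c", "d")), "within-group")
  expect_error(anosim(d0, c("a", "a", "a", "a")), "2 groups")
})

test_that("sampled ANOSIM p agrees with exhaustive enumeration", {
  set.seed(42)
  coords <- rnorm(6)
  d <- as.matrix(dist(coords))
  groups <- c("a", "a", "a", "b", "b", "b")
  exh <- anosim(d, groups, n_perm = 2000, seed = 1)  # 20 splits -> exhaustive
  expect_true(exh$exhaustive)
  # independent oracle: R for every split of 6 samples into 3+3
  r_all <- apply(combn(6, 3), 2, function(idx) {
    lab <- rep("b", 6); lab[idx] <- "a"
    oracle_anosim_r(d, lab)
  })
  expect_equal(exh$R, oracle_anosim_r(d, groups), tolerance = 1e-12)
  expect_equal(exh$p, mean(r_all >= exh$R - 1e-12), tolerance = 1e-12)
  # sampling route (forced by small n_perm budget exceeded check)
  d8 <- as.matrix(dist(rnorm(8)))
  g8 <- rep(c("a", "b"), each = 4)
  samp <- anosim(d8, g8, n_perm = 30, seed = 7)   # C(8,4)=70 > 30 -> sampled
  exh8 <- anosim(d8, g8, n_perm = 100, seed = 7)  # exhaustive
  expect_false(samp$exhaustive)
  expect_true(exh8$exhaustive)
  expect_lt(abs(samp$p - exh8$p), 0.25)
  expect_equal(samp$R, exh8$R)
})

test_that("ANOSIM R matches vegan and is rank-invariant", {
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(rpois(60, 20), nrow = 10,
              dimnames = list(NULL, sprintf("S%d", 1:6)))
  groups <- c("x", "x", "x", "y", "y", "y")
  d <- bray_curtis_matrix(m)
  ours <- anosim(d, groups, n_perm = 999, seed = 3)
  ref <- vegan::anosim(as.dist(d), grouping = factor(groups), permutations = 99)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
  # monotone transform of distances leaves R unchanged
  trans <- anosim(sqrt(d), groups, n_perm = 999, seed = 3)
  expect_equal(trans$R, ours$R, tolerance = 1e-12)
  expect_equal(trans$p, ours$p)
})

test_that("PCA ordination satisfies its contracts", {
  # samples on a line: one component explains everything
  line <- rbind(f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8))
  res <- pca_ordination(line)
  expect_equal(res$var_explained[1], 1, tolerance = 1e-12)

  # duplicated samples get identical scores
  m <- matrix(runif(12), nrow = 3,
              dimnames = list(sprintf("f%d", 1:3), sprintf("S%d", 1:4)))
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("S%d", 1:8)
  rd <- pca_ordination(dup)
  expect_equal(rd$scores[1:4, ], rd$scores[5:8, ], ignore_attr = TRUE)

  # component variances equal eigenvalues of the feature covariance
  set.seed(31)
  x <- matrix(rnorm(20), nrow = 5,
              dimnames = list(sprintf("f%d", 1:5), sprintf("S%d", 1:4)))
  res2 <- pca_ordination(x)
  ev <- eigen(cov(t(x)), symmetric = TRUE)$values
  score_var <- apply(res2$scores, 2, function(s) sum(s^2) / (ncol(x) - 1))
  expect_equal(unname(score_var), ev[seq_along(score_var)], tolerance = 1e-9)
  # sign convention: dominant loading positive in every component
  for (j in seq_len(ncol(res2$loadings))) {
    expect_gt(res2$loadings[which.max(abs(res2$loadings[, j])), j], 0)
  }
  expect_error(pca_ordination(x[, 1, drop = FALSE]), "2 samples")
})

test_that("PCA variance fractions are invariant to feature order", {
  set.seed(13)
  x <- matrix(rnorm(40), nrow = 8,
              dimnames = list(sprintf("f%d", 1:8), sprintf("S%d", 1:5)))
  a <- pca_ordination(x)$var_explained
  b <- pca_ordination(x[sample(8), ])$var_explained
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("Venn partitions report exclusive regions over the union", {
  v <- venn_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                           C = "c"))
  expect_equal(v$count[v$region == "A&B&C"], 1L)
  expect_equal(v$pct[v$region == "A&B&C"], 25.0)
  expect_equal(sum(v$count), attr(v, "union_size"))

  same <- venn_partition(list(X = c("u", "v"), Y = c("u", "v")))
  expect_identical(same$region, "X&Y")
  expect_equal(same$pct, 100)

  disj <- venn_partition(list(X = "a", Y = "b", Z = "c"))
  expect_identical(sort(disj$region), c("X", "Y", "Z"))
  expect_lt(abs(sum(disj$pct) - 100), 0.2)  # 1-decimal rounding

  expect_error(venn_partition(list(A = "a")), "2 or 3")
  expect_error(venn_partition(list(A = "a", A = "b")), "duplicate")
})

test_that("Venn region counts always sum to the union size", {
  set.seed(17)
  pool <- letters
  for (i in 1:20) {
    sets <- list(A = sample(pool, sample(1:10, 1)),
                 B = sample(pool, sample(1:10, 1)),
                 C = sample(pool, sample(1:10, 1)))
    v <- venn_partition(sets)
    expect_equal(sum(v$count), length(unique(unlist(sets))))
    expect_lt(abs(sum(v$pct) - 100), 0.5)  # 1-decimal rounding per region
  }
})
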