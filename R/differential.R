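#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the minimum-likelihood two-sided
#' convention: with margins fixed, the p-value is the sum of probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-12). Degenerate margins give p = 1.
#'
#' @param tab 2x2 integer matrix, or the four cells `a, b, c, d` (rows =
#'   feature / other hits, columns = the two samples).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_two_sided <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2, 2)))
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  } else {
    stopifnot(length(tab) == 4)
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("at least one margin must be positive")
  m <- a + c          # column-1 total
  n <- b + d          # column-2 total
  k <- a + b          # row-1 total
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  # extreme tables can underflow the double range; keep p in (0, 1]
  max(min(p, 1), .Machine$double.xmin)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery
#' rate: with p-values sorted ascending, `q_(i) = min_{j >= i} p_(j) * m / j`
#' capped at 1, returned in input order.
#'
#' @param pvals P-values, all in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Wilson score interval for a single proportion.
wilson_interval <- function(x, n, z = stats::qnorm(0.975)) {
  if (n == 0) return(c(0, 1))
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Newcombe-Wilson interval for a difference of proportions
#'
#' Hybrid score method: Wilson limits `(l1, u1)` and `(l2, u2)` for the two
#' proportions are combined into
#' `[d - sqrt((p1-l1)^2 + (u2-p2)^2), d + sqrt((u1-p1)^2 + (p2-l2)^2)]`
#' around `d = p1 - p2`.
#'
#' @param x1,n1 Successes and total for group 1.
#' @param x2,n2 Successes and total for group 2.
#' @param conf Confidence level (default 0.95).
#' @return `c(ci_low, ci_high)`.
#' @export
newcombe_ci <- function(x1, n1, x2, n2, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p1 <- if (n1 > 0) x1 / n1 else 0
  p2 <- if (n2 > 0) x2 / n2 else 0
  w1 <- wilson_interval(x1, n1, z)
  w2 <- wilson_interval(x2, n2, z)
  d <- p1 - p2
  c(d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2),
    d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2))
}

#' Per-feature two-sample exact tests
#'
#' For every feature (row) of a raw-count matrix, tests whether the
#' feature's proportion differs between two samples: the 2x2 table is
#' `[[count_A, total_A - count_A], [count_B, total_B - count_B]]`, the
#' p-value comes from [fisher_two_sided()], q-values from [bh_adjust()]
#' across all features of the level being tested, and the 95% CI for the
#' proportion difference from the Newcombe-Wilson hybrid score method. A
#' feature is called enriched in the sample with the larger proportion when
#' `q < q_alpha`.
#'
#' Exact tests require integer counts; normalized matrices are rejected.
#'
#' @param x An `abundance_matrix` or counts matrix with raw integer counts.
#' @param sample_a,sample_b Column names of the two samples to compare.
#' @param thresholds A [threshold_config()]; `q_alpha` sets the call level.
#' @return Data frame with one row per feature: `feature`, `prop_a`,
#'   `prop_b`, `difference`, `ci_low`, `ci_high`, `p`, `q`, `enriched_in`.
#' @export
two_sample_feature_test <- function(x, sample_a, sample_b,
                                    thresholds = threshold_config()) {
  counts <- as_abundance_counts(x)
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(counts)) stop("sample not found: ", s)
  ca <- counts[, sample_a]
  cb <- counts[, sample_b]
  if (any(abs(c(ca, cb) - round(c(ca, cb))) > 1e-9))
    stop("non-integer counts: exact tests need raw counts")
  ca <- round(ca); cb <- round(cb)
  ta <- sum(ca); tb <- sum(cb)
  feats <- rownames(counts)
  p <- vapply(seq_along(feats), function(i)
    fisher_two_sided(c(ca[i], cb[i], ta - ca[i], tb - cb[i])), numeric(1))
  q <- bh_adjust(p)
  ci <- t(vapply(seq_along(feats), function(i)
    newcombe_ci(ca[i], ta, cb[i], tb), numeric(2)))
  prop_a <- if (ta > 0) ca / ta else rep(0, length(ca))
  prop_b <- if (tb > 0) cb / tb else rep(0, length(cb))
  diffs <- prop_a - prop_b
  enriched <- ifelse(q < thresholds$q_alpha,
                     ifelse(diffs > 0, sample_a, sample_b), "none")
  enriched[q < thresholds$q_alpha & diffs == 0] <- "none"
  data.frame(feature = feats, prop_a = unname(prop_a), prop_b = unname(prop_b),
             difference = unname(diffs),
             ci_low = ci[, 1], ci_high = ci[, 2],
             p = p, q = q, enriched_in = enriched,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA with eta-squared effect size and Tukey-Kramer post hoc
#'
#' Classic one-way decomposition: `F = MSB / MSW`, p from the F
#' distribution, effect size `eta2 = SSB / SST`. If the within-group mean
#' square is zero while the between-group sum of squares is positive, F is
#' reported as `Inf` with p = 0. All observations identical is a degenerate
#' input and raises an error. Pairwise comparisons use [tukey_kramer()]
#' whenever `MSW > 0`.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation; at least 2 groups, at least
#'   one group with 2 or more observations.
#' @return A list of class `"anova_result"`: `F`, `p`, `eta2`, `df_between`,
#'   `df_within`, `posthoc` (data frame or `NULL`).
#' @export
anova_effect <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  g <- split(values, groups)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  n <- length(values)
  if (!any(lengths(g) >= 2)) stop("need at least one group with >= 2 observations")
  grand <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  sst <- ssb + ssw
  if (sst == 0) stop("degenerate: zero total variance")
  df_b <- k - 1
  df_w <- n - k
  msb <- ssb / df_b
  msw <- if (df_w > 0) ssw / df_w else 0
  if (msw == 0) {
    f_stat <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    f_stat <- msb / msw
    p <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }
  posthoc <- NULL
  if (msw > 0 && df_w >= 1) {
    posthoc <- tukey_kramer(vapply(g, mean, numeric(1)), lengths(g),
                            msw, df_w)
  }
  structure(list(F = f_stat, p = p, eta2 = ssb / sst,
                 df_between = df_b, df_within = df_w, posthoc = posthoc),
            class = "anova_result")
}

#' Tukey-Kramer pairwise post hoc comparisons
#'
#' For each pair of groups,
#' `q_ij = |mean_i - mean_j| / sqrt((MSW / 2) (1/n_i + 1/n_j))`, with the
#' p-value from the studentized range distribution with `k` groups and
#' `df_w` error degrees of freedom (evaluated by `stats::ptukey`). For
#' `k = 2` the p-value equals the two-sided pooled-variance t-test
#' (`q = t * sqrt(2)`), and p is monotone decreasing in q.
#'
#' @param means Named group means.
#' @param sizes Group sizes (same order).
#' @param msw Within-group mean square (> 0).
#' @param df_w Error degrees of freedom (>= 1).
#' @return Data frame with `group_i`, `group_j`, `q_stat`, `p`.
#' @export
tukey_kramer <- function(means, sizes, msw, df_w) {
  k <- length(means)
  stopifnot(k >= 2, length(sizes) == k, df_w >= 1)
  if (msw <= 0) stop("MSW must be > 0")
  labels <- names(means)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(idx) {
    i <- idx[1]; j <- idx[2]
    se <- sqrt((msw / 2) * (1 / sizes[i] + 1 / sizes[j]))
    q <- unname(abs(means[i] - means[j]) / se)
    c(q = q,
      p = stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE))
  })
  data.frame(group_i = labels[pairs[1, ]], group_j = labels[pairs[2, ]],
             q_stat = unname(res["q", ]), p = unname(res["p", ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-feature ANOVA across sample groups
#'
#' Runs [anova_effect()] on each feature of a (typically relative-abundance)
#' matrix with one observation per sample, grouped by `groups`, and adjusts
#' the p-values with [bh_adjust()]. Features whose values are constant
#' across all samples are reported with `F = 0`, `p = q = 1`, `eta2 = 0`.
#'
#' @param x An `abundance_matrix` or matrix (features x samples).
#' @param groups Group label per sample column.
#' @return Data frame with `feature`, `F`, `p`, `q`, `eta2`, sorted as the
#'   input rows.
#' @export
anova_feature_scan <- function(x, groups) {
  counts <- as_abundance_counts(x)
  stopifnot(length(groups) == ncol(counts))
  rows <- lapply(rownames(counts), function(f) {
    v <- counts[f, ]
    if (max(v) - min(v) == 0)
      return(data.frame(feature = f, F = 0, p = 1, eta2 = 0))
    a <- anova_effect(v, groups)
    data.frame(feature = f, F = a$F, p = a$p, eta2 = a$eta2)
  })
  out <- do.call(rbind, rows)
  # a zero-MSW feature reports p = 0; floor it for the step-up adjustment
  out$q <- bh_adjust(pmax(out$p, .Machine$double.xmin))
  out[, c("feature", "F", "p", "q", "eta2")]
}
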