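#' Expected rarefaction richness
#'
#' Analytic expected number of distinct taxa in a random subsample of
#' `depth` reads drawn without replacement from one sample's counts:
#' `sum_i [1 - C(N - N_i, depth) / C(N, depth)]`, evaluated with log-gamma
#' for numerical stability at large totals. At `depth` equal to the total
#' this is exactly the observed richness.
#'
#' @param counts Non-negative taxon counts for one sample.
#' @param depth Subsample size, between 0 and `sum(counts)`.
#' @return Expected richness (numeric scalar).
#' @export
rarefaction_expected <- function(counts, depth) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (depth < 0 || depth > total)
    stop("depth must lie between 0 and the total count")
  if (depth == 0) return(0)
  # P(taxon i absent) = C(N - N_i, d) / C(N, d); zero when N - N_i < d
  log_absent <- ifelse(total - counts < depth, -Inf,
                       lchoose(total - counts, depth) - lchoose(total, depth))
  sum(1 - exp(log_absent))
}

#' Rarefaction curve for one sample
#'
#' @param counts Taxon counts for one sample.
#' @param depths Subsample sizes; defaults to 20 evenly spaced depths.
#' @return Data frame with `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths = NULL) {
  total <- sum(counts)
  if (is.null(depths))
    depths <- unique(round(seq(0, total, length.out = 21)))
  data.frame(depth = depths,
             expected_richness = vapply(depths, function(d)
               rarefaction_expected(counts, d), numeric(1)))
}

#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over taxa with positive counts.
#'
#' @param counts Non-negative taxon counts.
#' @return Shannon index.
#' @export
shannon_diversity <- function(counts) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all-zero count vector")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(min(u, v)) / (sum(u) + sum(v))`; 0 for identical vectors,
#' 1 for disjoint supports.
#'
#' @param u,v Equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0))
  if (sum(u) + sum(v) == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))
}

#' Bray-Curtis distance matrix over samples
#'
#' @param x An `abundance_matrix` or counts matrix (features x samples).
#' @return Symmetric sample-by-sample dissimilarity matrix with zero
#'   diagonal.
#' @export
bray_curtis_matrix <- function(x) {
  counts <- as_abundance_counts(x)
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- bray_curtis(counts[, i], counts[, j])
  }
  d
}

# All distinct two-group (or k-group) label assignments as a list of integer
# label vectors; enumeration over combinations, recursively for k > 2.
enumerate_assignments <- function(group_sizes, n = sum(group_sizes)) {
  positions <- seq_len(n)
  assignments <- list()
  assign_rec <- function(avail, sizes, labels, current) {
    if (length(sizes) == 1) {
      current[avail] <- labels[1]
      assignments[[length(assignments) + 1]] <<- current
      return(invisible(NULL))
    }
    for (p in utils::combn(avail, sizes[1], simplify = FALSE)) {
      cur2 <- current
      cur2[p] <- labels[1]
      assign_rec(setdiff(avail, p), sizes[-1], labels[-1], cur2)
    }
  }
  assign_rec(positions, group_sizes, seq_along(group_sizes), integer(n))
  assignments
}

anosim_r_from_ranks <- function(rank_d, within) {
  m <- length(rank_d)
  (mean(rank_d[!within]) - mean(rank_d[within])) / (m / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. The statistic is
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2` pairwise distances ranked with mid-ranks for ties. The
#' p-value is one-sided (large R) by label permutation with the
#' `(exceedances + 1) / (n_perm + 1)` convention; when the number of
#' distinct label assignments is at most `n_perm`, all of them are
#' enumerated instead of sampled (the observed assignment counts as its own
#' exceedance). Deterministic for a fixed seed.
#'
#' @param d Symmetric distance matrix (samples x samples).
#' @param groups Group label per sample (length `ncol(d)`), at least 2
#'   groups.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `"anosim_result"`: `R`, `p`, `n_perm`,
#'   `exhaustive`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  n <- ncol(d)
  stopifnot(nrow(d) == n, length(groups) == n, n_perm >= 1)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  lower <- lower.tri(d)
  dist_vec <- d[lower]
  rank_d <- rank(dist_vec)  # mid-ranks for ties
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]
  within_obs <- groups[pair_i] == groups[pair_j]
  if (!any(within_obs))
    stop("no within-group pairs: every group is a singleton")
  r_obs <- anosim_r_from_ranks(rank_d, within_obs)

  sizes <- as.integer(table(factor(groups, levels = unique(groups))))
  total_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  r_for_labels <- function(lab) {
    anosim_r_from_ranks(rank_d, lab[pair_i] == lab[pair_j])
  }
  eps <- 1e-12
  if (total_assign <= n_perm + 0.5) {
    perms <- enumerate_assignments(sizes, n)
    r_perm <- vapply(perms, r_for_labels, numeric(1))
    p <- sum(r_perm >= r_obs - eps) / length(r_perm)
    n_used <- length(r_perm)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(k)
      r_for_labels(sample(groups)), numeric(1))
    p <- (sum(r_perm >= r_obs - eps) + 1) / (n_perm + 1)
    n_used <- n_perm
    exhaustive <- FALSE
  }
  structure(list(R = r_obs, p = p, n_perm = n_used, exhaustive = exhaustive),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p, if (x$exhaustive) "exhaustive" else "sampled",
              x$n_perm))
  invisible(x)
}

#' Principal component analysis of sample profiles
#'
#' Samples are the observations and features the variables. Features are
#' centered across samples (no unit-variance scaling); components come from
#' the singular value decomposition of the centered data. Sign convention:
#' within each component the loading of largest magnitude is positive.
#' Variance-explained fractions are the squared singular values over their
#' total.
#'
#' @param x An `abundance_matrix` (typically relative abundances) or matrix
#'   with features in rows and samples in columns.
#' @return A list of class `"ordination_result"`: `scores` (samples x
#'   components), `loadings` (features x components), `var_explained`.
#' @export
pca_ordination <- function(x) {
  counts <- as_abundance_counts(x)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  obs <- t(counts)                       # samples x features
  centered <- scale(obs, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(counts)
  rownames(loadings) <- rownames(counts)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d^2 / sum(sv$d^2)),
            class = "ordination_result")
}

#' Venn partition of up to three named sets
#'
#' Reports every non-empty intersection region with its exclusive member
#' count and its percentage of the union (to one decimal), the summary
#' behind shared-taxa Venn diagrams.
#'
#' @param sets Named list of 2 or 3 character vectors (duplicate members
#'   within a set are ignored).
#' @return A data frame of class `"venn_summary"` with `region` (set names
#'   joined by `"&"`), `count`, `pct`, plus attributes `union_size` and
#'   `members` (list of region member vectors).
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("venn_partition supports 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(sets)))
  key <- apply(membership, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  regions <- sort(unique(key))
  counts <- vapply(regions, function(r) sum(key == r), integer(1))
  members <- lapply(regions, function(r) universe[key == r])
  names(members) <- regions
  out <- data.frame(region = regions, count = as.integer(counts),
                    pct = round(100 * counts / length(universe), 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(universe)
  attr(out, "members") <- members
  class(out) <- c("venn_summary", "data.frame")
  out
}
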