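#' Redundancy bin definitions
#'
#' The enzyme-to-genus redundancy spectrum is summarized over four bins of
#' per-enzyme genus counts: enzymes found in exactly one genus ("single"),
#' in 2--4 ("low"), in 5--10 ("mid"), and in 11 or more ("high").
#'
#' @return Named list of `c(lower, upper)` genus-count ranges.
#' @export
redundancy_bins <- function() {
  list(single = c(1, 1), low = c(2, 4), mid = c(5, 10), high = c(11, Inf))
}

#' Noise model for annotation-quality fields
#'
#' Each simulated annotation record is drawn from one of two populations:
#' "pass" records satisfy all default annotation thresholds (e-value at most
#' 1e-5, identity at least 80%, alignment at least 15 bp), "fail" records
#' violate all of them, so the number of records removed by
#' [apply_annotation_filters()] is known exactly in expectation regardless of
#' profiling mode. Field values are drawn uniformly from the stated ranges
#' (e-value on the log10 scale).
#'
#' @param p_fail Probability that a record belongs to the "fail" population.
#' @param pass,fail Lists with elements `log10_evalue`, `identity`, `aln_len`,
#'   each a `c(min, max)` range.
#' @return A list of class `"noise_config"`.
#' @export
noise_config <- function(p_fail = 0.1,
                         pass = list(log10_evalue = c(-30, -6),
                                     identity = c(85, 100),
                                     aln_len = c(30, 120)),
                         fail = list(log10_evalue = c(-4.9, -1),
                                     identity = c(20, 55),
                                     aln_len = c(5, 14))) {
  stopifnot(p_fail >= 0, p_fail <= 1)
  for (pop in list(pass, fail)) {
    stopifnot(all(c("log10_evalue", "identity", "aln_len") %in% names(pop)))
    for (r in pop) stopifnot(length(r) == 2, r[1] <= r[2])
  }
  structure(list(p_fail = p_fail, pass = pass, fail = fail),
            class = "noise_config")
}

#' Synthetic-data generator configuration
#'
#' Defines the study conditions the generator emulates: a small number of
#' host species each sampled once per sex (single pooled sample per
#' species-sex group, the design of pooled tick-gut metagenomes), per-sample
#' genus abundance vectors with a heavy-tailed profile, planted sex-specific
#' fold changes on a subset of genera, and genus-to-enzyme repertoires whose
#' redundancy spectrum is planted exactly.
#'
#' Default spectrum targets place 12% of enzymes in a single genus, 27% in
#' five to ten genera, none in eleven or more, and the remainder in two to
#' four -- the redundancy structure reported for differential enzymes in tick
#' gut metagenomes.
#'
#' @param n_species Number of host species (default 3).
#' @param sexes Group labels within species (default `c("f", "m")`).
#' @param n_genera Number of bacterial genera in the community (default 30).
#' @param n_enzymes Number of EC-style enzyme functions (default 25).
#' @param spectrum_targets Proportion of enzymes per redundancy bin
#'   (`single`, `low` = 2--4, `mid` = 5--10, `high` = >= 11); must sum to 1.
#' @param n_diff_genera Number of genera given a planted sex effect.
#' @param fold_change Multiplicative sex effect (> 0): an affected genus has
#'   proportion `base * fold_change` in its enriched sex (unaffected mass is
#'   rescaled to the remainder), so the planted between-sex proportion ratio
#'   equals `fold_change` exactly.
#' @param diff_genus_base_prop Fixed base proportion given to every affected
#'   genus (default 0.02, keeping `n_diff_genera * base * fold_change < 1`);
#'   other genera share the remaining mass. `NULL` leaves affected genera on
#'   their random abundances (the caller must then keep the planted fold
#'   changes feasible).
#' @param reads_per_sample Sequencing depth per sample (default 10000).
#' @param p_unannotated_function Probability a read carries no functional
#'   annotation (default 0.1).
#' @param noise A [noise_config()].
#' @param n_replicates Samples per species-sex group (default 1, matching a
#'   single pooled sample per group).
#' @param seed Integer seed; one seeded stream drives each generation call.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_species = 3,
                             sexes = c("f", "m"),
                             n_genera = 30,
                             n_enzymes = 25,
                             spectrum_targets = c(single = 0.12, low = 0.61,
                                                  mid = 0.27, high = 0.00),
                             n_diff_genera = 5,
                             fold_change = 8,
                             diff_genus_base_prop = 0.02,
                             reads_per_sample = 10000,
                             p_unannotated_function = 0.1,
                             noise = noise_config(),
                             n_replicates = 1,
                             seed = 1) {
  stopifnot(n_species >= 1, length(sexes) >= 2, n_genera >= 1, n_enzymes >= 1,
            reads_per_sample >= 1, n_replicates >= 1)
  bins <- names(redundancy_bins())
  if (!all(bins %in% names(spectrum_targets)))
    stop("spectrum_targets must be named over bins: ",
         paste(bins, collapse = ", "))
  spectrum_targets <- spectrum_targets[bins]
  if (any(spectrum_targets < 0))
    stop("spectrum_targets proportions must be >= 0")
  if (abs(sum(spectrum_targets) - 1) > 1e-9)
    stop("spectrum_targets must sum to 1")
  if (n_diff_genera > n_genera)
    stop("n_diff_genera must not exceed n_genera")
  if (fold_change <= 0) stop("fold_change must be > 0")
  if (p_unannotated_function < 0 || p_unannotated_function > 1)
    stop("p_unannotated_function must lie in [0, 1]")
  if (!is.null(diff_genus_base_prop)) {
    stopifnot(diff_genus_base_prop > 0,
              n_diff_genera * diff_genus_base_prop < 1)
  }
  stopifnot(inherits(noise, "noise_config"))
  structure(list(n_species = n_species, sexes = sexes, n_genera = n_genera,
                 n_enzymes = n_enzymes, spectrum_targets = spectrum_targets,
                 n_diff_genera = n_diff_genera, fold_change = fold_change,
                 diff_genus_base_prop = diff_genus_base_prop,
                 reads_per_sample = reads_per_sample,
                 p_unannotated_function = p_unannotated_function,
                 noise = noise, n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Largest-remainder allocation of n items over target proportions.
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

# Deterministic nested lineage labels: genus i sits under family (i-1 mod 16),
# order (i-1 mod 8), class (i-1 mod 4), phylum (i-1 mod 2) -- each label fully
# determines the ones above it, so the lineage is prefix-consistent and at
# least two phyla are present whenever n_genera >= 2.
synthetic_lineage <- function(n_genera) {
  k <- seq_len(n_genera) - 1L
  data.frame(domain = "Bacteria",
             phylum = sprintf("SimPhylum%02d", k %% 2L + 1L),
             class = sprintf("SimClass%02d", k %% 4L + 1L),
             order = sprintf("SimOrder%02d", k %% 8L + 1L),
             family = sprintf("SimFamily%02d", k %% 16L + 1L),
             genus = sprintf("Genus%03d", k + 1L),
             stringsAsFactors = FALSE)
}

# Unique EC-style dot-notation identifiers, deterministic under the current
# RNG stream.
synthetic_ec_ids <- function(n) {
  grid <- expand.grid(a = 1:6, b = 1:9, c = 1:9, d = 1:40)
  idx <- sample.int(nrow(grid), n)
  sprintf("%d.%d.%d.%d", grid$a[idx], grid$b[idx], grid$c[idx], grid$d[idx])
}

#' Build the planted ground truth
#'
#' Constructs genus and enzyme catalogs, a binary genus-by-enzyme repertoire
#' realizing the configured redundancy-spectrum targets (exactly when
#' `n_enzymes * proportion` is integral, otherwise by largest-remainder
#' rounding), per-species genus abundance vectors, the set of genera given a
#' planted sex effect, and the sample plan. Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `"ground_truth"` with elements `genus_catalog`
#'   (lineage data frame), `enzyme_catalog`, `repertoire` (logical
#'   genus-by-enzyme matrix), `base_abundance` (species-by-genus matrix, rows
#'   sum to 1), `affected_genera` (data frame `genus`, `enriched_sex`,
#'   `fold_change`), `expected_spectrum` (named per-enzyme genus counts),
#'   `sample_plan`, and the `config`.
#' @export
build_ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  bins <- redundancy_bins()
  # feasibility: a bin with positive mass must be realizable with n_genera
  for (b in names(bins)) {
    if (config$spectrum_targets[[b]] > 0 && bins[[b]][1] > config$n_genera)
      stop("infeasible spectrum: bin '", b, "' needs >= ", bins[[b]][1],
           " genera but n_genera = ", config$n_genera)
  }
  set.seed(config$seed)
  lineage <- synthetic_lineage(config$n_genera)
  enzymes <- synthetic_ec_ids(config$n_enzymes)

  n_per_bin <- largest_remainder(config$n_enzymes, config$spectrum_targets)
  names(n_per_bin) <- names(bins)
  target_counts <- integer(0)
  for (b in names(bins)) {
    if (n_per_bin[[b]] == 0) next
    lo <- bins[[b]][1]
    hi <- min(bins[[b]][2], config$n_genera)
    draw <- if (lo == hi) rep(lo, n_per_bin[[b]]) else
      sample(seq(lo, hi), n_per_bin[[b]], replace = TRUE)
    target_counts <- c(target_counts, draw)
  }
  repertoire <- matrix(FALSE, nrow = config$n_genera, ncol = config$n_enzymes,
                       dimnames = list(lineage$genus, enzymes))
  for (e in seq_len(config$n_enzymes)) {
    repertoire[sample.int(config$n_genera, target_counts[e]), e] <- TRUE
  }
  # cover uncovered genera where the total incidence allows: swap them into
  # slots held by multiply-covered genera; per-enzyme counts (the planted
  # spectrum) are unchanged
  for (g in which(rowSums(repertoire) == 0)) {
    cover <- rowSums(repertoire)
    for (e in sample.int(config$n_enzymes)) {
      donors <- which(repertoire[, e] & cover >= 2)
      if (length(donors) > 0 && !repertoire[g, e]) {
        h <- donors[which.max(cover[donors])]
        repertoire[h, e] <- FALSE
        repertoire[g, e] <- TRUE
        break
      }
    }
  }

  # heavy-tailed per-species genus abundances
  affected_idx <- if (config$n_diff_genera > 0)
    sort(sample.int(config$n_genera, config$n_diff_genera)) else integer(0)
  base_abundance <- matrix(0, nrow = config$n_species, ncol = config$n_genera,
                           dimnames = list(sprintf("TickSp%d", seq_len(config$n_species)),
                                           lineage$genus))
  for (s in seq_len(config$n_species)) {
    w <- stats::rgamma(config$n_genera, shape = 0.7, rate = 1)
    w <- pmax(w, 1e-6)
    p <- w / sum(w)
    if (!is.null(config$diff_genus_base_prop) && length(affected_idx) > 0) {
      fixed <- config$diff_genus_base_prop
      p[affected_idx] <- 0
      p <- p / sum(p) * (1 - fixed * length(affected_idx))
      p[affected_idx] <- fixed
    }
    base_abundance[s, ] <- p
  }

  affected <- data.frame(
    genus = lineage$genus[affected_idx],
    enriched_sex = if (length(affected_idx) > 0)
      sample(config$sexes, length(affected_idx), replace = TRUE) else character(0),
    fold_change = rep(config$fold_change, length(affected_idx)),
    stringsAsFactors = FALSE)

  plan <- expand.grid(replicate = seq_len(config$n_replicates),
                      sex = config$sexes,
                      species = rownames(base_abundance),
                      stringsAsFactors = FALSE)[, c("species", "sex", "replicate")]
  plan$sample_id <- if (config$n_replicates == 1)
    paste0(sub("TickSp", "Sp", plan$species), plan$sex) else
    paste0(sub("TickSp", "Sp", plan$species), plan$sex, ".", plan$replicate)
  plan$depth <- config$reads_per_sample
  plan <- plan[, c("sample_id", "species", "sex", "depth")]

  structure(list(genus_catalog = lineage,
                 enzyme_catalog = enzymes,
                 repertoire = repertoire,
                 base_abundance = base_abundance,
                 affected_genera = affected,
                 expected_spectrum = colSums(repertoire),
                 sample_plan = plan,
                 config = config),
            class = "ground_truth")
}

#' Sex-adjusted genus proportions for one sample
#'
#' Applies the planted sex effect: every affected genus whose enriched sex
#' matches the sample's sex receives proportion `base * fold_change`; the
#' unaffected genera are rescaled to fill the remaining probability mass.
#' With `fold_change = 1` the vector is unchanged.
#'
#' @param truth A [build_ground_truth()] result.
#' @param species Species label (row of `base_abundance`).
#' @param sex Sex label.
#' @return Genus probability vector summing to 1.
#' @export
adjusted_proportions <- function(truth, species, sex) {
  p <- truth$base_abundance[species, ]
  aff <- truth$affected_genera
  hit <- aff$genus[aff$enriched_sex == sex]
  if (length(hit) > 0) {
    target <- p[hit] * aff$fold_change[match(hit, aff$genus)]
    if (sum(target) >= 1)
      stop("planted fold changes exceed total probability mass")
    rest <- setdiff(names(p), hit)
    p[rest] <- p[rest] / sum(p[rest]) * (1 - sum(target))
    p[hit] <- target
  }
  p / sum(p)
}

#' Simulate annotation tables with planted structure
#'
#' For each sample in the plan, reads are multinomial draws from the
#' sex-adjusted genus proportions; each read is assigned an enzyme drawn
#' uniformly from its genus' repertoire with probability
#' `1 - p_unannotated_function` (otherwise the functional fields are
#' missing); annotation-quality fields are drawn from the configured
#' pass/fail mixture so the fraction of records failing the default
#' thresholds converges to `noise$p_fail`. Each read is one record with
#' `hits = 1`. Deterministic for a fixed config seed.
#'
#' @param truth A [build_ground_truth()] result.
#' @return A list with `annotations` (annotation table data frame) and
#'   `metadata` (sample metadata data frame); the generator seed is attached
#'   as attribute `"seed"`.
#' @export
simulate_annotation_tables <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- truth$config
  if (any(truth$sample_plan$depth <= 0)) stop("sample depth must be > 0")
  # genera with empty repertoires can never supply a function
  if (config$p_unannotated_function == 0 &&
      any(rowSums(truth$repertoire) == 0 &
          colSums(truth$base_abundance > 0) > 0))
    stop("empty repertoire row for a sampled genus with function requested")
  set.seed(config$seed + 1L)
  # fixed functional hierarchy above each enzyme
  l1_pool <- c("Carbohydrates", "Amino Acids and Derivatives", "Stress Response",
               "Cofactors, Vitamins, Prosthetic Groups", "DNA Metabolism",
               "Respiration", "Protein Metabolism", "Cell Wall and Capsule")
  ez_l1 <- l1_pool[(seq_along(truth$enzyme_catalog) - 1L) %% length(l1_pool) + 1L]
  ez_l2 <- paste0(ez_l1, " subsystem ",
                  (seq_along(truth$enzyme_catalog) - 1L) %/% length(l1_pool) + 1L)
  ez_l3 <- paste0("Role group ", seq_along(truth$enzyme_catalog))
  names(ez_l1) <- names(ez_l2) <- names(ez_l3) <- truth$enzyme_catalog

  per_sample <- vector("list", nrow(truth$sample_plan))
  for (i in seq_len(nrow(truth$sample_plan))) {
    sm <- truth$sample_plan[i, ]
    p <- adjusted_proportions(truth, sm$species, sm$sex)
    counts <- stats::rmultinom(1, sm$depth, p)[, 1]
    genus <- rep(names(counts), counts)
    n <- length(genus)
    # uniform enzyme draw within each read's genus repertoire
    enzyme <- rep(NA_character_, n)
    want_fun <- stats::runif(n) >= config$p_unannotated_function
    for (g in names(counts)[counts > 0]) {
      reps <- which(truth$repertoire[g, ])
      sel <- which(genus == g & want_fun)
      if (length(reps) > 0 && length(sel) > 0)
        enzyme[sel] <- truth$enzyme_catalog[
          reps[sample.int(length(reps), length(sel), replace = TRUE)]]
    }
    fail <- stats::runif(n) < config$noise$p_fail
    draw <- function(rng_pass, rng_fail) {
      v <- stats::runif(n, rng_pass[1], rng_pass[2])
      v[fail] <- stats::runif(sum(fail), rng_fail[1], rng_fail[2])
      v
    }
    evalue <- 10 ^ draw(config$noise$pass$log10_evalue,
                        config$noise$fail$log10_evalue)
    identity <- round(draw(config$noise$pass$identity,
                           config$noise$fail$identity), 1)
    aln <- as.integer(round(draw(config$noise$pass$aln_len,
                                 config$noise$fail$aln_len)))
    gi <- match(genus, truth$genus_catalog$genus)
    per_sample[[i]] <- data.frame(
      feature_id = sprintf("%s_r%06d", sm$sample_id, seq_len(n)),
      sample_id = sm$sample_id,
      hits = 1L,
      evalue = evalue,
      identity_pct = identity,
      aln_len = aln,
      truth$genus_catalog[gi, , drop = FALSE],
      func_l1 = ifelse(is.na(enzyme), NA_character_, unname(ez_l1[enzyme])),
      func_l2 = ifelse(is.na(enzyme), NA_character_, unname(ez_l2[enzyme])),
      func_l3 = ifelse(is.na(enzyme), NA_character_, unname(ez_l3[enzyme])),
      func_l4 = enzyme,
      subject_id = sprintf("M5_%09d", sample.int(999999999L, n)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  annotations <- do.call(rbind, per_sample)
  rownames(annotations) <- NULL
  metadata <- truth$sample_plan[, c("sample_id", "species", "sex")]
  rownames(metadata) <- NULL
  out <- list(annotations = annotations, metadata = metadata)
  attr(out, "seed") <- config$seed
  out
}

#' QC simulation plan
#'
#' @param n_reads Total reads to emit.
#' @param read_len Length of each read (bp).
#' @param low_quality Number of planted low-quality reads (every window of
#'   `min_len` bases contains more than `max_below` bases under the Phred
#'   floor, so quality trimming removes them).
#' @param duplicates Number of planted artificial replicates (reads sharing an
#'   earlier read's `dup_prefix_len`-bp prefix but shorter, so dereplication
#'   removes them).
#' @param gc_mean Target mean GC proportion of emitted sequences (0--1).
#' @param params A [qc_params()] giving the thresholds the plants are built
#'   against.
#' @return A list of class `"qc_plan"`.
#' @export
qc_plan <- function(n_reads = 100, read_len = 120, low_quality = 0,
                    duplicates = 0, gc_mean = 0.5, params = qc_params()) {
  stopifnot(n_reads >= 1, read_len >= 1, low_quality >= 0, duplicates >= 0,
            gc_mean >= 0, gc_mean <= 1)
  if (low_quality + duplicates > n_reads)
    stop("planted read counts exceed total reads")
  if (read_len < params$dup_prefix_len)
    stop("read length shorter than duplicate-prefix length")
  structure(list(n_reads = n_reads, read_len = read_len,
                 low_quality = low_quality, duplicates = duplicates,
                 gc_mean = gc_mean, params = params),
            class = "qc_plan")
}

random_dna <- function(n_bases, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(probs), n_bases, replace = TRUE, prob = probs),
         collapse = "")
}

#' Simulate reads with planted QC removals
#'
#' Emits a read set in which exactly `plan$low_quality` reads fail the
#' quality-trimming rule (all bases below the Phred floor, so no admissible
#' window reaches `min_len`), exactly `plan$duplicates` reads replicate an
#' earlier read's prefix while being shorter (so dereplication drops the
#' replicate and keeps the original), and the remaining reads pass both
#' filters untouched. Sequence GC content targets `plan$gc_mean`.
#' Deterministic for a fixed truth seed.
#'
#' @param truth A [build_ground_truth()] result (supplies the seed).
#' @param plan A [qc_plan()].
#' @return A data frame with columns `id`, `seq`, `qual` (Phred+33).
#' @export
simulate_reads <- function(truth, plan) {
  stopifnot(inherits(truth, "ground_truth"), inherits(plan, "qc_plan"))
  set.seed(truth$config$seed + 2L)
  pm <- plan$params
  n_good <- plan$n_reads - plan$low_quality - plan$duplicates
  good_qual_chars <- strsplit(rawToChar(as.raw(33 + pm$phred_floor + 5:25)), "")[[1]]
  bad_qual_chars <- strsplit(rawToChar(as.raw(33 + seq(2, pm$phred_floor - 1))), "")[[1]]
  qual_string <- function(len, chars)
    paste0(sample(chars, len, replace = TRUE), collapse = "")

  good <- data.frame(
    id = sprintf("read%05d_ok", seq_len(n_good)),
    seq = vapply(seq_len(n_good), function(i) random_dna(plan$read_len, plan$gc_mean), ""),
    qual = vapply(seq_len(n_good), function(i) qual_string(plan$read_len, good_qual_chars), ""),
    stringsAsFactors = FALSE)

  low <- if (plan$low_quality > 0) data.frame(
    id = sprintf("read%05d_lowq", seq_len(plan$low_quality)),
    seq = vapply(seq_len(plan$low_quality), function(i) random_dna(plan$read_len, plan$gc_mean), ""),
    qual = vapply(seq_len(plan$low_quality), function(i) qual_string(plan$read_len, bad_qual_chars), ""),
    stringsAsFactors = FALSE) else NULL

  dup <- NULL
  if (plan$duplicates > 0) {
    if (n_good < plan$duplicates)
      stop("not enough originals to duplicate")
    src <- sample.int(n_good, plan$duplicates)
    dup_len <- max(pm$dup_prefix_len, plan$read_len - 10L)
    dup <- data.frame(
      id = sprintf("read%05d_dup", seq_len(plan$duplicates)),
      seq = vapply(src, function(s) {
        prefix <- substr(good$seq[s], 1, pm$dup_prefix_len)
        paste0(prefix, random_dna(dup_len - pm$dup_prefix_len, plan$gc_mean))
      }, ""),
      qual = vapply(seq_len(plan$duplicates),
                    function(i) qual_string(dup_len, good_qual_chars), ""),
      stringsAsFactors = FALSE)
  }
  reads <- rbind(good, low, dup)
  rownames(reads) <- NULL
  reads
}

#' Write ground truth to JSON
#'
#' Serializes the planted parameters (catalogs, repertoire, abundances,
#' affected genera, expected spectrum, sample plan, seed) for provenance.
#'
#' @param truth A [build_ground_truth()] result.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    genus_catalog = truth$genus_catalog,
    enzyme_catalog = truth$enzyme_catalog,
    repertoire = apply(truth$repertoire, 1, function(r)
      colnames(truth$repertoire)[r], simplify = FALSE),
    base_abundance = as.data.frame(truth$base_abundance),
    affected_genera = truth$affected_genera,
    expected_spectrum = as.list(truth$expected_spectrum),
    sample_plan = truth$sample_plan,
    seed = truth$config$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
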