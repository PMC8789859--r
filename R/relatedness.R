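# Clonal relatedness: clonality index with resampling-calibrated cutoff,
# recurrence pattern and location classification, breakpoint comparison,
# WGD and gene-level CNV classes.

#' Population probability of a mutation
#'
#' The occurrence count of the key divided by the total number of mutations
#' in the background cohort. Keys never observed in the cohort receive a
#' pseudo-count of 1 (`p = 1 / N`), the conservative floor: an unobserved
#' shared mutation is at most as common as a singleton.
#'
#' @param keys Character vector of normalized keys.
#' @param catalog A [cohort_catalog()].
#' @return Numeric vector of probabilities in `(0, 1]`.
#' @export
mutation_probability <- function(keys, catalog) {
  if (!inherits(catalog, "cohort_catalog")) stop("catalog must be a cohort_catalog")
  cnt <- catalog$counts[keys]
  cnt[is.na(cnt)] <- 1L
  unname(cnt) / catalog$n_total
}

#' Clonality index of a shared mutation set
#'
#' For each shared mutation the chance of independent co-occurrence in two
#' tumors is the binomial probability of two successes in two trials,
#' `P = p^2`, with `p` the population frequency of that exact mutation.
#' The clonality index is `CI = -log10 prod_m P_m = -2 * sum_m log10 p_m`,
#' evaluated in log space; an empty set gives CI = 0. By convention the
#' index is computed on shared nonsynonymous SNVs and indels.
#'
#' @param shared_keys Keys shared by the two tumors (already restricted to
#'   the eligible effect class by the caller).
#' @param catalog A [cohort_catalog()].
#' @return An object of class `clonality_result` with `ci`, `n_shared` and
#'   per-mutation `p`.
#' @export
clonality_index <- function(shared_keys, catalog) {
  shared_keys <- unique(shared_keys)
  p <- if (length(shared_keys)) mutation_probability(shared_keys, catalog)
       else numeric()
  ci <- if (length(p)) -2 * sum(log10(p)) else 0
  structure(list(ci = ci, n_shared = length(shared_keys),
                 p = setNames(p, shared_keys)),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat("<clonality_result> CI =", signif(x$ci, 6), "from", x$n_shared,
      "shared mutation(s)\n")
  invisible(x)
}

# fast CI over integer key ids given a contribution vector (-2 log10 p)
ci_from_contrib <- function(ids, contrib) sum(contrib[ids])

# Accuracy-maximizing threshold, placed at the low end of the optimal
# interval. When positive and negative controls separate, every threshold
# in the gap maximizes accuracy; genome-scale positive controls make that
# gap enormous, so the cutoff is anchored just above the strongest control
# value that must stay below it (one CI unit, far less than a single
# shared mutation contributes). This keeps the classifier sensitive to
# weakly related pairs while retaining specificity against the empirical
# null.
optimal_cutoff <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  n <- length(u)
  cum_pos <- cumsum(tabulate(findInterval(pos, u), nbins = n))
  cum_neg <- cumsum(tabulate(findInterval(neg, u), nbins = n))
  # candidate j = threshold between u[j] and u[j+1] (j = 0: below all)
  acc <- (length(pos) - c(0, cum_pos) + c(0, cum_neg)) /
    (length(pos) + length(neg))
  j <- which.max(acc) - 1L  # first (smallest) maximizer
  if (j == 0L) return(u[1] - 1)
  if (j == n) return(u[n] + 1)
  u[j] + min(1, (u[j + 1] - u[j]) / 2)
}

#' Calibrate the clonality-index cutoff by resampling
#'
#' Positive controls simulate clonally related pairs: for every reference
#' tumor and each fraction in `fractions`, two independent subsamples of
#' that tumor's mutation set are drawn (in duplicate) and their shared
#' mutations scored, giving `length(fractions) * n` related pairs per
#' repeat. Negative controls are an equal number of random unrelated tumor
#' pairs. Each repeat's optimal (accuracy-maximizing) cutoff is recorded
#' and the calibration result is the median over repeats.
#'
#' Tumor sets are put into a canonical content order first, so the median
#' cutoff does not depend on the order in which tumors are supplied.
#'
#' @param tumor_sets List of per-tumor key vectors (>= 2 tumors).
#' @param catalog A [cohort_catalog()].
#' @param fractions Subsampling fractions for the positive controls.
#' @param repeats Number of calibration repeats.
#' @param seed Seed.
#' @return An object of class `ci_calibration`: `cutoff` (median),
#'   `cutoffs` (per repeat), `accuracy` (mean accuracy at the median
#'   cutoff), `n_positive`, `n_negative`.
#' @export
calibrate_ci_cutoff <- function(tumor_sets, catalog,
                                fractions = c(0.4, 0.6, 0.8),
                                repeats = 100L, seed = NULL) {
  n <- length(tumor_sets)
  if (n < 2) stop("calibration needs at least two reference tumors")
  tumor_sets <- lapply(tumor_sets, unique)
  canon <- order(vapply(tumor_sets,
                        function(k) paste(sort(k), collapse = "\r"),
                        character(1)))
  tumor_sets <- tumor_sets[canon]
  all_keys <- unique(unlist(tumor_sets))
  contrib <- -2 * log10(mutation_probability(all_keys, catalog))
  ids <- lapply(tumor_sets, function(k) match(k, all_keys))
  m <- length(fractions)
  n_pairs <- m * n
  with_seed(seed, {
    cutoffs <- numeric(repeats)
    pos_all <- neg_all <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      pos <- numeric(n_pairs)
      k <- 0L
      for (i in seq_len(n)) {
        idv <- ids[[i]]
        sz <- length(idv)
        for (f in fractions) {
          take <- max(1L, round(f * sz))
          s1 <- logical(sz); s1[sample.int(sz, take)] <- TRUE
          s2 <- logical(sz); s2[sample.int(sz, take)] <- TRUE
          k <- k + 1L
          pos[k] <- sum(contrib[idv[s1 & s2]])
        }
      }
      neg <- numeric(n_pairs)
      buf <- logical(length(all_keys))  # scratch membership buffer
      for (k in seq_len(n_pairs)) {
        ij <- sample.int(n, 2L)
        a <- ids[[ij[1]]]; b <- ids[[ij[2]]]
        buf[b] <- TRUE
        neg[k] <- sum(contrib[a[buf[a]]])
        buf[b] <- FALSE
      }
      cutoffs[r] <- optimal_cutoff(pos, neg)
      pos_all[[r]] <- pos; neg_all[[r]] <- neg
    }
    cutoff <- median(cutoffs)
    acc <- mean(vapply(seq_len(repeats), function(r) {
      (sum(pos_all[[r]] >= cutoff) + sum(neg_all[[r]] < cutoff)) /
        (2 * n_pairs)
    }, numeric(1)))
    structure(list(cutoff = cutoff, cutoffs = cutoffs, accuracy = acc,
                   fractions = fractions, repeats = repeats,
                   n_positive = n_pairs, n_negative = n_pairs),
              class = "ci_calibration")
  })
}

#' @export
print.ci_calibration <- function(x, ...) {
  cat("<ci_calibration> median cutoff =", signif(x$cutoff, 5),
      "over", x$repeats, "repeats; accuracy", round(x$accuracy, 4), "\n")
  invisible(x)
}

#' Classify a recurrence as ancestral or de novo
#'
#' Ancestral iff the clonality index is at or above the cutoff (ties go to
#' ancestral); the shared-fraction grouping is reported alongside as a
#' concordance check, not used for the call.
#'
#' @param ci Clonality index (number or `clonality_result`).
#' @param cutoff Calibrated or user-supplied cutoff.
#' @return `"ancestral"` or `"de_novo"`.
#' @export
classify_recurrence <- function(ci, cutoff) {
  if (inherits(ci, "clonality_result")) ci <- ci$ci
  if (inherits(cutoff, "ci_calibration")) cutoff <- cutoff$cutoff
  ifelse(ci >= cutoff, "ancestral", "de_novo")
}

#' Hepatic segment interval and recurrence location
#'
#' The HSI is the smallest absolute difference between any Couinaud
#' segment occupied by the primary tumor and any occupied by the
#' recurrent tumor, capped at 4; a recurrence is local iff HSI <= 1.
#'
#' @param primary_segments,recurrent_segments Integer vectors in 1..8.
#' @return Integer HSI in 0..4.
#' @export
hepatic_segment_interval <- function(primary_segments, recurrent_segments) {
  ps <- as.integer(primary_segments); rs <- as.integer(recurrent_segments)
  if (!length(ps) || !length(rs)) stop("both tumors need hepatic segment labels")
  if (any(c(ps, rs) < 1L | c(ps, rs) > 8L)) {
    stop("hepatic segments must lie in 1..8")
  }
  min(min(abs(outer(ps, rs, "-"))), 4L)
}

#' @rdname hepatic_segment_interval
#' @param hsi Hepatic segment interval.
#' @return `classify_location()`: `"local"` (HSI <= 1) or `"distant"`.
#' @export
classify_location <- function(hsi) {
  ifelse(hsi <= 1, "local", "distant")
}

#' Count breakpoints shared between two samples
#'
#' Two breakpoints match iff they have the same type, the same chromosome
#' pair, and both positions within `tolerance_bp`.
#'
#' @param bp_a,bp_b Tibbles with `type`, `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param tolerance_bp Position tolerance (default 10).
#' @return Integer count of rows of `bp_a` matched in `bp_b`.
#' @export
shared_breakpoints <- function(bp_a, bp_b, tolerance_bp = 10) {
  if (is.null(bp_a) || is.null(bp_b) || !nrow(bp_a) || !nrow(bp_b)) return(0L)
  n <- 0L
  for (i in seq_len(nrow(bp_a))) {
    hit <- bp_b$type == bp_a$type[i] &
      bp_b$chrom1 == bp_a$chrom1[i] & bp_b$chrom2 == bp_a$chrom2[i] &
      abs(bp_b$pos1 - bp_a$pos1[i]) <= tolerance_bp &
      abs(bp_b$pos2 - bp_a$pos2[i]) <= tolerance_bp
    if (any(hit)) n <- n + 1L
  }
  n
}

#' Whole-genome doubling call
#'
#' A tumor has undergone WGD iff its ploidy is strictly greater than 2.9.
#' @param ploidy Positive ploidy estimate.
#' @return Logical.
#' @export
call_wgd <- function(ploidy) {
  if (any(ploidy <= 0, na.rm = TRUE)) stop("ploidy must be positive")
  ploidy > 2.9
}

#' Gene-level copy-number class
#'
#' Relative to the gene-level median ploidy: total cn 0 is a deletion;
#' more than twice the median ploidy an amplification; greater than the
#' median a gain; less than the median a loss; otherwise neutral
#' (precedence deletion > amplification > gain > loss).
#'
#' @param total_cn Integer total copy number (>= 0).
#' @param median_ploidy Gene-level median ploidy.
#' @return Character class.
#' @export
classify_gene_cnv <- function(total_cn, median_ploidy) {
  if (any(total_cn < 0)) stop("copy number must be >= 0")
  dplyr::case_when(
    total_cn == 0 ~ "deletion",
    total_cn > 2 * median_ploidy ~ "amplification",
    total_cn > median_ploidy ~ "gain",
    total_cn < median_ploidy ~ "loss",
    TRUE ~ "neutral"
  )
}
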