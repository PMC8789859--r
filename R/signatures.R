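# Mutational spectra and signature refitting.
#
# Conventions: substitutions are expressed relative to the pyrimidine of the
# mutated base pair, giving six classes (C>A, C>G, C>T, T>A, T>C, T>G) and,
# with the two flanking bases, 96 trinucleotide categories labelled
# "A[C>A]A" etc. Purine-reference records are reverse-complemented on the fly.

#' Six-class substitution labels
#' @return Character vector of the six pyrimidine-reference classes.
#' @export
sbs_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution categories
#'
#' Class-major ordering (16 contexts per class, 5' base then 3' base).
#' @return Tibble with `class`, `ref`, `alt`, `five`, `three`, `context`
#'   (the 3-mer) and `label` (e.g. `"A[C>A]A"`).
#' @export
sbs_categories <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(three = bases, five = bases, class = sbs_classes(),
                      stringsAsFactors = FALSE)[, c("class", "five", "three")]
  grid <- grid[order(match(grid$class, sbs_classes()), grid$five, grid$three), ]
  ref <- substr(grid$class, 1, 1)
  alt <- substr(grid$class, 3, 3)
  tibble(
    class = grid$class, ref = ref, alt = alt,
    five = grid$five, three = grid$three,
    context = paste0(grid$five, ref, grid$three),
    label = paste0(grid$five, "[", grid$class, "]", grid$three)
  )
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(b) paste(rev(b), collapse = ""),
                character(1)))
}

#' Six-class and 96-category mutation spectra
#'
#' Counts single-nucleotide substitutions by class, complementing
#' purine-reference records to the pyrimidine convention; indels are
#' excluded. With `mode = "96"` the trinucleotide `context` column is
#' required and the result additionally carries the 96-vector.
#'
#' @param mutations Tibble with `ref`, `alt` and (for 96-mode) `context`;
#'   rows with `variant_class != "SNV"` are dropped when that column exists.
#' @param mode `"6"` or `"96"`.
#' @return An object of class `mutation_spectrum`: list with `counts6`
#'   (named vector over the six classes) and, in 96-mode, `counts96`
#'   (named over [sbs_categories()] labels).
#' @export
spectrum <- function(mutations, mode = c("6", "96")) {
  mode <- match.arg(mode)
  m <- as_tibble(mutations)
  if ("variant_class" %in% names(m)) m <- m[m$variant_class == "SNV", ]
  m <- m[nchar(m$ref) == 1 & nchar(m$alt) == 1 & m$ref != "-" & m$alt != "-", ]
  ref <- toupper(m$ref); alt <- toupper(m$alt)
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, chartr("ACGT", "TGCA", ref), ref)
  alt2 <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  cls <- paste0(ref2, ">", alt2)
  counts6 <- setNames(integer(6), sbs_classes())
  tab <- table(factor(cls, levels = sbs_classes()))
  counts6[names(tab)] <- as.integer(tab)
  out <- list(counts6 = counts6)
  if (mode == "96") {
    if (!"context" %in% names(m)) stop("96-mode requires a context column")
    ctx <- toupper(m$context)
    if (any(is.na(ctx) | nchar(ctx) != 3)) {
      stop("96-mode requires a 3-letter context for every SNV")
    }
    ctx2 <- ifelse(flip, revcomp(ctx), ctx)
    if (any(substr(ctx2, 2, 2) != ref2)) {
      stop("context middle base does not match the reference allele")
    }
    lab <- paste0(substr(ctx2, 1, 1), "[", cls, "]", substr(ctx2, 3, 3))
    cats <- sbs_categories()
    counts96 <- setNames(integer(96), cats$label)
    tab96 <- table(factor(lab, levels = cats$label))
    counts96[names(tab96)] <- as.integer(tab96)
    out$counts96 <- counts96
  }
  structure(out, class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("<mutation_spectrum> n =", sum(x$counts6), "\n")
  print(x$counts6)
  invisible(x)
}

#' Deterministic synthetic reference signature matrix
#'
#' A stand-in, generated in code, for an external 30-signature reference
#' catalog: 30 probability columns over the 96 trinucleotide categories.
#' It is synthetic — columns are sparse random profiles with a few designed
#' anchors mirroring well-known etiologies at the same column positions:
#' column 1 is CpG-deamination-like C>T, column 4 C>A-heavy (tobacco-like),
#' column 5 near-flat (clock-like), column 22 T>A-dominant (aristolochic
#' acid-like, the hypermutator signature), column 24 C>A-skewed
#' (aflatoxin-like). Any user matrix with matching row labels can be used
#' instead everywhere a signature matrix is accepted.
#'
#' @param n_signatures Number of columns (default 30).
#' @return A 96 x n matrix; rows labelled by [sbs_categories()] labels,
#'   columns `"S1"`..., each column summing to 1.
#' @export
synthetic_signature_matrix <- function(n_signatures = 30L) {
  cats <- sbs_categories()
  with_seed(761543L, {
    S <- matrix(0, 96, n_signatures,
                dimnames = list(cats$label, paste0("S", seq_len(n_signatures))))
    rdir <- function(alpha) {
      g <- rgamma(length(alpha), alpha)
      g / sum(g)
    }
    for (j in seq_len(n_signatures)) S[, j] <- rdir(rep(0.15, 96))
    anchor <- function(classes, weight) {
      w <- rep(0.02 / 96, 96)
      sel <- cats$class %in% classes
      w[sel] <- w[sel] + weight * rdir(rep(0.5, sum(sel)))
      w / sum(w)
    }
    S[, 1] <- {  # C>T at NpCpG
      w <- rep(0.10 / 96, 96)
      sel <- cats$class == "C>T" & cats$three == "G"
      w[sel] <- w[sel] + 0.9 * rdir(rep(1, sum(sel)))
      w / sum(w)
    }
    S[, 4] <- anchor("C>A", 0.95)
    S[, 5] <- rdir(rep(8, 96))          # near-flat
    S[, 22] <- anchor("T>A", 0.97)      # T>A-dominant hypermutator signature
    S[, 24] <- anchor(c("C>A", "C>T"), 0.95)
    S
  })
}

#' Refit signature exposures by thresholded non-negative least squares
#'
#' Fits non-negative weights reconstructing a normalized 96-category
#' spectrum from the reference matrix, then iteratively zeroes any signature
#' whose normalized weight falls below `cutoff` and refits on the remaining
#' columns until stable. Final weights are renormalized to sum to 1.
#'
#' @param spectrum96 Numeric 96-vector (counts or frequencies) in
#'   [sbs_categories()] order, or a `mutation_spectrum` with `counts96`.
#' @param signature_matrix 96 x k matrix of probability columns.
#' @param cutoff Minimum retained normalized weight (default 0.06).
#' @return An object of class `signature_exposure`: list with `weights`
#'   (named, sums to 1), `rss` and `n_mutations`.
#' @export
refit_exposures <- function(spectrum96, signature_matrix, cutoff = 0.06) {
  if (inherits(spectrum96, "mutation_spectrum")) {
    if (is.null(spectrum96$counts96)) stop("spectrum lacks 96-category counts")
    spectrum96 <- spectrum96$counts96
  }
  v <- as.numeric(spectrum96)
  if (length(v) != nrow(signature_matrix)) {
    stop("spectrum length does not match the signature matrix rows")
  }
  n_mut <- sum(v)
  if (n_mut <= 0) stop("cannot refit an all-zero spectrum")
  v <- v / sum(v)
  keep <- seq_len(ncol(signature_matrix))
  repeat {
    fit <- pracma::lsqnonneg(signature_matrix[, keep, drop = FALSE], v)
    w <- fit$x
    if (sum(w) == 0) break
    wn <- w / sum(w)
    drop_i <- wn > 0 & wn < cutoff
    if (!any(drop_i)) break
    keep <- keep[!drop_i]
    if (!length(keep)) break
  }
  weights <- setNames(numeric(ncol(signature_matrix)),
                      colnames(signature_matrix))
  if (length(keep) && sum(fit$x) > 0) {
    weights[keep] <- fit$x / sum(fit$x)
    resid <- v - signature_matrix[, keep, drop = FALSE] %*% fit$x
  } else {
    resid <- v
  }
  structure(
    list(weights = weights, rss = sum(resid^2), n_mutations = n_mut),
    class = "signature_exposure"
  )
}

#' @export
print.signature_exposure <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat("<signature_exposure> n =", x$n_mutations, " rss =",
      signif(x$rss, 3), "\n")
  print(round(nz, 3))
  invisible(x)
}

#' Flag hypermutated samples
#'
#' A tumor is hypermutated when its genome-wide mutation rate exceeds the
#' threshold (strictly), using a fixed callable-genome denominator.
#'
#' @param n_mutations Mutation count (>= 0).
#' @param genome_mb Callable genome size in Mb (default 2,800).
#' @param threshold Rate threshold in mutations/Mb (default 9).
#' @return Logical.
#' @export
hypermutation_flag <- function(n_mutations, genome_mb = 2800, threshold = 9) {
  if (any(genome_mb <= 0)) stop("genome_mb must be positive")
  if (any(n_mutations < 0)) stop("n_mutations must be >= 0")
  n_mutations / genome_mb > threshold
}

#' Signature exposures per mutation-cluster category
#'
#' Pools the SNVs of each evolutionary category (e.g. trunk clone, trunk
#' subclone, branch subclones), normalizes each category's 96-spectrum and
#' refits exposures. Categories with fewer than `min_mutations` SNVs are
#' flagged low-confidence; empty categories are skipped with a warning.
#'
#' @param mutations Mutation tibble with `ref`, `alt`, `context`,
#'   `variant_class` and a `category` column.
#' @param signature_matrix Reference matrix (default
#'   [synthetic_signature_matrix()]).
#' @param cutoff Exposure cutoff passed to [refit_exposures()].
#' @param min_mutations Low-confidence threshold (default 50).
#' @return Tibble: `category`, `signature`, `weight`, `n_mutations`,
#'   `low_confidence`.
#' @export
category_exposures <- function(mutations,
                               signature_matrix = synthetic_signature_matrix(),
                               cutoff = 0.06, min_mutations = 50L) {
  m <- as_tibble(mutations)
  if (!"category" %in% names(m)) stop("mutations need a category column")
  m <- m[!is.na(m$category), ]
  out <- list()
  for (cat_i in unique(m$category)) {
    sub <- m[m$category == cat_i & m$variant_class == "SNV", ]
    if (!nrow(sub)) {
      warning("category ", cat_i, " has no SNVs; skipped")
      next
    }
    sp <- spectrum(sub, mode = "96")
    ex <- refit_exposures(sp, signature_matrix, cutoff = cutoff)
    out[[cat_i]] <- tibble(
      category = cat_i,
      signature = names(ex$weights),
      weight = unname(ex$weights),
      n_mutations = nrow(sub),
      low_confidence = nrow(sub) < min_mutations
    )
  }
  bind_rows(out)
}

#' Compare category exposures across patients
#'
#' For each signature and pair of categories, a paired t-test across
#' patients of the per-patient exposure difference. With a single patient
#' only descriptive differences are returned (no test).
#'
#' @param exposure_table Tibble with `patient`, `category`, `signature`,
#'   `weight` (long format, e.g. stacked [category_exposures()] results).
#' @param category_pairs List of length-2 character vectors; default: all
#'   category pairs present.
#' @return Tibble with per-signature mean difference, t statistic and
#'   p value (`NA` when not computable).
#' @export
compare_exposures <- function(exposure_table, category_pairs = NULL) {
  et <- as_tibble(exposure_table)
  cats <- unique(et$category)
  if (is.null(category_pairs)) {
    category_pairs <- utils::combn(cats, 2, simplify = FALSE)
  }
  out <- list()
  for (pr in category_pairs) {
    wide <- et |>
      filter(.data$category %in% pr) |>
      select("patient", "category", "signature", "weight") |>
      tidyr::pivot_wider(names_from = "category", values_from = "weight")
    for (sig in unique(wide$signature)) {
      sub <- wide[wide$signature == sig, ]
      a <- sub[[pr[[1]]]]; b <- sub[[pr[[2]]]]
      ok <- stats::complete.cases(a, b)
      a <- a[ok]; b <- b[ok]
      if (!length(a)) next
      d <- a - b
      if (length(d) >= 2 && sd(d) > 0) {
        tt <- stats::t.test(a, b, paired = TRUE)
        stat <- unname(tt$statistic); pv <- tt$p.value
      } else if (length(d) >= 2) {
        stat <- 0; pv <- 1
      } else {
        stat <- NA_real_; pv <- NA_real_
      }
      out[[length(out) + 1L]] <- tibble(
        category_a = pr[[1]], category_b = pr[[2]], signature = sig,
        n_patients = length(d), mean_diff = mean(d),
        t_statistic = stat, p_value = pv
      )
    }
  }
  bind_rows(out)
}
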