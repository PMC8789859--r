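# Harmonization of a patient's mutation sets across samples:
# high-confidence filtering, CNV drop, force calling, and the shared/private
# partition with its random-pair null.

#' High-confidence somatic call filter
#'
#' Keeps a (variant, tumor sample) observation iff tumor depth >= 10,
#' matched-normal depth >= 10, tumor VAF >= 0.05, normal VAF < 0.01
#' (strict) and tumor alt reads >= 3. Sites without a normal observation
#' are excluded with a warning.
#'
#' @param observations Tumor observations (`key`, `sample`, `alt_reads`,
#'   `ref_reads`).
#' @param normal_observations Matched-normal observations (`key`,
#'   `alt_reads`, `ref_reads`).
#' @return The retained rows of `observations`.
#' @export
filter_high_confidence <- function(observations, normal_observations) {
  obs <- as_tibble(observations) |>
    mutate(depth = .data$alt_reads + .data$ref_reads,
           vaf = ifelse(.data$depth > 0, .data$alt_reads / .data$depth, 0))
  nrm <- as_tibble(normal_observations) |>
    mutate(n_depth = .data$alt_reads + .data$ref_reads,
           n_vaf = ifelse(.data$n_depth > 0,
                          .data$alt_reads / .data$n_depth, 0)) |>
    select("key", "n_depth", "n_vaf")
  j <- obs |> left_join(nrm, by = "key")
  miss <- is.na(j$n_depth)
  if (any(miss)) {
    warning(sum(miss), " observation(s) lack a matched-normal site and were excluded")
  }
  keep <- !miss & j$depth >= 10 & j$n_depth >= 10 &
    j$vaf >= 0.05 & j$n_vaf < 0.01 & j$alt_reads >= 3
  observations[keep, , drop = FALSE]
}

new_harmonization_state <- function(case) {
  tum <- tumor_samples(case)
  nrm <- normal_sample(case)
  obs <- case$observations
  tum_obs <- obs |> filter(.data$sample %in% tum)
  nrm_obs <- obs |> filter(.data$sample == nrm)
  hc <- filter_high_confidence(tum_obs |> filter(.data$called), nrm_obs)
  structure(list(
    case = case,
    tumor_samples = tum,
    observations = tum_obs,
    called = hc |> distinct(.data$key, .data$sample) |> mutate(status = "called"),
    dropped = tibble(key = character(), sample = character(),
                     status = character()),
    forced = tibble(key = character(), sample = character(),
                    status = character()),
    audit = tibble(step = "high_confidence",
                   key = hc$key, sample = hc$sample, action = "kept")
  ), class = "harmonization_state")
}

#' Exclude mutations masked by copy-number loss (CNV drop)
#'
#' A mutation called in one sample but absent from another sample of the
#' same patient is excluded from all samples when the locus lies in a
#' copy-number loss region (total cn <= 1) of any non-carrying sample:
#' its absence there is explained by the loss, not by subclonal structure,
#' so the site cannot be interpreted.
#'
#' @param state Harmonization state (from within [harmonize_case()]).
#' @return Updated state with `cnv_dropped` statuses recorded.
#' @export
apply_cnv_drop <- function(state) {
  case <- state$case
  tum <- state$tumor_samples
  keys <- unique(state$called$key)
  if (!length(keys)) return(state)
  pos <- case$mutations |> filter(.data$key %in% keys)
  carrier <- state$called |> mutate(has = TRUE) |>
    tidyr::pivot_wider(id_cols = "key", names_from = "sample",
                       values_from = "has", values_fill = FALSE)
  for (s in setdiff(tum, names(carrier))) carrier[[s]] <- FALSE
  carrier <- carrier[match(pos$key, carrier$key), ]
  ploidy <- setNames(case$samples$ploidy, case$samples$sample)
  drop_key <- rep(FALSE, nrow(pos))
  for (s in tum) {
    fb <- if (is.finite(ploidy[[s]])) as.integer(round(ploidy[[s]])) else 2L
    cn_s <- local_copy_number_vec(sample_segments(case, s),
                                  pos$chrom, pos$pos, fallback = fb)
    drop_key <- drop_key | (!carrier[[s]] & cn_s <= 1L)
  }
  bad <- pos$key[drop_key]
  if (length(bad)) {
    removed <- state$called |> filter(.data$key %in% bad)
    state$dropped <- bind_rows(state$dropped,
                               removed |> mutate(status = "cnv_dropped"))
    state$called <- state$called |> filter(!.data$key %in% bad)
    state$audit <- bind_rows(state$audit,
                             tibble(step = "cnv_drop", key = removed$key,
                                    sample = removed$sample,
                                    action = "removed"))
  }
  state
}

#' Recover uncalled mutations with read support (force calling)
#'
#' For every mutation in the patient's aggregate (post CNV-drop) call set,
#' samples lacking a call gain one iff the site is covered at >= 10x with
#' at least two supporting reads. Mutations are only added, never removed.
#'
#' @param state Harmonization state.
#' @return Updated state with `force_called` statuses recorded.
#' @export
apply_force_calling <- function(state) {
  agg <- unique(state$called$key)
  if (!length(agg)) return(state)
  have <- state$called |> mutate(id = paste(.data$key, .data$sample))
  cand <- state$observations |>
    filter(.data$key %in% agg,
           !paste(.data$key, .data$sample) %in% have$id,
           .data$depth >= 10, .data$alt_reads >= 2)
  if (nrow(cand)) {
    state$forced <- cand |> distinct(.data$key, .data$sample) |>
      mutate(status = "force_called")
    state$audit <- bind_rows(state$audit,
                             tibble(step = "force_calling", key = cand$key,
                                    sample = cand$sample, action = "added"))
  }
  state
}

#' Harmonize a patient's mutation sets across samples
#'
#' Runs the high-confidence filter, CNV drop and force calling (in that
#' order) and returns per-sample final mutation sets with a per-site
#' status and a replayable audit log.
#'
#' @param case A [patient_case()].
#' @return An object of class `harmonized_case`: `final_sets` (named list
#'   of key vectors per tumor sample), `status` (tibble key x sample x
#'   status in called / force_called / cnv_dropped / absent), `audit`, and
#'   per-tumor pooled sets `tumor_sets` (`primary`, `recurrent`).
#' @export
harmonize_case <- function(case) {
  state <- new_harmonization_state(case)
  pre_sets <- split(state$called$key, state$called$sample)
  state <- apply_cnv_drop(state)
  state <- apply_force_calling(state)
  status <- bind_rows(state$called, state$forced, state$dropped)
  final <- bind_rows(state$called, state$forced)
  final_sets <- split(final$key, factor(final$sample,
                                        levels = state$tumor_samples))
  roles <- setNames(case$samples$role, case$samples$sample)
  pool <- function(role) {
    unique(unlist(final_sets[names(final_sets)[roles[names(final_sets)] == role]]))
  }
  pre_pool <- function(role) {
    ss <- intersect(names(pre_sets),
                    names(roles)[roles == role])
    unique(unlist(pre_sets[ss]))
  }
  structure(list(
    patient = case$patient,
    case = case,
    status = status,
    audit = state$audit,
    final_sets = final_sets,
    precall_sets = pre_sets,
    tumor_sets = list(primary = pool("primary"), recurrent = pool("recurrent")),
    precall_tumor_sets = list(primary = pre_pool("primary"),
                              recurrent = pre_pool("recurrent"))
  ), class = "harmonized_case")
}

#' @export
print.harmonized_case <- function(x, ...) {
  cat("<harmonized_case> ", x$patient, ": ",
      length(x$tumor_sets$primary), " primary / ",
      length(x$tumor_sets$recurrent), " recurrent final mutations\n", sep = "")
  invisible(x)
}

# Sharing metrics --------------------------------------------------------------

#' Partition two mutation sets into shared and private keys
#' @param set_a,set_b Character vectors of normalized keys.
#' @return List with `shared`, `private_a`, `private_b`.
#' @export
shared_partition <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  list(shared = shared,
       private_a = setdiff(set_a, shared),
       private_b = setdiff(set_b, shared))
}

#' Shared-mutation fractions between two samples
#'
#' `f_a = |A n B| / |A|`, `f_b = |A n B| / |B|` and their arithmetic mean;
#' fractions involving an empty set are 0.
#' @param set_a,set_b Key vectors.
#' @return Tibble with `n_shared`, `f_a`, `f_b`, `f_mean`.
#' @export
shared_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  ns <- length(intersect(set_a, set_b))
  f_a <- if (length(set_a)) ns / length(set_a) else 0
  f_b <- if (length(set_b)) ns / length(set_b) else 0
  tibble(n_shared = ns, f_a = f_a, f_b = f_b, f_mean = (f_a + f_b) / 2)
}

#' Jaccard similarity of two mutation sets
#' @param set_a,set_b Key vectors.
#' @return `|A n B| / |A u B|` (0 for two empty sets).
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Null distribution of shared fractions over unrelated tumor pairs
#'
#' Computes the mean shared fraction for every unordered pair of
#' independent tumors, the empirical background for judging whether a
#' primary/recurrent pair shares more than chance allows.
#'
#' @param tumor_sets List of >= 2 key vectors.
#' @return Tibble with `i`, `j`, `f_mean` (one row per unordered pair,
#'   `n * (n - 1) / 2` rows total).
#' @export
random_pair_null <- function(tumor_sets) {
  n <- length(tumor_sets)
  if (n < 2) stop("need at least two independent tumor sets")
  pairs <- utils::combn(n, 2)
  f <- vapply(seq_len(ncol(pairs)), function(k) {
    shared_fraction(tumor_sets[[pairs[1, k]]],
                    tumor_sets[[pairs[2, k]]])$f_mean
  }, numeric(1))
  tibble(i = pairs[1, ], j = pairs[2, ], f_mean = f)
}
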