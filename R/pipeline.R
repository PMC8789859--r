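# Per-case and per-cohort orchestration: harmonization -> relatedness ->
# subclonal inference -> evolution -> signatures, with aggregate tables.

#' Pipeline configuration
#'
#' @param max_clustered Cap on the number of mutations used to fit the
#'   CCF clustering; remaining mutations are assigned post hoc with
#'   [predict_clusters()] (default 3,000).
#' @param max_k,restarts,max_iter Clustering controls, see
#'   [cluster_mutations()].
#' @param eps Pigeonhole CCF tolerance.
#' @param presence_thr,clonal_thr Category thresholds.
#' @param exposure_cutoff Signature refit cutoff.
#' @param signature_matrix Reference matrix; default
#'   [synthetic_signature_matrix()].
#' @param min_cluster_frac Cluster size filter threshold.
#' @return Named list of settings.
#' @export
pipeline_config <- function(max_clustered = 3000L, max_k = 8L,
                            restarts = 10L, max_iter = 200L, eps = 0.05,
                            presence_thr = 0.05, clonal_thr = 0.8,
                            exposure_cutoff = 0.06,
                            signature_matrix = NULL,
                            min_cluster_frac = 0.005) {
  list(max_clustered = max_clustered, max_k = max_k, restarts = restarts,
       max_iter = max_iter, eps = eps, presence_thr = presence_thr,
       clonal_thr = clonal_thr, exposure_cutoff = exposure_cutoff,
       signature_matrix = signature_matrix,
       min_cluster_frac = min_cluster_frac)
}

# long CCF-observation table over the harmonized union set
build_ccf_obs <- function(case, keys) {
  tum <- case$samples |> filter(.data$role != "normal")
  pos <- case$mutations |> filter(.data$key %in% keys)
  rows <- lapply(seq_len(nrow(tum)), function(i) {
    s <- tum$sample[i]
    fb <- as.integer(round(tum$ploidy[i]))
    cn <- local_copy_number_vec(sample_segments(case, s),
                                pos$chrom, pos$pos, fallback = fb)
    case$observations |>
      filter(.data$sample == s, .data$key %in% keys) |>
      left_join(tibble(key = pos$key, cn_mut = pmax(cn, 1L)), by = "key") |>
      mutate(purity = tum$purity[i]) |>
      select("key", "sample", "alt_reads", "depth", "purity", "cn_mut")
  })
  bind_rows(rows)
}

#' Run the full pipeline on one patient case
#'
#' Stages: (1) harmonize the mutation sets (high-confidence filter, CNV
#' drop, force calling); (2) quantify relatedness (shared fractions,
#' Jaccard, clonality index against the cutoff, recurrence location,
#' shared breakpoints, WGD) and classify the recurrence pattern; (3)
#' estimate CCFs and cluster mutations, filter clusters, assign
#' clonal/subclonal categories under the scheme implied by the pattern and
#' sampling design; (4) build the subclonal architecture(s) and scaled
#' phylogeny, label drivers; (5) spatial/temporal heterogeneity and
#' polyclonal-seeding detection for multi-region cases; (6) per-category
#' signature exposures.
#'
#' @param case A [patient_case()].
#' @param catalog A [cohort_catalog()] for the clonality index.
#' @param cutoff Numeric CI cutoff or a `ci_calibration`.
#' @param config See [pipeline_config()].
#' @param seed Seed for the clustering stage.
#' @return An object of class `case_result` with `summary`, `tables`,
#'   `trees`, plus the underlying `harmonized` and `fit` objects.
#' @export
run_case <- function(case, catalog, cutoff, config = pipeline_config(),
                     seed = 1L) {
  if (missing(catalog) || is.null(catalog)) {
    stop("configuration error: a cohort catalog is required for the clonality index")
  }
  if (missing(cutoff) || is.null(cutoff)) {
    stop("configuration error: supply a CI cutoff or a calibration result")
  }
  if (inherits(cutoff, "ci_calibration")) cutoff <- cutoff$cutoff

  h <- harmonize_case(case)
  sets <- h$tumor_sets
  sf <- shared_fraction(sets$primary, sets$recurrent)
  sf_pre <- shared_fraction(h$precall_tumor_sets$primary,
                            h$precall_tumor_sets$recurrent)
  jac <- jaccard_index(sets$primary, sets$recurrent)

  eligible <- case$mutations |>
    filter(.data$effect == "nonsynonymous")
  shared_keys <- intersect(sets$primary, sets$recurrent)
  ci <- clonality_index(intersect(shared_keys, eligible$key), catalog)
  pattern <- classify_recurrence(ci, cutoff)

  samp <- case$samples
  roles <- setNames(samp$role, samp$sample)
  seg_p <- unique(unlist(samp$hepatic_segments[samp$role == "primary"]))
  seg_r <- unique(unlist(samp$hepatic_segments[samp$role == "recurrent"]))
  hsi <- if (length(seg_p) && length(seg_r)) {
    hepatic_segment_interval(seg_p, seg_r)
  } else NA_integer_
  location <- if (is.na(hsi)) NA_character_ else classify_location(hsi)

  bp <- case$breakpoints
  shared_sv <- shared_viral <- NA_integer_
  if (!is.null(bp)) {
    bp_role <- roles[bp$sample]
    sv_p <- bp[bp_role == "primary" & bp$type != "HBV", , drop = FALSE]
    sv_r <- bp[bp_role == "recurrent" & bp$type != "HBV", , drop = FALSE]
    shared_sv <- shared_breakpoints(sv_p, sv_r)
    hb_p <- bp[bp_role == "primary" & bp$type == "HBV", , drop = FALSE]
    hb_r <- bp[bp_role == "recurrent" & bp$type == "HBV", , drop = FALSE]
    shared_viral <- shared_breakpoints(hb_p, hb_r)
  }
  wgd <- samp |> filter(.data$role != "normal") |>
    mutate(wgd = call_wgd(.data$ploidy)) |>
    select("sample", "role", "ploidy", "wgd")

  # subclonal inference on the harmonized union
  keys <- unique(c(sets$primary, sets$recurrent))
  ccf_obs <- build_ccf_obs(case, keys)
  fit_keys <- keys
  if (length(keys) > config$max_clustered) {
    fit_keys <- with_seed(sub_seed(seed, 1L),
                          sample(keys, config$max_clustered))
  }
  fit <- cluster_mutations(ccf_obs |> filter(.data$key %in% fit_keys),
                           seed = sub_seed(seed, 2L),
                           max_k = config$max_k,
                           restarts = config$restarts,
                           max_iter = config$max_iter)
  assignments <- if (length(fit_keys) < length(keys)) {
    rest <- predict_clusters(fit, ccf_obs |>
                               filter(!.data$key %in% fit_keys))
    bind_rows(fit$assignments, rest)
  } else fit$assignments
  sizes <- assignments |> count(.data$cluster, name = "size")
  summary_tab <- assignments |>
    left_join(case$mutations |> select("key", "effect"), by = "key") |>
    group_by(.data$cluster) |>
    summarise(size = n(), silent_only = all(.data$effect == "silent"),
              .groups = "drop")
  kept <- filter_clusters(summary_tab, total_mutations = length(keys),
                          min_frac = config$min_cluster_frac)

  tum_ids <- tumor_samples(case)
  n_prim <- sum(roles[tum_ids] == "primary")
  n_rec <- sum(roles[tum_ids] == "recurrent")
  multi <- n_prim > 1 || n_rec > 1
  scheme <- if (multi && pattern == "ancestral") "multi_region" else pattern
  centers_kept <- fit$centers |> filter(.data$cluster %in% kept$cluster)
  categories <- classify_cluster_categories(
    centers_kept, roles, scheme = scheme,
    clonal_thr = config$clonal_thr, presence_thr = config$presence_thr)

  # architectures
  primary_total <- length(sets$primary)
  trees <- list()
  mk_tree <- function(cen, szs) {
    tr <- NULL
    for (mult in c(1, 2, 3)) {  # relax the tolerance if noise makes the
      tr <- tryCatch(            # nominal eps infeasible
        build_subclonal_architecture(cen, szs, eps = config$eps * mult),
        error = function(e) NULL)
      if (!is.null(tr)) break
    }
    if (is.null(tr)) {
      stop("evolution stage: no valid subclonal architecture up to eps = ",
           3 * config$eps)
    }
    build_phylogeny(tr, primary_total)
  }
  kept_sizes <- kept |> select("cluster", "size")
  if (pattern == "ancestral") {
    cl <- categories$cluster[!is.na(categories$category)]
    if (length(cl)) {
      trees$joint <- mk_tree(centers_kept |> filter(.data$cluster %in% cl),
                             kept_sizes |> filter(.data$cluster %in% cl))
    }
  } else {
    for (side in c("primary", "recurrent")) {
      pref <- if (side == "primary") c("primary_clone", "primary_subclone")
              else c("recurrence_clone", "recurrence_subclone")
      cl <- categories$cluster[categories$category %in% pref]
      if (!length(cl)) next
      cen_side <- centers_kept |>
        filter(.data$cluster %in% cl,
               .data$sample %in% names(roles)[roles == side])
      trees[[side]] <- mk_tree(cen_side,
                               kept_sizes |> filter(.data$cluster %in% cl))
    }
  }

  drivers <- label_drivers(case, assignments, categories)

  ith <- NULL
  polyclonal <- NULL
  if (multi) {
    ith <- spatial_temporal_ith(h$final_sets, roles)
    if (n_rec >= 2) {
      polyclonal <- detect_polyclonal_seeding(
        centers_kept, roles, presence_thr = config$presence_thr,
        clonal_thr = config$clonal_thr)
    }
  }

  sig_mat <- config$signature_matrix
  if (is.null(sig_mat)) sig_mat <- synthetic_signature_matrix()
  mut_cat <- case$mutations |>
    inner_join(assignments, by = "key") |>
    left_join(categories, by = "cluster")
  exposures <- suppressWarnings(
    category_exposures(mut_cat, sig_mat, cutoff = config$exposure_cutoff))

  burden <- tibble(
    tumor = c("primary", "recurrent"),
    n_mutations = c(length(sets$primary), length(sets$recurrent))
  ) |> mutate(hypermutated = hypermutation_flag(.data$n_mutations))

  summary <- list(
    patient = case$patient,
    pattern = pattern,
    scheme = scheme,
    ci = ci$ci,
    ci_n_shared = ci$n_shared,
    cutoff = cutoff,
    f_a = sf$f_a, f_b = sf$f_b, f_mean = sf$f_mean,
    f_mean_precall = sf_pre$f_mean,
    jaccard = jac,
    hsi = hsi, location = location,
    shared_sv = shared_sv, shared_viral_breakpoints = shared_viral,
    wgd_primary = any(wgd$wgd[wgd$role == "primary"]),
    wgd_recurrent = any(wgd$wgd[wgd$role == "recurrent"]),
    n_clusters = nrow(kept),
    recurrence_months = case$recurrence_months,
    polyclonal = if (!is.null(polyclonal)) polyclonal$verdict else NA_character_,
    spatial_mean = if (!is.null(ith)) ith$spatial_mean else NA_real_,
    temporal_mean = if (!is.null(ith)) ith$temporal_mean else NA_real_,
    seed = seed
  )
  structure(list(
    summary = summary,
    tables = list(
      sharing = tibble(patient = case$patient, ci = ci$ci, cutoff = cutoff,
                       pattern = pattern, f_a = sf$f_a, f_b = sf$f_b,
                       f_mean = sf$f_mean, jaccard = jac, hsi = hsi,
                       location = location, shared_sv = shared_sv,
                       shared_viral = shared_viral),
      clusters = centers_kept |>
        left_join(kept_sizes, by = "cluster"),
      categories = categories,
      drivers = drivers,
      exposures = exposures,
      wgd = wgd,
      burden = burden,
      heterogeneity = if (!is.null(ith)) ith$pairs else NULL
    ),
    trees = trees,
    harmonized = h,
    fit = fit,
    assignments = assignments,
    polyclonal = polyclonal
  ), class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  s <- x$summary
  cat("<case_result> ", s$patient, ": ", s$pattern,
      " (CI ", signif(s$ci, 4), " vs cutoff ", signif(s$cutoff, 4),
      "), shared ", round(100 * s$f_mean, 1), "%, ", s$location,
      " recurrence\n", sep = "")
  invisible(x)
}

# chi-square without continuity correction when all expected counts >= 5,
# Fisher's exact test otherwise
association_test <- function(tab) {
  if (any(dim(tab) < 2) || sum(tab) == 0) {
    return(list(method = "none", statistic = NA_real_, p_value = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chi-square", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  } else {
    ft <- stats::fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p_value = ft$p.value)
  }
}

#' Run the pipeline over a cohort and aggregate
#'
#' Runs [run_case()] per patient (cases are processed independently, so
#' the aggregate tables do not depend on input order) and assembles the
#' cohort-level summaries: pattern x location contingency (chi-square
#' without continuity correction when all expected counts are >= 5, else
#' Fisher's exact test), WGD x pattern, driver timing fractions and
#' per-signature exposure comparisons across categories.
#'
#' @param cases List of [patient_case()] objects.
#' @param catalog A [cohort_catalog()].
#' @param cutoff Numeric cutoff or `ci_calibration`; alternatively pass
#'   `calibrate_from` to calibrate here.
#' @param config See [pipeline_config()].
#' @param seed Base seed (per-case seeds derive from it).
#' @param calibrate_from Optional list of per-tumor key sets used to
#'   calibrate the cutoff when `cutoff` is missing.
#' @return An object of class `cohort_result` with `case_results`,
#'   `patients` (one summary row per patient) and `summary` (tables and
#'   tests).
#' @export
run_cohort <- function(cases, catalog, cutoff = NULL,
                       config = pipeline_config(), seed = 1L,
                       calibrate_from = NULL) {
  if (is.null(cutoff)) {
    if (is.null(calibrate_from)) {
      stop("configuration error: supply a cutoff or calibration tumor sets")
    }
    cutoff <- calibrate_ci_cutoff(calibrate_from, catalog,
                                  seed = sub_seed(seed, 999L))
  }
  results <- lapply(seq_along(cases), function(i) {
    run_case(cases[[i]], catalog, cutoff, config = config,
             seed = sub_seed(seed, i))
  })
  patients <- bind_rows(lapply(results, function(r) r$tables$sharing)) |>
    arrange(.data$patient)
  pl_tab <- table(pattern = patients$pattern, location = patients$location)
  pl_test <- association_test(pl_tab)
  wgd_rec <- vapply(results, function(r) r$summary$wgd_recurrent, logical(1))
  pat <- vapply(results, function(r) r$summary$pattern, character(1))
  wgd_tab <- table(pattern = pat, wgd_recurrent = wgd_rec)
  wgd_test <- association_test(wgd_tab)
  names(results) <- vapply(results, function(r) r$summary$patient, character(1))
  drv <- driver_timing_summary(lapply(results, function(r) r$tables$drivers))
  expo <- bind_rows(lapply(results, function(r) {
    if (is.null(r$tables$exposures) || !nrow(r$tables$exposures)) return(NULL)
    r$tables$exposures |> mutate(patient = r$summary$patient)
  }))
  expo_cmp <- if (nrow(expo) && dplyr::n_distinct(expo$patient) >= 2) {
    compare_exposures(expo)
  } else NULL
  structure(list(
    case_results = results,
    patients = patients,
    summary = list(
      pattern_location = list(table = pl_tab, test = pl_test),
      wgd_pattern = list(table = wgd_tab, test = wgd_test),
      driver_timing = drv,
      exposures = expo,
      exposure_comparison = expo_cmp,
      cutoff = if (inherits(cutoff, "ci_calibration")) cutoff$cutoff else cutoff
    )
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", nrow(x$patients), " patients: ",
      sum(x$patients$pattern == "ancestral"), " ancestral / ",
      sum(x$patients$pattern == "de_novo"), " de novo\n", sep = "")
  print(x$summary$pattern_location$table)
  invisible(x)
}
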