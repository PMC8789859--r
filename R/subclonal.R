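# Cancer cell fraction estimation, multi-sample mutation clustering,
# cluster filtering, and clonal/subclonal category assignment.

#' Cancer cell fraction from VAF, purity and local copy number
#'
#' Inverts the expected-VAF relation
#' `VAF = p * CCF / (cn_norm * (1 - p) + p * cn_mut)`:
#' `CCF = VAF * (cn_norm * (1 - p) + p * cn_mut) / p`, clipped to `[0, 1]`.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param cn_mut Local tumor copy number (>= 1 where `vaf > 0`).
#' @param cn_norm Normal copy number (2 on autosomes).
#' @param clip Clip the result to `[0, 1]` (default TRUE).
#' @return Numeric CCF vector.
#' @export
compute_ccf <- function(vaf, purity, cn_mut, cn_norm = 2, clip = TRUE) {
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(cn_mut < 1 & vaf > 0)) stop("cn_mut < 1 with positive VAF")
  ccf <- vaf * (cn_norm * (1 - purity) + purity * cn_mut) / purity
  if (clip) ccf <- pmin(pmax(ccf, 0), 1)
  ccf
}

# build per-mutation x per-sample matrices from a long CCF-observation table
ccf_matrices <- function(ccf_obs) {
  keys <- unique(ccf_obs$key)
  samples <- unique(ccf_obs$sample)
  idx <- cbind(match(ccf_obs$key, keys), match(ccf_obs$sample, samples))
  mk <- function(v, fill = 0) {
    m <- matrix(fill, length(keys), length(samples),
                dimnames = list(keys, samples))
    m[idx] <- v
    m
  }
  kappa <- ccf_obs$purity /
    (2 * (1 - ccf_obs$purity) + ccf_obs$purity * ccf_obs$cn_mut)
  list(keys = keys, samples = samples,
       alt = mk(ccf_obs$alt_reads), depth = mk(ccf_obs$depth),
       kappa = mk(kappa, fill = NA_real_))
}

row_max <- function(m) {
  out <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) out <- pmax(out, m[, k])
  out
}

em_loglik_mat <- function(alt, depth, kappa, phi) {
  # rows: mutations; per cluster column of phi (K x S) -> n x K loglik
  n <- nrow(alt); K <- nrow(phi)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    v <- sweep(kappa, 2, phi[k, ], "*")
    v <- pmin(pmax(v, 1e-9), 1 - 1e-9)
    ll[, k] <- rowSums(alt * log(v) + (depth - alt) * log(1 - v), na.rm = TRUE)
  }
  ll
}

em_fit <- function(alt, depth, kappa, phi0, max_iter = 200, tol = 1e-6) {
  K <- nrow(phi0)
  phi <- phi0
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  dk <- ifelse(is.na(kappa), 0, depth * kappa)
  for (it in seq_len(max_iter)) {
    lr <- sweep(em_loglik_mat(alt, depth, kappa, phi), 2, log(pi_k), "+")
    mx <- row_max(lr)
    r <- exp(lr - mx)
    rs <- rowSums(r)
    ll <- sum(mx + log(rs))
    r <- r / rs
    pi_k <- pmax(colMeans(r), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    num <- crossprod(r, alt)                  # K x S
    den <- crossprod(r, dk)
    phi <- pmin(pmax(num / pmax(den, 1e-12), 0), 1)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  lr <- sweep(em_loglik_mat(alt, depth, kappa, phi), 2, log(pi_k), "+")
  mx <- row_max(lr)
  list(phi = phi, pi = pi_k,
       loglik = sum(mx + log(rowSums(exp(lr - mx)))),
       assign = max.col(lr, ties.method = "first"))
}

#' Cluster mutations by shared cancer cell fractions across samples
#'
#' Finite binomial mixture over per-sample read counts: each cluster k has
#' one CCF per sample and a mutation's alt count in sample s is binomial
#' with success probability `kappa_ms * ccf_ks`, where `kappa` folds in
#' purity and local copy number. Fitted by EM with seeded restarts; the
#' number of clusters is chosen by BIC over `1..max_k`. Deterministic
#' under `seed`; with noiseless input and distinct CCF vectors the true
#' partition is recovered exactly.
#'
#' @param ccf_obs Long tibble with `key`, `sample`, `alt_reads`, `depth`,
#'   `purity`, `cn_mut` for every tumor sample of one patient.
#' @param seed Seed.
#' @param max_k Largest number of clusters considered (default 8).
#' @param restarts Random restarts per K (default 10).
#' @param max_iter EM iteration cap.
#' @return An object of class `ccf_cluster_fit`: `assignments` (key,
#'   cluster), `centers` (cluster, sample, ccf), `sizes`, `k`, `bic`
#'   (per-K table), `loglik`.
#' @export
cluster_mutations <- function(ccf_obs, seed = NULL, max_k = 8L,
                              restarts = 10L, max_iter = 200L) {
  mats <- ccf_matrices(ccf_obs)
  alt <- mats$alt; depth <- mats$depth; kappa <- mats$kappa
  n <- nrow(alt); S <- ncol(alt)
  if (n == 0) stop("no mutations to cluster")
  if (all(depth == 0)) stop("all observations have zero depth")
  raw <- pmin(pmax(ifelse(depth > 0, (alt / pmax(depth, 1)) / kappa, 0),
                   0), 1)
  raw[is.na(raw)] <- 0
  uniq <- unique(round(raw, 3))
  with_seed(seed, {
    best <- NULL
    bic_tab <- list()
    for (K in seq_len(min(max_k, n))) {
      inits <- list()
      # data-driven init: kmeans on raw per-mutation CCF estimates
      if (nrow(uniq) >= K) {
        km <- tryCatch(
          stats::kmeans(raw, centers = if (nrow(uniq) == K) uniq else K,
                        nstart = 1),
          error = function(e) NULL)
        if (!is.null(km)) inits[[1]] <- matrix(km$centers, K, S)
      }
      for (r in seq_len(restarts)) {
        inits[[length(inits) + 1L]] <-
          raw[sample.int(n, K, replace = n < K), , drop = FALSE]
      }
      # short EM runs per start, then polish the best one
      fit_k <- NULL
      best_ll <- -Inf; best_phi <- NULL
      for (ini in inits) {
        f <- em_fit(alt, depth, kappa, matrix(ini, K, S),
                    max_iter = min(25L, max_iter))
        if (f$loglik > best_ll + 1e-9) { best_ll <- f$loglik; best_phi <- f$phi }
      }
      fit_k <- em_fit(alt, depth, kappa, best_phi, max_iter = max_iter)
      n_par <- (K - 1) + K * S
      bic <- -2 * fit_k$loglik + n_par * log(n)
      bic_tab[[K]] <- tibble(k = K, loglik = fit_k$loglik, bic = bic)
      if (is.null(best) || bic < best$bic - 1e-9) {
        best <- list(fit = fit_k, k = K, bic = bic)
      }
    }
    fit <- best$fit
    used <- sort(unique(fit$assign))
    relab <- match(fit$assign, used)
    centers <- fit$phi[used, , drop = FALSE]
    ord <- order(-rowSums(centers))
    centers <- centers[ord, , drop = FALSE]
    relab <- match(relab, ord)
    cl_ids <- paste0("K", seq_along(used))
    structure(list(
      assignments = tibble(key = mats$keys, cluster = cl_ids[relab]),
      centers = tibble(
        cluster = rep(cl_ids, each = S),
        sample = rep(mats$samples, times = length(used)),
        ccf = as.numeric(t(centers))
      ),
      sizes = tibble(cluster = cl_ids,
                     size = as.integer(table(factor(relab,
                                                    levels = seq_along(used))))),
      k = length(used),
      pi = fit$pi[used][ord],
      bic = bind_rows(bic_tab),
      loglik = fit$loglik
    ), class = "ccf_cluster_fit")
  })
}

#' @export
print.ccf_cluster_fit <- function(x, ...) {
  cat("<ccf_cluster_fit> ", x$k, " cluster(s), ",
      nrow(x$assignments), " mutations\n", sep = "")
  print(tidyr::pivot_wider(x$centers, names_from = "sample",
                           values_from = "ccf"))
  invisible(x)
}

#' Assign additional mutations to fitted clusters
#'
#' Maximum-posterior assignment of mutations (typically those left out of
#' the clustering subsample) to the clusters of an existing fit, using the
#' fitted centers and mixing weights.
#'
#' @param fit A `ccf_cluster_fit`.
#' @param ccf_obs Long observation tibble as in [cluster_mutations()].
#' @return Tibble `key`, `cluster`.
#' @export
predict_clusters <- function(fit, ccf_obs) {
  mats <- ccf_matrices(ccf_obs)
  cen <- centers_matrix(fit$centers)
  cen <- cen[, mats$samples, drop = FALSE]
  lr <- sweep(em_loglik_mat(mats$alt, mats$depth, mats$kappa, cen),
              2, log(pmax(fit$pi, 1e-12)), "+")
  tibble(key = mats$keys, cluster = rownames(cen)[max.col(lr, "first")])
}

#' Summarize clusters with size and silent-only status
#'
#' @param fit A `ccf_cluster_fit`.
#' @param mutations Mutation tibble with `key` and `effect`.
#' @return Tibble: `cluster`, `size`, `silent_only`.
#' @export
cluster_summary <- function(fit, mutations) {
  fit$assignments |>
    left_join(mutations |> select("key", "effect"), by = "key") |>
    group_by(.data$cluster) |>
    summarise(size = n(), silent_only = all(.data$effect == "silent"),
              .groups = "drop")
}

#' Filter mutation clusters
#'
#' Drops clusters holding fewer than 5/1,000 of the patient's mutations
#' (strict) or containing only silent mutations.
#'
#' @param clusters Tibble with `cluster`, `size`, `silent_only` (see
#'   [cluster_summary()]).
#' @param total_mutations Total mutations in the patient (>= 1).
#' @param min_frac Size threshold as a fraction of `total_mutations`.
#' @return The retained rows; warns when nothing survives.
#' @export
filter_clusters <- function(clusters, total_mutations, min_frac = 0.005) {
  if (total_mutations < 1) stop("total_mutations must be >= 1")
  keep <- clusters$size >= min_frac * total_mutations & !clusters$silent_only
  out <- clusters[keep, , drop = FALSE]
  if (!nrow(out)) warning("all clusters were filtered out")
  out
}

#' Assign clonal/subclonal categories to clusters
#'
#' A cluster is present in a sample iff its CCF center is at least
#' `presence_thr`. Under the paired ancestral scheme, clusters present in
#' both tumors are trunk (the trunk clone requires CCF > `clonal_thr`,
#' strict, in every tumor sample; at most one qualifies — ties resolved
#' toward the largest minimum CCF) and one-sided clusters are primary or
#' recurrence branches. The de novo scheme classifies each tumor
#' separately into clone/subclone; the multi-region scheme distinguishes
#' trunk (all samples), branch (several samples) and leaf (one sample)
#' subclones.
#'
#' @param centers Tibble `cluster`, `sample`, `ccf` (tumor samples only).
#' @param roles Named character vector mapping sample -> role
#'   (`primary` / `recurrent`).
#' @param scheme `"ancestral"`, `"de_novo"` or `"multi_region"`.
#' @param clonal_thr CCF above which a cluster is clonal (default 0.8).
#' @param presence_thr CCF at or above which a cluster is present
#'   (default 0.05).
#' @return Tibble `cluster`, `category` (NA when present nowhere).
#' @export
classify_cluster_categories <- function(centers, roles,
                                        scheme = c("ancestral", "de_novo",
                                                   "multi_region"),
                                        clonal_thr = 0.8,
                                        presence_thr = 0.05) {
  scheme <- match.arg(scheme)
  if (!all(centers$sample %in% names(roles))) {
    stop("centers contain samples without a declared role")
  }
  w <- centers |>
    mutate(role = unname(roles[.data$sample])) |>
    group_by(.data$cluster) |>
    summarise(
      pres_p = any(.data$ccf >= presence_thr & .data$role == "primary"),
      pres_r = any(.data$ccf >= presence_thr & .data$role == "recurrent"),
      n_pres = sum(.data$ccf >= presence_thr),
      all_clonal = all(.data$ccf > clonal_thr),
      clonal_p = all(.data$ccf[.data$role == "primary"] > clonal_thr),
      clonal_r = all(.data$ccf[.data$role == "recurrent"] > clonal_thr),
      min_ccf = min(.data$ccf),
      min_ccf_p = suppressWarnings(min(.data$ccf[.data$role == "primary"])),
      min_ccf_r = suppressWarnings(min(.data$ccf[.data$role == "recurrent"])),
      .groups = "drop"
    )
  pick_one <- function(cand, key) {
    # at most one clone: ties resolved toward the largest minimum CCF
    if (sum(cand) <= 1) return(cand)
    best <- which(cand)[which.max(w[[key]][cand])]
    out <- rep(FALSE, length(cand)); out[best] <- TRUE
    out
  }
  cat_v <- rep(NA_character_, nrow(w))
  if (scheme == "ancestral") {
    trunk <- w$pres_p & w$pres_r
    clone <- pick_one(trunk & w$all_clonal, "min_ccf")
    cat_v[clone] <- "trunk_clone"
    cat_v[trunk & !clone] <- "trunk_subclone"
    cat_v[w$pres_p & !w$pres_r] <- "primary_branch"
    cat_v[!w$pres_p & w$pres_r] <- "recurrence_branch"
  } else if (scheme == "de_novo") {
    side_p <- w$pres_p & !w$pres_r
    side_r <- w$pres_r & !w$pres_p
    both <- w$pres_p & w$pres_r
    side_p[both] <- w$min_ccf_p[both] >= w$min_ccf_r[both]
    side_r[both] <- !side_p[both]
    clone_p <- pick_one(side_p & w$clonal_p, "min_ccf_p")
    clone_r <- pick_one(side_r & w$clonal_r, "min_ccf_r")
    cat_v[clone_p] <- "primary_clone"
    cat_v[side_p & !clone_p] <- "primary_subclone"
    cat_v[clone_r] <- "recurrence_clone"
    cat_v[side_r & !clone_r] <- "recurrence_subclone"
  } else {
    n_samples <- length(unique(centers$sample))
    trunk <- w$n_pres == n_samples
    clone <- pick_one(trunk & w$all_clonal, "min_ccf")
    cat_v[clone] <- "trunk_clone"
    cat_v[trunk & !clone] <- "trunk_subclone"
    cat_v[!trunk & w$n_pres >= 2] <- "branch_subclone"
    cat_v[w$n_pres == 1] <- "leaf_subclone"
  }
  tibble(cluster = w$cluster, category = cat_v)
}
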