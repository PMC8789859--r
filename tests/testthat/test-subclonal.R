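test_that("CCF computation inverts the expected-VAF relation", {
  expect_equal(compute_ccf(0.25, 0.5, 2), 1.0)
  expect_equal(compute_ccf(0, 0.5, 2), 0)
  expect_equal(compute_ccf(0.5, 1, 2), 1)   # clonal heterozygous, purity 1
  expect_error(compute_ccf(0.2, 0, 2), "purity")
  expect_error(compute_ccf(0.2, 0.5, 0), "cn_mut")

  # round trip: forward VAF then inversion recovers the input exactly
  set.seed(42)
  for (i in 1:200) {
    ccf <- runif(1); p <- runif(1, 0.05, 1); cn <- sample(1:6, 1)
    vaf <- p * ccf / (2 * (1 - p) + p * cn)
    expect_equal(compute_ccf(vaf, p, cn, clip = FALSE), ccf,
                 tolerance = 1e-12)
  }
})

make_ccf_obs <- function(ccf_mat, sizes, purity = 0.8, depth = 1000,
                         seed = 1, noiseless = FALSE) {
  rows <- list()
  with_seed_local <- function(code) code
  set.seed(seed)
  idx <- 0
  for (g in seq_len(nrow(ccf_mat))) {
    for (m in seq_len(sizes[g])) {
      idx <- idx + 1
      for (s in seq_len(ncol(ccf_mat))) {
        d <- if (noiseless) depth else rpois(1, depth)
        ev <- purity * ccf_mat[g, s] / (2 * (1 - purity) + purity * 2)
        a <- if (noiseless) round(d * ev) else rbinom(1, d, ev)
        rows[[length(rows) + 1]] <- tibble::tibble(
          key = paste0("m", idx), sample = paste0("S", s),
          alt_reads = a, depth = d, purity = purity, cn_mut = 2)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("clustering recovers well-separated CCF groups", {
  m <- rbind(c(1, 1), c(0.4, 0))
  obs <- make_ccf_obs(m, c(60, 60), depth = 1000, seed = 3)
  fit <- cluster_mutations(obs, seed = 5)
  expect_equal(fit$k, 2L)
  cen <- tidyr::pivot_wider(fit$centers, names_from = sample,
                            values_from = ccf)
  cen <- cen[order(-cen$S1), ]
  expect_lt(max(abs(as.matrix(cen[, -1]) - m)), 0.02)

  # identical seed, identical partition
  fit2 <- cluster_mutations(obs, seed = 5)
  expect_identical(fit$assignments, fit2$assignments)

  # a single mutation forms a singleton cluster
  single <- obs[obs$key == "m1", ]
  fs <- cluster_mutations(single, seed = 1)
  expect_equal(fs$k, 1L)

  # duplicated CCF vectors collapse to one cluster
  dup <- make_ccf_obs(rbind(c(0.5, 0.5), c(0.5, 0.5)), c(40, 40),
                      depth = 2000, seed = 4, noiseless = TRUE)
  fd <- cluster_mutations(dup, seed = 2)
  expect_equal(fd$k, 1L)

  expect_error(cluster_mutations(dplyr::mutate(obs, depth = 0, alt_reads = 0)),
               "zero depth")
})

test_that("noiseless clustering recovers the exact partition", {
  m <- rbind(c(1, 1), c(0.6, 0.7), c(0.3, 0.05), c(0, 0.4))
  obs <- make_ccf_obs(m, c(50, 40, 30, 30), depth = 2000, seed = 6,
                      noiseless = TRUE)
  fit <- cluster_mutations(obs, seed = 8)
  expect_equal(fit$k, 4L)
  truth <- rep(1:4, c(50, 40, 30, 30))
  est <- fit$assignments$cluster[match(paste0("m", seq_along(truth)),
                                       fit$assignments$key)]
  # same partition: every estimated cluster maps to exactly one true group
  expect_equal(length(unique(paste(truth, est))), 4L)
})

test_that("cluster filtering drops small and silent-only clusters strictly", {
  cl <- tibble::tibble(cluster = c("a", "b", "c"),
                       size = c(49L, 50L, 5000L),
                       silent_only = c(FALSE, FALSE, FALSE))
  kept <- filter_clusters(cl, total_mutations = 10000)
  expect_setequal(kept$cluster, c("b", "c"))  # "less than 5/1000" is strict

  sil <- tibble::tibble(cluster = "s", size = 4000L, silent_only = TRUE)
  expect_warning(out <- filter_clusters(sil, 10000), "filtered")
  expect_equal(nrow(out), 0L)
  expect_error(filter_clusters(cl, 0), ">= 1")
})

test_that("category assignment follows the scheme definitions", {
  roles <- c(P = "primary", R = "recurrent")
  cen <- function(...) {
    m <- rbind(...)
    tibble::tibble(cluster = rep(rownames(m), each = 2),
                   sample = rep(c("P", "R"), nrow(m)),
                   ccf = as.numeric(t(m)))
  }
  x <- cen(a = c(0.95, 0.90), b = c(0.85, 0.02), c = c(0.5, 0.4),
           d = c(0.02, 0.5))
  out <- classify_cluster_categories(x, roles, "ancestral")
  expect_equal(out$category[out$cluster == "a"], "trunk_clone")
  expect_equal(out$category[out$cluster == "b"], "primary_branch")
  expect_equal(out$category[out$cluster == "c"], "trunk_subclone")
  expect_equal(out$category[out$cluster == "d"], "recurrence_branch")

  # the trunk clone needs CCF strictly above 0.8 in both tumors
  y <- cen(a = c(0.8, 0.9), b = c(0.2, 0.3))
  outy <- classify_cluster_categories(y, roles, "ancestral")
  expect_equal(outy$category[outy$cluster == "a"], "trunk_subclone")

  # at most one trunk clone even when two clusters qualify
  z <- cen(a = c(0.99, 0.98), b = c(0.85, 0.95), c = c(0.3, 0.3))
  outz <- classify_cluster_categories(z, roles, "ancestral")
  expect_equal(sum(outz$category == "trunk_clone"), 1L)
  expect_equal(outz$category[outz$cluster == "a"], "trunk_clone")

  # de novo scheme: per-tumor clones and subclones
  d <- cen(a = c(0.95, 0.01), b = c(0.4, 0.01), c = c(0.01, 0.9),
           d = c(0.01, 0.2))
  outd <- classify_cluster_categories(d, roles, "de_novo")
  expect_equal(outd$category, c("primary_clone", "primary_subclone",
                                "recurrence_clone", "recurrence_subclone"))

  # multi-region scheme: trunk / branch / leaf by sample spread
  roles4 <- c(P1 = "primary", P2 = "primary", R1 = "recurrent",
              R2 = "recurrent")
  m4 <- rbind(a = c(0.9, 0.95, 0.92, 0.85), b = c(0.4, 0.3, 0.2, 0.5),
              c = c(0.3, 0.2, 0.01, 0.01), d = c(0.25, 0.01, 0.01, 0.01))
  x4 <- tibble::tibble(cluster = rep(rownames(m4), each = 4),
                       sample = rep(names(roles4), 4),
                       ccf = as.numeric(t(m4)))
  out4 <- classify_cluster_categories(x4, roles4, "multi_region")
  expect_equal(out4$category, c("trunk_clone", "trunk_subclone",
                                "branch_subclone", "leaf_subclone"))

  expect_error(
    classify_cluster_categories(x, c(Q = "primary"), "ancestral"),
    "without a declared role")
})
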