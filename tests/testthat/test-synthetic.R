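test_that("simulated clone trees are rooted, acyclic and seed-deterministic", {
  expect_equal(simulate_clone_tree(1), NA_integer_)
  expect_error(simulate_clone_tree(0), ">= 1")
  expect_identical(simulate_clone_tree(3, seed = 9),
                   simulate_clone_tree(3, seed = 9))
  for (s in 1:1000) {
    k <- (s %% 7L) + 2L
    par <- simulate_clone_tree(k, seed = s)
    expect_equal(sum(is.na(par)), 1L)
    expect_true(is.na(par[1]))
    # every node walks up to the root without revisiting
    for (v in 2:k) {
      u <- v; steps <- 0L
      while (!is.na(par[u])) {
        u <- par[u]; steps <- steps + 1L
        expect_lte(steps, k)
      }
      expect_equal(u, 1L)
    }
  }
})

test_that("stick-broken CCFs satisfy the sibling-sum constraint everywhere", {
  for (s in 1:60) {
    k <- (s %% 5L) + 2L
    par <- simulate_clone_tree(k, seed = s)
    pres <- matrix(TRUE, k, 2)
    ccf <- assign_sample_ccfs(par, pres, seed = s + 1000)
    expect_true(all(ccf[1, ] == 1))
    for (v in seq_len(k)) {
      ch <- which(!is.na(par) & par == v)
      if (length(ch)) {
        sums <- colSums(ccf[ch, , drop = FALSE])
        expect_true(all(sums <= ccf[v, ] + 1e-9))
      }
    }
  }
  # a present node with an absent parent is rejected
  pres <- matrix(c(TRUE, FALSE, TRUE), 3, 1)
  expect_error(assign_sample_ccfs(c(NA, 1L, 2L), pres), "absent parent")
})

test_that("read simulation matches the expected-VAF model", {
  # clonal heterozygous diploid limit: VAF -> 0.5
  rd <- simulate_reads(rep(1, 2000), purity = 1, cn_mut = 2,
                       depth_mean = 500, seed = 1)
  expect_equal(mean(rd$alt_reads / rd$depth), 0.5, tolerance = 0.01)
  expect_equal(unique(rd$expected_vaf), 0.5)

  # absent mutations never produce alt reads
  rd0 <- simulate_reads(rep(0, 500), 0.6, 2, 54, seed = 2)
  expect_true(all(rd0$alt_reads == 0))

  # Monte-Carlo: mean simulated VAF within 3 SE of the expectation
  n <- 10000
  ev <- 0.6 * 0.45 / (2 * (1 - 0.6) + 0.6 * 2)
  rd <- simulate_reads(rep(0.45, n), 0.6, 2, 54, seed = 3)
  vaf <- rd$alt_reads / pmax(rd$depth, 1)
  se <- sd(vaf) / sqrt(n)
  expect_lt(abs(mean(vaf) - ev), 3 * se)

  expect_error(simulate_reads(0.5, purity = 0, cn_mut = 2, depth_mean = 54),
               "purity")
  expect_error(simulate_reads(0.5, purity = 0.5, cn_mut = 0, depth_mean = 54),
               "cn_mut")

  # noiseless mode is the rounded infinite-depth oracle
  rd <- simulate_reads(c(0.3, 0.8), 0.5, 2, 2000, noiseless = TRUE)
  expect_equal(rd$alt_reads, round(2000 * rd$expected_vaf))
  expect_true(all(rd$depth == 2000))
})

test_that("catalog simulation conserves counts and shows the Zipf tail", {
  cs <- simulate_catalog(30, 200, seed = 7)
  expect_equal(cs$catalog$n_total, sum(lengths(cs$tumor_sets)))
  expect_equal(cs$catalog$n_tumors, 30L)
  expect_true(all(lengths(cs$tumor_sets) <= 200))

  # degenerate limit: a huge exponent with certain top-hotspot inclusion
  # leaves exactly one hotspot shared by all tumors
  deg <- simulate_catalog(20, 50, zipf_s = 50, seed = 8,
                          hotspot_top_incl = 1)
  shared <- Reduce(intersect, deg$tumor_sets)
  expect_equal(shared, deg$hotspots$key[1])

  # rank-frequency slope of the hotspot layer ~ -s (1e5 draws)
  cs2 <- simulate_catalog(1000, 100, zipf_s = 1.5, seed = 9)
  counts <- sort(cs2$catalog$counts, decreasing = TRUE)
  top <- counts[counts >= 3]
  fit <- stats::lm(log(as.numeric(top)) ~ log(seq_along(top)))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1.5), 0.2)
})

test_that("identical seeds give byte-identical emitted files", {
  p <- small_params(mutations_per_tumor = c(150, 300))
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  hs <- test_catalog_sim()$hotspots
  write_case_files(simulate_case("de_novo", p, seed = 33, hotspots = hs), d1)
  write_case_files(simulate_case("de_novo", p, seed = 33, hotspots = hs), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("de novo cases share few mutations and ancestral cases share many", {
  p <- small_params()
  hs <- test_catalog_sim()$hotspots
  for (s in 1:4) {
    dn <- simulate_case("de_novo", p, seed = s, hotspots = hs)
    h <- harmonize_case(dn$case)
    f <- shared_fraction(h$tumor_sets$primary, h$tumor_sets$recurrent)
    expect_lte(f$f_mean, 0.05 + 0.01)
    an <- simulate_case("ancestral", p, seed = s + 100, hotspots = hs)
    ha <- harmonize_case(an$case)
    fa <- shared_fraction(ha$tumor_sets$primary, ha$tumor_sets$recurrent)
    expect_gt(fa$f_mean, 0.15)
  }
})

test_that("hypermutator cases exceed 9 mutations/Mb with a T>A spectrum", {
  p <- sim_params(hypermutator_prob = 1,
                  hypermutator_burden = c(26000L, 30000L),
                  catalog_n_tumors = 10L, catalog_muts_per_tumor = 100L)
  sim <- simulate_case("de_novo", p, seed = 5)
  n_p <- sum(sim$truth$mutation_clusters$cluster %in%
               c("PC1", grep("^PS", unique(sim$truth$mutation_clusters$cluster),
                             value = TRUE)))
  expect_true(hypermutation_flag(n_p))
  sp <- spectrum(sim$case$mutations)
  expect_equal(names(which.max(sp$counts6)), "T>A")
  expect_true(sim$truth$hypermutator)
})

test_that("noiseless emission reproduces the ground truth exactly", {
  p <- small_params(noiseless = TRUE, mutations_per_tumor = c(400, 800))
  hs <- test_catalog_sim()$hotspots
  for (s in c(2, 5)) {
    sim <- simulate_case("ancestral", p, seed = s, hotspots = hs)
    h <- harmonize_case(sim$case)
    # per-sample final sets equal the analytic truth sets
    for (smp in names(sim$truth$truth_sets)) {
      expect_setequal(h$final_sets[[smp]], sim$truth$truth_sets[[smp]])
    }
    f <- shared_fraction(h$tumor_sets$primary, h$tumor_sets$recurrent)
    expect_equal(f$f_mean, sim$truth$shared_fraction, tolerance = 1e-12)
    # planted CNV artifacts are gone from every final set
    art <- sim$truth$mutation_clusters$key[
      sim$truth$mutation_clusters$kind == "cnv_artifact"]
    expect_gt(length(art), 0)
    expect_false(any(art %in% unlist(h$final_sets)))
  }
})
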