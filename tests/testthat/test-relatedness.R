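test_that("mutation probabilities divide counts by the cohort total", {
  cat <- cohort_catalog(c("1:1:A:T" = 2L, "1:2:C:G" = 5L), n_total = 1000L)
  expect_equal(mutation_probability("1:1:A:T", cat), 0.002)
  expect_equal(mutation_probability("9:9:G:C", cat), 0.001)  # pseudo-count 1
  full <- cohort_catalog(c(k = 7L), n_total = 7L)
  expect_equal(mutation_probability("k", full), 1)
})

test_that("the clonality index equals the closed-form binomial product", {
  cat <- cohort_catalog(c(a = 100L, b = 10L), n_total = 1000L)
  # one shared key with p = 0.1: CI = -log10(0.01) = 2
  expect_equal(clonality_index("a", cat)$ci, 2)
  # p = {0.01, 0.1}: product 1e-6 -> CI = 6
  expect_equal(clonality_index(c("a", "b"), cat)$ci, 6)
  expect_equal(clonality_index(character(), cat)$ci, 0)
  expect_equal(clonality_index(character(), cat)$n_shared, 0L)
})

test_that("CI is additive over disjoint key sets and matches brute force", {
  cs <- test_catalog_sim()
  keys <- names(cs$catalog$counts)
  for (s in 1:25) {
    set.seed(s)
    k1 <- sample(keys, sample(1:20, 1))
    k2 <- paste0("nov", s, "_", 1:sample(1:10, 1))
    ci1 <- clonality_index(k1, cs$catalog)$ci
    ci2 <- clonality_index(k2, cs$catalog)$ci
    ci12 <- clonality_index(c(k1, k2), cs$catalog)$ci
    expect_equal(ci12, ci1 + ci2, tolerance = 1e-9)
    # direct product oracle (no log-space)
    p <- mutation_probability(c(k1, k2), cs$catalog)
    expect_equal(ci12, -log10(prod(p^2)), tolerance = 1e-9)
  }
})

test_that("cutoff calibration has the documented design and determinism", {
  sets <- lapply(1:20, function(i) {
    c(paste0("t", i, "_", 1:30), names(test_catalog_sim()$catalog$counts)[1:3])
  })
  cal <- calibrate_ci_cutoff(sets, test_catalog_sim()$catalog, repeats = 5,
                             seed = 77)
  expect_equal(cal$n_positive, 3 * 20)   # 3 fractions x n tumors
  expect_equal(cal$n_negative, 3 * 20)
  expect_length(cal$cutoffs, 5)
  expect_equal(cal$cutoff, median(cal$cutoffs))
  cal2 <- calibrate_ci_cutoff(sets, test_catalog_sim()$catalog, repeats = 5,
                              seed = 77)
  expect_equal(cal$cutoff, cal2$cutoff)

  # invariance to the order in which tumors are supplied
  cal3 <- calibrate_ci_cutoff(rev(sets), test_catalog_sim()$catalog,
                              repeats = 5, seed = 77)
  expect_equal(cal3$cutoff, cal$cutoff)

  # perfectly separable classes are classified with accuracy 1 at the
  # median cutoff: each tumor is mostly private keys, so related
  # subsamples share rare mutations while unrelated pairs share nothing
  priv <- lapply(1:12, function(i) paste0("p", i, "_", 1:40))
  calp <- calibrate_ci_cutoff(priv, test_catalog_sim()$catalog,
                              repeats = 10, seed = 5)
  expect_equal(calp$accuracy, 1)

  expect_error(calibrate_ci_cutoff(priv[1], test_catalog_sim()$catalog),
               "two")
})

test_that("held-out related/unrelated pairs classify at >= 0.95 accuracy", {
  cs <- simulate_catalog(200, 1000, zipf_s = 1.5, seed = 7)
  cal <- calibrate_ci_cutoff(cs$tumor_sets, cs$catalog, repeats = 20,
                             seed = 7)
  # held-out pairs simulated with the same design
  set.seed(99)
  correct <- 0L; total <- 0L
  for (i in 1:60) {
    tum <- cs$tumor_sets[[sample(200, 1)]]
    f <- sample(c(0.4, 0.6, 0.8), 1)
    s1 <- sample(tum, round(f * length(tum)))
    s2 <- sample(tum, round(f * length(tum)))
    ci <- clonality_index(intersect(s1, s2), cs$catalog)$ci
    correct <- correct + (classify_recurrence(ci, cal$cutoff) == "ancestral")
    ij <- sample(200, 2)
    ci <- clonality_index(intersect(cs$tumor_sets[[ij[1]]],
                                    cs$tumor_sets[[ij[2]]]), cs$catalog)$ci
    correct <- correct + (classify_recurrence(ci, cal$cutoff) == "de_novo")
    total <- total + 2L
  }
  expect_gte(correct / total, 0.95)
})

test_that("recurrence classification uses >= with ties going ancestral", {
  expect_equal(classify_recurrence(883.2, 36.59), "ancestral")
  expect_equal(classify_recurrence(12, 36.59), "de_novo")
  expect_equal(classify_recurrence(36.59, 36.59), "ancestral")
})

test_that("hepatic segment interval and location follow the worked examples", {
  expect_equal(hepatic_segment_interval(6, 6), 0L)
  expect_equal(classify_location(0), "local")
  expect_equal(hepatic_segment_interval(c(5, 6), c(7, 8)), 1L)
  expect_equal(classify_location(1), "local")
  expect_equal(hepatic_segment_interval(6, 3), 3L)
  expect_equal(classify_location(3), "distant")
  expect_equal(hepatic_segment_interval(1, 8), 4L)  # capped at 4
  expect_error(hepatic_segment_interval(0, 6), "1..8")
  expect_error(hepatic_segment_interval(integer(), 6), "labels")
})

test_that("breakpoint matching respects type, chromosome pair and tolerance", {
  bp <- tibble::tibble(type = "DEL", chrom1 = "1", pos1 = 1000L,
                       chrom2 = "1", pos2 = 5000L)
  expect_equal(shared_breakpoints(bp, bp), 1L)
  off <- dplyr::mutate(bp, pos1 = pos1 + 11L)
  expect_equal(shared_breakpoints(bp, off), 0L)
  near <- dplyr::mutate(bp, pos1 = pos1 + 10L, pos2 = pos2 - 10L)
  expect_equal(shared_breakpoints(bp, near), 1L)
  other_type <- dplyr::mutate(bp, type = "DUP")
  expect_equal(shared_breakpoints(bp, other_type), 0L)
  many <- dplyr::bind_rows(bp, off, near)
  expect_equal(shared_breakpoints(many, many[c(3, 1, 2), ]), 3L)
  expect_equal(shared_breakpoints(bp, bp[0, ]), 0L)
})

test_that("WGD and gene-level CNV classes follow the threshold rules", {
  expect_true(call_wgd(3.3))
  expect_false(call_wgd(2.9))   # strictly greater than
  expect_true(call_wgd(2.91))
  expect_error(call_wgd(-1), "positive")

  expect_equal(classify_gene_cnv(5, 2), "amplification")
  expect_equal(classify_gene_cnv(4, 2), "gain")        # not "more than twice"
  expect_equal(classify_gene_cnv(3, 2), "gain")
  expect_equal(classify_gene_cnv(2, 2), "neutral")
  expect_equal(classify_gene_cnv(1, 2), "loss")
  expect_equal(classify_gene_cnv(0, 2), "deletion")
  expect_error(classify_gene_cnv(-1, 2), ">= 0")
})
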