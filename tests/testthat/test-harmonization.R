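test_that("high-confidence filter applies the exact thresholds", {
  nrm <- dplyr::bind_rows(
    obs_row("1:1:A:T", "N", 0, 50),
    obs_row("1:2:A:T", "N", 0, 50),
    obs_row("1:3:A:T", "N", 1, 99),
    obs_row("1:4:A:T", "N", 0, 9),
    obs_row("1:5:A:T", "N", 0, 50)
  )
  tum <- dplyr::bind_rows(
    obs_row("1:1:A:T", "T", 5, 95),    # VAF .05, alt 5 -> keep (boundary)
    obs_row("1:2:A:T", "T", 2, 98),    # alt < 3 -> drop
    obs_row("1:3:A:T", "T", 20, 80),   # normal VAF exactly 1% -> drop (strict)
    obs_row("1:4:A:T", "T", 20, 80),   # normal depth < 10 -> drop
    obs_row("1:5:A:T", "T", 4, 96),    # VAF .04 < .05 -> drop
    obs_row("1:6:A:T", "T", 20, 80)    # no normal site -> drop + warn
  )
  expect_warning(kept <- filter_high_confidence(tum, nrm), "matched-normal")
  expect_equal(kept$key, "1:1:A:T")
})

test_that("CNV drop removes mutations masked by loss in a non-carrier", {
  seg <- tibble::tibble(sample = "R", chrom = "1", start = 1L, end = 1000L,
                        total_cn = 1L)
  mk <- function(segments, r_alt) {
    toy_case(dplyr::bind_rows(
      obs_row("1:100:A:T", "T", 30, 70),
      obs_row("1:100:A:T", "R", r_alt, 100 - r_alt),
      obs_row("1:100:A:T", "N", 0, 50),
      obs_row("2:5:A:T", "T", 25, 75),
      obs_row("2:5:A:T", "R", 24, 76),
      obs_row("2:5:A:T", "N", 0, 50)
    ), segments = segments)
  }
  # present in T only, recurrent cn = 1 at the locus -> excluded everywhere
  h <- harmonize_case(mk(seg, 0))
  expect_false("1:100:A:T" %in% unlist(h$final_sets))
  expect_true(all(h$status$status[h$status$key == "1:100:A:T"] == "cnv_dropped"))
  # same but recurrent cn = 2 -> retained
  seg2 <- dplyr::mutate(seg, total_cn = 2L)
  h2 <- harmonize_case(mk(seg2, 0))
  expect_true("1:100:A:T" %in% h2$final_sets$T)
  # present in both samples -> retained despite the loss segment
  h3 <- harmonize_case(mk(seg, 30))
  expect_true("1:100:A:T" %in% h3$final_sets$R)
})

test_that("force calling recovers sites at the documented thresholds", {
  mk <- function(r_alt, r_ref) {
    toy_case(dplyr::bind_rows(
      obs_row("1:100:A:T", "T", 30, 70),
      obs_row("1:100:A:T", "R", r_alt, r_ref, called = FALSE),
      obs_row("1:100:A:T", "N", 0, 50)
    ))
  }
  h <- harmonize_case(mk(2, 18))      # depth 20, alt 2 -> recovered
  expect_true("1:100:A:T" %in% h$final_sets$R)
  expect_equal(h$status$status[h$status$sample == "R"], "force_called")
  h <- harmonize_case(mk(3, 6))       # depth 9 -> not recovered
  expect_false("1:100:A:T" %in% h$final_sets$R)
  h <- harmonize_case(mk(1, 199))     # alt 1 -> not recovered
  expect_false("1:100:A:T" %in% h$final_sets$R)
})

test_that("sharing metrics match hand counts", {
  A <- paste0("k", 1:100)
  B <- paste0("k", 76:125)  # |B| = 50, overlap 25
  f <- shared_fraction(A, B)
  expect_equal(f$n_shared, 25L)
  expect_equal(f$f_a, 0.25)
  expect_equal(f$f_b, 0.5)
  expect_equal(f$f_mean, 0.375)
  expect_equal(jaccard_index(A, B), 25 / 125)

  expect_equal(shared_fraction(A, A)$f_mean, 1)
  expect_equal(jaccard_index(A, A), 1)
  expect_equal(shared_fraction(A, paste0("z", 1:10))$f_mean, 0)
  expect_equal(shared_fraction(character(), A)$f_mean, 0)
  expect_equal(jaccard_index(character(), character()), 0)

  part <- shared_partition(A, B)
  expect_setequal(part$shared, paste0("k", 76:100))
  expect_equal(length(part$private_a), 75L)
  expect_equal(length(part$private_b), 25L)
})

test_that("the random-pair null enumerates all unordered pairs", {
  sets40 <- lapply(1:40, function(i) paste0("t", i, "_", 1:5))
  expect_equal(nrow(random_pair_null(sets40)), 780L)
  sets5 <- lapply(1:5, function(i) paste0("t", i, "_", 1:5))
  expect_equal(nrow(random_pair_null(sets5)), 10L)
  dup <- list(c("a", "b"), c("a", "b"), c("x", "y"))
  expect_true(1 %in% random_pair_null(dup)$f_mean)
  expect_error(random_pair_null(list(c("a"))), "two")
})

test_that("force calling only adds and CNV drop only removes; replay matches", {
  p <- small_params()
  hs <- test_catalog_sim()$hotspots
  for (s in 1:6) {
    sim <- simulate_case(if (s %% 2) "ancestral" else "de_novo", p,
                         seed = 200 + s, hotspots = hs)
    h <- harmonize_case(sim$case)
    # monotonicity of the mean shared fraction under force calling
    post <- shared_fraction(h$tumor_sets$primary, h$tumor_sets$recurrent)
    pre <- shared_fraction(h$precall_tumor_sets$primary,
                           h$precall_tumor_sets$recurrent)
    expect_gte(post$f_mean, pre$f_mean)
    # per-sample sets: final = (called after drop) + force-called additions
    for (smp in names(h$final_sets)) {
      pre_set <- h$precall_sets[[smp]]
      if (is.null(pre_set)) pre_set <- character()
      dropped <- h$status$key[h$status$sample == smp &
                                h$status$status == "cnv_dropped"]
      added <- h$status$key[h$status$sample == smp &
                              h$status$status == "force_called"]
      expect_setequal(h$final_sets[[smp]],
                      union(setdiff(pre_set, dropped), added))
    }
    # audit replay reproduces the final sets
    kept0 <- h$audit[h$audit$step == "high_confidence", ]
    rm1 <- h$audit[h$audit$step == "cnv_drop", ]
    add1 <- h$audit[h$audit$step == "force_calling", ]
    for (smp in names(h$final_sets)) {
      replay <- setdiff(kept0$key[kept0$sample == smp],
                        rm1$key[rm1$sample == smp])
      replay <- union(replay, add1$key[add1$sample == smp])
      expect_setequal(replay, h$final_sets[[smp]])
    }
  }
})
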