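cen_tbl <- function(m, samples = paste0("S", seq_len(ncol(m)))) {
  tibble::tibble(cluster = rep(rownames(m), each = ncol(m)),
                 sample = rep(samples, nrow(m)),
                 ccf = as.numeric(t(m)))
}

sz_tbl <- function(m, sizes = rep(100L, nrow(m))) {
  tibble::tibble(cluster = rownames(m), size = sizes)
}

test_that("CCF sums above 1 force a linear chain (pigeonhole rule 1)", {
  m <- rbind(a = 1.0, b = 0.6, c = 0.5)
  tr <- build_subclonal_architecture(cen_tbl(m), sz_tbl(m))
  expect_equal(tr$nodes$parent, c(NA, "a", "b"))
  # and that chain is the unique valid topology
  valid <- enumerate_valid_trees(cen_tbl(m))
  expect_length(valid, 1L)
  expect_equal(unname(valid[[1]]["c"]), "b")
})

test_that("reversed CCFs across samples force siblings (pigeonhole rule 2)", {
  m <- rbind(r = c(1, 1), a = c(0.6, 0.2), b = c(0.2, 0.6))
  tr <- build_subclonal_architecture(cen_tbl(m), sz_tbl(m))
  expect_equal(tr$nodes$parent[tr$nodes$cluster == "a"], "r")
  expect_equal(tr$nodes$parent[tr$nodes$cluster == "b"], "r")
})

test_that("single clusters give a root-only tree", {
  m <- rbind(only = c(1, 1))
  tr <- build_subclonal_architecture(cen_tbl(m), sz_tbl(m))
  expect_equal(nrow(tr$nodes), 1L)
  expect_true(is.na(tr$nodes$parent))
})

test_that("infeasible configurations yield no valid tree", {
  # the second cluster exceeds the first everywhere yet both exceed 0.5,
  # so neither nesting nor siblinghood under either root is possible
  m <- rbind(a = c(0.9, 0.2), b = c(0.2, 0.9), c = c(0.9, 0.9))
  expect_length(enumerate_valid_trees(m |> (\(x) cen_tbl(x))(), eps = 0.01), 0L)
  expect_error(build_subclonal_architecture(cen_tbl(m), sz_tbl(m), eps = 0.01),
               "no valid subclonal architecture")
  big <- matrix(runif(7 * 2), 7, 2, dimnames = list(letters[1:7], NULL))
  expect_error(enumerate_valid_trees(cen_tbl(big)), "6 clusters")
})

test_that("constructed architectures always lie in the brute-force valid set", {
  n_checked <- 0
  for (s in 1:300) {
    if (n_checked >= 200) break
    set.seed(s)
    k <- sample(2:5, 1)
    par <- simulate_clone_tree(k, seed = s)
    pres <- matrix(TRUE, k, 2)
    ccf <- assign_sample_ccfs(par, pres, seed = s + 5000)
    rownames(ccf) <- paste0("c", seq_len(k))
    # keep configurations whose nodes are separated enough to be real
    # clusters
    d <- as.matrix(stats::dist(ccf, method = "maximum")); diag(d) <- Inf
    if (min(d) < 0.08) next
    cen <- cen_tbl(ccf)
    built <- tryCatch(build_subclonal_architecture(cen, sz_tbl(ccf),
                                                   eps = 0.05),
                      error = function(e) NULL)
    valid <- enumerate_valid_trees(cen, eps = 0.05)
    expect_gt(length(valid), 0)
    expect_false(is.null(built))
    bp <- setNames(built$nodes$parent, built$nodes$cluster)[rownames(ccf)]
    hit <- any(vapply(valid, function(v) identical(unname(v[rownames(ccf)]),
                                                   unname(bp)), logical(1)))
    expect_true(hit)
    # exact recovery whenever the generator's tree is the unique valid one
    if (length(valid) == 1) {
      truth <- setNames(ifelse(is.na(par), NA_character_,
                               paste0("c", par)), rownames(ccf))
      expect_identical(unname(bp), unname(truth))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 200)
})

test_that("phylogeny branch lengths are fractions of the primary burden", {
  m <- rbind(a = c(1, 1), b = c(0.5, 0.6))
  tr <- build_subclonal_architecture(cen_tbl(m), sz_tbl(m, c(5000L, 2500L)))
  ph <- build_phylogeny(tr, primary_total = 10000)
  expect_equal(ph$nodes$length[ph$nodes$cluster == "a"], 0.5)
  expect_equal(ph$nodes$length[ph$nodes$cluster == "b"], 0.25)
  # root-to-leaf path length = path mutations / primary total
  expect_equal(sum(ph$nodes$length), (5000 + 2500) / 10000)
  expect_error(build_phylogeny(tr, 0), "positive")
})

test_that("trunk subclones carry more mutations than the trunk clone", {
  p <- small_params()
  hs <- test_catalog_sim()$hotspots
  hit <- 0; tot <- 0
  for (s in 1:8) {
    sim <- simulate_case("ancestral", p, seed = 700 + s, hotspots = hs)
    nd <- sim$truth$nodes
    ts <- sum(nd$size[nd$type == "trunk_subclone"])
    tc <- sum(nd$size[nd$type == "trunk_clone"])
    tot <- tot + 1
    if (ts > tc) hit <- hit + 1
  }
  expect_gte(hit / tot, 0.8)
})

test_that("Newick export is parseable and preserves labels", {
  m <- rbind(a = c(1, 1), b = c(0.5, 0.6), c = c(0.3, 0.1), d = c(0.1, 0.4))
  tr <- build_subclonal_architecture(cen_tbl(m), sz_tbl(m))
  nwk <- tree_to_newick(tr)
  ape_tr <- ape::read.tree(text = nwk)
  labs <- c(ape_tr$tip.label, ape_tr$node.label)
  expect_setequal(labs[labs != ""], rownames(m))
})

test_that("driver labeling times mutations by cluster and CNVs by presence", {
  p <- small_params(mutations_per_tumor = c(400, 900))
  hs <- test_catalog_sim()$hotspots
  found_tp53 <- FALSE
  for (s in c(1, 3, 5)) {
    sim <- simulate_case("ancestral", p, seed = 300 + s, hotspots = hs)
    res <- run_case(sim$case, test_catalog_sim()$catalog, cutoff = 20,
                    seed = s, config = pipeline_config(max_clustered = 800))
    drv <- res$tables$drivers
    tp53 <- drv[drv$gene == "TP53" & drv$alteration == "nonsynonymous_mutation", ]
    if (nrow(tp53) && any(tp53$timing == "trunk_clone")) found_tp53 <- TRUE
    # planted recurrent-only oncogene amplification -> branch timing
    if (!is.null(sim$case$driver_cnv)) {
      amp <- drv[grepl("^cnv_", drv$alteration), ]
      expect_true(all(amp$timing == "branch"))
    }
  }
  expect_true(found_tp53)

  # silent mutations in driver genes never qualify
  case <- toy_case(dplyr::bind_rows(
    obs_row("1:1:A:T", "T", 30, 70), obs_row("1:1:A:T", "R", 30, 70),
    obs_row("1:1:A:T", "N", 0, 50)))
  case$mutations$gene <- "TP53"
  case$mutations$effect <- "silent"
  lab <- label_drivers(case,
                       tibble::tibble(key = "1:1:A:T", cluster = "K1"),
                       tibble::tibble(cluster = "K1",
                                      category = "trunk_clone"))
  expect_equal(nrow(lab), 0L)
})

test_that("driver timing summarizes per-gene fractions across patients", {
  tabs <- list(
    P1 = tibble::tibble(gene = "TP53", alteration = "nonsynonymous_mutation",
                        cluster = "a", category = "trunk_clone",
                        timing = "trunk_clone"),
    P2 = tibble::tibble(gene = "TP53", alteration = "nonsynonymous_mutation",
                        cluster = "a", category = "recurrence_branch",
                        timing = "branch")
  )
  out <- driver_timing_summary(tabs)
  expect_equal(out$fraction[out$timing == "trunk_clone"], 0.5)
  expect_equal(sum(out$n_patients), 2L)
})

test_that("heterogeneity metrics span [0, 1] with the right direction", {
  expect_equal(pairwise_heterogeneity(c("a", "b"), c("a", "b")), 0)
  expect_equal(pairwise_heterogeneity(c("a"), c("b")), 1)
  expect_equal(pairwise_heterogeneity(c("a", "b"), c("b", "c")), 1 - 1 / 3)

  sets <- list(P1 = c("t", "p1"), P2 = c("t", "p2"),
               R1 = c("t", "r", "x1"), R2 = c("t", "r", "x2"))
  roles <- c(P1 = "primary", P2 = "primary",
             R1 = "recurrent", R2 = "recurrent")
  ith <- spatial_temporal_ith(sets, roles)
  expect_equal(nrow(ith$pairs), 6L)
  expect_true(all(ith$pairs$dissimilarity >= 0 & ith$pairs$dissimilarity <= 1))
  expect_gt(ith$temporal_mean, ith$spatial_mean)
  # symmetric by construction: swapping the pair order changes nothing
  expect_equal(pairwise_heterogeneity(sets$P1, sets$R1),
               pairwise_heterogeneity(sets$R1, sets$P1))
  # absent qualifying pairs give NA, not zero
  one <- spatial_temporal_ith(sets[c("P1", "R1")], roles)
  expect_true(is.na(one$spatial_mean))
})

test_that("polyclonal seeding is detected from multi-region truth", {
  p <- small_params(mutations_per_tumor = c(500, 900))
  hs <- test_catalog_sim()$hotspots
  sim <- simulate_case("ancestral", p, seed = 42, hotspots = hs,
                       n_regions = c(2L, 3L), polyclonal = TRUE)
  expect_true(sim$truth$polyclonal)
  roles <- setNames(sim$case$samples$role, sim$case$samples$sample)
  roles <- roles[roles != "normal"]
  det <- detect_polyclonal_seeding(sim$truth$node_ccf |>
                                     dplyr::filter(cluster != "D1"), roles)
  expect_equal(det$verdict, "polyclonal")
  expect_gte(length(det$supporting_clusters), 2L)

  # a single region-confined subclone is monoclonal
  m <- rbind(root = c(1, 1, 1, 1), s1 = c(0.4, 0.01, 0.3, 0.01))
  cc <- cen_tbl(m, samples = names(roles)[1:4])
  det2 <- detect_polyclonal_seeding(cc, roles[1:4])
  expect_equal(det2$verdict, "monoclonal")

  expect_error(detect_polyclonal_seeding(cc, c(A = "primary", B = "recurrent")),
               "not evaluable")
})

test_that("recurrence-ubiquitous clusters are flagged as monophyletic candidates", {
  roles <- c(P1 = "primary", P2 = "primary", R1 = "recurrent",
             R2 = "recurrent", R3 = "recurrent")
  m <- rbind(root = rep(1, 5),
             t1 = c(0.5, 0.4, 0.3, 0.45, 0.5),
             red = c(0.0, 0.0, 0.3, 0.2, 0.25))
  det <- detect_polyclonal_seeding(cen_tbl(m, names(roles)), roles)
  expect_true("red" %in% det$ubiquitous_recurrence_clusters)
})
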