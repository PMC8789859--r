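# Subclonal architecture under pigeonhole constraints, phylogeny with
# mutation-count branch lengths, driver labeling/timing, heterogeneity
# metrics and polyclonal-seeding detection.

centers_matrix <- function(centers) {
  wide <- tidyr::pivot_wider(centers, id_cols = "cluster",
                             names_from = "sample", values_from = "ccf")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cluster
  m
}

new_clone_tree <- function(nodes, centers) {
  structure(list(nodes = nodes, ccf = centers), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", nrow(x$nodes), " node(s): ",
      tree_to_newick(x), "\n", sep = "")
  invisible(x)
}

# check constraints for parent vector par (NA for root) on CCF matrix m:
# (a) parent dominates child in every sample (within eps)
# (b) per node and sample, children's CCF sum <= node CCF + eps
tree_constraints_ok <- function(par, m, eps) {
  k <- nrow(m)
  for (v in seq_len(k)) {
    p <- par[v]
    if (is.na(p)) next
    if (any(m[p, ] < m[v, ] - eps)) return(FALSE)
  }
  for (u in seq_len(k)) {
    ch <- which(!is.na(par) & par == u)
    if (length(ch) && any(colSums(m[ch, , drop = FALSE]) > m[u, ] + eps)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Build a subclonal architecture under pigeonhole constraints
#'
#' Orders clusters by decreasing total CCF (ties: larger size, then
#' cluster id) and greedily attaches each to a feasible parent, where a
#' parent is feasible iff it dominates the child in every sample (within
#' `eps`) and its children's CCFs never sum above its own (within `eps`).
#' Among feasible parents the one with the largest minimum CCF margin is
#' chosen (ties: larger size, then id), which makes construction
#' deterministic. The two pigeonhole rules follow from these constraints:
#' clusters whose CCFs sum above 1 in some sample can only be nested
#' (linear), and clusters with reversed CCFs across samples can only be
#' siblings (branching), since domination fails in both directions.
#'
#' @param centers Tibble `cluster`, `sample`, `ccf`.
#' @param sizes Tibble `cluster`, `size` (mutation counts).
#' @param eps CCF tolerance for the constraints (default 0.05).
#' @return A `clone_tree` (nodes tibble with `cluster`, `parent`, `size`;
#'   per-sample CCFs).
#' @export
build_subclonal_architecture <- function(centers, sizes, eps = 0.05) {
  m <- centers_matrix(centers)
  sz <- setNames(sizes$size, sizes$cluster)[rownames(m)]
  ord <- order(-rowSums(m), -sz, rownames(m))
  m <- m[ord, , drop = FALSE]
  sz <- sz[ord]
  k <- nrow(m)
  # depth-first insertion in decreasing total-CCF order; at each node the
  # feasible parents are tried by decreasing minimum margin (ties: larger
  # size, then id), backtracking when a later node becomes unplaceable
  search <- function(v, par) {
    if (v > k) return(par)
    placed <- seq_len(v - 1L)
    margin <- vapply(placed, function(u) {
      ch <- which(!is.na(par[placed]) & par[placed] == u)
      child_sum <- if (length(ch)) colSums(m[ch, , drop = FALSE]) else 0
      dom <- m[u, ] - m[v, ]
      room <- m[u, ] - child_sum - m[v, ]
      if (any(dom < -eps) || any(room < -eps)) return(-Inf)
      min(c(dom, room))
    }, numeric(1))
    for (u in placed[order(-margin, -sz[placed], rownames(m)[placed])]) {
      if (!is.finite(margin[match(u, placed)])) next
      par[v] <- u
      res <- search(v + 1L, par)
      if (!is.null(res)) return(res)
      par[v] <- NA_integer_
    }
    NULL
  }
  par <- rep(NA_integer_, k)
  if (k > 1) {
    par <- search(2L, par)
    if (is.null(par)) {
      stop("no valid subclonal architecture at eps = ", eps,
           ": domination or sibling-sum constraints cannot all be satisfied")
    }
  }
  nodes <- tibble(
    cluster = rownames(m),
    parent = ifelse(is.na(par), NA_character_, rownames(m)[par]),
    size = as.integer(sz)
  )
  new_clone_tree(nodes, centers)
}

#' Enumerate all valid subclonal architectures (brute force)
#'
#' Exhaustively checks every rooted tree over the clusters (any root, any
#' parent assignment, acyclic) against the domination and sibling-sum
#' constraints; the independent oracle for
#' [build_subclonal_architecture()].
#'
#' @param centers Tibble `cluster`, `sample`, `ccf` for <= 6 clusters.
#' @param eps CCF tolerance.
#' @return List of named character parent vectors (NA for the root).
#' @export
enumerate_valid_trees <- function(centers, eps = 0.05) {
  m <- centers_matrix(centers)
  k <- nrow(m)
  if (k > 6) stop("brute-force enumeration is limited to 6 clusters")
  ids <- rownames(m)
  if (k == 1) {
    return(list(setNames(NA_character_, ids)))
  }
  out <- list()
  for (root in seq_len(k)) {
    others <- setdiff(seq_len(k), root)
    grid <- expand.grid(lapply(others, function(v) setdiff(seq_len(k), v)))
    for (gi in seq_len(nrow(grid))) {
      par <- rep(NA_integer_, k)
      par[others] <- as.integer(grid[gi, ])
      if (!is.na(par[root])) next
      # acyclicity: walking up from every node must reach the root
      ok <- TRUE
      for (v in others) {
        u <- v; steps <- 0
        while (!is.na(par[u])) {
          u <- par[u]; steps <- steps + 1
          if (steps > k) { ok <- FALSE; break }
        }
        if (!ok || u != root) { ok <- FALSE; break }
      }
      if (!ok) next
      if (tree_constraints_ok(par, m, eps)) {
        out[[length(out) + 1L]] <-
          setNames(ifelse(is.na(par), NA_character_, ids[par]), ids)
      }
    }
  }
  out
}

#' Scale a clone tree into a phylogeny with relative branch lengths
#'
#' Branch lengths become the fraction of the primary tumor's mutation
#' count attributed to each cluster, so tree size is comparable across
#' patients (the whole tree is scaled to the primary tumor's burden).
#'
#' @param tree A `clone_tree`.
#' @param primary_total Total mutation count of the primary tumor (> 0).
#' @return The tree with a `length` column added to `nodes`.
#' @export
build_phylogeny <- function(tree, primary_total) {
  if (primary_total <= 0) stop("primary_total must be positive")
  tree$nodes$length <- tree$nodes$size / primary_total
  tree
}

#' Newick serialization of a clone tree
#'
#' Cluster ids are node labels; branch lengths are the `length` column
#' when present, otherwise raw mutation counts.
#' @param tree A `clone_tree`.
#' @return A single Newick string.
#' @export
tree_to_newick <- function(tree) {
  nd <- tree$nodes
  len <- if ("length" %in% names(nd)) nd$length else nd$size
  rec <- function(id) {
    i <- which(nd$cluster == id)
    ch <- nd$cluster[!is.na(nd$parent) & nd$parent == id]
    lab <- paste0(id, ":", format(len[i], trim = TRUE, scientific = FALSE))
    if (!length(ch)) return(lab)
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", lab)
  }
  root <- nd$cluster[is.na(nd$parent)]
  paste0(paste(vapply(root, rec, character(1)), collapse = ","), ";")
}

# nested-list (JSON-ready) view of a clone tree
tree_to_nested <- function(tree) {
  nd <- tree$nodes
  len <- if ("length" %in% names(nd)) nd$length else rep(NA_real_, nrow(nd))
  rec <- function(id) {
    i <- which(nd$cluster == id)
    ch <- nd$cluster[!is.na(nd$parent) & nd$parent == id]
    out <- list(cluster = id, size = nd$size[i], length = len[i])
    if (length(ch)) out$children <- lapply(ch, rec)
    out
  }
  roots <- nd$cluster[is.na(nd$parent)]
  if (length(roots) == 1) rec(roots) else list(forest = lapply(roots, rec))
}

#' Label driver alterations and their evolutionary timing
#'
#' Qualifying alterations are (1) nonsynonymous SNVs/indels and promoter
#' mutations in driver genes, timed by the category of the cluster holding
#' them; (2) gene-level amplifications/deletions of driver genes (from a
#' per-sample `gene`, `total_cn` table), timed by the sample set showing
#' the alteration: all tumor samples -> trunk clone, both tumors but not
#' all samples -> trunk subclone, one tumor only -> branch. Driver
#' mutations whose cluster was filtered out are labelled unplaced with a
#' warning.
#'
#' @param case A [patient_case()] (optionally with a `driver_cnv` table).
#' @param assignments Tibble `key`, `cluster` from [cluster_mutations()].
#' @param categories Tibble `cluster`, `category`.
#' @param driver_list Driver genes (default [driver_genes()]).
#' @return Tibble `gene`, `alteration`, `cluster`, `category`, `timing`
#'   (`trunk_clone` / `trunk_subclone` / `branch` / `unplaced`).
#' @export
label_drivers <- function(case, assignments, categories,
                          driver_list = driver_genes()) {
  timing_of <- function(category) {
    dplyr::case_when(
      category %in% c("trunk_clone", "primary_clone", "recurrence_clone") ~
        "trunk_clone",
      category %in% c("trunk_subclone", "primary_subclone",
                      "recurrence_subclone") ~ "trunk_subclone",
      is.na(category) ~ NA_character_,
      TRUE ~ "branch"
    )
  }
  mut <- case$mutations |>
    filter(.data$gene %in% driver_list,
           .data$effect %in% c("nonsynonymous", "promoter", "splice")) |>
    left_join(assignments, by = "key") |>
    left_join(categories, by = "cluster") |>
    mutate(
      alteration = ifelse(.data$effect == "promoter",
                          "promoter_mutation", "nonsynonymous_mutation"),
      timing = timing_of(.data$category)
    ) |>
    select("gene", "alteration", "cluster", "category", "timing")
  if (any(is.na(mut$timing))) {
    warning(sum(is.na(mut$timing)),
            " driver mutation(s) fall outside retained clusters; labelled unplaced")
    mut$timing[is.na(mut$timing)] <- "unplaced"
  }
  cnv <- NULL
  if (!is.null(case$driver_cnv) && nrow(case$driver_cnv)) {
    roles <- setNames(case$samples$role, case$samples$sample)
    ploidy <- setNames(case$samples$ploidy, case$samples$sample)
    tum <- tumor_samples(case)
    cnv <- case$driver_cnv |>
      filter(.data$gene %in% driver_list) |>
      mutate(class = classify_gene_cnv(.data$total_cn,
                                       ploidy[.data$sample])) |>
      filter(.data$class %in% c("amplification", "deletion")) |>
      group_by(.data$gene, .data$class) |>
      summarise(
        in_primary = any(roles[.data$sample] == "primary"),
        in_recurrent = any(roles[.data$sample] == "recurrent"),
        n_samples = dplyr::n_distinct(.data$sample),
        .groups = "drop"
      ) |>
      mutate(
        timing = dplyr::case_when(
          .data$n_samples == length(tum) ~ "trunk_clone",
          .data$in_primary & .data$in_recurrent ~ "trunk_subclone",
          TRUE ~ "branch"
        ),
        alteration = paste0("cnv_", .data$class),
        cluster = NA_character_, category = NA_character_
      ) |>
      select("gene", "alteration", "cluster", "category", "timing")
  }
  bind_rows(mut, cnv)
}

#' Cross-patient driver timing summary
#'
#' @param driver_tables Named list (by patient) of [label_drivers()]
#'   results, or one tibble with a `patient` column.
#' @return Tibble: per gene and timing class, number and fraction of
#'   patients with the alteration at that timing.
#' @export
driver_timing_summary <- function(driver_tables) {
  tab <- if (is.data.frame(driver_tables)) driver_tables else
    bind_rows(driver_tables, .id = "patient")
  n_pat <- dplyr::n_distinct(tab$patient)
  tab |>
    filter(.data$timing != "unplaced") |>
    distinct(.data$patient, .data$gene, .data$timing) |>
    count(.data$gene, .data$timing, name = "n_patients") |>
    mutate(fraction = .data$n_patients / n_pat)
}

#' Set dissimilarity between two mutation catalogs
#'
#' @param set_a,set_b Key vectors.
#' @return `1 - Jaccard(A, B)`.
#' @export
pairwise_heterogeneity <- function(set_a, set_b) {
  1 - jaccard_index(set_a, set_b)
}

#' Spatial and temporal intra-tumor heterogeneity
#'
#' Spatial heterogeneity is the mean dissimilarity between paired regions
#' within a tumor (primary and recurrent pooled); temporal heterogeneity
#' the mean over all primary-region x recurrent-region pairs.
#'
#' @param sample_sets Named list of per-sample mutation key sets.
#' @param roles Named character vector sample -> role.
#' @return List with `pairs` (tibble sample_a, sample_b, type,
#'   dissimilarity), `spatial_mean`, `temporal_mean` (NA when no
#'   qualifying pairs exist).
#' @export
spatial_temporal_ith <- function(sample_sets, roles) {
  ss <- names(sample_sets)
  rr <- roles[ss]
  pairs <- utils::combn(ss, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    type <- if (rr[[a]] == rr[[b]]) "spatial" else "temporal"
    tibble(sample_a = a, sample_b = b, type = type,
           dissimilarity = pairwise_heterogeneity(sample_sets[[a]],
                                                  sample_sets[[b]]))
  })
  tab <- bind_rows(rows)
  mean_of <- function(type) {
    v <- tab$dissimilarity[tab$type == type]
    if (length(v)) mean(v) else NA_real_
  }
  list(pairs = tab, spatial_mean = mean_of("spatial"),
       temporal_mean = mean_of("temporal"))
}

#' Detect polyclonal seeding of the recurrence
#'
#' With multi-region recurrent sampling, seeding is polyclonal when at
#' least two non-clonal trunk clusters are present subclonally
#' (`presence_thr <= CCF < clonal_thr`) in two or more recurrent regions.
#' Clusters present in every recurrent region but absent from all primary
#' regions are additionally flagged as monophyletic-dissemination
#' candidates.
#'
#' @param centers Tibble `cluster`, `sample`, `ccf` (tumor samples).
#' @param roles Named character vector sample -> role.
#' @param presence_thr,clonal_thr CCF thresholds.
#' @return List with `verdict` (`"polyclonal"` / `"monoclonal"`),
#'   `supporting_clusters`, `ubiquitous_recurrence_clusters`.
#' @export
detect_polyclonal_seeding <- function(centers, roles,
                                      presence_thr = 0.05,
                                      clonal_thr = 0.8) {
  rec <- names(roles)[roles == "recurrent"]
  prim <- names(roles)[roles == "primary"]
  if (length(rec) < 2) {
    stop("polyclonal seeding is not evaluable with a single recurrent region")
  }
  w <- centers |>
    mutate(role = unname(roles[.data$sample])) |>
    group_by(.data$cluster) |>
    summarise(
      trunk = any(.data$ccf[.data$role == "primary"] >= presence_thr) &
        any(.data$ccf[.data$role == "recurrent"] >= presence_thr),
      n_rec_subclonal = sum(.data$role == "recurrent" &
                              .data$ccf >= presence_thr &
                              .data$ccf < clonal_thr),
      n_rec_present = sum(.data$role == "recurrent" &
                            .data$ccf >= presence_thr),
      n_prim_present = sum(.data$role == "primary" &
                             .data$ccf >= presence_thr),
      .groups = "drop"
    )
  supporting <- w$cluster[w$trunk & w$n_rec_subclonal >= 2]
  ubiq <- w$cluster[w$n_rec_present == length(rec) & w$n_prim_present == 0]
  list(
    verdict = if (length(supporting) >= 2) "polyclonal" else "monoclonal",
    supporting_clusters = supporting,
    ubiquitous_recurrence_clusters = ubiq
  )
}
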