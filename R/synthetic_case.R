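# Simulation of whole patient cases (paired and multi-region) with ground
# truth: clone structure, per-sample CCFs, read counts, planted
# copy-number-loss artifacts, sub-threshold shared sites, silent decoy
# clusters, driver events, hotspot layer and signature-driven contexts.

#' Curated driver gene list
#'
#' Recurrently altered genes used for driver labeling and timing (TERT is
#' driven by promoter mutation or amplification; CDKN2A/2B, PTEN, ATM, TSC2
#' act as tumor suppressors; MYC, VEGFA, CCND1, FGF19, ERBB2/3, BCL9 as
#' amplified oncogenes).
#' @return Character vector of gene symbols.
#' @export
driver_genes <- function() {
  c("TP53", "AXIN1", "CTNNB1", "ARID1A", "TERT", "MYC", "VEGFA", "CCND1",
    "FGF19", "CDKN2A", "CDKN2B", "PTEN", "ATM", "TSC2", "IDH1", "IDH2",
    "ERBB2", "ERBB3", "BCL9")
}

# expected VAF given ccf, purity, local cn
expected_vaf <- function(ccf, purity, cn_mut, cn_norm = 2) {
  purity * ccf / (cn_norm * (1 - purity) + purity * cn_mut)
}

# minimal CCF that makes a cluster callable (VAF >= ~0.05) in a sample
calling_floor <- function(purity, cn_mut, cn_norm = 2, vaf_min = 0.055) {
  vaf_min * (cn_norm * (1 - purity) + purity * cn_mut) / purity
}

# Draw mutation attributes (positions, alleles, contexts, effects) for n
# mutations under a 96-category probability vector p96.
gen_mutations <- function(n, p96, effect_probs, indel_frac, gene_pool) {
  if (n <= 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), variant_class = character(),
                  gene = character(), effect = character(),
                  context = character(), key = character()))
  }
  cats <- sbs_categories()
  loc <- random_positions(n)
  is_indel <- runif(n) < indel_frac
  n_snv <- sum(!is_indel)
  ref <- alt <- context <- character(n)
  if (n_snv > 0) {
    idx <- sample.int(96L, n_snv, replace = TRUE, prob = p96)
    r <- cats$ref[idx]; a <- cats$alt[idx]; ctx <- cats$context[idx]
    flip <- runif(n_snv) < 0.5
    r[flip] <- chartr("ACGT", "TGCA", r[flip])
    a[flip] <- chartr("ACGT", "TGCA", a[flip])
    ctx[flip] <- revcomp(ctx[flip])
    ref[!is_indel] <- r; alt[!is_indel] <- a; context[!is_indel] <- ctx
  }
  n_ind <- sum(is_indel)
  if (n_ind > 0) {
    del <- runif(n_ind) < 0.6
    bases <- c("A", "C", "G", "T")
    piece <- vapply(sample.int(3L, n_ind, replace = TRUE), function(k) {
      paste(sample(bases, k, replace = TRUE), collapse = "")
    }, character(1))
    ref[is_indel] <- ifelse(del, piece, "-")
    alt[is_indel] <- ifelse(del, "-", piece)
    context[is_indel] <- ""
  }
  effect <- sample(names(effect_probs), n, replace = TRUE, prob = effect_probs)
  gene <- ifelse(effect == "noncoding", "",
                 sample(gene_pool, n, replace = TRUE))
  tibble(
    chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
    variant_class = ifelse(is_indel, "indel", "SNV"),
    gene = gene, effect = effect, context = context,
    key = paste(loc$chrom, loc$pos, ref, alt, sep = ":")
  )
}

# Clone structure for a paired ancestral case (or multi-region with
# region vectors). samples: tibble with sample, role, purity, cn (round
# ploidy). Returns nodes tibble + ccf matrix (nodes x tumor samples).
draw_ancestral_structure <- function(samples, polyclonal = FALSE,
                                     with_decoy = TRUE) {
  tum <- samples[samples$role != "normal", ]
  prim <- tum$sample[tum$role == "primary"]
  recu <- tum$sample[tum$role == "recurrent"]
  S <- tum$sample
  pur <- setNames(tum$purity, S)
  cnv <- setNames(tum$cn, S)
  floors <- setNames(calling_floor(tum$purity, tum$cn), S)
  # single-sided clusters are only observed where they are called, which
  # biases low-CCF branch centers upward; prefer CCFs comfortably above
  # the caller threshold where the budget allows
  floors_hi <- setNames(pmin(0.45, calling_floor(tum$purity, tum$cn,
                                                 vaf_min = 0.095)), S)
  multi <- length(prim) > 1L || length(recu) > 1L

  for (try_i in 1:120) {
    # late retries fall back to the leanest structure low purity can carry
    lean <- try_i > 40
    sep_min <- if (lean) 0.08 else 0.1
    n_ts <- if (polyclonal) 2L
            else if (lean) 1L else sample(1:2, 1, prob = c(0.45, 0.55))
    n_bp <- if (lean) 0L else sample(0:2, 1, prob = c(0.1, 0.75, 0.15))
    n_br <- if (lean) 1L else sample(1:2, 1, prob = c(0.7, 0.3))
    if (lean && !multi) with_decoy <- FALSE
    ids <- c("C1", paste0("T", seq_len(n_ts)),
             if (with_decoy) "D1",
             if (n_bp) paste0("BP", seq_len(n_bp)),
             paste0("BR", seq_len(n_br)),
             if (multi) paste0("LF", seq_along(S)))
    k <- length(ids)
    ccf <- matrix(0, k, length(S), dimnames = list(ids, S))
    parent <- setNames(rep(NA_character_, k), ids)
    type <- setNames(rep("", k), ids)
    used <- matrix(0, k, length(S), dimnames = list(ids, S))  # child budget used

    ok <- TRUE
    ccf["C1", ] <- 1; type["C1"] <- "trunk_clone"
    t_last <- "C1"
    for (j in seq_len(n_ts)) {
      id <- paste0("T", j)
      parent[id] <- t_last; type[id] <- "trunk_subclone"
      for (s in S) {
        hi <- 0.92 * (ccf[t_last, s] - used[t_last, s])
        hi <- min(hi, if (t_last == "C1") 0.74 else hi)
        lo <- max(0.14, if (t_last == "C1") 0.38 else 0.25 * ccf[t_last, s])
        if (hi <= lo * 1.02) { ok <- FALSE; break }
        ccf[id, s] <- runif(1, lo, hi)
        used[t_last, s] <- used[t_last, s] + ccf[id, s]
      }
      if (!ok) break
      t_last <- id
    }
    if (!ok) next
    # with one primary and one recurrent sample, make the deepest trunk
    # subclone sub-threshold in the primary sample half the time: its
    # members stay truly shared but are only recoverable there by force
    # calling
    if (!multi && n_ts >= 1 && runif(1) < 0.6) {
      s <- prim[[1]]
      old <- ccf[t_last, s]
      new <- runif(1, 0.12, 0.2)
      if (new < old) {
        ccf[t_last, s] <- new
        pa <- parent[t_last]
        used[pa, s] <- used[pa, s] - (old - new)
      }
    }
    if (with_decoy) {
      parent["D1"] <- "C1"; type["D1"] <- "decoy_silent"
      for (s in S) {
        hi <- min(if (multi) 0.18 else 0.3, 0.92 * (1 - used["C1", s]))
        if (hi <= 0.09) { ok <- FALSE; break }
        ccf["D1", s] <- runif(1, 0.08, hi)
        used["C1", s] <- used["C1", s] + ccf["D1", s]
      }
      if (!ok) next
    }
    draw_in <- function(lo_soft, lo_hard, hi) {
      # prefer the bias-safe floor, fall back to the bare calling floor
      if (hi > lo_soft * 1.02) runif(1, lo_soft, hi)
      else if (hi > lo_hard * 1.02) runif(1, lo_hard, hi)
      else NA_real_
    }
    if (n_bp) for (j in seq_len(n_bp)) {
      # commit the branch only if it fits in every primary sample;
      # otherwise skip the node (a leaner primary side is still valid)
      id <- paste0("BP", j)
      vs <- vapply(prim, function(s) {
        hi <- min(0.72, 0.95 * (1 - used["C1", s]))
        draw_in(floors_hi[s], floors[s], hi)
      }, numeric(1))
      if (anyNA(vs)) next
      parent[id] <- "C1"; type[id] <- "primary_branch"
      ccf[id, prim] <- vs
      used["C1", prim] <- used["C1", prim] + vs
    }
    trunk_chain <- c(if (n_ts) paste0("T", rev(seq_len(n_ts))), "C1")
    # the branch only has to be callable in its best-purity recurrent
    # region; elsewhere force calling recovers it at much lower CCF
    best_rec <- recu[which.max(pur[recu])]
    for (j in seq_len(n_br)) {
      id <- paste0("BR", j)
      type[id] <- "recurrence_branch"
      placed <- FALSE
      for (pa in trunk_chain) {
        vs <- vapply(recu, function(s) {
          hi <- min(0.72, 0.92 * (ccf[pa, s] - used[pa, s]))
          if (s == best_rec) draw_in(floors_hi[s], floors[s], hi)
          else draw_in(0.12, 0.07, hi)
        }, numeric(1))
        if (!anyNA(vs)) {
          parent[id] <- pa
          ccf[id, recu] <- vs
          used[pa, recu] <- used[pa, recu] + vs
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    if (multi) for (i in seq_along(S)) {
      id <- paste0("LF", i); s <- S[i]
      type[id] <- "leaf"
      placed <- FALSE
      for (lo_pair in list(c(NA, NA), c(0.12, 0.1))) {
        for (pa in c("C1", rev(trunk_chain))) {
          hi <- min(0.45, 0.92 * (ccf[pa, s] - used[pa, s]))
          v <- if (is.na(lo_pair[1])) draw_in(floors_hi[s], floors[s], hi)
               else draw_in(lo_pair[1], lo_pair[2], hi)
          if (!is.na(v)) {
            parent[id] <- pa
            ccf[id, s] <- v
            used[pa, s] <- used[pa, s] + v
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      # a leaf that cannot reach the calling floor in its only region is
      # invisible to the caller and therefore dropped, as in real
      # low-purity samples
      if (placed &&
          expected_vaf(ccf[id, s], pur[s], cnv[s]) < 0.056) {
        used[parent[id], s] <- used[parent[id], s] - ccf[id, s]
        ccf[id, s] <- 0
        parent[id] <- NA_character_
      }
      if (!placed) { type[id] <- "leaf"; ccf[id, s] <- 0 }
    }
    if (!ok) next

    # every non-decoy, non-dropped cluster must be callable somewhere
    callable <- vapply(ids, function(id) {
      all(ccf[id, ] == 0) ||
        any(expected_vaf(ccf[id, S], pur[S], cnv[S]) >= 0.056)
    }, logical(1))
    if (!all(callable[setdiff(ids, "D1")])) next
    # separation between cluster CCF vectors (dropped, all-zero nodes are
    # absent from every sample and do not count)
    live <- rowSums(ccf) > 0
    d <- as.matrix(stats::dist(ccf[live, , drop = FALSE],
                               method = "maximum"))
    diag(d) <- Inf
    if (min(d) < sep_min) next

    keep <- type != "" & rowSums(ccf) > 0
    return(list(
      nodes = tibble(cluster = ids[keep], parent = unname(parent[keep]),
                     type = unname(type[keep])),
      ccf = ccf[keep, , drop = FALSE]
    ))
  }
  stop("could not draw a feasible ancestral clone structure")
}

# Two disjoint trees plus a shared low-CCF silent background cluster.
draw_denovo_structure <- function(samples) {
  tum <- samples[samples$role != "normal", ]
  S <- tum$sample
  pur <- setNames(tum$purity, S)
  cnv <- setNames(tum$cn, S)
  floors <- setNames(calling_floor(tum$purity, tum$cn), S)
  floors_hi <- setNames(pmin(0.45, calling_floor(tum$purity, tum$cn,
                                                 vaf_min = 0.095)), S)
  side <- setNames(tum$role, S)

  for (try_i in 1:80) {
    ids <- character(); parent <- character(); type <- character()
    ccf <- NULL
    ok <- TRUE
    rows <- list()
    for (tumor in c("primary", "recurrent")) {
      ss <- S[side == tumor]
      pre <- if (tumor == "primary") "P" else "R"
      n_sub <- sample(1:3, 1, prob = c(0.4, 0.45, 0.15))
      root <- paste0(pre, "C1")
      nid <- c(root, paste0(pre, "S", seq_len(n_sub)))
      cc <- matrix(0, length(nid), length(S), dimnames = list(nid, S))
      cc[root, ss] <- 1
      par <- setNames(c(NA_character_, rep(root, n_sub)), nid)
      used <- setNames(rep(0, length(nid)), nid)
      prev <- root
      for (j in seq_len(n_sub)) {
        id <- paste0(pre, "S", j)
        pa <- if (j > 1 && runif(1) < 0.4) prev else root
        par[id] <- pa
        for (s in ss) {
          hi <- min(0.74, 0.92 * (cc[pa, s] - used[pa]))
          lo <- max(floors_hi[s], 0.15)
          if (hi <= lo * 1.02) lo <- max(floors[s], 0.15)
          if (hi <= lo * 1.02) { ok <- FALSE; break }
          cc[id, s] <- runif(1, lo, hi)
        }
        if (!ok) break
        used[pa] <- used[pa] + max(cc[id, ss])
        prev <- id
      }
      if (!ok) break
      rows[[tumor]] <- list(ids = nid, parent = par, cc = cc, used = used,
                            root = root)
    }
    if (!ok) next
    ids <- c(rows$primary$ids, rows$recurrent$ids, "D1")
    parent <- c(rows$primary$parent, rows$recurrent$parent,
                setNames(NA_character_, "D1"))
    type <- setNames(c(
      ifelse(rows$primary$ids == rows$primary$root, "primary_clone", "primary_subclone"),
      ifelse(rows$recurrent$ids == rows$recurrent$root, "recurrence_clone", "recurrence_subclone"),
      "decoy_shared"
    ), ids)
    ccf <- rbind(rows$primary$cc, rows$recurrent$cc,
                 D1 = rep(0, length(S)))
    # background shared silent cluster: callable in one tumor, sub-calling
    # (force-call only) in the other
    called_side <- sample(c("primary", "recurrent"), 1)
    for (s in S) {
      this_side <- side[s]
      root_s <- if (this_side == "primary") "PC1" else "RC1"
      budget <- 0.9 * (1 - rows[[this_side]]$used[root_s])
      if (this_side == called_side) {
        hi <- min(0.45, budget)
        lo <- floors[s]
        if (hi <= lo * 1.02) { ok <- FALSE; break }
        ccf["D1", s] <- runif(1, lo, hi)
      } else {
        hi <- min(0.11, budget)
        ccf["D1", s] <- if (hi <= 0.062) max(0.05, hi) else runif(1, 0.06, hi)
      }
    }
    if (!ok) next
    d <- as.matrix(stats::dist(ccf, method = "maximum"))
    diag(d) <- Inf
    if (min(d) < 0.1) next
    return(list(
      nodes = tibble(cluster = ids, parent = unname(parent),
                     type = unname(type[ids])),
      ccf = ccf
    ))
  }
  stop("could not draw a feasible de novo clone structure")
}

# allocate mutation counts to clusters
split_sizes <- function(total, shares) {
  sz <- floor(total * shares / sum(shares))
  rem <- total - sum(sz)
  if (rem > 0) sz[seq_len(rem)] <- sz[seq_len(rem)] + 1L
  as.integer(sz)
}

#' Simulate one patient case with ground truth
#'
#' Generates a complete paired (optionally multi-region) primary/recurrent
#' case: clone tree with per-sample CCFs, mutations with signature-driven
#' trinucleotide contexts, hotspot mutations shared with the background
#' catalog, planted copy-number-loss artifacts (exercising the CNV-drop
#' rule), sub-threshold read support at truly shared sites (exercising
#' force calling), a silent-only decoy cluster (exercising the silent
#' filter), planted drivers, read counts at the configured depth, hepatic
#' segment labels, breakpoint tables and whole-genome-doubling status.
#'
#' @param pattern `"ancestral"` or `"de_novo"`.
#' @param params Parameter list from [sim_params()].
#' @param seed Seed (required for reproducibility).
#' @param patient Patient id.
#' @param hotspots Hotspot tibble from [simulate_catalog()]; `NULL` disables
#'   the hotspot layer.
#' @param n_regions Integer c(primary, recurrent) region counts; c(1, 1)
#'   gives the standard paired design.
#' @param polyclonal For multi-region ancestral cases, force >= 2 trunk
#'   subclones present subclonally across recurrent regions (polyclonal
#'   seeding truth).
#' @return A list with `case` (a [patient_case()]) and `truth` (pattern,
#'   nodes, CCFs, per-mutation cluster labels, category truth, signature
#'   mixtures, WGD flags, hepatic segment interval, etc.).
#' @export
simulate_case <- function(pattern = c("ancestral", "de_novo"),
                          params = sim_params(), seed = NULL,
                          patient = "P01", hotspots = NULL,
                          n_regions = c(1L, 1L), polyclonal = FALSE) {
  pattern <- match.arg(pattern)
  with_seed(seed, {
    a <- n_regions[[1]]; b <- n_regions[[2]]
    multi <- a > 1L || b > 1L
    prim_ids <- paste0(patient, "_T", seq_len(a))
    rec_ids <- paste0(patient, "_R", seq_len(b))
    norm_id <- paste0(patient, "_N")

    wgd_p <- runif(1) < params$wgd_prob_primary
    wgd_r <- runif(1) < (if (pattern == "ancestral")
      params$wgd_prob_recurrent_ancestral else params$wgd_prob_recurrent_denovo)
    ploidy_p <- if (wgd_p) runif(1, 3.0, 3.45) else runif(1, 1.85, 2.2)
    ploidy_r <- if (wgd_r) runif(1, 3.0, 3.45) else runif(1, 1.85, 2.2)

    samples <- tibble(
      sample = c(prim_ids, rec_ids, norm_id),
      role = c(rep("primary", a), rep("recurrent", b), "normal"),
      region = c(paste0("T", seq_len(a)), paste0("R", seq_len(b)), "N"),
      purity = c(runif(a + b, params$purity_range[1], params$purity_range[2]), NA),
      ploidy = c(rep(ploidy_p, a), rep(ploidy_r, b), NA)
    )
    samples$cn <- ifelse(is.na(samples$ploidy), NA_integer_,
                         as.integer(round(samples$ploidy)))
    tum <- samples[samples$role != "normal", ]
    S <- tum$sample

    # burden
    hyper <- runif(1) < params$hypermutator_prob
    draw_n <- function() {
      r <- params$mutations_per_tumor
      as.integer(round(exp(runif(1, log(r[1]), log(r[2])))))
    }
    if (hyper) {
      hr <- params$hypermutator_burden
      n_p <- as.integer(round(runif(1, hr[1], hr[2])))
      n_r <- as.integer(round(runif(1, hr[1], hr[2])))
    } else {
      n_p <- draw_n()
      n_r <- if (pattern == "ancestral") {
        min(as.integer(round(n_p * runif(1, 1.05, 1.4))),
            max(params$mutations_per_tumor))
      } else draw_n()
    }

    # structure + CCFs (retried within the seeded stream: a rejection
    # sampler over budgets and floors can rarely exhaust one batch)
    struct <- NULL
    for (attempt in 1:8) {
      struct <- tryCatch(
        if (pattern == "ancestral") {
          draw_ancestral_structure(samples, polyclonal = polyclonal)
        } else {
          draw_denovo_structure(samples)
        },
        error = function(e) NULL)
      if (!is.null(struct)) break
    }
    if (is.null(struct)) stop("could not draw a feasible clone structure")
    nodes <- struct$nodes
    ccf <- struct$ccf

    # signature mixtures (trunk carries the planted T>A signature)
    nsig <- ncol(synthetic_signature_matrix())
    pool <- c(1, 4, 5, 12, 16, 24)
    active <- sample(pool, params$n_active_signatures)
    base_w <- setNames(numeric(nsig), paste0("S", seq_len(nsig)))
    raw <- rgamma(length(active), 2)
    base_w[active] <- raw / sum(raw)
    trunk_w <- branch_w <- base_w
    if (hyper) {
      trunk_w <- branch_w <- base_w * 0.25
      trunk_w[params$trunk_signature] <-
        branch_w[params$trunk_signature] <- 0.75
    } else if (pattern == "ancestral") {
      w22 <- runif(1, 0.3, 0.45)
      trunk_w <- base_w * (1 - w22)
      trunk_w[params$trunk_signature] <- w22
    }
    Smat <- synthetic_signature_matrix()
    p96_trunk <- as.numeric(Smat %*% trunk_w)
    p96_branch <- as.numeric(Smat %*% branch_w)

    # cluster sizes
    trunk_ids <- nodes$cluster[nodes$type %in% c("trunk_clone", "trunk_subclone")]
    f_target <- if (pattern == "ancestral") {
      runif(1, params$shared_frac_ancestral[1], params$shared_frac_ancestral[2])
    } else {
      runif(1, params$shared_frac_denovo[1], params$shared_frac_denovo[2])
    }
    hmean2 <- 2 * n_p * n_r / (n_p + n_r)
    sizes <- setNames(integer(nrow(nodes)), nodes$cluster)
    if (pattern == "ancestral") {
      T_shared <- min(as.integer(round(f_target * hmean2)),
                      as.integer(0.9 * min(n_p, n_r)))
      w_root <- runif(1, 0.12, 0.22)
      n_ts <- length(trunk_ids) - 1L
      ts_w <- if (n_ts > 0) {
        u <- rgamma(n_ts, 3); (1 - w_root) * u / sum(u)
      } else numeric()
      sizes[trunk_ids] <- split_sizes(T_shared, c(w_root, ts_w))
      bp <- nodes$cluster[nodes$type == "primary_branch"]
      br <- nodes$cluster[nodes$type == "recurrence_branch"]
      lf <- nodes$cluster[nodes$type == "leaf"]
      lf_budget <- if (length(lf)) 0.12 else 0
      if (length(bp)) {
        sizes[bp] <- split_sizes(as.integer((1 - lf_budget) * (n_p - T_shared)),
                                 rgamma(length(bp), 4))
      }
      sizes[br] <- split_sizes(as.integer((1 - lf_budget) * (n_r - T_shared)),
                               rgamma(length(br), 4))
      if (length(lf)) {
        per_tumor_n <- setNames(ifelse(tum$role == "primary",
                                       n_p - T_shared, n_r - T_shared), S)
        for (i in seq_along(S)) {
          sizes[paste0("LF", i)] <-
            max(8L, as.integer(round(lf_budget * per_tumor_n[S[i]] /
                                       sum(tum$role == tum$role[i]))))
        }
      }
      sizes["D1"] <- max(12L, as.integer(round(0.01 * max(n_p, n_r))))
    } else {
      bg <- min(as.integer(round(f_target * hmean2)),
                as.integer(0.2 * min(n_p, n_r)))
      for (tumor in c("primary", "recurrent")) {
        pre <- if (tumor == "primary") "P" else "R"
        nid <- nodes$cluster[startsWith(nodes$cluster, pre) &
                               nodes$cluster != "D1"]
        tot <- (if (tumor == "primary") n_p else n_r) - bg
        w <- c(runif(1, 0.35, 0.6))
        rest <- rgamma(length(nid) - 1L, 3)
        w <- c(w, (1 - w) * rest / sum(rest))
        sizes[nid] <- split_sizes(tot, w)
      }
      sizes["D1"] <- max(10L, bg)
    }
    sizes <- pmax(sizes, 6L)

    # mutation attributes per cluster
    gene_pool <- paste0("G", sprintf("%04d", 1:3000))
    mut_list <- list()
    for (i in seq_len(nrow(nodes))) {
      id <- nodes$cluster[i]
      is_trunk <- nodes$type[i] %in%
        c("trunk_clone", "trunk_subclone", "decoy_silent")
      p96 <- if (is_trunk) p96_trunk else p96_branch
      mm <- gen_mutations(sizes[id], p96, params$effect_probs,
                          params$indel_frac, gene_pool)
      if (nodes$type[i] %in% c("decoy_silent", "decoy_shared")) {
        mm$effect <- "silent"
        mm$gene <- sample(gene_pool, nrow(mm), replace = TRUE)
      }
      mm$cluster <- id
      mm$kind <- "regular"
      mut_list[[id]] <- mm
    }
    muts <- bind_rows(mut_list)

    # planted drivers (mutation-level)
    plant_driver <- function(muts, cluster_id, gene, effect = "nonsynonymous") {
      idx <- which(muts$cluster == cluster_id & muts$variant_class == "SNV")
      if (!length(idx)) return(muts)
      i <- idx[[1]]
      muts$gene[i] <- gene
      muts$effect[i] <- effect
      muts$kind[i] <- "driver"
      muts
    }
    drv <- list()
    add_drv <- function(cluster_id, gene, effect = "nonsynonymous") {
      drv[[length(drv) + 1L]] <<- tibble(gene = gene, cluster = cluster_id,
                                         effect = effect)
      muts <<- plant_driver(muts, cluster_id, gene, effect)
    }
    if (pattern == "ancestral") {
      add_drv("C1", "TP53")
      if (runif(1) < 0.6) add_drv("C1", "AXIN1")
      ts1 <- trunk_ids[min(2L, length(trunk_ids))]
      if (runif(1) < 0.7) add_drv(ts1, "CTNNB1")
      if (runif(1) < 0.5) add_drv(ts1, "TERT", effect = "promoter")
      br1 <- nodes$cluster[nodes$type == "recurrence_branch"][1]
      if (runif(1) < 0.5) add_drv(br1, "ARID1A")
    } else {
      add_drv("PC1", sample(c("TP53", "AXIN1"), 1))
      add_drv("RC1", sample(c("CTNNB1", "ARID1A", "BCL9"), 1))
      if (runif(1) < 0.5) add_drv("PS1", "TERT", effect = "promoter")
    }
    truth_drivers <- bind_rows(drv)

    # hotspot layer: clonal, assigned to the root cluster(s); in de novo
    # cases each tumor draws inclusions independently, so a hotspot shared
    # by chance becomes clonal in both tumors (kind "hotspot_shared")
    hotspot_row <- function(hs, cluster, kind) {
      tibble(chrom = hs$chrom, pos = hs$pos, ref = hs$ref, alt = hs$alt,
             variant_class = "SNV", gene = hs$gene, effect = hs$effect,
             context = hs$context, key = hs$key, cluster = cluster,
             kind = kind)
    }
    if (!is.null(hotspots)) {
      if (pattern == "ancestral") {
        sel <- runif(nrow(hotspots)) < hotspots$incl_prob
        if (any(sel)) {
          muts <- bind_rows(muts, hotspot_row(hotspots[sel, ], "C1", "hotspot"))
        }
      } else {
        sel_p <- runif(nrow(hotspots)) < hotspots$incl_prob
        sel_r <- runif(nrow(hotspots)) < hotspots$incl_prob
        both <- sel_p & sel_r
        if (any(both)) {
          muts <- bind_rows(muts, hotspot_row(hotspots[both, ],
                                              "PC1@BOTH", "hotspot_shared"))
        }
        if (any(sel_p & !both)) {
          muts <- bind_rows(muts, hotspot_row(hotspots[sel_p & !both, ],
                                              "PC1", "hotspot"))
        }
        if (any(sel_r & !both)) {
          muts <- bind_rows(muts, hotspot_row(hotspots[sel_r & !both, ],
                                              "RC1", "hotspot"))
        }
      }
    }

    # copy-number-loss artifacts: private to one tumor, located where the
    # other tumor carries a planted cn<=1 segment (reserved chr22 windows)
    chr22_mb <- autosome_mb[22]
    win_p <- c((chr22_mb - 25) * 1e6 + 1, (chr22_mb - 13) * 1e6)
    win_r <- c((chr22_mb - 12) * 1e6 + 1, chr22_mb * 1e6)
    seg_rows <- list()
    art_rows <- list()
    mk_art <- function(n_art, window, carrier_root) {
      if (n_art <= 0L) return(NULL)
      pos <- as.integer(floor(runif(n_art, window[1], window[2])))
      al <- random_snv_alleles(n_art)
      tibble(chrom = "22", pos = pos, ref = al$ref, alt = al$alt,
             variant_class = "SNV", gene = "",
             effect = "noncoding", context = flanked_context(al$ref),
             key = paste("22", pos, al$ref, al$alt, sep = ":"),
             cluster = carrier_root, kind = "cnv_artifact")
    }
    root_p <- if (pattern == "ancestral") "C1" else "PC1"
    root_r <- if (pattern == "ancestral") "C1" else "RC1"
    n_art_p <- as.integer(round(params$cnv_artifact_frac * n_p))
    n_art_r <- as.integer(round(params$cnv_artifact_frac * n_r))
    art_p <- mk_art(n_art_p, win_p, paste0(root_p, "@ARTP"))
    art_r <- mk_art(n_art_r, win_r, paste0(root_r, "@ARTR"))
    muts <- bind_rows(muts, art_p, art_r)
    for (s in rec_ids) {
      seg_rows[[length(seg_rows) + 1L]] <- tibble(
        sample = s, chrom = "22", start = as.integer(win_p[1]),
        end = as.integer(win_p[2]), total_cn = 1L)
    }
    for (s in prim_ids) {
      seg_rows[[length(seg_rows) + 1L]] <- tibble(
        sample = s, chrom = "22", start = as.integer(win_r[1]),
        end = as.integer(win_r[2]), total_cn = 1L)
    }
    segments <- bind_rows(seg_rows)

    # drop rare random key collisions
    muts <- muts[!duplicated(muts$key), ]

    # per-mutation per-sample true CCFs
    ccf_of <- function(cluster, s) {
      role_s <- tum$role[match(s, S)]
      base <- sub("@(ARTP|ARTR|BOTH)$", "", cluster)
      out <- ccf[base, s]
      art_p <- grepl("@ARTP$", cluster)
      if (any(art_p)) {
        out[art_p] <- if (role_s == "primary") ccf[base[art_p], s] else 0
      }
      art_r <- grepl("@ARTR$", cluster)
      if (any(art_r)) {
        out[art_r] <- if (role_s == "recurrent") ccf[base[art_r], s] else 0
      }
      out[grepl("@BOTH$", cluster)] <- 1  # chance-shared hotspot, clonal
      out
    }

    # read simulation per tumor sample
    obs_list <- list()
    truth_presence <- list()
    noiseless <- isTRUE(params$noiseless)
    for (si in seq_len(nrow(tum))) {
      s <- tum$sample[si]
      tccf <- ccf_of(muts$cluster, s)
      cn_s <- local_copy_number_vec(
        segments[segments$sample == s, , drop = FALSE],
        muts$chrom, muts$pos, fallback = tum$cn[si])
      rd <- simulate_reads(tccf, tum$purity[si], pmax(cn_s, 1L),
                           if (noiseless) params$noiseless_depth else params$depth_mean,
                           cn_norm = 2, noiseless = noiseless)
      obs_list[[s]] <- tibble(
        key = muts$key, sample = s,
        alt_reads = rd$alt_reads,
        ref_reads = rd$depth - rd$alt_reads,
        depth = rd$depth,
        expected_vaf = rd$expected_vaf,
        true_ccf = tccf
      )
    }
    obs <- bind_rows(obs_list)

    obs$called <- obs$alt_reads >= 3L & obs$depth >= 10L &
      obs$alt_reads / pmax(obs$depth, 1L) >= 0.05

    # truly shared sites with sub-threshold support in one sample
    # (called elsewhere, alt >= 2 here): the force-calling substrate.
    # obs is stacked per sample in muts order, so reshape to matrices.
    n_mut <- nrow(muts)
    called_m <- matrix(obs$called, nrow = n_mut)
    sub_m <- matrix(!obs$called & obs$alt_reads >= 2L & obs$depth >= 10L,
                    nrow = n_mut)
    is_trunk_key <- muts$cluster %in% trunk_ids
    planted_sub <- muts$key[is_trunk_key & rowSums(called_m) > 0 &
                              rowSums(sub_m) > 0]

    # normal sample observations
    nd <- if (noiseless) rep(params$noiseless_depth, nrow(muts)) else
      rpois(nrow(muts), params$depth_mean_normal)
    na_alt <- if (noiseless) rep(0L, nrow(muts)) else
      rbinom(nrow(muts), 1L, 0.005)
    obs_norm <- tibble(key = muts$key, sample = norm_id,
                       alt_reads = na_alt, ref_reads = as.integer(nd) - na_alt,
                       depth = as.integer(nd),
                       expected_vaf = 0, true_ccf = 0, called = FALSE)

    # deterministic truth of the harmonized per-sample sets (exact in
    # noiseless mode; the noiseless-limit target otherwise)
    D <- params$noiseless_depth
    pres <- matrix(FALSE, nrow(muts), length(S), dimnames = list(muts$key, S))
    called_t <- pres
    for (si in seq_len(nrow(tum))) {
      s <- tum$sample[si]
      o <- obs_list[[s]]
      ev <- ifelse(o$true_ccf > 0, o$expected_vaf, 0)
      alt_t <- round(D * ev)
      called_t[, si] <- alt_t >= 3 & alt_t / D >= 0.05
      pres[, si] <- alt_t >= 2
    }
    in_agg <- rowSums(called_t) > 0
    pres <- pres & in_agg
    pres[muts$kind == "cnv_artifact", ] <- FALSE  # removed by CNV drop
    truth_sets <- lapply(seq_along(S), function(si) muts$key[pres[, si]])
    names(truth_sets) <- S
    set_p <- unique(unlist(truth_sets[prim_ids]))
    set_r <- unique(unlist(truth_sets[rec_ids]))
    sh <- length(intersect(set_p, set_r))
    truth_f <- if (length(set_p) && length(set_r)) {
      mean(c(sh / length(set_p), sh / length(set_r)))
    } else 0

    # location / hepatic segments
    local <- runif(1) < (if (pattern == "ancestral")
      params$local_given_ancestral else params$local_given_denovo)
    if (local) {
      hsi <- sample(0:1, 1)
      seg_p <- sample(1:(8 - hsi), 1)
    } else {
      hsi <- sample(2:4, 1)
      seg_p <- sample(1:(8 - hsi), 1)
    }
    seg_r <- seg_p + hsi
    samples$hepatic_segments <- lapply(seq_len(nrow(samples)), function(i) {
      switch(samples$role[i], primary = seg_p, recurrent = seg_r,
             integer(0))
    })

    # breakpoints (SVs and viral integrations)
    gen_bp <- function(s, n, type_pool = c("DEL", "DUP", "INV", "TRA")) {
      if (n <= 0) return(NULL)
      l1 <- random_positions(n); l2 <- random_positions(n)
      tibble(sample = s, type = sample(type_pool, n, TRUE),
             chrom1 = l1$chrom, pos1 = l1$pos,
             chrom2 = l2$chrom, pos2 = l2$pos)
    }
    bp_p <- gen_bp(prim_ids[1], rpois(1, 40))
    bp_r_own <- gen_bp(rec_ids[1], rpois(1, 25))
    bp_shared <- NULL
    if (pattern == "ancestral" && !is.null(bp_p) && nrow(bp_p) > 0) {
      n_sh <- max(1L, as.integer(round(runif(1, 0.2, 0.6) * nrow(bp_p))))
      bp_shared <- bp_p[sample.int(nrow(bp_p), n_sh), ]
      bp_shared$sample <- rec_ids[1]
    }
    hbv <- NULL
    if (runif(1) < 0.55) {
      h <- gen_bp(prim_ids[1], 1L + rpois(1, 1), type_pool = "HBV")
      hbv <- h
      if (pattern == "ancestral") {
        h2 <- h; h2$sample <- rec_ids[1]
        hbv <- bind_rows(hbv, h2)
      } else {
        hbv <- bind_rows(hbv, gen_bp(rec_ids[1], 1L + rpois(1, 1),
                                     type_pool = "HBV"))
      }
    }
    breakpoints <- bind_rows(bp_p, bp_r_own, bp_shared, hbv)

    # planted CNV driver (oncogene amplification in recurrent samples)
    driver_cnv <- NULL
    if (pattern == "ancestral" && runif(1) < 0.5) {
      g <- sample(c("MYC", "VEGFA", "ERBB2", "BCL9"), 1)
      driver_cnv <- bind_rows(
        tibble(sample = rec_ids, gene = g,
               total_cn = as.integer(2 * round(ploidy_r) + 2L)),
        tibble(sample = prim_ids, gene = g,
               total_cn = as.integer(round(ploidy_p)))
      )
    }

    case <- patient_case(
      patient = patient,
      samples = samples[, c("sample", "role", "region", "purity", "ploidy",
                            "hepatic_segments")],
      mutations = muts[, c("key", "chrom", "pos", "ref", "alt",
                           "variant_class", "gene", "effect", "context")],
      observations = bind_rows(
        obs[, c("key", "sample", "alt_reads", "ref_reads", "depth", "called")] |>
          mutate(vaf = ifelse(.data$depth > 0,
                              .data$alt_reads / .data$depth, NA_real_)),
        obs_norm[, c("key", "sample", "alt_reads", "ref_reads", "depth",
                     "called")] |>
          mutate(vaf = ifelse(.data$depth > 0,
                              .data$alt_reads / .data$depth, NA_real_))
      ),
      segments = segments,
      breakpoints = breakpoints,
      recurrence_months = runif(1, 3, 24)
    )
    case$driver_cnv <- driver_cnv

    truth <- list(
      pattern = pattern,
      hypermutator = hyper,
      n_mutations = c(primary = length(set_p), recurrent = length(set_r)),
      nodes = nodes |> mutate(size = unname(sizes[nodes$cluster])),
      ccf = ccf,
      node_ccf = as_tibble(as.data.frame.table(ccf, stringsAsFactors = FALSE)) |>
        rlang::set_names(c("cluster", "sample", "ccf")),
      mutation_clusters = muts[, c("key", "cluster", "kind")],
      signature_mixtures = list(trunk = trunk_w, branch = branch_w),
      shared_fraction = truth_f,
      shared_keys = intersect(set_p, set_r),
      truth_sets = truth_sets,
      planted_subthreshold = planted_sub,
      drivers = truth_drivers,
      wgd = c(primary = wgd_p, recurrent = wgd_r),
      hsi = hsi, location = if (local) "local" else "distant",
      polyclonal = polyclonal && pattern == "ancestral" && multi
    )
    list(case = case, truth = truth)
  })
}

#' Simulate a full cohort with catalog
#'
#' Draws the background catalog once, then patient cases with the
#' configured ancestral/de novo mix; every case shares the catalog's
#' hotspot layer so clonality-index lookups are coherent.
#'
#' @param params From [sim_params()].
#' @param seed Seed.
#' @return List with `cases` (list of `simulate_case()` results),
#'   `catalog`, `tumor_sets`, `hotspots`, `patterns` and `params`.
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1L) {
  cat_sim <- simulate_catalog(
    params$catalog_n_tumors, params$catalog_muts_per_tumor,
    zipf_s = params$zipf_s, seed = sub_seed(seed, 0L),
    hotspot_universe = params$hotspot_universe,
    hotspot_top_incl = params$hotspot_top_incl,
    hotspot_effect_probs = params$hotspot_effect_probs
  )
  n <- params$n_patients
  n_anc <- round(params$ancestral_frac * n)
  patterns <- with_seed(sub_seed(seed, 1L), {
    sample(c(rep("ancestral", n_anc), rep("de_novo", n - n_anc)))
  })
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- simulate_case(
      patterns[i], params = params, seed = sub_seed(seed, 10L + i),
      patient = sprintf("P%02d", i), hotspots = cat_sim$hotspots
    )
  }
  list(cases = cases, catalog = cat_sim$catalog,
       tumor_sets = cat_sim$tumor_sets, hotspots = cat_sim$hotspots,
       patterns = patterns, params = params)
}

#' Write a simulated case to disk in the pipeline's input formats
#'
#' Emits the mutation TSV, segment TSV, breakpoint TSV and a YAML manifest
#' that [read_manifest()] parses back into an equivalent case.
#'
#' @param sim A `simulate_case()` result (or its `case`).
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_case_files <- function(sim, dir) {
  case <- if (!is.null(sim$case)) sim$case else sim
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mut <- case$observations |>
    inner_join(case$mutations, by = "key") |>
    select("chrom", "pos", "ref", "alt", "variant_class", "gene", "effect",
           "context", "sample", "alt_reads", "ref_reads", "called") |>
    arrange(.data$chrom, .data$pos, .data$sample)
  readr::write_tsv(mut, file.path(dir, "mutations.tsv"), progress = FALSE)
  readr::write_tsv(case$segments, file.path(dir, "segments.tsv"),
                   progress = FALSE)
  if (!is.null(case$breakpoints)) {
    readr::write_tsv(case$breakpoints, file.path(dir, "breakpoints.tsv"),
                     progress = FALSE)
  }
  man <- list(
    patient = case$patient,
    recurrence_months = case$recurrence_months,
    mutation_table = "mutations.tsv",
    segments = "segments.tsv",
    breakpoints = if (!is.null(case$breakpoints)) "breakpoints.tsv",
    samples = lapply(seq_len(nrow(case$samples)), function(i) {
      s <- case$samples[i, ]
      list(id = s$sample, role = s$role, region = s$region,
           purity = if (is.na(s$purity)) NULL else s$purity,
           ploidy = if (is.na(s$ploidy)) NULL else s$ploidy,
           hepatic_segments = s$hepatic_segments[[1]])
    })
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path, precision = 12L)
  invisible(path)
}
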