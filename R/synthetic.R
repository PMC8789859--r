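# Synthetic cohort generator: paired (and multi-region) primary/recurrent
# tumor cases with known ground truth, plus the background mutation catalog
# used by the clonality index.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream. A `NULL` seed runs the code unseeded.
#' @param seed Integer seed or `NULL`.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% 2147483646L + 1L)
  force(code)
}

sub_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 1000003 * i) %% 2147483647)
}

# Approximate autosome lengths (Mb); rate computations use a flat 2,800 Mb
# callable-genome constant.
autosome_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
                 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Default simulation parameters
#'
#' The defaults encode the cohort the generator emulates: 40 patients with a
#' 22/40 ancestral fraction, 2-5 mutation clusters per tumor, 3,000-85,000
#' genome-wide mutations per tumor (log-uniform), 54x mean tumor depth and
#' 36x normal depth, shared-mutation fraction targets of 0.25-0.80 for
#' ancestral pairs and 0-0.05 for de novo pairs, a 200-tumor x 1,000-mutation
#' background catalog with Zipf-tailed hotspot frequencies (s = 1.5), a
#' 12.5% per-patient hypermutator probability (T>A-dominant, >9 mutations/Mb)
#' and pattern-specific whole-genome-doubling and local-recurrence rates.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
sim_params <- function(...) {
  p <- list(
    n_patients = 40L,
    ancestral_frac = 22 / 40,
    clusters_per_tumor = c(2L, 5L),
    mutations_per_tumor = c(3000L, 85000L),
    depth_mean = 54,
    depth_mean_normal = 36,
    purity_range = c(0.3, 0.9),
    shared_frac_ancestral = c(0.25, 0.80),
    shared_frac_denovo = c(0.006, 0.05),
    effect_probs = c(nonsynonymous = 0.012, silent = 0.006,
                     noncoding = 0.975, splice = 0.002, promoter = 0.005),
    indel_frac = 0.08,
    catalog_n_tumors = 200L,
    catalog_muts_per_tumor = 1000L,
    zipf_s = 1.5,
    hotspot_universe = 500L,
    hotspot_top_incl = 0.35,
    hotspot_effect_probs = c(nonsynonymous = 0.12, silent = 0.05,
                             noncoding = 0.80, splice = 0, promoter = 0.03),
    hypermutator_prob = 0.125,
    hypermutator_burden = c(26000L, 83437L),
    wgd_prob_primary = 8 / 40,
    wgd_prob_recurrent_ancestral = 12 / 22,
    wgd_prob_recurrent_denovo = 2 / 18,
    local_given_ancestral = 20 / 22,
    local_given_denovo = 8 / 18,
    cnv_artifact_frac = 0.01,
    trunk_signature = 22L,
    n_active_signatures = 3L,
    presence_thr = 0.05,
    clonal_thr = 0.8,
    genome_mb = 2800,
    noiseless = FALSE,
    noiseless_depth = 2000L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$ancestral_frac >= 0, p$ancestral_frac <= 1,
            p$hypermutator_prob >= 0, p$hypermutator_prob <= 1,
            diff(p$mutations_per_tumor) >= 0,
            diff(p$shared_frac_ancestral) >= 0,
            diff(p$shared_frac_denovo) >= 0)
  p
}

#' Simulate a random rooted clone tree
#'
#' Node 1 is the clonal root; every later node attaches uniformly to one of
#' the previously created nodes, giving a random recursive tree.
#'
#' @param k_clusters Number of clusters (nodes), >= 1.
#' @param seed Optional seed.
#' @return Integer parent vector of length `k_clusters` (`NA` for the root).
#' @export
simulate_clone_tree <- function(k_clusters, seed = NULL) {
  if (k_clusters < 1L) stop("k_clusters must be >= 1")
  with_seed(seed, {
    parent <- rep(NA_integer_, k_clusters)
    if (k_clusters > 1L) {
      for (i in 2:k_clusters) parent[i] <- sample.int(i - 1L, 1L)
    }
    parent
  })
}

#' Assign per-sample CCFs to a clone tree by stick-breaking
#'
#' Given a parent vector and a node x sample presence mask, draws cancer
#' cell fractions top-down so that in every sample the children of a node
#' never sum to more than the node's own CCF (the pigeonhole constraint in
#' reverse). The root gets CCF 1 in every sample where its lineage exists.
#'
#' @param parent Parent vector from [simulate_clone_tree()].
#' @param presence Logical matrix (nodes x samples); a present node's
#'   ancestors must be present too.
#' @param seed Optional seed.
#' @param floor_main Minimum CCF required in at least one present sample.
#' @param floor_other Minimum CCF in other present samples.
#' @return Numeric matrix (nodes x samples) of CCFs.
#' @export
assign_sample_ccfs <- function(parent, presence, seed = NULL,
                               floor_main = 0.15, floor_other = 0.08) {
  presence <- as.matrix(presence)
  k <- length(parent)
  stopifnot(nrow(presence) == k)
  for (v in seq_len(k)) {
    pa <- parent[v]
    if (!is.na(pa) && any(presence[v, ] & !presence[pa, ])) {
      stop("present node with absent parent")
    }
  }
  with_seed(seed, {
    ccf <- matrix(0, k, ncol(presence), dimnames = dimnames(presence))
    ccf[1, presence[1, ]] <- 1
    if (k > 1L) {
      for (v in 2:k) {
        pa <- parent[v]
        for (s in seq_len(ncol(presence))) {
          if (!presence[v, s]) next
          sibs <- which(parent == pa & seq_len(k) < v)
          used <- if (length(sibs)) sum(ccf[sibs, s]) else 0
          budget <- ccf[pa, s] - used
          lo <- floor_other
          hi <- 0.92 * budget
          if (hi <= lo) {
            ccf[v, s] <- max(0, 0.9 * budget)
          } else {
            ccf[v, s] <- runif(1, lo, hi)
          }
        }
      }
      # ensure each node clears floor_main somewhere it is present
      for (v in 2:k) {
        pres <- which(presence[v, ])
        if (length(pres) && max(ccf[v, pres]) < floor_main) {
          s <- pres[which.max(ccf[v, pres])]
          sibs <- which(parent == parent[v] & seq_len(k) != v)
          used <- if (length(sibs)) sum(ccf[sibs, s]) else 0
          ccf[v, s] <- min(floor_main, 0.95 * (ccf[parent[v], s] - used))
        }
      }
    }
    ccf
  })
}

#' Simulate read counts for observed cancer cell fractions
#'
#' Sequencing depth is Poisson with the given mean and alt reads are
#' binomial around the expected variant allele fraction
#' `p * ccf / (cn_norm * (1 - p) + p * cn_mut)`. In noiseless mode the depth
#' is fixed and alt counts are the rounded expectation, which gives the
#' infinite-depth oracle used by exactness tests.
#'
#' @param true_ccf Vector of true CCFs in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]` (scalar or vector).
#' @param cn_mut Local tumor copy number (>= 1 wherever `true_ccf > 0`).
#' @param depth_mean Mean sequencing depth.
#' @param seed Optional seed.
#' @param cn_norm Normal copy number (2 for autosomes).
#' @param noiseless Disable Poisson/binomial noise.
#' @return A tibble with `alt_reads`, `ref_reads`, `depth`, `expected_vaf`.
#' @export
simulate_reads <- function(true_ccf, purity, cn_mut, depth_mean, seed = NULL,
                           cn_norm = 2, noiseless = FALSE) {
  n <- length(true_ccf)
  purity <- rep_len(purity, n)
  cn_mut <- rep_len(cn_mut, n)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(cn_mut == 0 & true_ccf > 0)) {
    stop("cn_mut = 0 is incompatible with a positive CCF")
  }
  ev <- purity * true_ccf / (cn_norm * (1 - purity) + purity * cn_mut)
  with_seed(seed, {
    if (noiseless) {
      depth <- rep_len(as.integer(depth_mean), n)
      alt <- as.integer(round(depth * ev))
    } else {
      depth <- rpois(n, depth_mean)
      alt <- rbinom(n, depth, pmin(ev, 1))
    }
    tibble(alt_reads = alt, ref_reads = depth - alt, depth = depth,
           expected_vaf = ev)
  })
}

# Random genomic positions over the 22 modeled autosomes. chr22 keeps a
# reserved tail window for planted copy-number-loss artifacts so that the
# artifact windows never swallow ordinary mutations.
random_positions <- function(n) {
  usable <- autosome_mb
  usable[22] <- usable[22] - 25
  chrom_i <- sample.int(22L, n, replace = TRUE, prob = usable)
  pos <- floor(runif(n, 1, usable[chrom_i] * 1e6)) + 1L
  tibble(chrom = as.character(chrom_i), pos = as.integer(pos))
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ri <- sample.int(4L, n, replace = TRUE)
  ai <- (ri - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  list(ref = bases[ri], alt = bases[ai])
}

#' Simulate a background cohort mutation catalog
#'
#' Per-tumor mutation sets combine a shared hotspot layer — hotspot key `k`
#' enters a tumor independently with probability proportional to
#' `k^-zipf_s`, giving the long-tailed rank-frequency curve of recurrent
#' sites — with tumor-private keys filling each set to `muts_per_tumor`.
#' Returns both the catalog (occurrence counts) and the per-tumor key sets
#' needed as controls by [calibrate_ci_cutoff()].
#'
#' @param n_tumors Number of tumors.
#' @param muts_per_tumor Distinct mutations per tumor.
#' @param zipf_s Zipf exponent of the hotspot rank-frequency curve.
#' @param seed Optional seed.
#' @param hotspot_universe Number of hotspot keys.
#' @param hotspot_top_incl Per-tumor inclusion probability of the top
#'   hotspot.
#' @param hotspot_effect_probs Effect class probabilities for hotspot keys.
#' @return A list with `catalog` (a [cohort_catalog()]), `tumor_sets`
#'   (list of key vectors) and `hotspots` (tibble: key, rank, incl_prob,
#'   effect, context, ref, alt).
#' @export
simulate_catalog <- function(n_tumors, muts_per_tumor, zipf_s = 1.5,
                             seed = NULL, hotspot_universe = 500L,
                             hotspot_top_incl = 0.35,
                             hotspot_effect_probs = c(nonsynonymous = 0.12,
                                                      silent = 0.05,
                                                      noncoding = 0.80,
                                                      splice = 0,
                                                      promoter = 0.03)) {
  if (n_tumors < 1L) stop("n_tumors must be >= 1")
  with_seed(seed, {
    U <- hotspot_universe
    q <- pmin(1, hotspot_top_incl * seq_len(U)^(-zipf_s))
    loc <- random_positions(U)
    al <- random_snv_alleles(U)
    hotspots <- tibble(
      rank = seq_len(U),
      chrom = loc$chrom, pos = loc$pos, ref = al$ref, alt = al$alt,
      key = paste(loc$chrom, loc$pos, al$ref, al$alt, sep = ":"),
      incl_prob = q,
      effect = sample(names(hotspot_effect_probs), U, replace = TRUE,
                      prob = hotspot_effect_probs),
      gene = paste0("HOT", seq_len(U)),
      context = flanked_context(al$ref)
    )
    tumor_sets <- vector("list", n_tumors)
    for (i in seq_len(n_tumors)) {
      hot <- hotspots$key[runif(U) < q]
      n_priv <- max(0L, muts_per_tumor - length(hot))
      locp <- random_positions(n_priv)
      alp <- random_snv_alleles(n_priv)
      priv <- paste(locp$chrom, locp$pos, alp$ref, alp$alt, sep = ":")
      tumor_sets[[i]] <- unique(c(hot, priv))
    }
    counts <- table(unlist(tumor_sets))
    list(
      catalog = cohort_catalog(counts, n_tumors = n_tumors,
                               n_total = sum(lengths(tumor_sets))),
      tumor_sets = tumor_sets,
      hotspots = hotspots
    )
  })
}

# random trinucleotide contexts around given reference bases
flanked_context <- function(ref) {
  b <- c("A", "C", "G", "T")
  n <- length(ref)
  paste0(sample(b, n, TRUE), ref, sample(b, n, TRUE))
}
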