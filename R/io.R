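#' @importFrom rlang .data .env
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct n rename count across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median rbinom rpois runif setNames optimize quantile sd
NULL

# Canonical variant keys ------------------------------------------------------

#' Normalize a somatic variant to its canonical key
#'
#' Variant records arrive in several indel dialects (anchored "CA>C", dashed
#' "A>-", padded alleles). All of them are reduced to one canonical form by
#' trimming the common suffix and then the common prefix of the ref/alt
#' alleles, advancing the position over the trimmed prefix. Empty alleles are
#' written as `"-"`. Chromosome names are stripped of any `"chr"` prefix;
#' the convention is 1-based coordinates throughout.
#'
#' @param chrom Chromosome name (with or without a "chr" prefix).
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Allele strings; `"-"`, `""` and `NA` all mean "empty".
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `variant_class` (`"SNV"` or `"indel"`).
#' @examples
#' normalize_variant("chr1", 100, "CA", "C")  # same key as ("1", 101, "A", "-")
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  pos <- as.integer(pos)
  clean <- function(a) {
    a <- toupper(as.character(a))
    a[is.na(a) | a == "-" | a == "."] <- ""
    a
  }
  ref <- clean(ref)
  alt <- clean(alt)
  if (any(pos < 1, na.rm = TRUE)) stop("variant position must be >= 1")
  if (any(ref == alt)) stop("ref and alt alleles must differ")

  norm1 <- function(p, r, a) {
    # trim common suffix
    while (nchar(r) > 0 && nchar(a) > 0 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix, advancing pos
    while (nchar(r) > 0 && nchar(a) > 0 && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    c(p = p, ref = if (nchar(r)) r else "-", alt = if (nchar(a)) a else "-")
  }
  out <- purrr::pmap(list(pos, ref, alt), norm1)
  pos2 <- as.integer(purrr::map_chr(out, "p"))
  ref2 <- purrr::map_chr(out, "ref")
  alt2 <- purrr::map_chr(out, "alt")
  vclass <- ifelse(nchar(ref2) == 1L & nchar(alt2) == 1L &
                     ref2 != "-" & alt2 != "-", "SNV", "indel")
  tibble(
    chrom = chrom, pos = pos2, ref = ref2, alt = alt2,
    key = paste(chrom, pos2, ref2, alt2, sep = ":"),
    variant_class = vclass
  )
}

effect_levels <- function() {
  c("nonsynonymous", "silent", "noncoding", "splice", "promoter")
}

# Readers ---------------------------------------------------------------------

mutation_table_cols <- c(
  "chrom", "pos", "ref", "alt", "variant_class", "gene", "effect",
  "context", "sample", "alt_reads", "ref_reads", "called"
)

#' Read a per-patient somatic mutation table
#'
#' The expected format is a MAF-like TSV with one row per (variant, sample)
#' observation and the columns `chrom, pos, ref, alt, variant_class, gene,
#' effect, context, sample, alt_reads, ref_reads, called`. Variant keys are
#' normalized (see [normalize_variant()]); the mitochondrial chromosome is
#' excluded; duplicate (key, sample) rows are an error.
#'
#' @param path Path to the TSV file.
#' @return A list with `mutations` (one row per distinct variant) and
#'   `observations` (one row per variant x sample, with `vaf`).
#' @export
read_mutation_table <- function(path) {
  raw <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(chrom = "c", ref = "c", alt = "c", gene = "c",
                            effect = "c", context = "c", sample = "c",
                            .default = readr::col_guess()))
  missing <- setdiff(mutation_table_cols, names(raw))
  if (length(missing)) {
    stop("mutation table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(raw$alt_reads < 0 | raw$ref_reads < 0)) {
    stop("read counts must be non-negative")
  }
  mutation_table_from_df(raw)
}

#' Build mutation/observation tibbles from an in-memory data frame
#'
#' Same contract as [read_mutation_table()] but starting from a data frame,
#' which is what the synthetic generator emits.
#' @param df A data frame with the mutation-table columns.
#' @return A list with `mutations` and `observations` tibbles.
#' @export
mutation_table_from_df <- function(df) {
  df <- as_tibble(df)
  norm <- normalize_variant(df$chrom, df$pos, df$ref, df$alt)
  df <- df |>
    mutate(
      chrom = norm$chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
      key = norm$key, variant_class = norm$variant_class,
      called = as.logical(.data$called)
    ) |>
    filter(!.data$chrom %in% c("M", "MT"))
  dup <- df |> count(.data$key, .data$sample) |> filter(n > 1L)
  if (nrow(dup)) {
    stop("duplicate (variant, sample) rows, e.g. ", dup$key[[1]],
         " in sample ", dup$sample[[1]])
  }
  mutations <- df |>
    distinct(.data$key, .keep_all = TRUE) |>
    select("key", "chrom", "pos", "ref", "alt", "variant_class",
           "gene", "effect", "context")
  observations <- df |>
    mutate(depth = .data$alt_reads + .data$ref_reads,
           vaf = ifelse(.data$depth > 0, .data$alt_reads / .data$depth, NA_real_)) |>
    select("key", "sample", "alt_reads", "ref_reads", "depth", "vaf", "called")
  list(mutations = mutations, observations = observations)
}

#' Read per-sample copy-number segments
#'
#' SEG-like TSV with columns `sample, chrom, start, end, total_cn` and
#' optionally `major_cn, minor_cn`. Coordinates are 1-based and end-inclusive.
#' Segments of one sample must not overlap within a chromosome.
#'
#' @param path Path to the TSV file.
#' @return A tibble of segments.
#' @export
read_cnv_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample", "chrom", "start", "end", "total_cn")
  missing <- setdiff(needed, names(seg))
  if (length(missing)) {
    stop("segment table is missing column(s): ", paste(missing, collapse = ", "))
  }
  seg <- seg |> mutate(chrom = sub("^chr", "", as.character(.data$chrom)))
  if (any(seg$start > seg$end)) stop("segment start must be <= end")
  if (any(seg$total_cn < 0)) stop("total_cn must be >= 0")
  check <- seg |>
    arrange(.data$sample, .data$chrom, .data$start) |>
    group_by(.data$sample, .data$chrom) |>
    summarise(ok = all(.data$start[-1] > .data$end[-n()]) || n() == 1L,
              .groups = "drop")
  if (!all(check$ok)) stop("overlapping segments within a sample/chromosome")
  seg
}

#' Local total copy number at a position
#'
#' Returns the `total_cn` of the unique segment of one sample covering
#' (`chrom`, `pos`) under the 1-based end-inclusive convention, or `fallback`
#' when the position is unsegmented.
#'
#' @param segments Segment tibble for a single sample.
#' @param chrom,pos Query locus.
#' @param fallback Copy number for unsegmented loci; default 2 (use
#'   `round(ploidy)` when a sample ploidy estimate is available).
#' @return An integer copy number.
#' @export
local_copy_number <- function(segments, chrom, pos, fallback = 2L) {
  chrom <- sub("^chr", "", as.character(chrom))
  hit <- segments$chrom == chrom & segments$start <= pos & segments$end >= pos
  nhit <- sum(hit)
  if (nhit > 1L) stop("overlapping segments cover ", chrom, ":", pos)
  if (nhit == 0L) return(as.integer(fallback))
  as.integer(segments$total_cn[hit])
}

# vectorized helper used by harmonization/CCF: one sample's segments
local_copy_number_vec <- function(segments, chrom, pos, fallback = 2L) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(rep(as.integer(fallback), length(pos)))
  }
  q <- tibble(chrom = sub("^chr", "", as.character(chrom)), pos = pos,
              .row = seq_along(pos))
  j <- q |>
    left_join(segments |> select("chrom", "start", "end", "total_cn"),
              by = "chrom", relationship = "many-to-many") |>
    filter(.data$start <= .data$pos, .data$end >= .data$pos)
  if (anyDuplicated(j$.row)) stop("overlapping segments cover a query position")
  out <- rep(as.integer(fallback), length(pos))
  out[j$.row] <- as.integer(j$total_cn)
  out
}

#' Read a background cohort mutation catalog
#'
#' Builds the occurrence catalog used by the clonality index from a MAF-like
#' TSV: identical normalized keys are counted across the whole file. A
#' `sample` (or `tumor`) column, when present, sets the number of tumors.
#'
#' @param path Path to the TSV file (columns `chrom, pos, ref, alt`, optional
#'   `sample`).
#' @return A `cohort_catalog` object; see [cohort_catalog()].
#' @export
read_cohort_catalog <- function(path) {
  raw <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                            .default = readr::col_guess()))
  needed <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("catalog table is missing column(s): ", paste(missing, collapse = ", "))
  }
  keys <- normalize_variant(raw$chrom, raw$pos, raw$ref, raw$alt)$key
  samp_col <- intersect(c("sample", "tumor"), names(raw))
  n_tumors <- if (length(samp_col)) {
    length(unique(raw[[samp_col[[1]]]]))
  } else {
    NA_integer_
  }
  cohort_catalog(table(keys), n_tumors = n_tumors)
}

#' Construct a cohort mutation catalog
#'
#' @param counts Named integer vector (or `table`) of occurrence counts per
#'   normalized key; all counts >= 1.
#' @param n_tumors Number of tumors contributing to the catalog (optional).
#' @param n_total Total number of mutations in the cohort; defaults to
#'   `sum(counts)`.
#' @return An object of class `cohort_catalog`.
#' @export
cohort_catalog <- function(counts, n_tumors = NA_integer_, n_total = NULL) {
  counts <- setNames(as.integer(counts), names(counts))
  if (any(counts < 1L)) stop("catalog counts must be >= 1")
  n_total <- if (is.null(n_total)) sum(counts) else as.integer(n_total)
  if (n_total < sum(counts)) stop("total mutations smaller than sum of counts")
  if (n_total <= 0L) stop("catalog must contain at least one mutation")
  structure(
    list(counts = counts, n_total = n_total, n_tumors = as.integer(n_tumors)),
    class = "cohort_catalog"
  )
}

#' @export
print.cohort_catalog <- function(x, ...) {
  cat("<cohort_catalog> ", length(x$counts), " distinct keys, ",
      x$n_total, " mutations",
      if (!is.na(x$n_tumors)) paste0(", ", x$n_tumors, " tumors"), "\n", sep = "")
  invisible(x)
}

# Patient cases ---------------------------------------------------------------

#' Assemble a patient case
#'
#' A patient case bundles everything the pipeline needs for one patient:
#' a sample sheet (roles, purity, ploidy, hepatic segments), the mutation and
#' observation tables, per-sample copy-number segments, and optional
#' breakpoint tables (structural variants and viral integrations).
#'
#' @param patient Patient identifier.
#' @param samples Tibble with columns `sample, role, purity, ploidy` and
#'   optionally `region` and `hepatic_segments` (a list column of integer
#'   Couinaud segment numbers 1-8). Roles are `primary`, `recurrent`,
#'   `normal`; exactly one normal is required.
#' @param mutations,observations Tables as returned by
#'   [read_mutation_table()].
#' @param segments Copy-number segments for the tumor samples (may be empty).
#' @param breakpoints Optional tibble with columns
#'   `sample, type, chrom1, pos1, chrom2, pos2` (`type` distinguishes e.g.
#'   SV classes and viral integration).
#' @param recurrence_months Time from resection to recurrence, in months.
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(patient, samples, mutations, observations,
                         segments = NULL, breakpoints = NULL,
                         recurrence_months = NA_real_) {
  samples <- as_tibble(samples)
  if (!"region" %in% names(samples)) samples$region <- samples$sample
  if (!"hepatic_segments" %in% names(samples)) {
    samples$hepatic_segments <- vector("list", nrow(samples))
  }
  roles <- samples$role
  if (sum(roles == "normal") != 1L) {
    stop("a patient case requires exactly one normal sample")
  }
  if (!any(roles == "primary") || !any(roles == "recurrent")) {
    stop("a patient case requires at least one primary and one recurrent tumor sample")
  }
  tum <- samples[roles != "normal", ]
  if (any(!is.finite(tum$purity)) || any(tum$purity <= 0 | tum$purity > 1)) {
    stop("every tumor sample needs purity in (0, 1]")
  }
  if (any(!is.finite(tum$ploidy)) || any(tum$ploidy <= 0)) {
    stop("every tumor sample needs a positive ploidy")
  }
  bad <- setdiff(unique(observations$sample), samples$sample)
  if (length(bad)) {
    stop("observations reference undeclared sample(s): ",
         paste(bad, collapse = ", "))
  }
  segs <- unlist(tum$hepatic_segments)
  if (length(segs) && any(segs < 1L | segs > 8L)) {
    stop("hepatic segments must lie in 1..8")
  }
  structure(
    list(
      patient = patient, samples = samples,
      mutations = as_tibble(mutations), observations = as_tibble(observations),
      segments = if (is.null(segments)) {
        tibble(sample = character(), chrom = character(), start = integer(),
               end = integer(), total_cn = integer())
      } else as_tibble(segments),
      breakpoints = if (is.null(breakpoints)) NULL else as_tibble(breakpoints),
      recurrence_months = recurrence_months
    ),
    class = "patient_case"
  )
}

#' @export
print.patient_case <- function(x, ...) {
  cat("<patient_case> ", x$patient, ": ",
      sum(x$samples$role == "primary"), " primary / ",
      sum(x$samples$role == "recurrent"), " recurrent tumor sample(s), ",
      nrow(x$mutations), " variants\n", sep = "")
  invisible(x)
}

tumor_samples <- function(case) {
  case$samples$sample[case$samples$role != "normal"]
}

normal_sample <- function(case) {
  case$samples$sample[case$samples$role == "normal"]
}

sample_segments <- function(case, sample_id) {
  case$segments[case$segments$sample == sample_id, , drop = FALSE]
}

#' Read a case manifest
#'
#' The manifest is a JSON or YAML document naming the patient's files and
#' per-sample metadata:
#' \preformatted{
#' patient: P01
#' recurrence_months: 11
#' mutation_table: P01_mutations.tsv
#' segments: P01_segments.tsv        # optional
#' breakpoints: P01_breakpoints.tsv  # optional
#' samples:
#'   - {id: P01_T, role: primary,   purity: 0.7, ploidy: 2.1, hepatic_segments: [6]}
#'   - {id: P01_R, role: recurrent, purity: 0.6, ploidy: 3.2, hepatic_segments: [7]}
#'   - {id: P01_N, role: normal}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest (`.json`, `.yaml` or `.yml`).
#' @return A [patient_case()] object.
#' @export
read_manifest <- function(path) {
  man <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    if (!file.exists(full)) stop("manifest references missing file: ", p)
    full
  }
  mt <- resolve(man$mutation_table)
  if (is.null(mt)) stop("manifest must name a mutation_table")
  tabs <- read_mutation_table(mt)
  segments <- if (!is.null(man$segments)) read_cnv_segments(resolve(man$segments))
  breakpoints <- if (!is.null(man$breakpoints)) {
    readr::read_tsv(resolve(man$breakpoints), show_col_types = FALSE,
                    progress = FALSE)
  }
  samples <- purrr::map_dfr(man$samples, function(s) {
    tibble(
      sample = s$id,
      role = s$role,
      region = s$region %||% s$id,
      purity = as.numeric(s$purity %||% NA_real_),
      ploidy = as.numeric(s$ploidy %||% NA_real_),
      hepatic_segments = list(as.integer(unlist(s$hepatic_segments)))
    )
  })
  patient_case(
    patient = man$patient, samples = samples,
    mutations = tabs$mutations, observations = tabs$observations,
    segments = segments, breakpoints = breakpoints,
    recurrence_months = as.numeric(man$recurrence_months %||% NA_real_)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Report writing --------------------------------------------------------------

#' Write a case result to disk
#'
#' Emits a JSON summary (`summary.json`), each result table as TSV, and the
#' clone tree both as nested JSON (`tree.json`) and Newick (`tree.nwk`) with
#' cluster ids as labels and member mutation counts as branch lengths.
#'
#' @param result A `case_result` from [run_case()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_case_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  summ <- result$summary
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  for (nm in names(result$tables)) {
    tab <- result$tables[[nm]]
    if (!is.data.frame(tab)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  for (i in seq_along(result$trees)) {
    tree <- result$trees[[i]]
    stem <- if (length(result$trees) == 1L) "tree" else paste0("tree_", names(result$trees)[i])
    p <- file.path(dir, paste0(stem, ".json"))
    jsonlite::write_json(tree_to_nested(tree), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    p <- file.path(dir, paste0(stem, ".nwk"))
    writeLines(tree_to_newick(tree), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a written case report
#'
#' Counterpart of [write_case_report()]; used for round-trip checks and to
#' resume downstream stages from intermediates.
#' @param dir Directory written by [write_case_report()].
#' @return A list with `summary`, `tables` and `trees` (nested lists).
#' @export
read_case_report <- function(dir) {
  summ <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  tsvs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tables <- lapply(tsvs, readr::read_tsv, show_col_types = FALSE, progress = FALSE)
  names(tables) <- sub("\\.tsv$", "", basename(tsvs))
  nwks <- list.files(dir, pattern = "\\.nwk$", full.names = TRUE)
  trees <- lapply(nwks, function(p) ape::read.tree(p))
  names(trees) <- sub("\\.nwk$", "", basename(nwks))
  list(summary = summ, tables = tables, trees = trees)
}
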