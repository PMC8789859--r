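# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.clonality_result <- function(x, ...) {
  tibble(key = names(x$p), p = unname(x$p),
         contribution = -2 * log10(unname(x$p)))
}

#' @export
glance.clonality_result <- function(x, ...) {
  tibble(ci = x$ci, n_shared = x$n_shared)
}

#' @export
tidy.ci_calibration <- function(x, ...) {
  tibble(repeat_id = seq_along(x$cutoffs), cutoff = x$cutoffs)
}

#' @export
glance.ci_calibration <- function(x, ...) {
  tibble(cutoff = x$cutoff, accuracy = x$accuracy, repeats = x$repeats,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @export
tidy.ccf_cluster_fit <- function(x, ...) {
  x$centers |> left_join(x$sizes, by = "cluster")
}

#' @export
glance.ccf_cluster_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik,
         bic = x$bic$bic[x$bic$k == x$k][1],
         n_mutations = nrow(x$assignments))
}

#' @export
tidy.clone_tree <- function(x, ...) x$nodes

#' @export
tidy.harmonized_case <- function(x, ...) x$status

#' @export
glance.harmonized_case <- function(x, ...) {
  sf <- shared_fraction(x$tumor_sets$primary, x$tumor_sets$recurrent)
  tibble(patient = x$patient,
         n_primary = length(x$tumor_sets$primary),
         n_recurrent = length(x$tumor_sets$recurrent),
         n_shared = sf$n_shared, f_mean = sf$f_mean)
}

#' @export
tidy.case_result <- function(x, ...) x$tables$sharing

#' @export
glance.case_result <- function(x, ...) {
  s <- x$summary
  tibble(patient = s$patient, pattern = s$pattern, ci = s$ci,
         cutoff = s$cutoff, f_mean = s$f_mean, jaccard = s$jaccard,
         location = s$location, n_clusters = s$n_clusters)
}

#' @export
tidy.cohort_result <- function(x, ...) x$patients
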