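# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_segment
#'   geom_hline geom_text labs theme_minimal facet_wrap scale_fill_manual
#'   autoplot
NULL

#' Shared-fraction and clonality-index overview of a cohort
#'
#' One point per patient: mean shared-mutation fraction against clonality
#' index (log10 scale), colored by the called pattern, with the cutoff as
#' a dashed line.
#' @param cohort A `cohort_result`.
#' @return A ggplot.
#' @export
plot_relatedness <- function(cohort) {
  d <- cohort$patients
  ggplot(d, aes(x = .data$f_mean, y = .data$ci + 1, color = .data$pattern)) +
    geom_point(size = 2) +
    geom_hline(yintercept = cohort$summary$cutoff + 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    labs(x = "mean shared-mutation fraction", y = "clonality index + 1",
         color = "pattern",
         title = "Clonal relatedness of primary/recurrent pairs") +
    theme_minimal()
}

#' Six-class substitution spectrum barplot
#' @param spec A `mutation_spectrum`.
#' @param object,x,... For the autoplot method.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spec) {
  d <- tibble(class = factor(names(spec$counts6), levels = sbs_classes()),
              count = as.numeric(spec$counts6))
  ggplot(d, aes(x = .data$class, y = .data$count, fill = .data$class)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "mutations", title = "Substitution spectrum") +
    theme_minimal()
}

#' @rdname plot_spectrum
#' @export
autoplot.mutation_spectrum <- function(object, ...) plot_spectrum(object)

#' Clone tree sketch
#'
#' Simple segment layout of a clone tree: depth on x (cumulative branch
#' length), one leaf slot per node on y, labels at nodes.
#' @param tree A `clone_tree`.
#' @param object,x,... For the autoplot method.
#' @return A ggplot.
#' @export
plot_clone_tree <- function(tree) {
  nd <- tree$nodes
  len <- if ("length" %in% names(nd)) nd$length else nd$size
  depth <- setNames(rep(0, nrow(nd)), nd$cluster)
  ord <- nd$cluster
  for (i in seq_along(ord)) {
    p <- nd$parent[i]
    depth[nd$cluster[i]] <- len[i] + if (is.na(p)) 0 else depth[p]
  }
  ypos <- setNames(seq_len(nrow(nd)), nd$cluster)
  d <- tibble(
    cluster = nd$cluster,
    x0 = depth[nd$cluster] - len,
    x1 = depth[nd$cluster],
    y = ypos[nd$cluster],
    yp = ifelse(is.na(nd$parent), ypos[nd$cluster], ypos[nd$parent])
  )
  ggplot(d) +
    geom_segment(aes(x = .data$x0, xend = .data$x0, y = .data$yp,
                     yend = .data$y), color = "grey60") +
    geom_segment(aes(x = .data$x0, xend = .data$x1, y = .data$y,
                     yend = .data$y), linewidth = 1) +
    geom_text(aes(x = .data$x1, y = .data$y, label = .data$cluster),
              hjust = -0.2, size = 3) +
    labs(x = "relative mutation load", y = NULL,
         title = "Subclonal architecture") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname plot_clone_tree
#' @export
autoplot.clone_tree <- function(object, ...) plot_clone_tree(object)

#' Per-category signature exposures
#' @param exposures Tibble from [category_exposures()] (optionally with a
#'   `patient` column; faceted if so).
#' @return A ggplot.
#' @export
plot_exposures <- function(exposures) {
  d <- exposures |> filter(.data$weight > 0)
  p <- ggplot(d, aes(x = .data$category, y = .data$weight,
                     fill = .data$signature)) +
    geom_col() +
    labs(x = NULL, y = "exposure", fill = "signature",
         title = "Signature exposures by evolutionary stage") +
    theme_minimal()
  if ("patient" %in% names(d)) p <- p + facet_wrap(~patient)
  p
}
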