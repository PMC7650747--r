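#' Tidy an ANI matrix into a long pair table
#'
#' @param x An `ani_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `id_a`, `id_b`, `ani` (one row per unordered
#'   pair incl. the diagonal).
#' @export
tidy.ani_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(id_a = rownames(m)[idx[, 1]], id_b = colnames(m)[idx[, 2]],
                 ani = m[idx])
}

#' Tidy a coverage profile into a per-base tibble
#'
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return Tibble with columns `position` (0-based), `depth`, `starts_fwd`,
#'   `starts_rev`.
#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble::tibble(position = seq_len(x$genome_length) - 1L, depth = x$depth,
                 starts_fwd = x$starts_fwd, starts_rev = x$starts_rev)
}

#' Summary statistics of a coverage profile
#'
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return One-row tibble: read counts, mapped fraction, depth summary.
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble::tibble(genome_length = x$genome_length,
                 n_reads_total = x$n_reads_total,
                 n_reads_mapped = x$n_reads_mapped,
                 mapped_fraction = x$n_reads_mapped / x$n_reads_total,
                 mean_depth = mean(x$depth), median_depth = stats::median(x$depth))
}

#' Tidy a termini call into a one-row tibble
#'
#' @param x A `termini_call`.
#' @param ... Unused.
#' @return One-row tibble with class, interval/pac fields and evidence.
#' @export
tidy.termini_call <- function(x, ...) {
  tibble::tibble(
    termini_class = x$klass,
    dtr_start = if (is.null(x$dtr_interval)) NA_integer_ else x$dtr_interval[["start"]],
    dtr_end = if (is.null(x$dtr_interval)) NA_integer_ else x$dtr_interval[["end"]],
    pac_position = if (is.null(x$pac_position)) NA_integer_ else x$pac_position,
    coverage_ratio = unname(x$evidence["coverage_ratio"]),
    start_peak_score = unname(x$evidence["start_peak_score"])
  )
}

#' Tidy a dendrogram into a merge table
#'
#' @param x A `phage_dendrogram`.
#' @param ... Unused.
#' @return Tibble with columns `merge_step`, `left`, `right` (hclust
#'   conventions: negative = leaf index) and `height`.
#' @export
tidy.phage_dendrogram <- function(x, ...) {
  tibble::tibble(merge_step = seq_along(x$height), left = x$merge[, 1],
                 right = x$merge[, 2], height = x$height)
}

#' One-row summary of a congruence result
#'
#' @param x A `congruence_result`.
#' @param ... Unused.
#' @return One-row tibble with the adjusted Rand index and partition sizes.
#' @export
glance.congruence_result <- function(x, ...) {
  tibble::tibble(adjusted_rand = x$adjusted_rand, n_genomes = x$n_genomes,
                 partition_a_k = x$partition_a_k, partition_b_k = x$partition_b_k)
}

#' One-row summary of a pipeline report
#'
#' @param x A `phage_report`.
#' @param ... Unused.
#' @return One-row tibble: genome count, termini accuracy against the
#'   planted models, mean mapped fraction and the three adjusted Rand
#'   indices.
#' @export
glance.phage_report <- function(x, ...) {
  truth_class <- ifelse(x$termini$true_model == "HEADFUL_PAC", "HEADFUL_PAC",
                        ifelse(x$termini$true_model == "DTR", "DTR",
                               "UNDETERMINED"))
  called <- ifelse(x$termini$termini_class %in% c("DTR_LONG", "DTR_SHORT"),
                   "DTR", x$termini$termini_class)
  ari <- stats::setNames(x$congruence$adjusted_rand, x$congruence$comparison)
  tibble::tibble(
    n_genomes = nrow(x$summary),
    termini_accuracy = mean(called == truth_class),
    mean_mapped_fraction = x$mapped_fraction,
    ari_ani_vs_truth = unname(ari["ani_vs_truth"]),
    ari_domain_vs_truth = unname(ari["domain_vs_truth"]),
    ari_ani_vs_domain = unname(ari["ani_vs_domain"])
  )
}

#' Heatmap of an ANI matrix
#'
#' @param object An `ani_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ani_matrix <- function(object, ...) {
  m <- unclass(object)
  long <- tidyr::expand_grid(id_a = rownames(m), id_b = colnames(m))
  long$ani <- m[cbind(long$id_a, long$id_b)]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                     fill = .data$ani)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "ANI (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Depth and read-start plot of a coverage profile
#'
#' @param object A `coverage_profile`.
#' @param ... Unused.
#' @return A ggplot object with a depth track and strand-specific
#'   read-start tracks.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_profile <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("depth", "starts_fwd", "starts_rev"),
                              names_to = "track", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Simple dendrogram plot
#'
#' @param object A `phage_dendrogram`.
#' @param ... Unused.
#' @return A ggplot object drawing the merge tree with leaf labels.
#' @exportS3Method ggplot2::autoplot
autoplot.phage_dendrogram <- function(object, ...) {
  n <- length(object$labels)
  leaf_x <- stats::setNames(seq_len(n), object$order)
  xpos <- function(i) if (i < 0) unname(leaf_x[as.character(-i)]) else node_x[i]
  ypos <- function(i) if (i < 0) 0 else object$height[i]
  node_x <- numeric(nrow(object$merge))
  segs <- list()
  for (s in seq_len(nrow(object$merge))) {
    l <- object$merge[s, 1]; r <- object$merge[s, 2]
    xl <- xpos(l); xr <- xpos(r); h <- object$height[s]
    node_x[s] <- (xl + xr) / 2
    segs[[s]] <- tibble::tibble(
      x = c(xl, xl, xr), xend = c(xl, xr, xr),
      y = c(ypos(l), h, h), yend = c(h, h, ypos(r)))
  }
  segs <- dplyr::bind_rows(segs)
  leaves <- tibble::tibble(x = seq_len(n), label = object$labels[object$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
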