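#' Heatmap of a percent-identity matrix
#'
#' The classic delineation figure: pairwise 16S identities of the clade
#' representatives, optionally annotated with genus-level cluster
#' boundaries (sequences are then ordered by cluster).
#'
#' @param object A `cb_identity` matrix.
#' @param clusters Optional `genus_clusters` object used to order and
#'   facet the heatmap.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cb_identity <- function(object, clusters = NULL, ...) {
  ids <- rownames(object)
  if (!is.null(clusters)) {
    ord <- clusters$assignments$clade_id[
      order(clusters$assignments$cluster_id, clusters$assignments$clade_id)]
    ord <- c(intersect(ord, ids), setdiff(ids, ord))
    ids <- ord
  }
  m <- unclass(object)[ids, ids]
  df <- tidyr::expand_grid(id_a = factor(ids, levels = ids),
                           id_b = factor(ids, levels = ids))
  df$identity <- m[cbind(as.integer(df$id_a), as.integer(df$id_b))]
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% identity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-site cluster composition plot
#'
#' Stacked per-site bars of sequence counts by genus-level cluster,
#' faceted by salinity category - the bar-chart analogue of per-site
#' cluster pie charts.
#'
#' @param object A `biogeo_summary` from [site_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biogeo_summary <- function(object, ...) {
  df <- object$composition
  df$cluster_id <- ifelse(is.na(df$cluster_id), "(none)", df$cluster_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$site_id, .data$n_sequences,
                                   fill = .data$cluster_id)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ category, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "site", y = "sequences", fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Delineation overview plot
#'
#' Identity heatmap of the valid-clade representatives ordered by
#' genus-level cluster.
#'
#' @param object A `cable_delineation` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cable_delineation <- function(object, ...) {
  if (is.null(object$genus))
    stop("no genus-level clustering in this result", call. = FALSE)
  reps <- object$clades$representative_id[object$clades$valid]
  im <- object$identity[reps, reps, drop = FALSE]
  class(im) <- c("cb_identity", class(im))
  autoplot(im, clusters = object$genus)
}

#' Clades-per-site distribution plot
#'
#' @param summary A `biogeo_summary`.
#' @return A ggplot object.
#' @export
plot_clades_per_site <- function(summary) {
  stopifnot(inherits(summary, "biogeo_summary"))
  ggplot2::ggplot(summary$distribution,
                  ggplot2::aes(factor(.data$n_clades), .data$n_sites)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "species-level clades at site", y = "sites") +
    ggplot2::theme_minimal()
}
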