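#' Delineation summary
#'
#' Collects the headline numbers of a delineation run: clade and cluster
#' counts, singleton fraction, per-source retention accounting, and the
#' intra/inter-cluster identity extremes.
#'
#' @param clades Clade table from [finalize_clades()].
#' @param genus A `genus_clusters` object from [cluster_genus()] (or
#'   `NULL` when genus clustering was not run).
#' @param im Identity matrix over the clade representatives (used for the
#'   identity extremes; may be `NULL`).
#' @param report Curation report tibble (`id`, `source`, `status`) or
#'   `NULL`.
#' @return A `delineation_summary` object; `glance()` returns the one-row
#'   headline tibble.
#' @export
summarize_delineation <- function(clades, genus = NULL, im = NULL,
                                  report = NULL) {
  n_groups <- nrow(clades)
  valid <- clades[clades$valid, , drop = FALSE]
  n_valid <- nrow(valid)
  n_singleton <- sum(valid$singleton)
  n_clusters <- if (!is.null(genus)) nrow(genus$clusters) else NA_integer_
  min_intra <- max_inter <- NA_real_
  if (!is.null(genus) && nrow(genus$clusters)) {
    min_intra <- suppressWarnings(
      min(genus$clusters$min_intra_identity, na.rm = TRUE))
    max_inter <- suppressWarnings(
      max(genus$clusters$max_inter_identity, na.rm = TRUE))
    if (!is.finite(min_intra)) min_intra <- NA_real_
    if (!is.finite(max_inter)) max_inter <- NA_real_
  }
  per_source <- NULL
  if (!is.null(report)) per_source <- accounting_table(report, clades)
  structure(list(
    n_groups = n_groups,
    n_valid_clades = n_valid,
    n_invalid_clades = n_groups - n_valid,
    n_singletons = n_singleton,
    n_clusters = n_clusters,
    min_intra_cluster_identity = min_intra,
    max_inter_cluster_identity = max_inter,
    per_source = per_source
  ), class = "delineation_summary")
}

#' @export
print.delineation_summary <- function(x, ...) {
  cat("Delineation summary\n")
  cat("  species-level groups:", x$n_groups,
      sprintf("(%d valid, %d without a >=1,200 bp member)\n",
              x$n_valid_clades, x$n_invalid_clades))
  if (x$n_valid_clades > 0)
    cat(sprintf("  singleton clades: %d (%.0f%% of valid clades)\n",
                x$n_singletons, 100 * x$n_singletons / x$n_valid_clades))
  if (!is.na(x$n_clusters))
    cat("  genus-level clusters:", x$n_clusters, "\n")
  if (!is.na(x$min_intra_cluster_identity))
    cat(sprintf("  intra-cluster identity minimum: %.1f%%; inter-cluster maximum: %.1f%%\n",
                x$min_intra_cluster_identity, x$max_inter_cluster_identity))
  if (!is.null(x$per_source)) {
    cat("  per-source accounting:\n")
    print(as.data.frame(x$per_source), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname summarize_delineation
#' @param x A `delineation_summary`.
#' @param ... Unused.
#' @export
glance.delineation_summary <- function(x, ...) {
  tibble::tibble(
    n_groups = x$n_groups,
    n_valid_clades = x$n_valid_clades,
    n_invalid_clades = x$n_invalid_clades,
    n_singletons = x$n_singletons,
    n_clusters = x$n_clusters,
    min_intra_cluster_identity = x$min_intra_cluster_identity,
    max_inter_cluster_identity = x$max_inter_cluster_identity
  )
}

#' Source-by-stage accounting table
#'
#' One row per sequence source with cumulative survivor counts through the
#' curation cascade (initial, identity screen, within-clade, length
#' filter) plus the number of species-level clades attributed to that
#' source.  A clade is attributed to the highest-priority source among its
#' members (enrichment > literature > silva > genbank > synthetic), so the
#' clade column sums to the total clade count.
#'
#' @param report Curation report tibble (`id`, `source`, `status`).
#' @param clades Optional clade table from [finalize_clades()].
#' @return A tibble with a `Total` row appended.
#' @export
accounting_table <- function(report, clades = NULL) {
  stopifnot(all(c("id", "source", "status") %in% names(report)))
  src_levels <- intersect(SEQ_SOURCES, unique(report$source))
  clade_src <- NULL
  if (!is.null(clades) && nrow(clades)) {
    src_of <- setNames(report$source, report$id)
    clade_src <- vapply(clades$member_ids, function(ids) {
      s <- unique(src_of[ids])
      s[order(match(s, SEQ_SOURCES))][1]
    }, character(1))
  }
  rows <- lapply(src_levels, function(s) {
    sub <- report[report$source == s, , drop = FALSE]
    tibble::tibble(
      source = s,
      n_initial = nrow(sub),
      n_screened = sum(sub$status != "screen_rejected"),
      n_in_clade = sum(!sub$status %in%
                         c("screen_rejected", "conserved_violation", "off_clade")),
      n_long = sum(sub$status == "retained"),
      n_clades = if (is.null(clade_src)) NA_integer_ else sum(clade_src == s)
    )
  })
  out <- dplyr::bind_rows(rows)
  total <- tibble::tibble(
    source = "Total",
    n_initial = sum(out$n_initial),
    n_screened = sum(out$n_screened),
    n_in_clade = sum(out$n_in_clade),
    n_long = sum(out$n_long),
    n_clades = if (is.null(clade_src)) NA_integer_ else length(clade_src)
  )
  dplyr::bind_rows(out, total)
}
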