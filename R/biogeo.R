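#' Classify salinity into the four standard categories
#'
#' Freshwater (S < 0.5), brackish (0.5 <= S < 30), marine (30 <= S <= 36)
#' and hypersaline (S > 36); practical salinity, dimensionless.
#'
#' @param s Numeric vector of non-negative salinities.
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_salinity(c(0.4, 17, 33, 40))
classify_salinity <- function(s) {
  if (any(s < 0, na.rm = TRUE))
    stop("negative salinity", call. = FALSE)
  out <- rep(NA_character_, length(s))
  out[!is.na(s) & s < 0.5] <- "freshwater"
  out[!is.na(s) & s >= 0.5 & s < 30] <- "brackish"
  out[!is.na(s) & s >= 30 & s <= 36] <- "marine"
  out[!is.na(s) & s > 36] <- "hypersaline"
  out
}

#' Per-site composition and co-occurrence summary
#'
#' Tallies the clade / cluster composition of every sampling site:
#' which sites harbor several species-level clades or even several
#' genus-level clusters, the distribution of clades per site, and which
#' clades are "endemic" (found at a single site only).  Records without
#' resolvable site metadata are reported in an `unsited` bucket rather
#' than dropped.  Two site tallies are emitted: `n_sites_assigned` counts
#' sites with at least one record that survived curation (the
#' co-occurrence denominator), `n_sites_any` counts sites with any input
#' record at all.
#'
#' @param assignments Tibble with `id`, `clade_id` and optionally
#'   `cluster_id` for every retained record.
#' @param records Full input record tibble (with `site_id`), used for the
#'   all-records site tally.
#' @param metadata Site metadata tibble (see [read_site_metadata()]).
#' @param min_clades Threshold k for the "sites with >= k clades" count.
#' @return A `biogeo_summary`: `composition` (site x clade counts),
#'   `site_stats`, `clade_sites`, `distribution`, `counts`, `unsited`.
#' @export
site_summary <- function(assignments, records, metadata, min_clades = 4L) {
  stopifnot(all(c("id", "clade_id") %in% names(assignments)))
  if (!"cluster_id" %in% names(assignments))
    assignments$cluster_id <- NA_character_
  rec_site <- setNames(records$site_id, records$id)
  df <- dplyr::mutate(assignments, site_id = unname(rec_site[.data$id]))
  df$site_known <- !is.na(df$site_id) & df$site_id %in% metadata$site_id
  unsited <- sum(!df$site_known)
  sited <- df[df$site_known, , drop = FALSE]

  sal <- setNames(metadata$salinity, metadata$site_id)
  composition <- sited |>
    dplyr::count(.data$site_id, .data$clade_id, .data$cluster_id,
                 name = "n_sequences") |>
    dplyr::mutate(category = classify_salinity(unname(sal[.data$site_id])))

  site_stats <- composition |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      category = .data$category[1],
      n_sequences = sum(.data$n_sequences),
      n_clades = dplyr::n_distinct(.data$clade_id),
      n_clusters = dplyr::n_distinct(.data$cluster_id[!is.na(.data$cluster_id)]),
      .groups = "drop"
    )

  clade_sites <- composition |>
    dplyr::group_by(.data$clade_id) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site_id),
                     .groups = "drop") |>
    dplyr::mutate(endemic = .data$n_sites == 1L)

  distribution <- dplyr::count(site_stats, .data$n_clades, name = "n_sites")

  counts <- tibble::tibble(
    n_sites_assigned = nrow(site_stats),
    n_sites_any = dplyr::n_distinct(
      records$site_id[!is.na(records$site_id) &
                        records$site_id %in% metadata$site_id]),
    multi_clade_sites = sum(site_stats$n_clades >= 2L),
    multi_cluster_sites = sum(site_stats$n_clusters >= 2L),
    sites_ge_k_clades = sum(site_stats$n_clades >= min_clades),
    k = as.integer(min_clades),
    endemic_clades = sum(clade_sites$endemic),
    unsited_records = unsited
  )

  structure(list(composition = composition, site_stats = site_stats,
                 clade_sites = clade_sites, distribution = distribution,
                 counts = counts, unsited = unsited),
            class = "biogeo_summary")
}

#' @export
print.biogeo_summary <- function(x, ...) {
  c0 <- x$counts
  cat("Biogeographic summary over", c0$n_sites_assigned, "sites",
      sprintf("(%d with any record)\n", c0$n_sites_any))
  cat(sprintf("  sites with >=2 clades: %d; with >=2 clusters: %d; with >=%d clades: %d\n",
              c0$multi_clade_sites, c0$multi_cluster_sites, c0$k,
              c0$sites_ge_k_clades))
  cat(sprintf("  endemic (single-site) clades: %d; unsited records: %d\n",
              c0$endemic_clades, c0$unsited_records))
  invisible(x)
}

#' @rdname site_summary
#' @param x A `biogeo_summary`.
#' @param ... Unused.
#' @export
glance.biogeo_summary <- function(x, ...) x$counts

#' @rdname site_summary
#' @export
tidy.biogeo_summary <- function(x, ...) x$composition
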