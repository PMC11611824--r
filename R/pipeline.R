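#' Pipeline configuration
#'
#' Flat list of every stage threshold of the delineation pipeline, with
#' the study defaults: 92% reference screen, conserved-violation filter
#' (0.95 conservation, at most 5 violations), monophyly filter, 800 bp
#' length cutoff, 98.7% species cutoff with a >= 1,200 bp representative
#' requirement, and 94.5% genus guide value.
#'
#' @param screen_cutoff Reference-screen identity cutoff (percent).
#' @param min_len Length cutoff in bp.
#' @param min_rep_len Minimum longest-member length for a valid clade.
#' @param full_len Full-length annotation threshold in bp.
#' @param species_cutoff Species-level identity cutoff (percent).
#' @param genus_cutoff Genus-level identity guide value (percent).
#' @param genus_tolerance Slack subtracted from the genus guide.
#' @param species_linkage `"complete"` or `"single"`.
#' @param genus_linkage `"min"` or `"mean"`.
#' @param min_conservation Conservation threshold for profile columns.
#' @param max_violations Tolerated conserved-column violations.
#' @param distance_correction `"p"` or `"jc"` for tree distances.
#' @param whitelist Record ids exempt from the identity screen.
#' @param seed Integer seed recorded for provenance (the pipeline itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(screen_cutoff = 92, min_len = 800L,
                            min_rep_len = 1200L, full_len = 1450L,
                            species_cutoff = 98.7, genus_cutoff = 94.5,
                            genus_tolerance = 0,
                            species_linkage = c("complete", "single"),
                            genus_linkage = c("min", "mean"),
                            min_conservation = 0.95, max_violations = 5L,
                            distance_correction = c("p", "jc"),
                            whitelist = character(), seed = 1L) {
  species_linkage <- match.arg(species_linkage)
  genus_linkage <- match.arg(genus_linkage)
  distance_correction <- match.arg(distance_correction)
  stopifnot(
    screen_cutoff > 0, screen_cutoff <= 100,
    species_cutoff > 0, species_cutoff <= 100,
    genus_cutoff > 0, genus_cutoff <= 100,
    species_cutoff > genus_cutoff,
    genus_tolerance >= 0, min_len >= 1L, min_rep_len >= 1L
  )
  structure(list(
    screen_cutoff = screen_cutoff, min_len = as.integer(min_len),
    min_rep_len = as.integer(min_rep_len), full_len = as.integer(full_len),
    species_cutoff = species_cutoff, genus_cutoff = genus_cutoff,
    genus_tolerance = genus_tolerance, species_linkage = species_linkage,
    genus_linkage = genus_linkage, min_conservation = min_conservation,
    max_violations = as.integer(max_violations),
    distance_correction = distance_correction,
    whitelist = whitelist, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full delineation pipeline
#'
#' Executes the curation and clustering cascade in the study's narrative
#' order: identity screen against trusted queries, conserved-region
#' violation filter, tree building (or import) with monophyly filtering
#' against the query seeds, length filter, species-level clustering and
#' clade validation, genus-level cluster delineation on the valid-clade
#' representatives, and summary / biogeography accounting.  The length
#' filter runs after the tree stage because the monophyly tree is built
#' before short fragments are discarded.
#'
#' Every stage is conservative: the per-record statuses (`retained`,
#' `screen_rejected`, `conserved_violation`, `off_clade`, `too_short`)
#' partition the input.  The run is fully deterministic given its inputs
#' and configuration.
#'
#' @param records Record tibble (see [seq_records()]).
#' @param queries Character vector of trusted record ids within
#'   `records` (identity-screen queries and monophyly seeds), or a record
#'   tibble of queries that are also present in `records`.
#' @param outgroup Single-row record tibble with the outgroup sequence
#'   (required for the monophyly stage unless `external_tree` is given
#'   and contains an `outgroup_id` leaf).
#' @param metadata Optional site metadata for the biogeography stage.
#' @param profile_refs Optional aligned trusted reference records for the
#'   conserved-region filter; stage skipped when `NULL`.
#' @param config A [pipeline_config()].
#' @param external_tree Optional [ape::phylo] tree to use for the
#'   monophyly stage instead of the built-in neighbor-joining tree; must
#'   contain all post-screen records and the outgroup as leaves.
#' @param verbose Emit stage-tagged progress lines to stderr.
#' @return A `cable_delineation` object: `report` (per-record status),
#'   `assignments` (id, clade_id, cluster_id), `clades`, `genus`,
#'   `summary`, `accounting`, `biogeo`, `trees`, `identity`, `config`.
#' @export
run_pipeline <- function(records, queries, outgroup = NULL, metadata = NULL,
                         profile_refs = NULL, config = pipeline_config(),
                         external_tree = NULL, verbose = FALSE) {
  validate_records(records)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))

  if (is.data.frame(queries)) queries <- queries$id
  queries <- as.character(queries)
  if (!length(queries) || !all(queries %in% records$id))
    stop("stage screen: queries must be ids present in records",
         call. = FALSE)

  status <- setNames(rep("retained", nrow(records)), records$id)
  params <- align_params()

  ## stage 1: identity screen -------------------------------------------
  qrec <- records[match(queries, records$id), , drop = FALSE]
  screen <- screen_references(records, qrec, cutoff = config$screen_cutoff,
                              whitelist = config$whitelist, params = params)
  status[screen$record_id[!screen$retained]] <- "screen_rejected"
  say("screen", sum(screen$retained), "/", nrow(records), " retained")

  ## stage 2: conserved-region violations -------------------------------
  profile <- NULL
  if (!is.null(profile_refs)) {
    profile <- build_conserved_profile(profile_refs,
                                       min_conservation = config$min_conservation)
    alive <- records[status[records$id] == "retained", , drop = FALSE]
    flags <- flag_conserved_violations(alive, profile,
                                       max_violations = config$max_violations,
                                       params = params)
    status[flags$id[flags$flagged]] <- "conserved_violation"
    say("conserved", sum(flags$flagged), " flagged")
  }

  ## stage 3: tree + monophyly filter ------------------------------------
  alive <- records[status[records$id] == "retained", , drop = FALSE]
  im_full <- NULL
  tree_records <- NULL
  if (nrow(alive) >= 2L && (!is.null(outgroup) || !is.null(external_tree))) {
    og_id <- if (!is.null(outgroup)) outgroup$id else NULL
    if (!is.null(external_tree)) {
      tree_records <- external_tree
      if (is.null(og_id)) og_id <- "OUTGROUP"
      missing <- setdiff(c(alive$id, og_id), tree_records$tip.label)
      if (length(missing))
        stop("stage monophyly: external tree lacks leaf '", missing[1], "'",
             call. = FALSE)
      im_full <- identity_matrix(rbind(alive, outgroup), params)
    } else {
      im_full <- identity_matrix(rbind(alive, outgroup), params)
      dm <- identity_to_distance(im_full, config$distance_correction)
      tree_records <- nj_tree(dm)
    }
    seeds <- intersect(queries, alive$id)
    if (length(seeds) == 0L)
      stop("stage monophyly: no query survived to seed the clade",
           call. = FALSE)
    mono <- monophyly_filter(tree_records, seeds, og_id)
    off <- intersect(mono$removed, alive$id)
    status[off] <- "off_clade"
    say("monophyly", length(off), " removed as off-clade")
  } else if (nrow(alive) >= 2L) {
    im_full <- identity_matrix(alive, params)
    say("monophyly", "skipped (no outgroup and no external tree)")
  } else if (nrow(alive) == 1L) {
    im_full <- identity_matrix(alive, params)
  }

  ## stage 4: length filter ----------------------------------------------
  alive <- records[status[records$id] == "retained", , drop = FALSE]
  if (nrow(alive)) {
    len <- filter_length(alive, min_len = config$min_len,
                         nearly_complete_len = config$min_rep_len,
                         full_len = config$full_len)
    status[len$id[!len$retained]] <- "too_short"
    say("length", sum(!len$retained), " below ", config$min_len, " bp")
  }

  report <- tibble::tibble(
    id = records$id,
    source = if ("source" %in% names(records)) records$source else "synthetic",
    status = unname(status[records$id])
  )

  final <- records[status[records$id] == "retained", , drop = FALSE]
  empty_out <- function() {
    structure(list(
      report = report,
      assignments = tibble::tibble(id = character(), clade_id = character(),
                                   cluster_id = character()),
      clades = finalize_clades(tibble::tibble(id = character(),
                                              clade_id = character()),
                               records, config$min_rep_len),
      genus = NULL,
      summary = summarize_delineation(
        finalize_clades(tibble::tibble(id = character(),
                                       clade_id = character()),
                        records, config$min_rep_len),
        NULL, NULL, report),
      accounting = accounting_table(report),
      biogeo = NULL, trees = list(records = tree_records, representatives = NULL),
      identity = im_full, config = config
    ), class = "cable_delineation")
  }
  if (nrow(final) == 0L) {
    say("cluster", "no sequence survived curation; empty result")
    return(empty_out())
  }

  ## stage 5: species-level clades ---------------------------------------
  if (is.null(im_full)) im_full <- identity_matrix(
    if (is.null(outgroup)) final else rbind(final, outgroup), params)
  im_final <- im_full[final$id, final$id, drop = FALSE]
  class(im_final) <- c("cb_identity", class(im_final))
  sp <- cluster_species(im_final, cutoff = config$species_cutoff,
                        linkage = config$species_linkage)
  clades <- finalize_clades(sp, final, min_rep_len = config$min_rep_len)
  say("species", nrow(clades), " groups (", sum(clades$valid), " valid)")

  ## stage 6: genus-level clusters ---------------------------------------
  genus <- NULL
  reps <- clades$representative_id[clades$valid]
  can_tree <- !is.null(outgroup) || !is.null(external_tree)
  if (length(reps) >= 2L && can_tree) {
    og_id <- if (!is.null(outgroup)) outgroup$id else "OUTGROUP"
    rep_ids <- c(reps, og_id)
    im_rep <- im_full[rep_ids, rep_ids, drop = FALSE]
    class(im_rep) <- c("cb_identity", class(im_rep))
    tree_reps <- if (!is.null(external_tree)) {
      ape::keep.tip(external_tree, rep_ids)
    } else if (length(rep_ids) >= 3L) {
      nj_tree(identity_to_distance(im_rep, config$distance_correction))
    } else NULL
    if (!is.null(tree_reps)) {
      genus <- cluster_genus(tree_reps, im_rep,
                             guide_cutoff = config$genus_cutoff,
                             tolerance = config$genus_tolerance,
                             linkage = config$genus_linkage,
                             outgroup = og_id)
      say("genus", nrow(genus$clusters), " clusters")
    }
  } else if (length(reps) == 1L) {
    genus <- structure(list(
      assignments = tibble::tibble(clade_id = reps, cluster_id = "GC1"),
      clusters = tibble::tibble(cluster_id = "GC1", n_clades = 1L,
                                clade_ids = list(reps), monophyletic = TRUE,
                                min_intra_identity = NA_real_,
                                max_inter_identity = NA_real_),
      tree = NULL, guide_cutoff = config$genus_cutoff,
      tolerance = config$genus_tolerance, linkage = config$genus_linkage
    ), class = "genus_clusters")
    say("genus", "single valid clade; one cluster")
  }

  ## stage 7: assignments + summaries -------------------------------------
  clade_of <- setNames(sp$clade_id, sp$id)
  cluster_of_clade <- if (!is.null(genus))
    setNames(genus$assignments$cluster_id,
             clades$clade_id[match(genus$assignments$clade_id,
                                   clades$representative_id)])
  else setNames(character(0), character(0))
  assignments <- tibble::tibble(
    id = final$id,
    clade_id = unname(clade_of[final$id]),
    cluster_id = unname(cluster_of_clade[clade_of[final$id]])
  )

  summary <- summarize_delineation(clades, genus,
                                   if (length(reps) >= 2L && !is.null(genus))
                                     im_full[reps, reps, drop = FALSE]
                                   else NULL,
                                   report)
  accounting <- accounting_table(report, clades)

  biogeo <- NULL
  if (!is.null(metadata))
    biogeo <- site_summary(assignments, records, metadata)

  structure(list(
    report = report, assignments = assignments, clades = clades,
    genus = genus, summary = summary, accounting = accounting,
    biogeo = biogeo,
    trees = list(records = tree_records,
                 representatives = if (!is.null(genus)) genus$tree else NULL),
    identity = im_full, config = config
  ), class = "cable_delineation")
}

#' @export
print.cable_delineation <- function(x, ...) {
  cat("Cable bacteria 16S delineation\n")
  tab <- table(x$report$status)
  cat("  records:", nrow(x$report), "-",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  cat("  species-level groups:", nrow(x$clades),
      "| valid clades:", sum(x$clades$valid),
      "| singletons:", sum(x$clades$valid & x$clades$singleton), "\n")
  if (!is.null(x$genus))
    cat("  genus-level clusters:", nrow(x$genus$clusters), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `cable_delineation` object.
#' @param ... Unused.
#' @export
tidy.cable_delineation <- function(x, ...) {
  dplyr::left_join(x$report, x$assignments, by = "id")
}

#' @rdname run_pipeline
#' @export
glance.cable_delineation <- function(x, ...) {
  g <- glance(x$summary)
  g$n_records <- nrow(x$report)
  g$n_retained <- sum(x$report$status == "retained")
  g
}
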