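#' Species-level clade clustering at a percent-identity cutoff
#'
#' Agglomerative clustering on distance `100 - identity`, cut at
#' `100 - cutoff`.  Complete linkage (the default) guarantees that every
#' within-clade pair meets the cutoff, which is what a species delineation
#' statement promises; single linkage is available for sensitivity
#' analysis.  Merges are processed smallest-distance-first with ties
#' broken toward the lexicographically smallest pair of cluster labels (a
#' cluster is labelled by its smallest member id).
#'
#' @param im A `cb_identity` matrix.
#' @param cutoff Identity cutoff in percent (members of one clade are at
#'   least this similar under complete linkage); the conventional
#'   species-level value is 98.7.
#' @param linkage `"complete"` or `"single"`.
#' @return A tibble `id`, `clade_id` (clades numbered `SC001`, ... in
#'   order of their smallest member id).
#' @export
cluster_species <- function(im, cutoff = 98.7,
                            linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(cutoff > 0, cutoff <= 100)
  m <- unclass(as.matrix(im))
  ids <- rownames(m)
  n <- length(ids)
  h <- (100 - cutoff) + 1e-9
  members <- as.list(ids)
  lab <- ids
  CD <- 100 - m
  diag(CD) <- Inf
  alive <- rep(TRUE, n)
  comb <- if (linkage == "complete") pmax else pmin

  while (sum(alive) > 1L) {
    sub <- which(alive)
    block <- CD[sub, sub, drop = FALSE]
    dmin <- min(block)
    if (dmin > h) break
    cand <- which(block <= dmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keylo <- pmin(lab[sub[cand[, 1]]], lab[sub[cand[, 2]]])
    keyhi <- pmax(lab[sub[cand[, 1]]], lab[sub[cand[, 2]]])
    pick <- order(keylo, keyhi)[1]
    i <- sub[cand[pick, 1]]; j <- sub[cand[pick, 2]]
    members[[i]] <- c(members[[i]], members[[j]])
    lab[i] <- min(lab[i], lab[j])
    newd <- comb(CD[i, ], CD[j, ])
    CD[i, ] <- newd; CD[, i] <- newd
    CD[i, i] <- Inf
    alive[j] <- FALSE
    CD[j, ] <- Inf; CD[, j] <- Inf
  }

  groups <- members[alive]
  ord <- order(vapply(groups, min, character(1)))
  groups <- groups[ord]
  width <- max(3L, nchar(as.character(length(groups))))
  out <- tibble::tibble(
    id = unlist(groups),
    clade_id = rep(sprintf(paste0("SC%0", width, "d"), seq_along(groups)),
                   lengths(groups))
  )
  out[match(ids, out$id), ]
}

#' Finalize species-level clades
#'
#' Chooses each clade's representative (the longest member, ties broken
#' toward the lexicographically smallest id), marks validity (a genuine
#' species-level clade must contain at least one nearly complete sequence,
#' >= `min_rep_len` bp) and flags singletons.
#'
#' @param assignments Tibble `id`, `clade_id` from [cluster_species()].
#' @param records Record tibble covering all assigned ids.
#' @param min_rep_len Minimum length (bp) of the longest member for a
#'   clade to count as valid.
#' @return A tibble: `clade_id`, `n_members`, `member_ids` (list column),
#'   `representative_id`, `representative_length`, `valid`, `singleton`.
#' @export
finalize_clades <- function(assignments, records, min_rep_len = 1200L) {
  stopifnot(all(c("id", "clade_id") %in% names(assignments)))
  if (nrow(assignments) == 0L)
    return(tibble::tibble(clade_id = character(), n_members = integer(),
                          member_ids = list(), representative_id = character(),
                          representative_length = integer(), valid = logical(),
                          singleton = logical()))
  missing <- setdiff(assignments$id, records$id)
  if (length(missing))
    stop("no record for assigned id '", missing[1], "'", call. = FALSE)
  lens <- setNames(ungapped_length(records$residues), records$id)
  assignments |>
    dplyr::group_by(.data$clade_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      member_ids = list(sort(.data$id)),
      representative_id = {
        l <- lens[.data$id]
        cand <- .data$id[l == max(l)]
        sort(cand)[1]
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      representative_length = unname(lens[.data$representative_id]),
      valid = .data$representative_length >= min_rep_len,
      singleton = .data$n_members == 1L
    ) |>
    dplyr::arrange(.data$clade_id)
}

#' Genus-level cluster delineation (identity guide + tree topology)
#'
#' Pre-order decomposition of the rooted ingroup: a node's leaves become
#' one genus-level cluster as soon as their linkage identity (mean or
#' minimum pairwise identity) reaches `guide_cutoff - tolerance`;
#' otherwise the node is split into its children and the rule recurses.
#' Every cluster is therefore monophyletic by construction.  The
#' conventional guide value is 94.5% identity.  Minimum linkage is the
#' default because it is the only rule whose clusters carry a guarantee
#' ("every member pair is within tolerance of the guide"); with very
#' unbalanced cluster sizes the mean is dominated by the large group's
#' within-pairs and can absorb a small divergent neighbor.  Published
#' genus-level groups are ultimately drawn on the tree and may contain
#' sub-cutoff pairs (the observed intra-cluster minimum is 89.7%), so
#' reproducing such partitions needs `tolerance > 0` (or mean linkage).
#'
#' @param tree Tree over the valid-clade representative sequences; must
#'   also contain `outgroup` as a leaf.
#' @param im Identity matrix covering all representative leaves.
#' @param guide_cutoff Genus-level identity guide value in percent.
#' @param tolerance Non-negative slack subtracted from the guide.
#' @param linkage `"min"` (default) or `"mean"` pairwise identity within a node.
#' @param outgroup Outgroup leaf label used for rooting.
#' @return A `genus_clusters` object; `tidy()` gives the leaf-to-cluster
#'   assignments, `glance()` the partition-level summary (cluster count
#'   and intra/inter identity extremes).
#' @export
cluster_genus <- function(tree, im, guide_cutoff = 94.5, tolerance = 0,
                          linkage = c("min", "mean"), outgroup) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(tree, "phylo"), tolerance >= 0)
  m <- unclass(as.matrix(im))
  leaves <- setdiff(tree$tip.label, outgroup)
  if (!all(leaves %in% rownames(m)))
    stop("identity matrix is missing tree leaf '",
         setdiff(leaves, rownames(m))[1], "'", call. = FALSE)
  rooted <- root_on_outgroup(tree, outgroup)
  root <- length(rooted$tip.label) + 1L
  og_tip <- which(rooted$tip.label == outgroup)
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  start <- setdiff(kids, og_tip)
  stat_fun <- if (linkage == "mean") mean else min
  thr <- guide_cutoff - tolerance - 1e-9
  desc <- phangorn::Descendants(rooted, type = "tips")

  clusters <- list()
  visit <- function(node) {
    labs <- rooted$tip.label[desc[[node]]]
    ok <- length(labs) == 1L ||
      stat_fun(m[labs, labs][upper.tri(m[labs, labs])]) >= thr
    if (ok) {
      clusters[[length(clusters) + 1L]] <<- sort(labs)
    } else {
      for (ch in rooted$edge[rooted$edge[, 1] == node, 2]) visit(ch)
    }
  }
  for (s in sort(start)) visit(s)

  ids <- sprintf("GC%d", seq_along(clusters))
  assignments <- tibble::tibble(
    clade_id = unlist(clusters),
    cluster_id = rep(ids, lengths(clusters))
  )
  intra <- vapply(clusters, function(g) {
    if (length(g) < 2L) return(NA_real_)
    min(m[g, g][upper.tri(m[g, g])])
  }, numeric(1))
  inter <- vapply(seq_along(clusters), function(k) {
    other <- setdiff(unlist(clusters), clusters[[k]])
    if (!length(other)) return(NA_real_)
    max(m[clusters[[k]], other, drop = FALSE])
  }, numeric(1))
  structure(list(
    assignments = assignments,
    clusters = tibble::tibble(
      cluster_id = ids, n_clades = lengths(clusters),
      clade_ids = clusters, monophyletic = TRUE,
      min_intra_identity = intra, max_inter_identity = inter
    ),
    tree = rooted, guide_cutoff = guide_cutoff, tolerance = tolerance,
    linkage = linkage
  ), class = "genus_clusters")
}

#' @export
print.genus_clusters <- function(x, ...) {
  cat("Genus-level delineation:", nrow(x$clusters), "monophyletic clusters over",
      nrow(x$assignments), "species-clade representatives\n")
  cat(sprintf("  guide %.1f%% (tolerance %.1f, %s linkage); intra min %.1f%%, inter max %.1f%%\n",
              x$guide_cutoff, x$tolerance, x$linkage,
              suppressWarnings(min(x$clusters$min_intra_identity, na.rm = TRUE)),
              suppressWarnings(max(x$clusters$max_inter_identity, na.rm = TRUE))))
  invisible(x)
}

#' @rdname cluster_genus
#' @param x A `genus_clusters` object.
#' @param ... Unused.
#' @export
tidy.genus_clusters <- function(x, ...) x$assignments

#' @rdname cluster_genus
#' @export
glance.genus_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_clades = nrow(x$assignments),
    min_intra_identity = suppressWarnings(
      min(x$clusters$min_intra_identity, na.rm = TRUE)),
    max_inter_identity = suppressWarnings(
      max(x$clusters$max_inter_identity, na.rm = TRUE)),
    guide_cutoff = x$guide_cutoff,
    tolerance = x$tolerance
  )
}
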