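#' Length-based curation flags
#'
#' Long sequences (>= 800 bp by default) carry enough signal for
#' species-level resolution; sequences of >= 1,200 bp count as nearly
#' complete (required for a clade to be accepted as genuine) and
#' >= 1,450 bp as full-length 16S rRNA genes.
#'
#' @param records Record tibble.
#' @param min_len Retention cutoff in bp (boundary inclusive).
#' @param nearly_complete_len,full_len Annotation thresholds in bp.
#' @return The records with added columns `seq_length`, `retained`,
#'   `nearly_complete`, `full_length`.
#' @export
filter_length <- function(records, min_len = 800L,
                          nearly_complete_len = 1200L, full_len = 1450L) {
  validate_records(records)
  stopifnot(min_len >= 1L)
  len <- ungapped_length(records$residues)
  dplyr::mutate(records,
                seq_length = len,
                retained = len >= min_len,
                nearly_complete = len >= nearly_complete_len,
                full_length = len >= full_len)
}

#' Build a conserved-region profile from an aligned reference set
#'
#' Operationalizes the manual curation step "remove sequences with indels
#' and mutations in conserved regions": a per-column consensus is computed
#' from an *aligned* set of trusted reference sequences, and a column is
#' marked conserved when the modal residue reaches the `min_conservation`
#' frequency.  A deep, family-level reference alignment shows near-total
#' disagreement at genuinely variable 16S columns, so the conserved flags
#' recover the conserved regions and nothing else.
#'
#' @param refs Record tibble of aligned references (equal string lengths;
#'   `-` allowed) or a character vector of aligned sequences.
#' @param min_conservation Modal-base frequency required to call a column
#'   conserved.
#' @return A `conserved_profile`: the ungapped consensus string, a logical
#'   `conserved` flag per consensus position, and the column statistics.
#' @export
build_conserved_profile <- function(refs, min_conservation = 0.95) {
  seqs <- if (is.data.frame(refs)) refs$residues else as.character(refs)
  if (length(seqs) == 0L) stop("empty reference profile", call. = FALSE)
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("profile references must be aligned (equal lengths)", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cons_char <- character(L)
  conservation <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    tab <- sort(table(col), decreasing = TRUE)
    modal <- names(tab)[order(-tab, names(tab))][1]   # ties: alphabetical
    cons_char[j] <- modal
    conservation[j] <- tab[[modal]] / length(col)
  }
  keep <- cons_char != "-"
  structure(list(
    consensus = paste(cons_char[keep], collapse = ""),
    conserved = (conservation >= min_conservation)[keep],
    conservation = conservation[keep],
    n_refs = length(seqs),
    min_conservation = min_conservation
  ), class = "conserved_profile")
}

#' @export
print.conserved_profile <- function(x, ...) {
  cat("Conserved-region profile:", nchar(x$consensus), "columns,",
      sum(x$conserved), "conserved (threshold", x$min_conservation,
      "over", x$n_refs, "references)\n")
  invisible(x)
}

#' Flag sequences violating conserved 16S regions
#'
#' Each record is aligned semi-globally to the profile consensus with all
#' non-conserved columns masked to `N`; since `N` intersects every base,
#' the alignment is anchored purely by the conserved columns and cannot be
#' distracted by noise in the variable regions (whose consensus carries no
#' signal).  A violation is a conserved consensus column where the record
#' has a gap or a non-intersecting base.  End-gap columns (fragment
#' overhang) are not counted - incomplete sequences are the length
#' filter's business, not this filter's.  Records with more than
#' `max_violations` violations are flagged.
#'
#' @param records Record tibble.
#' @param profile A [build_conserved_profile()] result.
#' @param max_violations Tolerated number of violated conserved columns.
#' @param params Alignment scoring parameters.
#' @return A tibble: `id`, `violations`, `flagged`.
#' @export
flag_conserved_violations <- function(records, profile, max_violations = 5L,
                                      params = align_params()) {
  validate_records(records)
  if (!inherits(profile, "conserved_profile"))
    stop("profile must come from build_conserved_profile()", call. = FALSE)
  if (!any(profile$conserved))
    stop("profile has no conserved columns", call. = FALSE)
  cons_ch <- strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  cons_ch[!profile$conserved] <- "N"      # anchor alignment on conserved columns
  cons <- paste(cons_ch, collapse = "")
  cons_mask <- iupac_mask(cons)
  mask_tab <- integer(256)
  mask_tab[utf8ToInt("-") + 1L] <- 0L
  for (ch in names(IUPAC_MASK))
    mask_tab[utf8ToInt(ch) + 1L] <- IUPAC_MASK[[ch]]
  gap <- as.raw(45L)
  violations <- vapply(seq_len(nrow(records)), function(i) {
    r <- cpp_align_pair(records$residues[i], cons, params$match,
                        params$mismatch, params$gap_open,
                        params$gap_extension)
    ga <- charToRaw(r$aligned_a)
    gb <- charToRaw(r$aligned_b)
    rec_res <- which(ga != gap)
    core_lo <- rec_res[1]
    core_hi <- rec_res[length(rec_res)]
    cons_cols <- which(gb != gap)
    cons_pos <- seq_along(cons_cols)             # consensus position per column
    keep <- cons_cols >= core_lo & cons_cols <= core_hi
    cols <- cons_cols[keep]
    cp <- cons_pos[keep]
    is_cons <- profile$conserved[cp]
    rec_mask <- mask_tab[as.integer(ga[cols]) + 1L]   # 0 for a gap
    sum(is_cons & bitwAnd(rec_mask, cons_mask[cp]) == 0L)
  }, integer(1))
  tibble::tibble(id = records$id, violations = violations,
                 flagged = violations > max_violations)
}

#' Monophyly filter against trusted seed sequences
#'
#' Roots the tree on the outgroup, finds the most recent common ancestor
#' of the trusted seed leaves, and keeps exactly the leaves descending
#' from it; everything else (except the outgroup) is removed as falling
#' outside the monophyletic clade.
#'
#' @param tree An [ape::phylo] tree whose leaves include the seeds and the
#'   outgroup.
#' @param seed_ids Character vector of trusted leaf labels.
#' @param outgroup Outgroup leaf label.
#' @return A list with character vectors `retained` and `removed`.
#' @export
monophyly_filter <- function(tree, seed_ids, outgroup) {
  q <- clade_query(tree, outgroup, seed_ids)
  retained <- q$tips
  removed <- setdiff(tree$tip.label, c(retained, outgroup))
  list(retained = retained, removed = removed)
}
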