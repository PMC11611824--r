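#' Alignment scoring parameters
#'
#' Defaults chosen for aligning 800-1,500 bp 16S fragments against
#' full-length references: end gaps are always free on both sequences
#' (semi-global / overlap alignment), so a short fragment is never
#' penalized for the reference overhang.  A column counts as a match iff
#' the IUPAC sets of the two symbols intersect (degenerate codes such as M,
#' R, Y therefore match their constituent bases).
#'
#' @param match Score for an intersecting column (> 0).
#' @param mismatch Score for a non-intersecting column (<= 0).
#' @param gap_open Penalty of the first column of a gap (>= 0); a gap of
#'   length L costs `gap_open + (L - 1) * gap_extension`.
#' @param gap_extension Penalty per additional gap column (>= 0).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 2L, mismatch = -1L, gap_open = 5L,
                         gap_extension = 2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extension >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extension = as.integer(gap_extension)),
            class = "align_params")
}

# Accept a single-row record tibble, a named length-1 character, or a bare
# string; return list(id, residues).
as_seq_input <- function(x, default_id) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected exactly one sequence record", call. = FALSE)
    return(list(id = x$id, residues = normalize_residues(x$residues, x$id)))
  }
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x))) names(x) else default_id
    return(list(id = id, residues = normalize_residues(unname(x), id)))
  }
  stop("sequences must be single-row record tibbles or character strings",
       call. = FALSE)
}

#' Optimal semi-global alignment of two sequences
#'
#' Computes the optimal overlap alignment (end gaps free on both
#' sequences) under [align_params()], with a deterministic traceback
#' (diagonal preferred over up over left on score ties).  Swapping the two
#' inputs yields the mirrored alignment, so [percent_identity()] is exactly
#' symmetric.
#'
#' @param a,b Single-row record tibbles (see [seq_records()]) or character
#'   strings.
#' @param params Scoring parameters from [align_params()].
#' @return A `cb_alignment` object: ids, the two gapped strings (equal
#'   length; removing gaps recovers the inputs), the score, and the match /
#'   comparable column counts.
#' @export
#' @examples
#' align_pair("ACGTACGT", "ACGACGT")
align_pair <- function(a, b, params = align_params()) {
  sa <- as_seq_input(a, "seq_a")
  sb <- as_seq_input(b, "seq_b")
  # canonical internal order makes the result symmetric in (a, b)
  swap <- sb$residues < sa$residues
  x <- if (swap) sb else sa
  y <- if (swap) sa else sb
  r <- cpp_align_pair(x$residues, y$residues, params$match, params$mismatch,
                      params$gap_open, params$gap_extension)
  out <- list(
    id_a = sa$id, id_b = sb$id,
    aligned_a = if (swap) r$aligned_b else r$aligned_a,
    aligned_b = if (swap) r$aligned_a else r$aligned_b,
    score = r$score, matches = r$matches, comparable = r$comparable,
    params = params
  )
  class(out) <- "cb_alignment"
  out
}

#' @export
print.cb_alignment <- function(x, ...) {
  cat("Semi-global alignment ", x$id_a, " / ", x$id_b,
      "  (score ", x$score, ", ", x$matches, "/", x$comparable,
      " matching columns)\n", sep = "")
  w <- 60L
  n <- nchar(x$aligned_a)
  for (s in seq(1L, n, by = w)) {
    e <- min(s + w - 1L, n)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$aligned_b, s, e), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' Percent identity of an alignment (pairwise deletion)
#'
#' `100 * matches / comparable`, where comparable columns are those with a
#' residue in both sequences; columns containing a gap in either sequence
#' are excluded, so internal gaps never count as mismatches.
#'
#' @param aln A `cb_alignment` from [align_pair()].
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' percent_identity(align_pair("ACGTACGT", "ACGAACGT"))  # 87.5
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "cb_alignment"))
  if (aln$comparable == 0L)
    stop("undefined identity: alignment of '", aln$id_a, "' and '", aln$id_b,
         "' has no comparable (gap-free) columns", call. = FALSE)
  100 * aln$matches / aln$comparable
}

# identity from two already-gapped strings (used by the consensus merger)
pid_from_gapped <- function(ga, gb) {
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(list(identity = NA_real_, comparable = 0L))
  ma <- unname(IUPAC_MASK[ca[keep]])
  mb <- unname(IUPAC_MASK[cb[keep]])
  list(identity = 100 * sum(bitwAnd(ma, mb) > 0L) / sum(keep),
       comparable = sum(keep))
}

#' All-vs-all percent-identity matrix
#'
#' Every pair is aligned once with [align_pair()] semantics and scored
#' under pairwise deletion, giving a symmetric matrix with 100 on the
#' diagonal.
#'
#' @param records Record tibble with unique ids.
#' @param params Scoring parameters.
#' @return A `cb_identity` matrix (ids as dimnames).
#' @export
identity_matrix <- function(records, params = align_params()) {
  validate_records(records)
  if (nrow(records) < 1L) stop("need at least one record", call. = FALSE)
  res <- normalize_residues(records$residues, records$id)
  m <- cpp_identity_matrix(res, params$match, params$mismatch,
                           params$gap_open, params$gap_extension)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("undefined identity: '", records$id[idx[1]], "' and '",
         records$id[idx[2]], "' share no comparable columns", call. = FALSE)
  }
  dimnames(m) <- list(records$id, records$id)
  class(m) <- c("cb_identity", class(m))
  m
}

#' @export
print.cb_identity <- function(x, ...) {
  cat("Percent-identity matrix over", nrow(x), "sequences",
      sprintf("(off-diagonal range %.1f-%.1f)\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' @rdname identity_matrix
#' @param x A `cb_identity` matrix.
#' @param ... Unused.
#' @export
tidy.cb_identity <- function(x, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                 identity = x[ut])
}

#' Write an identity matrix as CSV
#'
#' Ids as header row/column, values rounded to 4 decimals.
#'
#' @param im A `cb_identity` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_csv <- function(im, path) {
  m <- round(unclass(im), 4)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read back an identity matrix written by [write_identity_csv()]
#' @param path CSV path.
#' @return A `cb_identity` matrix.
#' @export
read_identity_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  class(m) <- c("cb_identity", class(m))
  m
}

#' Screen candidate sequences against a trusted reference set
#'
#' The local stand-in for a blastn screen of database sequences against
#' known cable bacteria references: each record is aligned to every query
#' and kept iff its best identity reaches the cutoff (default 92%) or its
#' id is whitelisted.  The whitelist reproduces curator overrides for
#' sequences recognized as cable bacteria despite sub-cutoff identity.
#'
#' @param records Record tibble to screen.
#' @param queries Record tibble of trusted reference sequences (>= 1 row).
#' @param cutoff Retention cutoff in percent identity.
#' @param whitelist Character vector of record ids retained regardless.
#' @param params Scoring parameters.
#' @return A tibble: `record_id`, `best_query_id`, `best_identity`,
#'   `retained`, `whitelisted`.
#' @export
screen_references <- function(records, queries, cutoff = 92,
                              whitelist = character(),
                              params = align_params()) {
  validate_records(records)
  if (!is.data.frame(queries) || nrow(queries) == 0L)
    stop("need at least one query sequence", call. = FALSE)
  validate_records(queries, "queries")
  qord <- order(queries$id)
  queries <- queries[qord, , drop = FALSE]
  cross <- cpp_identity_cross(
    normalize_residues(records$residues, records$id),
    normalize_residues(queries$residues, queries$id),
    params$match, params$mismatch, params$gap_open, params$gap_extension
  )
  cross[is.na(cross)] <- -Inf
  best_j <- apply(cross, 1L, which.max)    # queries sorted by id: ties -> smallest
  best <- cross[cbind(seq_len(nrow(cross)), best_j)]
  wl <- records$id %in% whitelist
  tibble::tibble(
    record_id = records$id,
    best_query_id = queries$id[best_j],
    best_identity = as.numeric(best),
    whitelisted = wl,
    retained = best >= cutoff - 1e-9 | wl
  )
}
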