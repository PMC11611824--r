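#' Locate degenerate-primer binding sites on a template
#'
#' Scans both strands of the template for primer binding sites.  A
#' position is a site iff at most `max_mismatch` columns have
#' non-intersecting IUPAC sets *and* the `anchor3` 3'-terminal primer
#' bases all intersect (polymerase extension requires a matched 3' end).
#' Thermodynamics are deliberately not modelled; this is sequence-level
#' feasibility only.
#'
#' Coordinates are 0-based half-open on the plus strand of the template.
#' For a minus-strand site the primer anneals to the plus strand's
#' reverse complement, so its 3' anchor sits at the *left* (start) edge of
#' the reported interval.
#'
#' @param template Single-row record tibble or character string.
#' @param primer Single-row primer tibble (see [cable_primers()]) or a
#'   named character string.
#' @param max_mismatch Tolerated non-intersecting columns.
#' @param anchor3 Number of 3'-terminal bases that must match exactly
#'   (by IUPAC intersection).
#' @return A tibble: `primer_name`, `strand` (`"plus"`/`"minus"`),
#'   `start`, `end`, `mismatches`, ordered by `start`.
#' @export
#' @examples
#' p <- cable_primers()[1, ]  # 27F
#' tmpl <- paste0(strrep("G", 30), "AGAGTTTGATCATGGCTCAG", strrep("C", 30))
#' find_primer_sites(tmpl, p)
find_primer_sites <- function(template, primer, max_mismatch = 0L,
                              anchor3 = 3L) {
  tm <- as_seq_input(template, "template")
  if (is.data.frame(primer)) {
    stopifnot(nrow(primer) == 1L)
    pname <- primer$name
    pseq <- primer$sequence
  } else {
    pname <- names(primer) %||% "primer"
    pseq <- unname(primer)
  }
  pseq <- normalize_residues(pseq, pname)
  tmask <- iupac_mask(tm$residues)
  L <- length(tmask)
  m <- nchar(pseq)
  if (m >= L) stop("primer must be shorter than the template", call. = FALSE)
  anchor3 <- min(anchor3, m)

  scan <- function(pmask, anchor_idx) {
    n_off <- L - m + 1L
    mm <- integer(n_off)
    anchor_bad <- logical(n_off)
    for (k in seq_len(m)) {
      hit <- bitwAnd(tmask[k:(L - m + k)], pmask[k]) > 0L
      mm <- mm + !hit
      if (k %in% anchor_idx) anchor_bad <- anchor_bad | !hit
    }
    which(mm <= max_mismatch & !anchor_bad) - 1L  # 0-based starts
  }

  pmask_plus <- iupac_mask(pseq)
  pmask_minus <- iupac_mask(revcomp(pseq))
  plus_starts <- scan(pmask_plus, seq(m - anchor3 + 1L, m))
  minus_starts <- scan(pmask_minus, seq_len(anchor3))

  mism_at <- function(pmask, s) sum(bitwAnd(tmask[(s + 1):(s + m)], pmask) == 0L)
  out <- tibble::tibble(
    primer_name = pname,
    strand = c(rep("plus", length(plus_starts)),
               rep("minus", length(minus_starts))),
    start = c(plus_starts, minus_starts),
    end = c(plus_starts, minus_starts) + m,
    mismatches = c(vapply(plus_starts, mism_at, integer(1), pmask = pmask_plus),
                   vapply(minus_starts, mism_at, integer(1), pmask = pmask_minus))
  )
  dplyr::arrange(out, .data$start, .data$strand)
}

#' In-silico PCR amplification
#'
#' Emits one amplicon for every plus-strand site of the forward primer
#' combined with every minus-strand site of the reverse primer lying
#' downstream of it, provided the spanned length is within
#' `[min_len, max_len]`.  Amplicons are reported on the plus strand, in
#' deterministic order (by start, then end).
#'
#' @param template Single-row record tibble or character string.
#' @param fwd,rev Primer rows (or named strings): forward and reverse
#'   primer of the pair.
#' @param min_len,max_len Accepted amplicon length bounds (bp).
#' @param max_mismatch,anchor3 Passed to [find_primer_sites()].
#' @return A tibble: `template_id`, `fwd_primer`, `rev_primer`, `start`,
#'   `end`, `length`, `residues`.
#' @export
amplify <- function(template, fwd, rev, min_len = 100L, max_len = 100000L,
                    max_mismatch = 0L, anchor3 = 3L) {
  tm <- as_seq_input(template, "template")
  fs <- find_primer_sites(tm$residues, fwd, max_mismatch, anchor3)
  rs <- find_primer_sites(tm$residues, rev, max_mismatch, anchor3)
  fs <- fs[fs$strand == "plus", , drop = FALSE]
  rs <- rs[rs$strand == "minus", , drop = FALSE]
  empty <- tibble::tibble(template_id = character(), fwd_primer = character(),
                          rev_primer = character(), start = integer(),
                          end = integer(), length = integer(),
                          residues = character())
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(empty)
  combos <- tidyr::expand_grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
  combos <- combos[rs$start[combos$r] >= fs$end[combos$f], , drop = FALSE]
  if (nrow(combos) == 0L) return(empty)
  start <- fs$start[combos$f]
  end <- rs$end[combos$r]
  len <- end - start
  keep <- len >= min_len & len <= max_len
  if (!any(keep)) return(empty)
  out <- tibble::tibble(
    template_id = tm$id,
    fwd_primer = fs$primer_name[combos$f][keep],
    rev_primer = rs$primer_name[combos$r][keep],
    start = start[keep], end = end[keep], length = len[keep],
    residues = substr(rep(tm$residues, sum(keep)), start[keep] + 1L, end[keep])
  )
  dplyr::arrange(out, .data$start, .data$end)
}

#' In-silico nested PCR with consensus assembly
#'
#' Twin of the laboratory protocol for single cable bacterium filaments:
#' a first-round amplification with universal primers spanning the whole
#' 16S rRNA gene, second-round amplifications with primer pairs nested
#' inside the first-round product, and assembly of the second-round
#' fragments into a consensus sequence by best semi-global overlap.
#' Fragments merge when they share at least `min_overlap` comparable
#' columns at `min_overlap_identity` percent identity or better;
#' conflicting overlap columns are resolved by majority with ties written
#' as `N`.
#'
#' @param template Single-row record tibble or character string.
#' @param pcr1 List/tibble with the first-round forward and reverse primer
#'   (two primer rows, e.g. `cable_primers()[c(1, 4), ]` for 27F/1492R).
#' @param pcr2_pairs List of second-round primer pairs (each a two-row
#'   primer tibble or list `list(fwd, rev)`).
#' @param min_overlap Minimum comparable columns of a usable overlap.
#' @param min_overlap_identity Minimum overlap identity in percent.
#' @param min_len,max_len Amplicon length bounds for both rounds.
#' @param params Alignment scoring parameters for the overlap merge.
#' @return A `consensus_assembly`: `fragment_ids`, `residues`, `length`.
#' @export
nested_consensus <- function(template, pcr1, pcr2_pairs, min_overlap = 50L,
                             min_overlap_identity = 99, min_len = 100L,
                             max_len = 100000L, params = align_params()) {
  tm <- as_seq_input(template, "template")
  pair_rows <- function(p) {
    if (is.data.frame(p)) {
      stopifnot(nrow(p) == 2L)
      list(fwd = p[1, ], rev = p[2, ])
    } else list(fwd = p[[1]], rev = p[[2]])
  }
  p1 <- pair_rows(pcr1)
  prods <- amplify(tm$residues, p1$fwd, p1$rev, min_len, max_len)
  if (nrow(prods) == 0L)
    stop("nested PCR failed: no first-round amplicon on template '",
         tm$id, "'", call. = FALSE)

  frags <- list()
  for (pi in seq_len(nrow(prods))) {
    for (qi in seq_along(pcr2_pairs)) {
      p2 <- pair_rows(pcr2_pairs[[qi]])
      sub <- amplify(prods$residues[pi], p2$fwd, p2$rev, min_len, max_len)
      if (nrow(sub)) {
        for (k in seq_len(nrow(sub))) {
          fid <- paste0(tm$id, "|", sub$fwd_primer[k], "-", sub$rev_primer[k],
                        "|", prods$start[pi] + sub$start[k])
          frags[[fid]] <- sub$residues[k]
        }
      }
    }
  }
  if (length(frags) == 0L)
    stop("nested PCR failed: no second-round amplicon on template '",
         tm$id, "'", call. = FALSE)
  frags <- frags[!duplicated(unlist(frags))]
  frag_ids <- as.list(names(frags))

  merge_two <- function(sa, sb) {
    r <- cpp_align_pair(sa, sb, params$match, params$mismatch,
                        params$gap_open, params$gap_extension)
    ga <- strsplit(r$aligned_a, "", fixed = TRUE)[[1]]
    gb <- strsplit(r$aligned_b, "", fixed = TRUE)[[1]]
    both <- ga != "-" & gb != "-"
    pid <- if (r$comparable > 0L) 100 * r$matches / r$comparable else NA_real_
    if (r$comparable < min_overlap || is.na(pid) ||
        pid < min_overlap_identity - 1e-9) return(NULL)
    out <- character(length(ga))
    for (i in seq_along(ga)) {
      a <- ga[i]; b <- gb[i]
      if (a == b) { out[i] <- a }
      else if (a == "-") { out[i] <- b }
      else if (b == "-") { out[i] <- a }
      else {
        inter <- bitwAnd(IUPAC_MASK[[a]], IUPAC_MASK[[b]])
        out[i] <- if (inter > 0L) mask_to_char(inter) else "N"
      }
    }
    list(seq = paste(out, collapse = ""), overlap = r$comparable)
  }

  while (length(frags) > 1L) {
    ids <- names(frags)
    best <- NULL
    for (i in seq_len(length(frags) - 1L)) {
      for (j in seq((i + 1L), length(frags))) {
        m <- merge_two(frags[[i]], frags[[j]])
        if (!is.null(m) &&
            (is.null(best) || m$overlap > best$overlap ||
             (m$overlap == best$overlap &&
              paste(ids[i], ids[j]) < paste(ids[best$i], ids[best$j])))) {
          best <- c(m, list(i = i, j = j))
        }
      }
    }
    if (is.null(best))
      stop("unmergeable fragments (overlap < ", min_overlap, " columns or < ",
           min_overlap_identity, "% identity): ",
           paste(unlist(frag_ids), collapse = ", "), call. = FALSE)
    frags[[best$i]] <- best$seq
    frag_ids[[best$i]] <- c(frag_ids[[best$i]], frag_ids[[best$j]])
    frags[[best$j]] <- NULL
    frag_ids[[best$j]] <- NULL
  }

  structure(list(
    fragment_ids = frag_ids[[1]],
    residues = frags[[1]],
    length = nchar(frags[[1]])
  ), class = "consensus_assembly")
}

#' @export
print.consensus_assembly <- function(x, ...) {
  cat("Consensus assembly of", length(x$fragment_ids), "fragment(s),",
      x$length, "bp\n")
  invisible(x)
}

#' Write primer sites as a BED-like TSV
#'
#' @param sites Site tibble from [find_primer_sites()].
#' @param template_id Template identifier for the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_sites <- function(sites, template_id, path) {
  out <- tibble::tibble(template = template_id, start = sites$start,
                        end = sites$end, primer = sites$primer_name,
                        strand = ifelse(sites$strand == "plus", "+", "-"),
                        mismatches = sites$mismatches)
  readr::write_tsv(out, path)
  invisible(path)
}
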