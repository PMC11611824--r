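# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).  Two symbols
# "match" iff their masks intersect; this is the matching rule used
# throughout (alignments, primer sites, consensus comparison).

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# mask value -> canonical IUPAC letter (index = mask)
MASK_CHAR <- c("A", "C", "M", "G", "R", "S", "V",
               "T", "W", "Y", "H", "K", "D", "B", "N")

iupac_mask <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- unname(IUPAC_MASK[chars])
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("non-IUPAC nucleotide character '", chars[bad],
         "' at position ", bad, call. = FALSE)
  }
  m
}

iupac_intersects <- function(mask_a, mask_b) {
  bitwAnd(mask_a, mask_b) > 0L
}

mask_to_char <- function(mask) MASK_CHAR[mask]

#' Reverse-complement a DNA sequence
#'
#' Handles all IUPAC degenerate codes (e.g. the complement of M = A/C is
#' K = G/T).
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AGAGTTTGATCMTGGCTCAG")
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Normalize residues: uppercase, RNA U -> T; error (with position) on
# anything outside the IUPAC alphabet.
normalize_residues <- function(x, ids = NULL) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGTMRWSYKVHDBN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    who <- if (is.null(ids)) paste0("sequence ", i) else paste0("'", ids[i], "'")
    stop("non-IUPAC nucleotide character '",
         substr(x[i], bad[i], bad[i]), "' at position ", bad[i],
         " in ", who, call. = FALSE)
  }
  x
}

check_unique_ids <- function(ids) {
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate sequence id '", dup, "'", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", ids))) {
    bad <- ids[grepl("[[:space:]]", ids)][1]
    stop("sequence id '", bad, "' contains whitespace", call. = FALSE)
  }
  invisible(ids)
}

SEQ_SOURCES <- c("enrichment", "literature", "silva", "genbank", "synthetic")

# Validate a record table (id, residues, source, site_id, description).
validate_records <- function(records, arg = "records") {
  if (!is.data.frame(records) || !all(c("id", "residues") %in% names(records)))
    stop(arg, " must be a data frame with at least columns 'id' and 'residues'",
         call. = FALSE)
  check_unique_ids(records$id)
  if (any(!nzchar(records$residues)))
    stop("empty residues for id '", records$id[!nzchar(records$residues)][1],
         "'", call. = FALSE)
  invisible(records)
}

ungapped_length <- function(residues) nchar(gsub("-", "", residues, fixed = TRUE))
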