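#' Build a sequence record table
#'
#' The central data structure of the package: one row per 16S rRNA gene
#' sequence, with a unique whitespace-free `id`, uppercase IUPAC DNA
#' `residues` (RNA `U` is mapped to `T`), a `source` tag, and optional
#' `site_id` / `description`.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of IUPAC DNA strings (no gaps).
#' @param source One of `"enrichment"`, `"literature"`, `"silva"`,
#'   `"genbank"`, `"synthetic"` (recycled).
#' @param site_id Optional site identifiers linking records to metadata.
#' @param description Optional free-text descriptions.
#' @return A tibble with columns `id`, `residues`, `source`, `site_id`,
#'   `description`.
#' @export
#' @examples
#' seq_records(c("a", "b"), c("acgt", "ACGU"))
seq_records <- function(id, residues, source = "synthetic",
                        site_id = NA_character_,
                        description = NA_character_) {
  id <- as.character(id)
  if (length(id) == 0L) {
    return(tibble::tibble(id = character(), residues = character(),
                          source = character(), site_id = character(),
                          description = character()))
  }
  check_unique_ids(id)
  residues <- normalize_residues(as.character(residues), id)
  source <- match.arg(source, SEQ_SOURCES, several.ok = TRUE)
  out <- tibble::tibble(
    id = id,
    residues = residues,
    source = rep_len(source, length(id)),
    site_id = rep_len(as.character(site_id), length(id)),
    description = rep_len(as.character(description), length(id))
  )
  validate_records(out)
  out
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param source Source tag recorded for every sequence.
#' @return A record tibble (see [seq_records()]); empty for an empty file.
#'   The id is the first whitespace-delimited token of each header, the
#'   remainder is kept as `description`.
#' @export
read_fasta <- function(path, source = "genbank") {
  source <- match.arg(source, SEQ_SOURCES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(seq_records(character(), character(), source = character()))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    return(seq_records(character(), character(), source = character()))
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers),
                 NA_character_)
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "' in ", path,
         call. = FALSE)
  seq_records(ids, as.character(set), source = source, description = desc)
}

#' Write a record table to FASTA
#'
#' @param records Record tibble.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  validate_records(records)
  headers <- ifelse(
    !is.na(records$description) & nzchar(records$description),
    paste(records$id, records$description),
    records$id
  )
  set <- Biostrings::DNAStringSet(setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

SITE_COLUMNS <- c("site_id", "location_name", "latitude", "longitude",
                  "habitat", "salinity", "water_depth_m", "sulfide_class")

#' Read a site-metadata table
#'
#' Expects a UTF-8, tab-delimited file with "." as decimal separator and a
#' header row containing at least the columns `site_id`, `location_name`,
#' `latitude`, `longitude`, `habitat`, `salinity`, `water_depth_m`,
#' `sulfide_class`.  Coordinates are signed decimal degrees (southern /
#' western hemisphere negative).  Unknown sulfide classes become
#' `"unknown"`.
#'
#' A transcription of the enrichment-study sampling table ships with the
#' package: `system.file("extdata", "sites_table1.tsv", package = "cabletax")`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the columns above; empty for a header-only file.
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(SITE_COLUMNS, names(raw))
  if (length(missing))
    stop("missing required column '", missing[1], "' in ", path, call. = FALSE)
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(
      site_id = character(), location_name = character(),
      latitude = double(), longitude = double(), habitat = character(),
      salinity = double(), water_depth_m = double(), sulfide_class = character()
    )
    return(out)
  }
  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v) & any(!is.na(x) & nzchar(x))) {
      bad <- which(is.na(v) & !is.na(x) & nzchar(x))
      if (length(bad))
        stop("unparsable ", col, " '", x[bad[1]], "' in row ", bad[1],
             " of ", path, call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    site_id = raw$site_id,
    location_name = raw$location_name,
    latitude = num(raw$latitude, "latitude"),
    longitude = num(raw$longitude, "longitude"),
    habitat = raw$habitat,
    salinity = num(raw$salinity, "salinity"),
    water_depth_m = num(raw$water_depth_m, "water_depth_m"),
    sulfide_class = ifelse(
      is.na(raw$sulfide_class) | !raw$sulfide_class %in% c("low", "high"),
      "unknown", raw$sulfide_class
    )
  )
  if (anyDuplicated(out$site_id))
    stop("duplicate site_id '", out$site_id[duplicated(out$site_id)][1],
         "' in ", path, call. = FALSE)
  if (any(out$latitude < -90 | out$latitude > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90] in ", path, call. = FALSE)
  if (any(out$longitude < -180 | out$longitude > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180] in ", path, call. = FALSE)
  if (any(out$salinity < 0, na.rm = TRUE))
    stop("negative salinity in ", path, call. = FALSE)
  out
}

#' Read a primer table
#'
#' Tab-delimited with columns `name`, `sequence` (IUPAC, degenerate codes
#' allowed) and `orientation` (`forward` / `reverse`).  The primer set used
#' to amplify full-length 16S rRNA genes from single cable bacterium
#' filaments ships as
#' `system.file("extdata", "primers_table2.tsv", package = "cabletax")`;
#' see also [cable_primers()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name`, `sequence`, `orientation`, `length`.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("name", "sequence", "orientation")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing required column '", missing[1], "' in ", path, call. = FALSE)
  primer_table(raw$name, raw$sequence, raw$orientation)
}

primer_table <- function(name, sequence, orientation) {
  sequence <- normalize_residues(gsub(" ", "", sequence), name)
  if (any(!nzchar(sequence))) stop("empty primer sequence", call. = FALSE)
  if (!all(orientation %in% c("forward", "reverse")))
    stop("primer orientation must be 'forward' or 'reverse'", call. = FALSE)
  tibble::tibble(name = name, sequence = sequence, orientation = orientation,
                 length = nchar(sequence))
}

#' The nested-PCR primer set
#'
#' The six primers used for nested PCR on single cable bacterium filaments:
#' universal primers 27F and 1492R (first round, complete 16S rRNA gene),
#' the Desulfobulbaceae-specific pair DSBB280wF / DSBB+1297R, and the
#' alternative forward primers 39Fc and 64Fc (shortened / edited variants
#' of 39F and 64F without degenerate bases).
#'
#' @return A primer tibble (`name`, `sequence`, `orientation`, `length`).
#' @export
#' @examples
#' cable_primers()
cable_primers <- function() {
  primer_table(
    name = c("27F", "39Fc", "64Fc", "1492R", "DSBB280wF", "DSBB+1297R"),
    sequence = c(
      "AGAGTTTGATCMTGGCTCAG",
      "GGCTCAGAACGAACGCTG",
      "RTGCTTAACACATGCAAGTCG",
      "GGYTACCTTGTTACGACTT",
      "CGATGGTTARCGGGTCTG",
      "AGACTCCAATCCGGACTGA"
    ),
    orientation = c("forward", "forward", "forward", "reverse",
                    "forward", "reverse")
  )
}

#' Read a phylogenetic tree from a Newick file
#'
#' Import hook for externally computed trees (e.g. maximum-likelihood trees
#' from IQ-TREE); any tree-consuming stage of the pipeline accepts such a
#' tree in place of the built-in neighbor-joining tree.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

parse_newick <- function(txt) {
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: not a valid tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("Newick parse error: duplicate leaf label '",
         tree$tip.label[duplicated(tree$tip.label)][1], "'", call. = FALSE)
  tree
}

#' Write a phylogenetic tree to a Newick file
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves them to well below 1e-9.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  writeLines(deparse_newick(tree), path)
  invisible(path)
}

# Own serializer: ape::write.tree rounds branch lengths harder than the
# 1e-9 round-trip guarantee we document.
deparse_newick <- function(tree) {
  nt <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.15g", x)
  rec <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      bl <- if (is.null(tree$edge.length)) "" else
        paste0(":", fmt(tree$edge.length[r]))
      paste0(rec(child), bl)
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}
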