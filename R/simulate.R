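#' Specification of a synthetic cable-bacteria radiation
#'
#' Describes a two-level genus/species radiation with controlled pairwise
#' identity bands.  Divergence parameters are target *pairwise* proportions
#' of differing sites: sequences within one species differ by about
#' `d_within_species`, species within one genus by `d_between_species`,
#' genera by `d_between_genera`.  The defaults straddle the species
#' (98.7%) and genus (94.5%) identity cutoffs with at least one identity
#' point of separation on either side, so that threshold clustering can
#' recover the planted structure exactly.
#'
#' The generator uses a two-class site model: half of the root sequence
#' (in blocks of `block_length` bp, plus all primer windows) is conserved
#' and never mutates within the clade, emulating the conserved regions of
#' real 16S rRNA genes; all substitutions fall on the variable columns.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param root_length Root sequence length in bp (default 1,500, a
#'   full-length 16S gene).
#' @param n_genera Number of genus-level groups.
#' @param species_per_genus Integer (recycled) or vector of per-genus
#'   species counts.
#' @param seqs_per_species Integer (recycled) or vector (one entry per
#'   species, in genus order) of sequences per species.
#' @param d_within_species,d_between_species,d_between_genera Target
#'   pairwise substitution proportions; must satisfy
#'   `d_within < 0.013 < d_between_species < 0.055 < d_between_genera`.
#' @param d_offclade Divergence of off-clade contaminants and the
#'   outgroup (must exceed `d_between_genera`).
#' @param indel_rate Per-site probability of a single-event indel
#'   (geometric length, mean 3) on each terminal branch.  Default 0: the
#'   radiation is substitution-only, which keeps realized identities
#'   verifiable by exact position-wise comparison.
#' @param n_offclade Number of off-clade contaminant lineages.
#' @param n_short Number of records later truncated to < 800 bp by
#'   [inject_artifacts()].
#' @param n_conserved_violators Number of records later given a 20-bp
#'   deletion inside a conserved block by [inject_artifacts()].
#' @param conserved_fraction Fraction of the root that is conserved.
#' @param block_length Length of conserved/variable blocks (bp).
#' @param n_profile_refs Size of the emitted saturated reference
#'   alignment used for conserved-region profiling.
#' @param max_attempts Bounded rejection sampling: draws are repeated
#'   until the realized identity bands respect the declared divergence
#'   ordering, at most this many times.
#' @return A `radiation_spec` list.
#' @export
radiation_spec <- function(seed = 1L, root_length = 1500L, n_genera = 2L,
                           species_per_genus = 2L, seqs_per_species = 2L,
                           d_within_species = 0.006,
                           d_between_species = 0.035,
                           d_between_genera = 0.085,
                           d_offclade = 0.25,
                           indel_rate = 0,
                           n_offclade = 0L, n_short = 0L,
                           n_conserved_violators = 0L,
                           conserved_fraction = 0.5, block_length = 50L,
                           n_profile_refs = 12L, max_attempts = 100L) {
  stopifnot(
    root_length >= 1400L, n_genera >= 1L,
    d_within_species < (100 - 98.7) / 100,
    (100 - 98.7) / 100 < d_between_species,
    d_between_species < (100 - 94.5) / 100,
    (100 - 94.5) / 100 < d_between_genera,
    d_between_genera < d_offclade,
    indel_rate >= 0, indel_rate <= 1,
    conserved_fraction > 0, conserved_fraction < 1,
    max_attempts >= 1L
  )
  species_per_genus <- rep_len(as.integer(species_per_genus), n_genera)
  n_species <- sum(species_per_genus)
  seqs_per_species <- rep_len(as.integer(seqs_per_species), n_species)
  stopifnot(all(species_per_genus >= 1L), all(seqs_per_species >= 1L))
  structure(list(
    seed = as.integer(seed), root_length = as.integer(root_length),
    n_genera = as.integer(n_genera), species_per_genus = species_per_genus,
    seqs_per_species = seqs_per_species,
    d_within_species = d_within_species,
    d_between_species = d_between_species,
    d_between_genera = d_between_genera,
    d_offclade = d_offclade, indel_rate = indel_rate,
    n_offclade = as.integer(n_offclade), n_short = as.integer(n_short),
    n_conserved_violators = as.integer(n_conserved_violators),
    conserved_fraction = conserved_fraction,
    block_length = as.integer(block_length),
    n_profile_refs = as.integer(n_profile_refs),
    max_attempts = as.integer(max_attempts)
  ), class = "radiation_spec")
}

#' The packaged "survey" scenario
#'
#' Six genus-level groups with species counts `c(14, 3, 1, 2, 35, 35)`
#' (90 species in total), 38 of which are singleton clades with a single
#' sequence; all other species carry two sequences (142 records).  Which
#' species are singletons is drawn from the seed.
#'
#' @param seed Integer seed.
#' @return A `radiation_spec`.
#' @export
scenario_survey <- function(seed = 1L) {
  spg <- c(14L, 3L, 1L, 2L, 35L, 35L)
  n_species <- sum(spg)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  singles <- sample.int(n_species, 38L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sps <- rep(2L, n_species)
  sps[singles] <- 1L
  radiation_spec(seed = seed, n_genera = 6L, species_per_genus = spg,
                 seqs_per_species = sps)
}

BASES <- c("A", "C", "G", "T")

# mutate integer-coded sequence at k distinct variable positions
mutate_seq <- function(x, k, var_pos) {
  if (k == 0L) return(x)
  pos <- if (length(var_pos) == 1L) var_pos else sample(var_pos, k)
  shift <- sample.int(3L, k, replace = TRUE)
  x[pos] <- ((x[pos] - 1L + shift) %% 4L) + 1L
  x
}

# expand degenerate codes to the alphabetically first concrete base
concrete_expand <- function(seq) {
  masks <- iupac_mask(seq)
  first_base <- function(m) BASES[which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)[1]]
  paste(vapply(masks, first_base, character(1)), collapse = "")
}

#' Simulate a cable-bacteria 16S radiation with ground truth
#'
#' Draws a random root sequence, plants the four nested-PCR primer
#' windows (27F at the 5' end, DSBB280wF and DSBB+1297R internally at
#' their E. coli-like coordinates, 1492R at the 3' end; all
#' mutation-masked), and evolves the root down a genus > species >
#' individual tree with fixed per-branch substitution counts on the
#' variable columns.  Off-clade contaminants branch from the root at
#' `d_offclade / 2`, the appended outgroup at `d_offclade`.  Realized
#' identity bands are verified by exact position-wise comparison and the
#' draw is rejected and resampled (bounded) if any band is violated.
#'
#' @param spec A [radiation_spec()].
#' @return A `cable_simulation` list: `records` (in-clade + contaminants),
#'   `outgroup` (one-row record tibble), `profile_refs` (saturated
#'   reference alignment for [build_conserved_profile()]), `truth`
#'   (record_id, genus, species, artifact), `queries` (one trusted record
#'   id per genus), `tree` (the planted [ape::phylo]), `primer_windows`,
#'   `conserved` (logical per root position), and `spec`.
#' @export
simulate_radiation <- function(spec) {
  stopifnot(inherits(spec, "radiation_spec"))
  set.seed(spec$seed)
  L <- spec$root_length

  primers <- cable_primers()
  pseq <- setNames(primers$sequence, primers$name)
  w27 <- concrete_expand(pseq[["27F"]])
  w280 <- concrete_expand(pseq[["DSBB280wF"]])
  w1297 <- revcomp(concrete_expand(pseq[["DSBB+1297R"]]))
  w1492 <- revcomp(concrete_expand(pseq[["1492R"]]))
  windows <- tibble::tibble(
    primer = c("27F", "DSBB280wF", "DSBB+1297R", "1492R"),
    start = c(0L, 262L, 1297L - nchar(w1297), L - nchar(w1492)),
    end = c(nchar(w27), 262L + nchar(w280), 1297L, L),
    strand = c("plus", "plus", "minus", "minus")
  )

  # conserved blocks: alternate conserved/variable runs of block_length
  conserved <- rep(rep(c(TRUE, FALSE), length.out = ceiling(L / spec$block_length)),
                   each = spec$block_length)[seq_len(L)]
  n_cons_target <- round(spec$conserved_fraction * L)
  if (sum(conserved) > n_cons_target) {
    flip <- which(conserved)
    conserved[tail(flip, sum(conserved) - n_cons_target)] <- FALSE
  }
  for (k in seq_len(nrow(windows)))
    conserved[(windows$start[k] + 1L):windows$end[k]] <- TRUE
  var_pos <- which(!conserved)

  n_species <- sum(spec$species_per_genus)
  genus_of_species <- rep(seq_len(spec$n_genera), spec$species_per_genus)
  bi <- max(1L, round(spec$d_within_species / 2 * L))
  bs <- max(1L, round((spec$d_between_species - spec$d_within_species) / 2 * L))
  bg <- max(0L, round((spec$d_between_genera - spec$d_between_species) / 2 * L))
  bcont <- round(spec$d_offclade / 2 * L)
  bout <- min(round(spec$d_offclade * L), length(var_pos) - 1L)

  window_ints <- lapply(seq_len(nrow(windows)), function(k) {
    list(at = (windows$start[k] + 1L):windows$end[k],
         val = match(strsplit(c(w27, w280, w1297, w1492)[k], "")[[1]], BASES))
  })

  for (attempt in seq_len(spec$max_attempts)) {
    root <- sample.int(4L, L, replace = TRUE)
    for (wi in window_ints) root[wi$at] <- wi$val

    seqs <- vector("list", sum(spec$seqs_per_species))
    rec_ids <- character(length(seqs))
    rec_genus <- integer(length(seqs))
    rec_species <- integer(length(seqs))
    idx <- 0L
    sp_global <- 0L
    for (g in seq_len(spec$n_genera)) {
      ganc <- mutate_seq(root, bg, var_pos)
      for (s in seq_len(spec$species_per_genus[g])) {
        sp_global <- sp_global + 1L
        sanc <- mutate_seq(ganc, bs, var_pos)
        for (r in seq_len(spec$seqs_per_species[sp_global])) {
          idx <- idx + 1L
          seqs[[idx]] <- mutate_seq(sanc, bi, var_pos)
          rec_ids[idx] <- sprintf("CB%02d_S%03d_%02d", g, sp_global, r)
          rec_genus[idx] <- g
          rec_species[idx] <- sp_global
        }
      }
    }
    n_inclade <- idx

    cont_seqs <- lapply(seq_len(spec$n_offclade), function(k)
      mutate_seq(root, bcont, var_pos))
    out_seq <- mutate_seq(root, bout, var_pos)

    if (spec$indel_rate > 0) {
      seqs <- lapply(seqs, apply_indels, rate = spec$indel_rate,
                     var_pos = var_pos)
    }

    # --- verify realized identity bands (exact, position-wise) ----------
    M <- do.call(rbind, seqs[seq_len(n_inclade)])
    ok <- TRUE
    if (spec$indel_rate == 0 && n_inclade > 1L) {
      pid <- hamming_identity(M)
      same_sp <- outer(rec_species[1:n_inclade], rec_species[1:n_inclade], "==")
      same_g <- outer(rec_genus[1:n_inclade], rec_genus[1:n_inclade], "==")
      ut <- upper.tri(pid)
      w_within <- ut & same_sp
      w_between_sp <- ut & same_g & !same_sp
      w_between_g <- ut & !same_g
      if (any(w_within) && min(pid[w_within]) < 98.7 + 0.3) ok <- FALSE
      if (any(w_between_sp) &&
          (max(pid[w_between_sp]) > 98.7 - 1 ||
           min(pid[w_between_sp]) < 94.5 + 0.8)) ok <- FALSE
      if (any(w_between_g) && max(pid[w_between_g]) > 94.5 - 1) ok <- FALSE
    }
    if (ok) break
    if (attempt == spec$max_attempts)
      stop("infeasible radiation spec: identity bands not attained after ",
           spec$max_attempts, " attempts", call. = FALSE)
  }

  to_str <- function(x) paste(BASES[x], collapse = "")
  cont_ids <- if (spec$n_offclade > 0L)
    sprintf("CONT_%02d", seq_len(spec$n_offclade)) else character()
  records <- seq_records(
    id = c(rec_ids[seq_len(n_inclade)], cont_ids),
    residues = c(vapply(seqs[seq_len(n_inclade)], to_str, character(1)),
                 vapply(cont_seqs, to_str, character(1))),
    source = "synthetic"
  )
  truth <- tibble::tibble(
    record_id = records$id,
    genus = c(sprintf("G%d", rec_genus[seq_len(n_inclade)]),
              rep(NA_character_, length(cont_ids))),
    species = c(sprintf("S%03d", rec_species[seq_len(n_inclade)]),
                rep(NA_character_, length(cont_ids))),
    artifact = c(rep("none", n_inclade),
                 rep("offclade", length(cont_ids)))
  )
  outgroup <- seq_records("OUTGROUP", to_str(out_seq), source = "synthetic")

  refs <- vapply(seq_len(spec$n_profile_refs), function(k) {
    x <- root
    x[var_pos] <- sample.int(4L, length(var_pos), replace = TRUE)
    to_str(x)
  }, character(1))
  profile_refs <- seq_records(sprintf("REF%02d", seq_len(spec$n_profile_refs)),
                              refs, source = "synthetic")

  queries <- vapply(seq_len(spec$n_genera), function(g)
    rec_ids[which(rec_genus == g)[1]], character(1))

  tree <- planted_tree(rec_ids[seq_len(n_inclade)],
                       rec_genus[seq_len(n_inclade)],
                       rec_species[seq_len(n_inclade)],
                       cont_ids, bi / L, bs / L, bg / L, bcont / L, bout / L)

  structure(list(
    records = records, outgroup = outgroup, profile_refs = profile_refs,
    truth = truth, queries = queries, tree = tree,
    primer_windows = windows, conserved = conserved, spec = spec
  ), class = "cable_simulation")
}

# exact percent identities for equal-length ungapped integer matrices
hamming_identity <- function(M) {
  L <- ncol(M)
  matches <- matrix(0, nrow(M), nrow(M))
  for (b in 1:4) {
    I <- (M == b) * 1
    matches <- matches + tcrossprod(I)
  }
  100 * matches / L
}

apply_indels <- function(x, rate, var_pos) {
  n_events <- stats::rbinom(1L, length(var_pos), rate)
  if (n_events == 0L) return(x)
  for (k in seq_len(n_events)) {
    len <- min(stats::rgeom(1L, 1 / 3) + 1L, 10L)
    at <- sample(var_pos[var_pos <= length(x) - len], 1L)
    if (stats::runif(1) < 0.5) {
      x <- x[-(at:(at + len - 1L))]            # deletion
    } else {
      x <- append(x, sample.int(4L, len, replace = TRUE), after = at)
    }
  }
  x
}

# Build the planted genus > species > individual topology as Newick.
# Unary nodes (single-species genera, singleton species) are collapsed by
# summing branch lengths, so the tree is the true generating tree.
planted_tree <- function(ids, genus, species, cont_ids,
                         li, ls, lg, lcont, lout) {
  fmt <- function(x) sprintf("%.10g", x)
  node <- function(parts, bls)
    paste0("(", paste0(parts, ":", vapply(bls, fmt, character(1)),
                       collapse = ","), ")")
  genus_parts <- character(0); genus_bl <- numeric(0)
  for (g in unique(genus)) {
    sp_str <- character(0); sp_bl <- numeric(0)
    for (s in unique(species[genus == g])) {
      tips <- ids[species == s]
      if (length(tips) > 1L) {
        sp_str <- c(sp_str, node(tips, rep(li, length(tips))))
        sp_bl <- c(sp_bl, ls)
      } else {
        sp_str <- c(sp_str, tips)
        sp_bl <- c(sp_bl, li + ls)
      }
    }
    if (length(sp_str) > 1L) {
      genus_parts <- c(genus_parts, node(sp_str, sp_bl))
      genus_bl <- c(genus_bl, lg)
    } else {
      genus_parts <- c(genus_parts, sp_str)
      genus_bl <- c(genus_bl, sp_bl + lg)
    }
  }
  parts <- genus_parts; bls <- genus_bl
  if (length(cont_ids)) {
    parts <- c(parts, cont_ids)
    bls <- c(bls, rep(lcont, length(cont_ids)))
  }
  parts <- c(parts, "OUTGROUP"); bls <- c(bls, lout)
  ape::read.tree(text = paste0(node(parts, bls), ";"))
}

#' @export
print.cable_simulation <- function(x, ...) {
  cat("Synthetic cable-bacteria radiation (seed ", x$spec$seed, "): ",
      nrow(x$records), " records, ", x$spec$n_genera, " genera, ",
      sum(x$spec$species_per_genus), " species, ",
      sum(x$truth$artifact == "offclade"), " off-clade contaminant(s)\n",
      sep = "")
  invisible(x)
}

#' Inject curation-target artifacts into a simulation
#'
#' Truncates `n_short` records to random lengths in `[300, 799]` bp and
#' introduces a 20-bp deletion inside a conserved block (away from primer
#' windows) into `n_conserved_violators` records, tagging the ground
#' truth accordingly.  Victims are drawn from in-clade, non-query records.
#'
#' @param sim A `cable_simulation`.
#' @return The modified simulation.
#' @export
inject_artifacts <- function(sim) {
  stopifnot(inherits(sim, "cable_simulation"))
  spec <- sim$spec
  n_art <- spec$n_short + spec$n_conserved_violators
  if (n_art == 0L) return(sim)
  set.seed(spec$seed + 500009L)
  pool <- sim$truth$record_id[sim$truth$artifact == "none" &
                                !sim$truth$record_id %in% sim$queries]
  if (length(pool) < n_art)
    stop("requested ", n_art, " artifact records but only ", length(pool),
         " eligible records exist", call. = FALSE)
  victims <- sample(pool, n_art)
  short_ids <- head(victims, spec$n_short)
  viol_ids <- tail(victims, spec$n_conserved_violators)

  rec <- sim$records
  for (id in short_ids) {
    i <- which(rec$id == id)
    len <- sample(300:799, 1L)
    rec$residues[i] <- substr(rec$residues[i], 1L, len)
    sim$truth$artifact[sim$truth$record_id == id] <- "short"
  }
  if (spec$n_conserved_violators > 0L) {
    runs <- rle(sim$conserved)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    in_window <- function(a, b) any(a <= sim$primer_windows$end &
                                      b >= sim$primer_windows$start + 1L)
    cand <- which(runs$values & runs$lengths >= 28L)
    cand <- cand[!vapply(cand, function(k) in_window(starts[k], ends[k]),
                         logical(1))]
    if (!length(cand))
      stop("no conserved block available for deletion artifacts", call. = FALSE)
    for (id in viol_ids) {
      k <- if (length(cand) == 1L) cand else sample(cand, 1L)
      mid <- floor((starts[k] + ends[k]) / 2)
      del_start <- mid - 10L
      i <- which(rec$id == id)
      rec$residues[i] <- paste0(substr(rec$residues[i], 1L, del_start - 1L),
                                substr(rec$residues[i], del_start + 20L,
                                       nchar(rec$residues[i])))
      sim$truth$artifact[sim$truth$record_id == id] <- "conserved_violation"
    }
  }
  sim$records <- rec
  sim
}

#' Attach site metadata to a simulation
#'
#' Creates sampling sites spanning all four salinity categories
#' (freshwater, brackish, marine, hypersaline) and assigns every species
#' to a home site by genus-level salinity affinity.  The `"survey"`
#' scenario additionally plants one site hosting species from three
#' different genus-level groups and a second multi-genus site, mirroring
#' the observed co-occurrence structure; all other clades stay endemic to
#' a single site.
#'
#' @param sim A `cable_simulation`.
#' @param scenario `"default"` or `"survey"`.
#' @return The simulation with `metadata` (site tibble) added and
#'   `records$site_id` filled for in-clade records.
#' @export
make_metadata <- function(sim, scenario = c("default", "survey")) {
  stopifnot(inherits(sim, "cable_simulation"))
  scenario <- match.arg(scenario)
  spec <- sim$spec
  set.seed(spec$seed + 900007L)
  metadata <- tibble::tibble(
    site_id = c("SFW1", "SBK1", "SBK2", "SMA1", "SMA2", "SHY1"),
    location_name = c("Synthetic lake", "Synthetic estuary A",
                      "Synthetic estuary B", "Synthetic coastal zone",
                      "Synthetic salt marsh", "Synthetic saline lagoon"),
    latitude = c(56.1, 37.43, -37.83, 51.27, 51.26, 40.64),
    longitude = c(10.2, 13.25, 145.03, 2.9, 4.1, 0.75),
    habitat = c("freshwater lake sediment", "estuarine river bank",
                "estuary with salinity fluctuations", "subtidal marine mud",
                "intertidal salt marsh creek", "evaporitic lagoon"),
    salinity = c(0.3, 2, 17, 30, 33, 40),
    water_depth_m = c(1, 0.5, 2, 10, 0.5, 0.3),
    sulfide_class = c("unknown", "low", "high", "low", "high", "unknown")
  )
  n_species <- sum(spec$species_per_genus)
  genus_of_species <- rep(seq_len(spec$n_genera), spec$species_per_genus)
  pref <- (genus_of_species - 1L) %% nrow(metadata) + 1L
  home <- metadata$site_id[pref]
  if (scenario == "survey" && spec$n_genera >= 3L) {
    gpick <- tail(seq_len(spec$n_genera), 3L)
    tri <- vapply(gpick, function(g) which(genus_of_species == g)[1],
                  integer(1))
    home[tri] <- "SMA1"
    gpick2 <- head(seq_len(spec$n_genera), 2L)
    duo <- vapply(gpick2, function(g) {
      w <- which(genus_of_species == g)
      w[min(2L, length(w))]
    }, integer(1))
    home[duo] <- "SBK2"
  }
  sp_idx <- match(sim$truth$species, sprintf("S%03d", seq_len(n_species)))
  sim$records$site_id <- ifelse(is.na(sp_idx), NA_character_, home[sp_idx])
  sim$metadata <- metadata
  sim$site_of_species <- tibble::tibble(
    species = sprintf("S%03d", seq_len(n_species)), site_id = home)
  sim
}
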