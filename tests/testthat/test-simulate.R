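test_that("simulation is deterministic given the seed", {
  s1 <- small_sim(seed = 4)
  s2 <- small_sim(seed = 4)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$outgroup$residues, s2$outgroup$residues)
  s3 <- small_sim(seed = 5)
  expect_false(identical(s1$records$residues, s3$records$residues))
})

test_that("realized identity bands straddle both taxonomic cutoffs", {
  sim <- small_sim(seed = 8)   # 2 genera x 2 species x 2 sequences
  im <- identity_matrix(sim$records)
  tr <- sim$truth
  for (i in 1:(nrow(tr) - 1)) {
    for (j in (i + 1):nrow(tr)) {
      pid <- im[tr$record_id[i], tr$record_id[j]]
      if (tr$species[i] == tr$species[j]) {
        expect_gte(pid, 98.7)
      } else if (tr$genus[i] == tr$genus[j]) {
        expect_lt(pid, 98.7)
        expect_gte(pid, 94.5)
      } else {
        expect_lt(pid, 94.5)
      }
    }
  }
})

test_that("an invalid divergence ordering is rejected up front", {
  expect_error(radiation_spec(d_within_species = 0.02), "d_within_species")
  expect_error(radiation_spec(d_between_genera = 0.03))
  expect_error(radiation_spec(d_offclade = 0.05))
})

test_that("off-clade contaminants fall outside the seed MRCA", {
  sim <- simulate_radiation(radiation_spec(seed = 6, n_genera = 2,
                                           species_per_genus = 2,
                                           seqs_per_species = 2,
                                           n_offclade = 1L))
  im <- identity_matrix(rbind(sim$records, sim$outgroup))
  tr <- nj_tree(identity_to_distance(im))
  q <- clade_query(tr, "OUTGROUP", sim$queries)
  expect_false("CONT_01" %in% q$tips)
  expect_true(all(sim$truth$record_id[sim$truth$artifact == "none"] %in%
                    q$tips))
})

test_that("artifact injection is count-exact and closes the filter loop", {
  spec <- radiation_spec(seed = 12, n_genera = 2, species_per_genus = 3,
                         seqs_per_species = 3, n_short = 3L,
                         n_conserved_violators = 2L)
  sim <- inject_artifacts(simulate_radiation(spec))
  short_ids <- sim$truth$record_id[sim$truth$artifact == "short"]
  viol_ids <- sim$truth$record_id[sim$truth$artifact == "conserved_violation"]
  expect_length(short_ids, 3L)
  expect_length(viol_ids, 2L)
  lens <- nchar(sim$records$residues[match(short_ids, sim$records$id)])
  expect_true(all(lens >= 300 & lens < 800))
  # the planted deletions are exactly what the conserved filter flags
  prof <- build_conserved_profile(sim$profile_refs)
  flags <- flag_conserved_violations(
    sim$records[!sim$records$id %in% short_ids, ], prof)
  expect_setequal(flags$id[flags$flagged], viol_ids)
})

test_that("an all-zero artifact spec leaves records unchanged", {
  sim <- small_sim(seed = 4)
  expect_identical(inject_artifacts(sim)$records, sim$records)
})

test_that("artifact demand beyond the eligible pool errors", {
  spec <- radiation_spec(seed = 12, n_genera = 2, species_per_genus = 1,
                         seqs_per_species = 1, n_short = 5L)
  expect_error(inject_artifacts(simulate_radiation(spec)),
               "eligible records")
})

test_that("site metadata spans all salinity categories deterministically", {
  sim <- make_metadata(small_sim(seed = 4))
  expect_setequal(unique(classify_salinity(sim$metadata$salinity)),
                  c("freshwater", "brackish", "marine", "hypersaline"))
  expect_true(all(!is.na(sim$records$site_id)))
  sim2 <- make_metadata(small_sim(seed = 4))
  expect_identical(sim$records$site_id, sim2$records$site_id)
})

test_that("the survey metadata scenario plants a multi-genus site", {
  sim <- simulate_radiation(radiation_spec(seed = 4, n_genera = 4,
                                           species_per_genus = 3,
                                           seqs_per_species = 1))
  sim <- make_metadata(sim, scenario = "survey")
  joined <- dplyr::left_join(sim$truth, sim$records[, c("id", "site_id")],
                             by = c(record_id = "id"))
  per_site <- dplyr::summarise(dplyr::group_by(joined, .data$site_id),
                               n_genera = dplyr::n_distinct(.data$genus))
  expect_gte(max(per_site$n_genera), 3L)
})

test_that("the planted tree carries every record and the outgroup", {
  sim <- simulate_radiation(radiation_spec(seed = 10, n_genera = 3,
                                           species_per_genus = c(2, 1, 3),
                                           seqs_per_species = c(2, 1, 1, 3, 1, 2),
                                           n_offclade = 1L))
  expect_setequal(sim$tree$tip.label, c(sim$records$id, "OUTGROUP"))
  expect_s3_class(sim$tree, "phylo")
})

test_that("the survey scenario has the published structure", {
  spec <- scenario_survey(seed = 3)
  expect_equal(spec$n_genera, 6L)
  expect_equal(spec$species_per_genus, c(14L, 3L, 1L, 2L, 35L, 35L))
  expect_equal(sum(spec$seqs_per_species == 1L), 38L)
  expect_equal(sum(spec$seqs_per_species), 142L)
  # reproducible and seed-dependent singleton placement
  expect_identical(scenario_survey(seed = 3)$seqs_per_species,
                   spec$seqs_per_species)
})
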