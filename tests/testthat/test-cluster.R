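im_from <- function(ids, fill) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  class(m) <- c("cb_identity", class(m))
  m
}

test_that("species clustering respects the 98.7 cutoff", {
  m <- im_from(c("a", "b"), 99)
  expect_equal(dplyr::n_distinct(cluster_species(m)$clade_id), 1L)
  m2 <- im_from(c("a", "b"), 98)
  expect_equal(dplyr::n_distinct(cluster_species(m2)$clade_id), 2L)
  # boundary: exactly at the cutoff means "at least 98.7" -> one clade
  m3 <- im_from(c("a", "b"), 98.7)
  expect_equal(dplyr::n_distinct(cluster_species(m3)$clade_id), 1L)
})

test_that("complete linkage splits chains that single linkage joins", {
  ids <- c("a", "b", "c")
  m <- im_from(ids, 99)
  m["a", "c"] <- m["c", "a"] <- 98
  sp <- cluster_species(m, linkage = "complete")
  grp <- split(sp$id, sp$clade_id)
  expect_identical(canon_partition(grp), canon_partition(list(c("a", "b"), "c")))
  sl <- cluster_species(m, linkage = "single")
  expect_equal(dplyr::n_distinct(sl$clade_id), 1L)
})

test_that("species clustering matches the brute-force linkage oracle", {
  set.seed(91)
  for (k in 1:40) {
    n <- sample(4:10, 1)
    ids <- sprintf("s%02d", seq_len(n))
    m <- matrix(100, n, n, dimnames = list(ids, ids))
    v <- runif(n * (n - 1) / 2, 96.5, 100)
    m[lower.tri(m)] <- v
    m <- pmin(m, t(m)); diag(m) <- 100
    for (lk in c("complete", "single")) {
      got <- cluster_species(m, cutoff = 98.7, linkage = lk)
      want <- oracle_linkage_clusters(100 - m, 100 - 98.7, lk)
      expect_identical(canon_partition(split(got$id, got$clade_id)),
                       canon_partition(want))
    }
  }
})

test_that("tie-free instances agree with stats::hclust", {
  set.seed(97)
  n <- 9
  ids <- sprintf("s%02d", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- runif(n * (n - 1) / 2, 96, 100)
  m <- pmin(m, t(m)); diag(m) <- 100
  got <- cluster_species(m, cutoff = 98.7)
  hc <- stats::hclust(stats::as.dist(100 - m), method = "complete")
  want <- stats::cutree(hc, h = 100 - 98.7)
  expect_identical(canon_partition(split(ids, got$clade_id[match(ids, got$id)])),
                   canon_partition(split(ids, want)))
})

test_that("raising the species cutoff never decreases the clade count", {
  set.seed(101)
  sim <- small_sim(seed = 13)
  im <- identity_matrix(sim$records)
  counts <- vapply(c(94, 96, 98.7, 99.5, 99.9), function(cut)
    dplyr::n_distinct(cluster_species(im, cutoff = cut)$clade_id), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("clade finalization picks representatives and validity", {
  rec <- seq_records(c("x", "y", "z", "solo"),
                     c(random_dna(1500), random_dna(900), random_dna(1500),
                       random_dna(1199)))
  asg <- tibble::tibble(id = c("x", "y", "z", "solo"),
                        clade_id = c("SC001", "SC001", "SC001", "SC002"))
  cl <- finalize_clades(asg, rec)
  big <- cl[cl$clade_id == "SC001", ]
  expect_equal(big$representative_id, "x")      # 1500-bp tie -> smaller id
  expect_true(big$valid)
  expect_false(big$singleton)
  solo <- cl[cl$clade_id == "SC002", ]
  expect_false(solo$valid)                      # longest member is 1,199 bp
  expect_true(solo$singleton)
  # raising the representative length requirement never adds valid clades
  n_valid <- vapply(c(800, 1200, 1500, 1501), function(L)
    sum(finalize_clades(asg, rec, min_rep_len = L)$valid), numeric(1))
  expect_true(all(diff(n_valid) <= 0))
  expect_error(finalize_clades(tibble::tibble(id = "ghost", clade_id = "SC1"),
                               rec), "no record for assigned id")
})

test_that("genus decomposition follows the identity guide on the tree", {
  # two sisters at 96% stay together; a node whose pairs fall below the
  # guide is split into its children
  ids <- c("r1", "r2", "r3")
  m <- im_from(ids, 96)
  m["r1", "r3"] <- m["r3", "r1"] <- 93
  m["r2", "r3"] <- m["r3", "r2"] <- 93
  tr <- ape::read.tree(text = "(((r1:1,r2:1):1,r3:2):1,OG:5);")
  gc <- cluster_genus(tr, m, outgroup = "OG")
  expect_equal(nrow(gc$clusters), 2L)
  expect_identical(
    canon_partition(split(gc$assignments$clade_id, gc$assignments$cluster_id)),
    canon_partition(list(c("r1", "r2"), "r3")))
  # with tolerance covering the deficit the whole ingroup is one cluster
  gc2 <- cluster_genus(tr, m, tolerance = 2, outgroup = "OG")
  expect_equal(nrow(gc2$clusters), 1L)
})

test_that("genus clusters are a monophyletic partition of the clades", {
  sim <- simulate_radiation(radiation_spec(seed = 17, n_genera = 3,
                                           species_per_genus = c(4, 2, 3),
                                           seqs_per_species = 1))
  im <- identity_matrix(rbind(sim$records, sim$outgroup))
  tr <- nj_tree(identity_to_distance(im))
  gc <- cluster_genus(tr, im, outgroup = "OUTGROUP")
  # partition: every record exactly once
  expect_setequal(gc$assignments$clade_id, sim$records$id)
  expect_equal(anyDuplicated(gc$assignments$clade_id), 0L)
  # planted genus labels recovered
  truth_split <- split(sim$truth$record_id, sim$truth$genus)
  expect_identical(
    canon_partition(split(gc$assignments$clade_id, gc$assignments$cluster_id)),
    canon_partition(truth_split))
  # every emitted cluster passes an independent monophyly re-check
  for (k in seq_len(nrow(gc$clusters))) {
    q <- clade_query(tr, "OUTGROUP", gc$clusters$clade_ids[[k]])
    expect_true(q$monophyletic)
  }
  g <- glance(gc)
  expect_equal(g$n_clusters, 3L)
  expect_lt(g$max_inter_identity, g$min_intra_identity)
})

test_that("delineation summary counts are conservative", {
  expect_equal(glance(summarize_delineation(
    finalize_clades(tibble::tibble(id = character(), clade_id = character()),
                    seq_records(character(), character(), character()))))$n_groups,
    0L)
  sim <- small_sim(seed = 23)
  im <- identity_matrix(sim$records)
  sp <- cluster_species(im)
  clades <- finalize_clades(sp, sim$records)
  report <- tibble::tibble(id = sim$records$id, source = sim$records$source,
                           status = "retained")
  acct <- accounting_table(report, clades)
  tot <- acct[acct$source == "Total", ]
  expect_equal(tot$n_initial, nrow(sim$records))
  expect_equal(tot$n_clades, nrow(clades))
  per <- acct[acct$source != "Total", ]
  expect_equal(sum(per$n_initial), tot$n_initial)
  expect_equal(sum(per$n_clades), tot$n_clades)
})
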