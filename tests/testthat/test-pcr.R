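primers <- cable_primers()
p27 <- primers[primers$name == "27F", ]
p1492 <- primers[primers$name == "1492R", ]

test_that("degenerate primer sites are found by IUPAC intersection", {
  # 27F carries M (= A or C); both concrete templates bind with 0 mismatches
  tA <- paste0(random_dna(30), "AGAGTTTGATCATGGCTCAG", random_dna(30))
  tC <- sub("GATCATGG", "GATCCTGG", tA, fixed = TRUE)
  sA <- find_primer_sites(tA, p27)
  sC <- find_primer_sites(tC, p27)
  expect_equal(nrow(sA), 1L)
  expect_equal(sA$start, 30L)
  expect_equal(sA$end, 50L)
  expect_equal(sA$mismatches, 0L)
  expect_equal(sA$strand, "plus")
  expect_equal(nrow(sC), 1L)
  expect_equal(sC$mismatches, 0L)
})

test_that("a mismatched 3-prime anchor kills a site", {
  set.seed(111)
  tmpl <- paste0(random_dna(25), "AGAGTTTGATCATGGCTCAG", random_dna(25))
  # break the 3'-terminal base of the planted site (last primer base = G)
  broken <- tmpl
  substr(broken, 25 + 20, 25 + 20) <- "A"
  expect_equal(nrow(find_primer_sites(tmpl, p27, max_mismatch = 1)), 1L)
  expect_equal(nrow(find_primer_sites(broken, p27, max_mismatch = 1)), 0L)
  # an internal mismatch within the allowance is fine
  internal <- tmpl
  substr(internal, 25 + 3, 25 + 3) <- "C"   # primer pos 3 (G -> C on template)
  s <- find_primer_sites(internal, p27, max_mismatch = 1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mismatches, 1L)
})

test_that("primer site search is strand symmetric", {
  set.seed(121)
  for (k in 1:5) {
    tmpl <- paste0(random_dna(40), "AGAGTTTGATCATGGCTCAG", random_dna(60))
    L <- nchar(tmpl)
    fwd <- find_primer_sites(tmpl, p27)
    rev <- find_primer_sites(revcomp(tmpl), p27)
    expect_equal(nrow(fwd), nrow(rev))
    # mirrored coordinates: [s, e) on plus maps to [L - e, L - s) on minus
    expect_setequal(paste(L - fwd$end, L - fwd$start),
                    paste(rev$start, rev$end))
    expect_setequal(setdiff(c("plus", "minus"), fwd$strand), rev$strand)
  }
})

test_that("amplification spans forward to reverse site coordinates", {
  set.seed(131)
  # plant 27F at [10, 30) and the 1492R binding site at [1290, 1309)
  t_core <- random_dna(1400)
  tmpl <- paste0(substr(t_core, 1, 10), "AGAGTTTGATCATGGCTCAG",
                 substr(t_core, 31, 1290), revcomp("GGCTACCTTGTTACGACTT"),
                 substr(t_core, 1310, 1400))
  amp <- amplify(tmpl, p27, p1492)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 10L)
  expect_equal(amp$end, 1309L)
  expect_equal(amp$length, 1299L)   # 1309 - 10
  expect_equal(nchar(amp$residues), 1299L)
  # the amplicon starts with a forward-primer match and ends with the
  # reverse complement of the reverse primer
  expect_equal(nrow(find_primer_sites(amp$residues, p27)), 1L)
  expect_true(startsWith(amp$residues, "AGAGTTTGATCATGGCTCAG"))
  expect_true(endsWith(amp$residues, revcomp("GGCTACCTTGTTACGACTT")))
})

test_that("no downstream reverse site means no amplicon", {
  tmpl <- paste0(random_dna(50), "AGAGTTTGATCATGGCTCAG", random_dna(100))
  expect_equal(nrow(amplify(tmpl, p27, p1492)), 0L)
})

test_that("simulated templates yield one full-length first-round amplicon", {
  for (sd in c(2, 9)) {
    sim <- small_sim(seed = sd)
    tmpl <- sim$records[1, ]
    amp <- amplify(tmpl, p27, p1492, min_len = 1000)
    expect_equal(nrow(amp), 1L)
    expect_gte(amp$length, 1464L)   # published first-round product range
    expect_lte(amp$length, 1515L)
  }
})

test_that("nested PCR reconstructs the template by overlap consensus", {
  sim <- small_sim(seed = 14)
  tmpl <- sim$records[1, ]
  pcr2 <- list(rbind(p27, primers[primers$name == "DSBB+1297R", ]),
               rbind(primers[primers$name == "DSBB280wF", ], p1492))
  cons <- nested_consensus(tmpl, pcr1 = rbind(p27, p1492), pcr2_pairs = pcr2,
                           min_len = 500)
  expect_s3_class(cons, "consensus_assembly")
  expect_identical(cons$residues, tmpl$residues)  # exact string equality
  expect_equal(length(cons$fragment_ids), 2L)
})

test_that("a single second-round fragment is its own consensus", {
  sim <- small_sim(seed = 14)
  tmpl <- sim$records[1, ]
  pcr2 <- list(rbind(primers[primers$name == "DSBB280wF", ], p1492))
  cons <- nested_consensus(tmpl, pcr1 = rbind(p27, p1492), pcr2_pairs = pcr2,
                           min_len = 500)
  frag <- amplify(tmpl, primers[primers$name == "DSBB280wF", ], p1492,
                  min_len = 500)
  expect_identical(cons$residues, frag$residues[1])
})

test_that("fragments overlapping less than the minimum are unmergeable", {
  set.seed(141)
  tmpl <- random_dna(1000)
  # custom primer pairs cut [0, 520) and [490, 1000): 30 bp overlap
  f1 <- substr(tmpl, 1, 20);   r1 <- revcomp(substr(tmpl, 501, 520))
  f2 <- substr(tmpl, 491, 510); r2 <- revcomp(substr(tmpl, 981, 1000))
  mk <- function(nm, sq, o) cabletax:::primer_table(nm, sq, o)
  pcr2 <- list(rbind(mk("F1", f1, "forward"), mk("R1", r1, "reverse")),
               rbind(mk("F2", f2, "forward"), mk("R2", r2, "reverse")))
  pcr1 <- rbind(mk("FO", substr(tmpl, 1, 20), "forward"),
                mk("RO", revcomp(substr(tmpl, 981, 1000)), "reverse"))
  expect_error(
    nested_consensus(tmpl, pcr1, pcr2, min_overlap = 50, min_len = 50),
    "unmergeable")
})
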