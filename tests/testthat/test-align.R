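test_that("worked alignment examples behave as specified", {
  a <- align_pair("ACGT", "ACGT")
  expect_equal(a$score, 8)
  expect_equal(a$matches, 4L)
  expect_false(grepl("-", a$aligned_a, fixed = TRUE))

  # one internal gap beats shifted overlap under the default scoring
  b <- align_pair("ACGTACGT", "ACGACGT")
  expect_equal(b$matches, 7L)
  expect_equal(b$comparable, 7L)
  expect_equal(sum(strsplit(b$aligned_b, "")[[1]] == "-") +
                 sum(strsplit(b$aligned_a, "")[[1]] == "-"), 1L)
  expect_equal(percent_identity(b), 100)

  # fully dissimilar: free end-gap skip (score 0) beats 4 mismatches (-4)
  d <- align_pair("AAAA", "TTTT")
  expect_equal(d$score, 0)
  expect_equal(d$comparable, 0L)
  expect_error(percent_identity(d), "undefined identity")
})

test_that("alignments recover the inputs when gaps are removed", {
  set.seed(11)
  for (k in 1:10) {
    x <- random_dna(sample(20:200, 1))
    y <- mutate_dna(random_dna(sample(20:200, 1)), 0.1)
    al <- align_pair(x, y)
    expect_identical(gsub("-", "", al$aligned_a), x)
    expect_identical(gsub("-", "", al$aligned_b), y)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  }
})

test_that("percent identity uses pairwise deletion and IUPAC intersection", {
  expect_equal(percent_identity(align_pair("ACGTACGT", "ACGTACGT")), 100)
  expect_equal(percent_identity(align_pair("ACGTACGT", "ACGAACGT")), 87.5)
  # degenerate codes match their constituent bases
  expect_equal(percent_identity(align_pair("ACGM", "ACGA")), 100)
  expect_equal(percent_identity(align_pair("ACGM", "ACGC")), 100)
  expect_equal(percent_identity(align_pair("ACGM", "ACGG")), 75)
})

test_that("percent identity is symmetric and reverse-complement invariant", {
  set.seed(21)
  for (k in 1:15) {
    x <- random_dna(300)
    y <- mutate_dna(x, runif(1, 0.02, 0.15))
    f <- align_pair(x, y); r <- align_pair(y, x)
    expect_identical(f$score, r$score)
    expect_identical(percent_identity(f), percent_identity(r))
    rc <- align_pair(revcomp(x), revcomp(y))
    expect_identical(f$score, rc$score)
    expect_identical(percent_identity(f), percent_identity(rc))
  }
})

test_that("alignment scores agree with an independent implementation", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(5)
  for (k in 1:25) {
    x <- random_dna(sample(40:400, 1))
    y <- if (k %% 2) mutate_dna(x, runif(1, 0.05, 0.3)) else
      random_dna(sample(40:400, 1))
    ours <- align_pair(x, y)$score
    # our gap(L) = open + (L-1)*ext equals Biostrings' opening = open - ext
    theirs <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, type = "overlap", substitutionMatrix = mat,
      gapOpening = 3, gapExtension = 2))
    expect_equal(ours, theirs)
  }
})

test_that("banded and full dynamic programming agree on long sequences", {
  set.seed(31)
  for (div in c(0.01, 0.08, 0.2)) {
    x <- random_dna(1200)
    y <- mutate_dna(x, div)
    fast <- cabletax:::cpp_align_pair(x, y, 2L, -1L, 5L, 2L, FALSE)
    full <- cabletax:::cpp_align_pair(x, y, 2L, -1L, 5L, 2L, TRUE)
    expect_identical(fast$score, full$score)
    expect_identical(fast$matches, full$matches)
    expect_identical(fast$comparable, full$comparable)
  }
  # unequal lengths (fragment vs full template)
  x <- random_dna(1500)
  y <- mutate_dna(substr(x, 201, 1100), 0.05)
  fast <- cabletax:::cpp_align_pair(x, y, 2L, -1L, 5L, 2L, FALSE)
  full <- cabletax:::cpp_align_pair(x, y, 2L, -1L, 5L, 2L, TRUE)
  expect_identical(fast$score, full$score)
  expect_identical(fast$matches, full$matches)
})

test_that("identity_matrix equals naive per-pair recomputation", {
  set.seed(41)
  base <- random_dna(150)
  rec <- seq_records(sprintf("r%d", 1:5),
                     c(base, mutate_dna(base, 0.02), mutate_dna(base, 0.05),
                       mutate_dna(base, 0.2), random_dna(140)))
  im <- identity_matrix(rec)
  expect_true(isSymmetric(unclass(im)))
  expect_equal(unname(diag(im)), rep(100, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(im[i, j],
                 percent_identity(align_pair(rec[i, ], rec[j, ])))
  }
  # tidy layout carries every unordered pair once
  td <- tidy(im)
  expect_equal(nrow(td), 10L)
})

test_that("identity matrix round-trips through CSV", {
  set.seed(43)
  rec <- seq_records(c("a", "b", "c"),
                     replicate(3, mutate_dna(random_dna(120), 0.01)))
  im <- identity_matrix(rec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_identity_csv(im, f)
  back <- read_identity_csv(f)
  expect_equal(unclass(back), round(unclass(im), 4), ignore_attr = TRUE)
})

test_that("reference screening applies the cutoff and the whitelist", {
  set.seed(51)
  q <- random_dna(800)
  rec <- seq_records(
    c("hit_exact", "hit_near", "miss_far", "miss_whitelisted"),
    c(q, mutate_dna(q, 0.05), mutate_dna(q, 0.2), mutate_dna(q, 0.2)))
  queries <- seq_records("Q1", q)
  res <- screen_references(rec, queries, cutoff = 92,
                           whitelist = "miss_whitelisted")
  expect_equal(res$best_identity[res$record_id == "hit_exact"], 100)
  expect_true(res$retained[res$record_id == "hit_near"])
  expect_false(res$retained[res$record_id == "miss_far"])
  wl <- res[res$record_id == "miss_whitelisted", ]
  expect_true(wl$retained)
  expect_true(wl$whitelisted)
  expect_lt(wl$best_identity, 92)
  expect_error(screen_references(rec, queries[0, ]), "at least one query")
})

test_that("raising the screen cutoff never retains more records", {
  set.seed(61)
  q <- random_dna(500)
  rec <- seq_records(sprintf("r%02d", 1:12),
                     vapply(runif(12, 0, 0.25), function(p) mutate_dna(q, p),
                            character(1)))
  queries <- seq_records("Q1", q)
  prev <- NULL
  for (cut in c(99, 95, 92, 85, 75)) {
    keep <- screen_references(rec, queries, cutoff = cut)
    keep <- keep$record_id[keep$retained]
    if (!is.null(prev)) expect_true(all(prev %in% keep))
    prev <- keep
  }
})
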