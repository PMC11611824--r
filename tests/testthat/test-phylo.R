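test_that("identity-to-distance conversions match closed forms", {
  m <- matrix(c(100, 90, 90, 100), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(identity_to_distance(m, "p")["a", "b"], 0.1)
  expect_equal(identity_to_distance(m, "jc")["a", "b"],
               -0.75 * log(1 - 0.4 / 3))
  expect_equal(diag(identity_to_distance(m, "jc")), c(a = 0, b = 0))
  # beyond the Jukes-Cantor domain the raw proportion is used
  m[1, 2] <- m[2, 1] <- 20
  expect_equal(identity_to_distance(m, "jc")["a", "b"], 0.8)
})

test_that("three-taxon neighbor joining solves the three-point equations", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, ignore_attr = TRUE)
})

test_that("an additive four-taxon matrix is recovered exactly", {
  # caterpillar ((a,b),(c,d)) with every branch length 1
  gen <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  D <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(gen), tr)[1], 0)
  cd <- ape::cophenetic.phylo(tr)
  expect_lt(max(abs(cd[rownames(D), colnames(D)] - D)), 1e-9)
})

test_that("equal distances give a deterministic, reproducible tree", {
  ids <- c("d", "b", "a", "c")
  D <- matrix(2, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  t1 <- nj_tree(D); t2 <- nj_tree(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, ids)
  expect_equal(t1$Nnode, 2L)
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(71)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    ad <- random_additive(n)
    tr <- nj_tree(ad$D)
    expect_equal(ape::dist.topo(tr, ad$tree)[1], 0)
    cd <- ape::cophenetic.phylo(tr)
    expect_lt(max(abs(cd[rownames(ad$D), colnames(ad$D)] - ad$D)), 1e-9)
    # independent cross-check: same topology as ape's implementation
    expect_equal(ape::dist.topo(tr, ape::nj(ad$D))[1], 0)
  }
})

test_that("negative branch estimates are clamped, preserving pair sums", {
  # a non-additive matrix known to produce a negative NJ branch estimate
  ids <- letters[1:4]
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 0.001   # near-zero cherry
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("rooting splits the outgroup pendant edge at its midpoint", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,out:4):0.5);")
  tr <- ape::unroot(tr)
  r <- root_on_outgroup(tr, "out")
  root <- length(r$tip.label) + 1L
  kid_edges <- which(r$edge[, 1] == root)
  og_edge <- kid_edges[r$edge[kid_edges, 2] == which(r$tip.label == "out")]
  expect_equal(length(kid_edges), 2L)
  expect_equal(r$edge.length[og_edge], sum(r$edge.length[kid_edges]) / 2)
  # total tree length is unchanged by where the root splits the edge
  expect_equal(sum(r$edge.length), sum(tr$edge.length))
})

test_that("clade queries report the MRCA leaf set and monophyly", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,out:1);")
  q <- clade_query(tr, "out", c("a", "b"))
  expect_true(q$monophyletic)
  expect_setequal(q$tips, c("a", "b"))
  q2 <- clade_query(tr, "out", c("a", "c"))
  expect_false(q2$monophyletic)
  expect_setequal(q2$tips, c("a", "b", "c"))
  q3 <- clade_query(tr, "out", c("a", "b", "c"))
  expect_true(q3$monophyletic)
  expect_error(clade_query(tr, "out", c("a", "zz")), "unknown leaf id 'zz'")
  expect_error(clade_query(tr, "out", c("a", "out")), "outgroup")
})

test_that("monophyly agrees with a brute-force bipartition check", {
  set.seed(81)
  for (k in 1:30) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    out <- tr$tip.label[1]
    pool <- setdiff(tr$tip.label, out)
    leafset <- sample(pool, sample(2:(n - 1), 1))
    q <- clade_query(tr, out, leafset)
    expect_identical(q$monophyletic, oracle_monophyletic(q$tree, leafset))
  }
})
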