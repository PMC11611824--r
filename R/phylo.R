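#' Convert a percent-identity matrix to evolutionary distances
#'
#' @param im A `cb_identity` matrix (or any symmetric percent matrix with
#'   dimnames).
#' @param correction `"p"` for the raw proportion of differing sites
#'   `(100 - identity)/100`, or `"jc"` for the Jukes-Cantor correction
#'   `-(3/4) ln(1 - 4p/3)` (falling back to `p` where `p >= 0.75`, beyond
#'   the validity of the correction).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
identity_to_distance <- function(im, correction = c("p", "jc")) {
  correction <- match.arg(correction)
  p <- (100 - unclass(im)) / 100
  d <- p
  if (correction == "jc") {
    idx <- p < 0.75
    d[idx] <- -0.75 * log(1 - 4 * p[idx] / 3)
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration with two fixed conventions:
#' score ties in the Q criterion are broken toward the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member id), and negative estimated branch lengths are clamped to zero
#' with the deficit moved to the sibling branch (so the pair's summed
#' length is preserved).  Exact on additive matrices.
#'
#' @param dm Symmetric distance matrix with unique dimnames, n >= 3.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  n <- length(ids)
  if (is.null(ids) || anyDuplicated(ids))
    stop("distance matrix needs unique rownames", call. = FALSE)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(grepl("[,():;\\[\\]' ]", ids)))
    stop("taxon labels may not contain Newick metacharacters", call. = FALSE)
  D <- unname(dm)
  fmt <- function(x) sprintf("%.15g", x)
  nwk <- ids
  lab <- ids
  act <- seq_len(n)

  while (length(act) > 3L) {
    na <- length(act)
    Dm <- D[act, act]
    r <- rowSums(Dm)
    Q <- (na - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keylo <- pmin(lab[act[cand[, 1]]], lab[act[cand[, 2]]])
    keyhi <- pmax(lab[act[cand[, 1]]], lab[act[cand[, 2]]])
    pick <- order(keylo, keyhi)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    dij <- Dm[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (na - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    ai <- act[i]; aj <- act[j]
    k <- act[-c(i, j)]
    dnew <- 0.5 * (D[ai, k] + D[aj, k] - dij)
    D[ai, k] <- dnew; D[k, ai] <- dnew
    nwk[ai] <- paste0("(", nwk[ai], ":", fmt(vi), ",", nwk[aj], ":", fmt(vj), ")")
    lab[ai] <- min(lab[ai], lab[aj])
    act <- act[-j]
  }

  a <- act[1]; b <- act[2]; c_ <- act[3]
  va <- (D[a, b] + D[a, c_] - D[b, c_]) / 2
  vb <- (D[a, b] + D[b, c_] - D[a, c_]) / 2
  vc <- (D[a, c_] + D[b, c_] - D[a, b]) / 2
  if (va < 0) { vb <- vb + va / 2; vc <- vc + va / 2; va <- 0 }
  if (vb < 0) { va <- va + vb / 2; vc <- vc + vb / 2; vb <- 0 }
  if (vc < 0) { va <- va + vc / 2; vb <- vb + vc / 2; vc <- 0 }
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  txt <- paste0("(", nwk[a], ":", fmt(va), ",", nwk[b], ":", fmt(vb), ",",
                nwk[c_], ":", fmt(vc), ");")
  ape::read.tree(text = txt)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge (a
#' concrete convention for outgroup rooting).
#'
#' @param tree An [ape::phylo] tree containing `outgroup` as a leaf.
#' @param outgroup Leaf label to root on.
#' @return A rooted [ape::phylo] tree.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("unknown leaf id '", outgroup, "'", call. = FALSE)
  r <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root <- length(r$tip.label) + 1L
  kid_edges <- which(r$edge[, 1] == root)
  if (length(kid_edges) == 2L && !is.null(r$edge.length)) {
    og_tip <- which(r$tip.label == outgroup)
    og_edge <- kid_edges[r$edge[kid_edges, 2] == og_tip]
    other <- setdiff(kid_edges, og_edge)
    if (length(og_edge) == 1L) {
      total <- sum(r$edge.length[kid_edges])
      r$edge.length[og_edge] <- total / 2
      r$edge.length[other] <- total / 2
    }
  }
  r
}

#' Root a tree and query a clade
#'
#' Roots `tree` on `outgroup`, finds the most recent common ancestor of
#' `leafset`, and reports the full leaf set beneath it and whether
#' `leafset` is exactly that set (monophyly).
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Leaf label used for rooting (not part of `leafset`).
#' @param leafset Character vector of leaf labels.
#' @return A list: `tree` (rooted), `mrca` (node number), `tips` (leaf
#'   labels under the MRCA), `monophyletic` (logical).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,out:1);")
#' clade_query(tr, "out", c("a", "b"))$monophyletic
clade_query <- function(tree, outgroup, leafset) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(c(outgroup, leafset), tree$tip.label)
  if (length(unknown))
    stop("unknown leaf id '", unknown[1], "'", call. = FALSE)
  if (outgroup %in% leafset)
    stop("outgroup cannot be part of the query leafset", call. = FALSE)
  rooted <- root_on_outgroup(tree, outgroup)
  leafset <- unique(leafset)
  if (length(leafset) == 1L) {
    return(list(tree = rooted, mrca = which(rooted$tip.label == leafset),
                tips = leafset, monophyletic = TRUE))
  }
  node <- ape::getMRCA(rooted, leafset)
  tipnos <- phangorn::Descendants(rooted, type = "tips")[[node]]
  tips <- rooted$tip.label[tipnos]
  list(tree = rooted, mrca = node, tips = tips,
       monophyletic = setequal(tips, leafset))
}
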