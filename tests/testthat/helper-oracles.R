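# Independent oracles used across the suite.  These deliberately take the
# most direct route (definitions, enumeration, external packages), never
# the package's own algorithms.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# substitute a fraction of positions, keeping lengths equal
mutate_dna <- function(x, p) {
  ch <- strsplit(x, "")[[1]]
  k <- max(1L, round(p * length(ch)))
  idx <- sample(length(ch), k)
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

# Complete/single linkage straight from the definition: cluster distances
# recomputed from the original matrix at every step (no Lance-Williams
# updates), merges smallest-first, ties toward the lexicographically
# smallest pair of smallest-member labels.
oracle_linkage_clusters <- function(D, h, linkage = "complete") {
  ids <- rownames(D)
  groups <- as.list(ids)
  stat <- if (linkage == "complete") max else min
  repeat {
    if (length(groups) == 1L) break
    best <- NULL
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq((i + 1L), length(groups))) {
        d <- stat(D[groups[[i]], groups[[j]]])
        key <- c(min(min(groups[[i]]), min(groups[[j]])),
                 max(min(groups[[i]]), min(groups[[j]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, i = i, j = j, key = key)
        }
      }
    }
    if (best$d > h + 1e-9) break
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
  }
  lapply(groups, sort)
}

# canonical form of a partition for comparison
canon_partition <- function(groups) {
  groups <- unname(lapply(groups, sort))
  groups[order(vapply(groups, `[`, character(1), 1))]
}

# tip sets under every node by manual edge traversal (independent of
# phangorn); returns a list indexed by node number
oracle_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  sets <- vector("list", nn)
  for (t in seq_len(nt)) sets[[t]] <- tree$tip.label[t]
  repeat {
    done <- TRUE
    for (node in (nt + 1):nn) {
      if (is.null(sets[[node]])) {
        kids <- tree$edge[tree$edge[, 1] == node, 2]
        if (all(!vapply(sets[kids], is.null, logical(1)))) {
          sets[[node]] <- sort(unlist(sets[kids]))
        } else {
          done <- FALSE
        }
      }
    }
    if (done) break
  }
  sets
}

# brute-force monophyly: a leafset is monophyletic in a rooted tree iff
# some node's tip set equals it exactly
oracle_monophyletic <- function(rooted, leafset) {
  sets <- oracle_tipsets(rooted)
  any(vapply(sets, function(s) setequal(s, leafset), logical(1)))
}

# random additive distance matrix from a random tree with known shape
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

small_sim <- function(seed = 1, ...) {
  simulate_radiation(radiation_spec(seed = seed, n_genera = 2,
                                    species_per_genus = 2,
                                    seqs_per_species = 2, ...))
}
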