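# Shared fixtures and brute-force helpers for the test suite.

# symmetric reference fixture: one donor branch born exactly at FECA and
# spanning the whole window; analytic shift probability 1/4 (see the
# methods vignette for the derivation)
sym_fixture <- function() {
  fixture_spec(feca = 2.42, leca = 1.89,
               branches = data.frame(birth = 2.42, death = 0, label = "S"))
}

# random valid two-branch fixture (window and intervals drawn afresh)
rand_fixture <- function(seed, n_branches = 2L) {
  set.seed(seed)
  feca <- runif(1, 1.5, 3)
  leca <- runif(1, 0.2, feca - 0.4)
  birth <- runif(n_branches, leca + 0.05, feca + 1.5)
  death <- runif(n_branches, 0, pmin(birth, feca) - 0.05)
  fixture_spec(feca, leca,
               data.frame(birth = birth, death = death,
                          label = paste0("L", seq_len(n_branches))))
}

# brute-force node ages: root-to-node path sums over the raw edge matrix,
# ages as height above the deepest tip
oracle_node_ages <- function(phy) {
  n_nodes <- length(phy$tip.label) + phy$Nnode
  depth <- rep(NA_real_, n_nodes)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  depth[root] <- 0
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(phy$edge))) {
      p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + phy$edge.length[k]
        done <- FALSE
      }
    }
    if (done) break
  }
  max(depth[seq_along(phy$tip.label)]) - depth
}

# brute-force ancestor list of a node (walking the edge matrix)
oracle_ancestors <- function(phy, node) {
  parent_of <- integer(length(phy$tip.label) + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  out <- integer(0)
  while (parent_of[node] != 0L) {
    node <- parent_of[node]
    out <- c(out, node)
  }
  out
}

# brute-force MRCA: youngest node common to all tips' ancestor paths
oracle_mrca_age <- function(tree, tips) {
  phy <- tree$phy
  idx <- match(tips, phy$tip.label)
  paths <- lapply(idx, function(i) c(i, oracle_ancestors(phy, i)))
  common <- Reduce(intersect, paths)
  min(tree$node_age[common])
}

# brute-force descendant tip set of every node
oracle_descendant_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  desc <- vector("list", ntip + phy$Nnode)
  desc[seq_len(ntip)] <- as.list(phy$tip.label)
  ed <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    desc[[ed[k, 1]]] <- c(desc[[ed[k, 1]]], desc[[ed[k, 2]]])
  desc
}

# three-sigma tolerance for a difference of two proportion estimates
mc_tol <- function(p1, n1, p2 = p1, n2 = n1) {
  3 * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}
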