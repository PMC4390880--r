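# Shared fixtures and independent oracles.

# worked 4-leaf tree used across the weighting tests
worked_tree <- function() parse_newick("((A:1,B:1):1,C:3);")

# independent recursive oracle for the weight distribution: walks the
# tree as a nested structure, no shared code with distribute_weights()
oracle_weights <- function(tree, root_weight) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  sub_len <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(0)
    sum(vapply(rows, function(i) {
      tree$edge.length[i] + sub_len(tree$edge[i, 2])
    }, numeric(1)))
  }
  w <- numeric(ntip)
  recurse <- function(node, weight) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) { w[node] <<- weight; return(invisible()) }
    share <- vapply(rows, function(i) tree$edge.length[i] + sub_len(tree$edge[i, 2]),
                    numeric(1))
    frac <- if (sum(share) > 0) share / sum(share) else rep(1 / length(rows), length(rows))
    for (k in seq_along(rows)) recurse(tree$edge[rows[k], 2], weight * frac[k])
  }
  recurse(ntip + 1L, root_weight)
  stats::setNames(w, tree$tip.label)
}

# brute-force affinity-node oracle: checks the three selection criteria
# on every node using phangorn::Descendants
oracle_affinity_nodes <- function(tree, target, w, cl, threshold = 0.75) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  clade_levels <- sort(unique(cl))
  totals <- vapply(clade_levels,
                   function(x) sum(w[names(cl)[cl == x]]), numeric(1))
  names(totals) <- clade_levels
  cover <- function(node, clade) {
    tips <- phangorn::Descendants(tree, node, "tips")[[1]]
    g <- unique(sub("\\|.*$", "", tree$tip.label[tips]))
    g <- g[!is.na(cl[g]) & cl[g] == clade]
    sum(w[g]) / totals[clade]
  }
  ok12 <- vapply(seq_len(nn), function(node) {
    c1 <- cover(node, target) >= threshold
    oth <- setdiff(clade_levels, target)
    c2 <- any(vapply(oth, function(x) cover(node, x) >= threshold, logical(1)))
    c1 && c2
  }, logical(1))
  q <- which(ok12)
  keep <- vapply(q, function(node) {
    below <- setdiff(unlist(phangorn::Descendants(tree, node, "all")), node)
    !any(below %in% q)
  }, logical(1))
  sort(q[keep])
}

# random clade-labelled tree for property tests: n leaves over k clades,
# leaf labels "g<i>", genome = label
random_clade_tree <- function(n, k) {
  tr <- ape::rtree(n, br = function(x) stats::rexp(x, 2))
  tr$tip.label <- paste0("g", seq_len(n))
  cl <- stats::setNames(sample(paste0("cl", seq_len(k)), n, replace = TRUE),
                        tr$tip.label)
  w <- stats::setNames(stats::runif(n, 0.1, 2), tr$tip.label)
  list(tree = tr, clades = cl, weights = w)
}

# small membership fixture: 2 clades x 2 genomes, 3 clusters
toy_membership <- function() {
  data.frame(
    genome_id = c("g1", "g2", "g3", "g1", "g1", "g3", "g4"),
    gene_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c2"),
    cluster_id = c("cogA", "cogA", "cogA", "cogB", "cogB", "cogC", "cogC"),
    stringsAsFactors = FALSE)
}

toy_clades <- function() c(g1 = "X", g2 = "X", g3 = "Y", g4 = "Y")

random_alignment <- function(nrow, ncol, gap_p = 0.2) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(sample(aa, nrow * ncol, replace = TRUE), nrow)
  m[matrix(stats::runif(nrow * ncol) < gap_p, nrow)] <- "-"
  rownames(m) <- paste0("g", seq_len(nrow))
  m
}
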