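## Phylogenetic affinity of a focal clade across gene trees.
##
## For each (midpoint-rooted) gene tree, the affinity node(s) of the
## target clade are the minimal nodes covering >= 75% of the target
## clade's weight together with >= 75% of at least one other clade's
## weight.  At the selected node(s) the sister representation of every
## other clade i is W_i* = (weight of clade-i genomes under the node) /
## (weight of clade-i genomes anywhere in the tree); the normalised
## affinities R_i* = W_i*/sum(W*) read as "which clade is the target's
## neighbour".  A value near 1 marks a sister relationship; a series of
## small, nearly equal values marks a near-basal position.

## list of descendant tip ids per node (tips listed under themselves)
.tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  acc <- vector("list", nn)
  for (i in seq_len(ntip)) acc[[i]] <- i
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    acc[[p]] <- c(acc[[p]], acc[[ch]])
  }
  acc
}

## list of descendant *node* ids (internal + tips, excluding self)
.nodes_under <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  acc <- vector("list", nn)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    acc[[p]] <- c(acc[[p]], ch, acc[[ch]])
  }
  acc
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of its longest leaf-to-leaf path.  Ties
#' on the longest path are broken deterministically by the
#' lexicographically smallest (sorted) leaf-label pair.  If the
#' midpoint falls exactly on an existing node, that node becomes the
#' root (possibly multifurcating).
#'
#' @param tree a `phylo` object with branch lengths (any current
#'   rooting is ignored: only the unrooted shape matters).
#' @return a rooted `phylo` object.
#' @export
root_midpoint <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("midpoint rooting requires at least 3 leaves")
  d <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip)]
  dmax <- max(d)
  hit <- which(d >= dmax - 1e-12 & upper.tri(d), arr.ind = TRUE)
  lab <- tree$tip.label
  p1 <- pmin(lab[hit[, 1]], lab[hit[, 2]])
  p2 <- pmax(lab[hit[, 1]], lab[hit[, 2]])
  o <- order(p1, p2)[1]
  a <- hit[o, 1]; b <- hit[o, 2]
  if (lab[a] > lab[b]) { tmp <- a; a <- b; b <- tmp }

  path <- ape::nodepath(tree, a, b)
  edge <- tree$edge
  elen <- tree$edge.length
  ekey <- paste(edge[, 1], edge[, 2])
  elookup <- function(u, v) {
    i <- match(paste(u, v), ekey)
    if (is.na(i)) i <- match(paste(v, u), ekey)
    elen[i]
  }
  half <- dmax / 2
  cum <- 0
  root_node <- NA_integer_; root_edge <- NULL; d_from_u <- NA_real_
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    l <- elookup(u, v)
    if (cum + l >= half - 1e-12) {
      off <- half - cum
      if (off <= 1e-12) {
        root_node <- u
      } else if (l - off <= 1e-12) {
        root_node <- v
      } else {
        root_edge <- c(u, v); d_from_u <- off
      }
      break
    }
    cum <- cum + l
  }

  ## adjacency of the unrooted graph
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edge))) {
    u <- edge[i, 1]; v <- edge[i, 2]; l <- elen[i]
    adj[[u]] <- rbind(adj[[u]], c(v, l))
    adj[[v]] <- rbind(adj[[v]], c(u, l))
  }
  fmt <- function(x) sprintf("%.10g", x)
  subtree_str <- function(node, parent) {
    nb <- adj[[node]]
    nb <- nb[nb[, 1] != parent, , drop = FALSE]
    if (!nrow(nb)) return(.quote_label(lab[node]))
    parts <- vapply(seq_len(nrow(nb)), function(j) {
      paste0(subtree_str(nb[j, 1], node), ":", fmt(nb[j, 2]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- if (!is.na(root_node)) {
    nb <- adj[[root_node]]
    parts <- vapply(seq_len(nrow(nb)), function(j) {
      paste0(subtree_str(nb[j, 1], root_node), ":", fmt(nb[j, 2]))
    }, character(1))
    if (nrow(nb) == 1L) {          # midpoint at a leaf (degenerate)
      paste0("(", .quote_label(lab[root_node]), ":0,", parts, ");")
    } else {
      paste0("(", paste(parts, collapse = ","), ");")
    }
  } else {
    u <- root_edge[1]; v <- root_edge[2]
    paste0("(", subtree_str(u, v), ":", fmt(d_from_u), ",",
           subtree_str(v, u), ":", fmt(elookup(u, v) - d_from_u), ");")
  }
  parse_newick(nwk)
}

## per-node x per-clade weight of *distinct* genomes under the node
## (a genome counts once regardless of paralogous leaves)
.node_clade_weight <- function(tree, w, cl) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  genomes <- leaf_genomes(tree)
  known <- genomes %in% names(cl) & genomes %in% names(w)
  clade_levels <- sort(unique(cl[genomes[known]]))
  tu <- .tips_under(tree)
  out <- base::matrix(0, nn, length(clade_levels),
                      dimnames = list(NULL, clade_levels))
  for (node in seq_len(nn)) {
    g <- unique(genomes[tu[[node]]])
    g <- g[g %in% names(cl) & g %in% names(w)]
    if (!length(g)) next
    s <- tapply(w[g], cl[g], sum)
    out[node, names(s)] <- as.numeric(s)
  }
  out
}

#' Weighted genome coverage of a clade under a node
#'
#' Fraction of a clade's total weight (as recorded in the weight table,
#' including genomes absent from this tree) carried by the distinct
#' genomes of that clade with at least one leaf below `node`.
#'
#' @param tree rooted `phylo`; leaves keyed by genome prefix (see
#'   [leaf_genomes()]).
#' @param node node id (ape numbering).
#' @param clade clade id.
#' @param weights genome weights.
#' @param clades genome -> clade map.
#' @return a fraction in `[0, 1]`.
#' @export
genome_coverage <- function(tree, node, clade, weights, clades) {
  w <- .as_weights_vector(weights)
  cl <- .as_clade_map(clades)
  members <- names(cl)[cl == clade & names(cl) %in% names(w)]
  if (!length(members)) stop(sprintf("clade '%s' absent from the weight table", clade))
  total <- sum(w[members])
  tu <- .tips_under(tree)
  g <- unique(leaf_genomes(tree)[tu[[node]]])
  sum(w[intersect(g, members)]) / total
}

#' Locate the affinity node(s) of a target clade
#'
#' Returns every node satisfying: (1) coverage of the target clade
#' >= `threshold`; (2) coverage of at least one other clade
#' >= `threshold`; (3) no node strictly below it satisfies (1) and (2).
#' Coverage denominators are the clades' full weight-table totals, so a
#' tree sampling less than `threshold` of the target clade's weight has
#' no qualifying node: the empty result carries
#' `attr(, "unclassifiable") = TRUE`.  With deep paralogy several nodes
#' may qualify.
#'
#' @inheritParams genome_coverage
#' @param target the focal clade id (must have at least one leaf in the
#'   tree).
#' @param threshold coverage threshold, default 0.75.
#' @return integer vector of node ids; attributes `coverage` (node x
#'   clade matrix of coverages) and possibly `unclassifiable`.
#' @export
find_affinity_nodes <- function(tree, target, weights, clades, threshold = 0.75) {
  w <- .as_weights_vector(weights)
  cl <- .as_clade_map(clades)
  genomes <- leaf_genomes(tree)
  if (!any(cl[genomes[genomes %in% names(cl)]] == target)) {
    stop(sprintf("target clade '%s' has no leaf in the tree", target))
  }
  ncw <- .node_clade_weight(tree, w, cl)
  clade_levels <- colnames(ncw)
  totals <- vapply(clade_levels, function(x) sum(w[names(cl)[cl == x & names(cl) %in% names(w)]]),
                   numeric(1))
  cov <- sweep(ncw, 2, totals, "/")
  if (!(target %in% clade_levels)) {
    stop(sprintf("target clade '%s' absent from the clade map for this tree", target))
  }
  others <- setdiff(clade_levels, target)
  c1 <- cov[, target] >= threshold
  c2 <- if (length(others)) {
    rowSums(cov[, others, drop = FALSE] >= threshold) > 0
  } else {
    rep(FALSE, nrow(cov))
  }
  q <- which(c1 & c2)
  if (!length(q)) {
    res <- integer(0)
    attr(res, "unclassifiable") <- TRUE
    attr(res, "coverage") <- cov
    return(res)
  }
  nu <- .nodes_under(tree)
  minimal <- q[vapply(q, function(n) !any(q %in% nu[[n]]), logical(1))]
  res <- sort(as.integer(minimal))
  attr(res, "coverage") <- cov
  res
}

#' Per-clade affinity of a target clade at its selected node(s)
#'
#' For each selected node and every non-target clade i:
#' `W_i* = weight(clade-i genomes under node) / weight(clade-i genomes
#' in the tree)`.  With several (paralogous) nodes, W* is averaged
#' arithmetically across nodes before normalisation to
#' `R_i* = W_i*/sum(W*)`.  An all-zero W vector yields all-zero R and
#' topology class "X".
#'
#' @inheritParams find_affinity_nodes
#' @param nodes node ids from [find_affinity_nodes()] (may be empty).
#' @param tree_id optional identifier carried into reports.
#' @return object of class `affinity_result`: list with `tree_id`,
#'   `nodes`, `W_star`, `R_star` (named by clade), `qualifying` (per
#'   node, the non-target clades with coverage >= threshold), `class`
#'   (NA until [classify_topology()]).
#' @export
compute_affinity <- function(tree, nodes, target, weights, clades,
                             threshold = 0.75, tree_id = NULL) {
  w <- .as_weights_vector(weights)
  cl <- .as_clade_map(clades)
  ncw <- .node_clade_weight(tree, w, cl)
  clade_levels <- colnames(ncw)
  others <- setdiff(clade_levels, target)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  in_tree <- ncw[root, ]                  # weight of each clade present in tree

  cov <- attr(nodes, "coverage")
  if (is.null(cov)) {
    totals <- vapply(clade_levels, function(x) sum(w[names(cl)[cl == x & names(cl) %in% names(w)]]),
                     numeric(1))
    cov <- sweep(ncw, 2, totals, "/")
  }

  if (length(nodes)) {
    Wn <- base::matrix(0, length(nodes), length(others),
                       dimnames = list(NULL, others))
    for (k in seq_along(nodes)) {
      num <- ncw[nodes[k], others]
      den <- in_tree[others]
      Wn[k, ] <- ifelse(den > 0, num / den, 0)
    }
    W_star <- colMeans(Wn)
    qualifying <- lapply(seq_along(nodes), function(k) {
      others[cov[nodes[k], others] >= threshold]
    })
  } else {
    Wn <- base::matrix(0, 0, length(others), dimnames = list(NULL, others))
    W_star <- stats::setNames(rep(0, length(others)), others)
    qualifying <- list()
  }
  s <- sum(W_star)
  R_star <- if (s > 0) W_star / s else stats::setNames(rep(0, length(others)), others)
  structure(list(tree_id = tree_id, nodes = as.integer(nodes),
                 W_node = Wn, W_star = W_star, R_star = R_star,
                 qualifying = qualifying, target = target,
                 class = NA_character_),
            class = "affinity_result")
}

#' Topology-classification configuration
#'
#' Names the target clade, the candidate sister clades whose grouping
#' with the target defines topology II, and the enclosing higher-order
#' group (e.g. the euryarchaeal clades) whose basal position defines
#' topology I.
#'
#' @param target focal clade id.
#' @param sister_set clade ids forming the topology-II sister set.
#' @param enclosing clade ids of the enclosing group (must contain
#'   `target` and `sister_set`).
#' @return object of class `topology_config`.
#' @export
topology_config <- function(target, sister_set, enclosing) {
  stopifnot(length(target) == 1L, length(sister_set) >= 1L)
  if (!all(sister_set %in% enclosing)) {
    stop("sister_set must be contained in the enclosing group")
  }
  structure(list(target = target, sister_set = setdiff(sister_set, target),
                 enclosing = unique(c(enclosing, target))),
            class = "topology_config")
}

.classify_node <- function(q, config) {
  q <- setdiff(q, config$target)
  if (!length(q)) return("X")
  inside <- q %in% config$enclosing
  in_sister <- q %in% config$sister_set
  if (all(in_sister)) return("II")
  if (all(inside) && length(q) >= 2 && any(!in_sister)) return("I")
  "X"
}

#' Classify the topology support of a gene tree
#'
#' Per selected node: class "II" when every qualifying sister clade
#' (coverage >= threshold, target excluded) belongs to the configured
#' sister set (and at least one qualifies); class "I" when the
#' qualifying clades comprise two or more enclosing-group clades
#' including at least one outside the sister set, with no qualifying
#' clade outside the enclosing group (the target sits basal to the
#' group); "X" otherwise.  Multiple nodes vote; ties (or an empty node
#' list) give "X".
#'
#' @param result an `affinity_result`.
#' @param config a [topology_config()].
#' @return the `affinity_result` with `class` set to "I", "II" or "X".
#' @export
classify_topology <- function(result, config) {
  stopifnot(inherits(result, "affinity_result"),
            inherits(config, "topology_config"))
  if (!length(result$nodes)) {
    result$class <- "X"
    return(result)
  }
  votes <- vapply(result$qualifying, .classify_node, character(1), config = config)
  tab <- table(votes)
  top <- tab[tab == max(tab)]
  result$class <- if (length(top) == 1L) names(top) else "X"
  result
}

#' Analyse one gene tree end-to-end
#'
#' Midpoint-roots the tree (optional), locates the target clade's
#' affinity node(s), computes W*/R* and classifies the topology.
#' Returns `NULL` when the target clade has no leaf in the tree (such
#' trees are skipped, not classified).
#'
#' @inheritParams find_affinity_nodes
#' @param config a [topology_config()] naming target, sister set and
#'   enclosing group.
#' @param midpoint re-root by [root_midpoint()] first (set `FALSE` for
#'   trees whose rooting is already meaningful).
#' @param tree_id optional identifier.
#' @return an `affinity_result` with topology class, or `NULL`.
#' @export
analyze_gene_tree <- function(tree, weights, clades, config,
                              threshold = 0.75, midpoint = TRUE,
                              tree_id = NULL) {
  cl <- .as_clade_map(clades)
  genomes <- leaf_genomes(tree)
  present <- genomes[genomes %in% names(cl)]
  if (!any(cl[present] == config$target)) return(NULL)
  if (midpoint && length(tree$tip.label) >= 3L) tree <- root_midpoint(tree)
  nodes <- find_affinity_nodes(tree, config$target, weights, cl, threshold)
  res <- compute_affinity(tree, nodes, config$target, weights, cl,
                          threshold = threshold, tree_id = tree_id)
  classify_topology(res, config)
}

#' Aggregate affinity results across gene trees
#'
#' @param results list of `affinity_result` objects (NULL entries, from
#'   trees lacking the target, are dropped).
#' @return object of class `affinity_summary`: list with `n_trees`,
#'   `mean_R` (per-clade arithmetic mean of R* over trees, sorted
#'   decreasing) and `class_counts` (named I/II/X tallies summing to
#'   `n_trees`).
#' @export
aggregate_affinity <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no affinity results to aggregate")
  all_clades <- sort(unique(unlist(lapply(results, function(r) names(r$R_star)))))
  acc <- stats::setNames(rep(0, length(all_clades)), all_clades)
  for (r in results) acc[names(r$R_star)] <- acc[names(r$R_star)] + r$R_star
  mean_R <- sort(acc / length(results), decreasing = TRUE)
  cls <- vapply(results, function(r) r$class, character(1))
  counts <- stats::setNames(integer(3), c("I", "II", "X"))
  tab <- table(factor(cls, levels = c("I", "II", "X")))
  counts[names(tab)] <- as.integer(tab)
  structure(list(n_trees = length(results), mean_R = mean_R,
                 class_counts = counts),
            class = "affinity_summary")
}

#' @export
print.affinity_summary <- function(x, ...) {
  cat(sprintf("affinity_summary over %d gene trees\n", x$n_trees))
  cat(sprintf("  topology classes: I=%d II=%d X=%d\n",
              x$class_counts["I"], x$class_counts["II"], x$class_counts["X"]))
  cat("  mean affinity R* (top 5):\n")
  top <- utils::head(x$mean_R, 5)
  for (i in seq_along(top)) cat(sprintf("    %-20s %.3f\n", names(top)[i], top[i]))
  invisible(x)
}
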