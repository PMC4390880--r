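## Relative genome weighting.
##
## A rooted species tree with branch lengths defines relative genome
## weights: the root carries a total weight W (by convention the number
## of genomes); at every node the weight is apportioned among the
## descendant subtrees proportionally to (incoming branch length +
## subtree branch-length sum).  Closely related genomes thereby share
## weight that a lone deep-branching genome keeps to itself, which
## corrects taxon-sampling bias in any statistic aggregated over
## genomes.

#' Subtree branch-length sums
#'
#' For every node, the sum of all branch lengths strictly below it
#' (leaf-to-root pass).  Leaves have subtree length 0.
#'
#' @param tree a rooted `phylo` object.
#' @return numeric vector indexed by node id (ape convention: tips
#'   `1..Ntip`, internals `Ntip+1..`), tip entries named by label.
#' @export
subtree_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(tree$edge))
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(edge))
  T <- numeric(nn)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    T[p] <- T[p] + elen[i] + T[ch]
  }
  names(T) <- c(tree$tip.label, rep("", tree$Nnode))
  T
}

#' Distribute genome weights down a rooted species tree
#'
#' The root is assigned `root_weight` and every internal node splits its
#' weight among its children proportionally to (incoming branch length
#' + child subtree length).  Leaves inherit the final weights, which by
#' construction sum to `root_weight`.  If all children of a node have
#' zero (branch + subtree) length, the weight is split equally, which
#' keeps every leaf weight strictly positive.
#'
#' @param tree rooted `phylo` with branch lengths (missing lengths are
#'   treated as 0).
#' @param root_weight total weight at the root; defaults to the number
#'   of leaves, so weights read as genome-equivalents.
#' @return an object of class `genome_weights`: list with `weights`
#'   (named numeric, per leaf), `root_weight`, `node_weights` (per node
#'   id), and `subtree_lengths`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:3);")
#' distribute_weights(tr, root_weight = 5)$weights  # A=1.25 B=1.25 C=2.5
#' @export
distribute_weights <- function(tree, root_weight = length(tree$tip.label)) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(root_weight) || length(root_weight) != 1L ||
      !is.finite(root_weight) || root_weight <= 0) {
    stop("root_weight must be a single positive finite number")
  }
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  T <- subtree_lengths(tree)
  cw <- ape::reorder.phylo(tree, "cladewise")
  edge <- cw$edge
  elen <- cw$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(edge))
  w <- numeric(nn)
  root <- ntip + 1L
  w[root] <- root_weight
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (p in unique(edge[, 1])) {          # cladewise: parents before children
    rows <- kids[[as.character(p)]]
    share <- elen[rows] + T[edge[rows, 2]]
    s <- sum(share)
    frac <- if (s > 0) share / s else rep(1 / length(rows), length(rows))
    w[edge[rows, 2]] <- w[p] * frac
  }
  structure(list(
    weights = stats::setNames(w[seq_len(ntip)], tree$tip.label),
    root_weight = root_weight,
    node_weights = w,
    subtree_lengths = T), class = "genome_weights")
}

#' @export
print.genome_weights <- function(x, ...) {
  cat(sprintf("genome_weights: %d genomes, root weight %g (leaf sum %.9g)\n",
              length(x$weights), x$root_weight, sum(x$weights)))
  rng <- range(x$weights)
  cat(sprintf("  weight range: %.4g .. %.4g\n", rng[1], rng[2]))
  invisible(x)
}

#' Per-clade weight totals
#'
#' Sums leaf weights within each clade.  Weighted genomes absent from
#' the clade map are excluded with a warning.
#'
#' @param weights a `genome_weights` object, named numeric vector, or
#'   (genome_id, weight) data frame.
#' @param clades named character vector `genome_id -> clade_id` or a
#'   (genome_id, clade_id) data frame.
#' @return named numeric vector of clade totals (sorted by clade name).
#' @export
clade_weight_totals <- function(weights, clades) {
  w <- .as_weights_vector(weights)
  cl <- .as_clade_map(clades)
  common <- intersect(names(w), names(cl))
  if (!length(common)) stop("no genome occurs in both the weight table and the clade map")
  unmapped <- setdiff(names(w), names(cl))
  if (length(unmapped)) {
    warning(sprintf("%d weighted genome(s) absent from clade map, excluded: %s",
                    length(unmapped), paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  tot <- tapply(w[common], cl[common], sum)
  out <- stats::setNames(as.numeric(tot), names(tot))
  out[order(names(out))]
}

#' Read / write a genome weight table
#'
#' TSV with header columns `genome_id`, `weight`.
#'
#' @param path file path.
#' @return `read_weights`: named numeric vector.
#' @export
read_weights <- function(path) {
  df <- .read_tsv(path, c("genome_id", "weight"))
  w <- as.numeric(df$weight)
  if (anyNA(w)) stop(sprintf("%s: non-numeric weight", path))
  stats::setNames(w, df$genome_id)
}

#' @rdname read_weights
#' @param weights a `genome_weights` object or named numeric vector.
#' @export
write_weights <- function(weights, path) {
  w <- .as_weights_vector(weights)
  utils::write.table(
    data.frame(genome_id = names(w), weight = format(w, digits = 12),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
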