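## Phyletic-pattern statistics.
##
## A phyletic matrix records, per ortholog cluster, how many members
## each genome contributes (paralogs counted).  Two families of
## statistics are derived:
##
##  * weighted clade representation -- for a clade, the weight of its
##    genomes possessing the cluster divided by the clade's total
##    weight; drives core-gene and gene-tree-candidate selection;
##  * the exclusivity index R_E = (min C_in + 1e-4)/(max C_out + 1e-4),
##    a count-based (not weight-based) screen for genes exclusively
##    shared by a designated set of clades.

#' Build a phyletic matrix from a membership table
#'
#' @param membership data frame (genome_id, gene_id, cluster_id), e.g.
#'   from [read_membership()].
#' @return integer matrix, rows = cluster ids, columns = genome ids,
#'   entries = member counts (paralogs counted, absences 0).
#' @export
phyletic_matrix <- function(membership) {
  stopifnot(is.data.frame(membership),
            all(c("genome_id", "cluster_id") %in% names(membership)))
  tab <- table(factor(membership$cluster_id), factor(membership$genome_id))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Weighted clade representation of clusters
#'
#' For each cluster and clade: sum of weights of the clade's genomes
#' that possess the cluster (count >= 1), divided by the summed weight
#' of all the clade's genomes.  Genomes carrying weight but absent from
#' the matrix count as absences; matrix genomes missing from the weight
#' table or clade map are excluded with a warning.
#'
#' @param matrix phyletic matrix from [phyletic_matrix()] (clusters x
#'   genomes).
#' @param weights genome weights (see [clade_weight_totals()]).
#' @param clades genome -> clade map.
#' @return numeric matrix clusters x clades with entries in `[0, 1]`.
#' @export
clade_representation <- function(matrix, weights, clades) {
  w <- .as_weights_vector(weights)
  cl <- .as_clade_map(clades)
  genomes <- intersect(names(w), names(cl))
  if (!length(genomes)) stop("no genome occurs in both the weight table and the clade map")
  stray <- setdiff(colnames(matrix), genomes)
  if (length(stray)) {
    warning(sprintf("%d matrix genome(s) lack weight or clade assignment, excluded: %s",
                    length(stray), paste(utils::head(stray, 5), collapse = ", ")))
  }
  clade_levels <- sort(unique(cl[genomes]))
  totals <- tapply(w[genomes], cl[genomes], sum)[clade_levels]
  if (any(totals <= 0)) {
    stop(sprintf("clade with zero total weight: %s",
                 clade_levels[which(totals <= 0)[1]]))
  }
  ## presence over the genome universe (absent-from-matrix genomes = 0)
  pres <- base::matrix(0, nrow(matrix), length(genomes),
                       dimnames = list(rownames(matrix), genomes))
  hit <- intersect(colnames(matrix), genomes)
  pres[, hit] <- (matrix[, hit, drop = FALSE] >= 1) + 0
  ## genomes x clades weight indicator
  ind <- base::matrix(0, length(genomes), length(clade_levels),
                      dimnames = list(genomes, clade_levels))
  ind[cbind(genomes, cl[genomes])] <- w[genomes]
  rep_mat <- pres %*% ind
  sweep(rep_mat, 2, as.numeric(totals), "/")
}

#' Select core clusters
#'
#' Clusters represented at `>= threshold` (non-strict) in every clade
#' except the explicitly excluded ones.
#'
#' @param profile representation matrix from [clade_representation()].
#' @param excluded_clades clade ids ignored by the test (e.g. a
#'   poorly-sampled symbiont clade).
#' @param threshold representation cut-off in `(0, 1]`, default 0.75.
#' @return character vector of cluster ids.
#' @export
select_core <- function(profile, excluded_clades = character(), threshold = 0.75) {
  stopifnot(is.matrix(profile), threshold > 0, threshold <= 1)
  keep <- setdiff(colnames(profile), excluded_clades)
  if (!length(keep)) stop("all clades excluded: core selection undefined")
  sel <- rowSums(profile[, keep, drop = FALSE] >= threshold) == length(keep)
  rownames(profile)[sel]
}

#' Select clusters suitable for gene-tree analysis
#'
#' Clusters with at least `min_clades` clades represented by *more than*
#' `threshold` (strict) of the clade's weighted genomes.
#'
#' @param profile representation matrix.
#' @param min_clades minimum number of well-represented clades (>= 2),
#'   default 4.
#' @param threshold strict representation cut-off, default 0.5.
#' @return character vector of cluster ids.
#' @export
select_tree_candidates <- function(profile, min_clades = 4, threshold = 0.5) {
  stopifnot(is.matrix(profile), min_clades >= 2)
  sel <- rowSums(profile > threshold) >= min_clades
  rownames(profile)[sel]
}

.clade_counts <- function(matrix, cl) {
  genomes <- names(cl)
  clade_levels <- sort(unique(cl))
  cnt <- base::matrix(0, nrow(matrix), length(clade_levels),
                      dimnames = list(rownames(matrix), clade_levels))
  hit <- intersect(colnames(matrix), genomes)
  if (length(hit)) {
    ind <- base::matrix(0, length(hit), length(clade_levels),
                        dimnames = list(hit, clade_levels))
    ind[cbind(hit, cl[hit])] <- 1
    cnt <- matrix[, hit, drop = FALSE] %*% ind
  }
  cnt
}

#' Exclusivity index of clusters for a clade set
#'
#' `R_E = (min C_in + p) / (max C_out + p)` with pseudocount
#' `p = 0.0001`, where `C` are per-clade member counts (paralogs
#' counted): the minimum over the clades in `in_set`, the maximum over
#' all other clades.  Large values flag clusters exclusively shared by
#' the in-set clades; the index is deliberately count-based and
#' independent of genome weights.
#'
#' @param matrix phyletic matrix (clusters x genomes).
#' @param clades genome -> clade map.
#' @param in_set clade ids forming the analysed set; must be a
#'   non-empty proper subset of all clades.
#' @param pseudocount numerator/denominator stabiliser, default 1e-4.
#' @return named numeric vector of R_E per cluster.
#' @export
exclusivity_index <- function(matrix, clades, in_set, pseudocount = 1e-4) {
  cl <- .as_clade_map(clades)
  all_clades <- sort(unique(cl))
  in_set <- unique(as.character(in_set))
  if (!length(in_set)) stop("in_set must not be empty")
  if (!all(in_set %in% all_clades)) {
    stop(sprintf("unknown clade(s) in in_set: %s",
                 paste(setdiff(in_set, all_clades), collapse = ", ")))
  }
  out_set <- setdiff(all_clades, in_set)
  if (!length(out_set)) stop("in_set must be a proper subset of the clades")
  if (!nrow(matrix)) return(stats::setNames(numeric(0), character(0)))
  cnt <- .clade_counts(matrix, cl)
  cmin <- apply(cnt[, in_set, drop = FALSE], 1, min)
  cmax <- apply(cnt[, out_set, drop = FALSE], 1, max)
  stats::setNames((cmin + pseudocount) / (cmax + pseudocount), rownames(matrix))
}

#' Screen for exclusively-shared clusters
#'
#' Retains clusters with `R_E` strictly greater than `cutoff`, sorted
#' by decreasing exclusivity.
#'
#' @inheritParams exclusivity_index
#' @param cutoff strict lower bound on R_E, default 10.
#' @return data frame (cluster_id, R_E) sorted by decreasing R_E.
#' @export
exclusive_screen <- function(matrix, clades, in_set, cutoff = 10,
                             pseudocount = 1e-4) {
  stopifnot(cutoff > 0)
  re <- exclusivity_index(matrix, clades, in_set, pseudocount)
  re <- re[re > cutoff]
  re <- re[order(-re, names(re))]
  data.frame(cluster_id = names(re), R_E = as.numeric(re),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Contribution units of a screened cluster
#'
#' Screened clusters (R_E > 10) contribute 1 to 3 units to a clade
#' pair's shared-gene tally, monotonically in R_E.  Default tiers:
#' `(10, 100] -> 1`, `(100, 1e4] -> 2`, `> 1e4 -> 3`; with the 1e-4
#' pseudocount a strictly exclusive single-copy cluster scores >= ~1e4,
#' so the top tier isolates strict exclusivity.
#'
#' @param R_E exclusivity values (all must exceed `cutoff`).
#' @param cutoff screening cut-off below which scoring is undefined.
#' @param tiers increasing two-vector of tier boundaries.
#' @return integer vector in `{1, 2, 3}`.
#' @export
contribution_units <- function(R_E, cutoff = 10, tiers = c(100, 1e4)) {
  stopifnot(length(tiers) == 2, tiers[1] > cutoff, tiers[2] > tiers[1])
  if (any(R_E <= cutoff)) {
    stop(sprintf("contribution units defined only for screened clusters (R_E > %g)", cutoff))
  }
  as.integer(1L + (R_E > tiers[1]) + (R_E > tiers[2]))
}
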