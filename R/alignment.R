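## Alignment cleaning before tree inference.
##
## Protein alignments are held as character matrices (rows = sequences,
## columns = sites; rownames = labels).  Sites are dropped when too
## gappy or too heterogeneous; fragmented rows are dropped afterwards,
## and clades are re-qualified on the surviving rows.

.GAP_CHARS <- c("-", ".")

.pkg_cache <- new.env(parent = emptyenv())

## BLOSUM62, affinely rescaled so the maximal diagonal entry (W/W = 11)
## maps to 1 and the minimum entry (-4) to 0.
.blosum62_scaled <- function() {
  if (is.null(.pkg_cache$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b <- e$BLOSUM62
    .pkg_cache$b62 <- (b - min(b)) / (max(diag(b)) - min(b))
  }
  .pkg_cache$b62
}

.clean_residues <- function(res) {
  res <- toupper(res)
  known <- rownames(.blosum62_scaled())
  res[!(res %in% known)] <- "X"
  res
}

#' Read an aligned FASTA file
#'
#' @param path aligned protein FASTA (all rows equal length).
#' @return character matrix, rows = sequences (rownames = labels),
#'   columns = sites.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (!length(x)) stop(sprintf("empty alignment: %s", path))
  if (length(unique(Biostrings::width(x))) != 1L) {
    stop(sprintf("%s: unequal sequence lengths (not an alignment)", path))
  }
  labels <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(labels)) {
    stop(sprintf("%s: duplicate sequence label '%s'", path,
                 labels[duplicated(labels)][1]))
  }
  m <- do.call(rbind, strsplit(as.character(x), ""))
  rownames(m) <- labels
  m
}

#' Write an alignment to FASTA
#' @param alignment character matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  seqs <- apply(alignment, 1, paste, collapse = "")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- rownames(alignment)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Column homogeneity
#'
#' Mean pairwise residue similarity over all unordered pairs of non-gap
#' residues in the column, using BLOSUM62 rescaled to `[0, 1]` (maximal
#' diagonal -> 1, minimum entry -> 0).  Columns with fewer than two
#' non-gap residues score 0 by convention.  Gap characters are `-` and
#' `.`; unknown residues are treated as `X`.
#'
#' @param column character vector of single residues (one alignment
#'   column).
#' @return a number in `[0, 1]`.
#' @export
column_homogeneity <- function(column) {
  res <- column[!(column %in% .GAP_CHARS)]
  n <- length(res)
  if (n < 2L) return(0)
  res <- .clean_residues(res)
  s <- .blosum62_scaled()
  cnt <- table(res)
  r <- names(cnt)
  nv <- as.numeric(cnt)
  sub <- s[r, r, drop = FALSE]
  ordered_sum <- drop(t(nv) %*% sub %*% nv) - sum(nv * diag(sub))
  ordered_sum / (n * (n - 1))
}

#' Per-site gap fraction and homogeneity
#'
#' @param alignment character matrix.
#' @return data frame (column, gap_fraction, homogeneity).
#' @export
site_stats <- function(alignment) {
  stopifnot(is.matrix(alignment), nrow(alignment) >= 1)
  gap <- colMeans(base::matrix(alignment %in% .GAP_CHARS, nrow(alignment)))
  hom <- apply(alignment, 2, column_homogeneity)
  data.frame(column = seq_len(ncol(alignment)), gap_fraction = gap,
             homogeneity = as.numeric(hom))
}

#' Filter alignment sites by gap fraction and homogeneity
#'
#' A site is removed when its gap fraction is strictly greater than
#' `max_gap` *or* its homogeneity is strictly below `min_hom` (remove
#' on either failure: a wholly gappy but homogeneous column is still
#' useless for tree inference).  Surviving columns keep their order.
#'
#' @param alignment character matrix.
#' @param max_gap maximum tolerated gap fraction (default 0.5; a site
#'   at exactly 0.5 is kept).
#' @param min_hom minimum tolerated homogeneity (default 0.1; a site at
#'   exactly 0.1 is kept).
#' @return list with `alignment` (filtered matrix) and `stats` (the
#'   [site_stats()] frame plus `removed` and `reason` columns).
#' @export
filter_sites <- function(alignment, max_gap = 0.5, min_hom = 0.1) {
  st <- site_stats(alignment)
  bad_gap <- st$gap_fraction > max_gap
  bad_hom <- st$homogeneity < min_hom
  st$removed <- bad_gap | bad_hom
  st$reason <- ifelse(bad_gap & bad_hom, "gap_fraction+homogeneity",
                      ifelse(bad_gap, "gap_fraction",
                             ifelse(bad_hom, "homogeneity", "")))
  if (all(st$removed)) {
    stop(sprintf("all %d sites removed (max_gap = %g, min_hom = %g)",
                 ncol(alignment), max_gap, min_hom))
  }
  list(alignment = alignment[, !st$removed, drop = FALSE], stats = st)
}

#' Drop fragmented sequences
#'
#' Removes rows whose gap fraction over the (already filtered) columns
#' is strictly greater than `max_row_gap`.
#'
#' @param alignment character matrix.
#' @param max_row_gap maximum tolerated per-row gap fraction; default
#'   2/3.
#' @return the alignment without fragmented rows.
#' @export
drop_fragmented <- function(alignment, max_row_gap = 2 / 3) {
  stopifnot(is.matrix(alignment), max_row_gap >= 0, max_row_gap <= 1)
  gap <- rowMeans(base::matrix(alignment %in% .GAP_CHARS, nrow(alignment)))
  keep <- gap <= max_row_gap
  if (!any(keep)) {
    stop(sprintf("all %d sequences removed as fragmented (max_row_gap = %g)",
                 nrow(alignment), max_row_gap))
  }
  alignment[keep, , drop = FALSE]
}

#' Re-qualify clades after alignment cleaning
#'
#' Recomputes each clade's weighted representation among the genomes
#' still present in the alignment (row labels keyed by the genome
#' prefix before the first `|`) and removes rows of clades whose
#' representation fell strictly below `threshold`.  Rows from genomes
#' absent from the clade map are dropped with a warning.
#'
#' @param alignment character matrix with genome-keyed rownames.
#' @param clades genome -> clade map.
#' @param weights genome weights.
#' @param threshold minimum weighted representation, default 0.5
#'   (strictly-below clades are removed).
#' @return list with `alignment` (surviving rows) and `clades`
#'   (character vector of surviving clade ids); callers re-test the
#'   minimum-clade-count condition on `clades`.
#' @export
requalify_clades <- function(alignment, clades, weights, threshold = 0.5) {
  cl <- .as_clade_map(clades)
  w <- .as_weights_vector(weights)
  genomes <- leaf_genomes(rownames(alignment))
  unmapped <- !(genomes %in% names(cl)) | !(genomes %in% names(w))
  if (any(unmapped)) {
    warning(sprintf("%d row(s) from genomes without clade/weight assignment dropped",
                    sum(unmapped)))
    alignment <- alignment[!unmapped, , drop = FALSE]
    genomes <- genomes[!unmapped]
  }
  totals <- clade_weight_totals(w, cl)
  present <- tapply(w[unique(genomes)], cl[unique(genomes)], sum)
  repc <- stats::setNames(numeric(length(totals)), names(totals))
  repc[names(present)] <- as.numeric(present) / totals[names(present)]
  surviving <- names(repc)[repc >= threshold]
  keep <- cl[genomes] %in% surviving
  list(alignment = alignment[keep, , drop = FALSE],
       clades = intersect(surviving, unique(cl[genomes])))
}
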