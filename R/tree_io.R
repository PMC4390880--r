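#' @keywords internal
#' @importFrom ape reorder.phylo dist.nodes nodepath getMRCA bind.tree
#'   drop.tip keep.tip
"_PACKAGE"

## Shared data model
##
## Trees are `ape::phylo` objects throughout: an `edge` matrix
## (parent, child), `edge.length` in substitutions/site, `tip.label`,
## `Nnode`.  All trees handled here are rooted; multifurcations and
## degree-2 (single-child) nodes are permitted.  Clade maps are named
## character vectors genome_id -> clade_id; membership tables are data
## frames with columns genome_id, gene_id, cluster_id.

.NEWICK_TOKEN_RE <- "'(?:[^']|'')*'|[(),;:]|[^(),;:'[:space:]]+"

.is_quoted <- function(tok) startsWith(tok, "'")

.unquote_label <- function(tok) {
  if (.is_quoted(tok)) {
    gsub("''", "'", substr(tok, 2L, nchar(tok) - 1L), fixed = TRUE)
  } else {
    tok
  }
}

.quote_label <- function(label) {
  needs <- grepl("[][(),;:'[:space:]]", label)
  out <- label
  out[needs] <- paste0("'", gsub("'", "''", label[needs], fixed = TRUE), "'")
  out
}

#' Parse a Newick string into a rooted tree
#'
#' Accepts standard Newick with branch lengths, multifurcations,
#' single-quoted labels (with `''` escapes) and internal node labels.
#' Underscores in unquoted labels are kept literal (they are common in
#' genome identifiers).  Missing branch lengths default to 0; the root's
#' own incoming length, if present, is stored as `root.edge`.
#'
#' @param text a single Newick string, terminated by `;`.
#' @return an object of class `phylo` (rooted; internal labels, when
#'   present, in `node.label`).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:3);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr(.NEWICK_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("empty Newick string")
  toks <- regmatches(text, list(m))[[1]]
  pos <- as.integer(m)

  perr <- function(i, msg) {
    p <- if (i <= length(pos)) pos[i] else nchar(text) + 1L
    stop(sprintf("Newick parse error at position %d: %s", p, msg), call. = FALSE)
  }

  ## node records
  parent <- integer(0); label <- character(0)
  len <- numeric(0); internal <- logical(0)
  nnode <- 0L
  new_node <- function(par, is_int) {
    nnode <<- nnode + 1L
    parent[nnode] <<- par
    label[nnode] <<- NA_character_
    len[nnode] <<- NA_real_
    internal[nnode] <<- is_int
    nnode
  }

  stack <- integer(0)        # open internal nodes
  cur <- NA_integer_         # last completed node (awaiting label/length)
  done <- FALSE
  i <- 1L
  n_tok <- length(toks)
  while (i <= n_tok) {
    tok <- toks[i]
    if (done) perr(i, "content after terminating ';'")
    if (tok == "(") {
      par <- if (length(stack)) stack[length(stack)] else 0L
      id <- new_node(par, TRUE)
      stack <- c(stack, id)
      cur <- NA_integer_
    } else if (tok == ")") {
      if (!length(stack)) perr(i, "unbalanced ')'")
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ",") {
      if (!length(stack)) perr(i, "',' outside parentheses")
      cur <- NA_integer_
    } else if (tok == ":") {
      if (is.na(cur)) perr(i, "':' with no preceding node")
      if (i == n_tok) perr(i, "':' at end of input")
      v <- suppressWarnings(as.numeric(toks[i + 1L]))
      if (is.na(v)) perr(i + 1L, sprintf("expected a branch length, got '%s'", toks[i + 1L]))
      len[cur] <- v
      i <- i + 1L
    } else if (tok == ";") {
      if (length(stack)) perr(i, "unbalanced '(' at ';'")
      if (is.na(cur)) perr(i, "';' with no tree content")
      done <- TRUE
    } else {
      ## a label token
      if (!is.na(cur)) {
        ## label of the node just closed (internal label)
        if (!is.na(label[cur])) perr(i, "two consecutive labels")
        label[cur] <- .unquote_label(tok)
      } else {
        par <- if (length(stack)) stack[length(stack)] else 0L
        id <- new_node(par, FALSE)
        label[id] <- .unquote_label(tok)
        cur <- id
      }
    }
    i <- i + 1L
  }
  if (!done) perr(n_tok + 1L, "missing terminating ';'")
  if (sum(parent == 0L) != 1L) perr(1L, "tree must have exactly one root")

  bad <- which(!is.na(len) & (!is.finite(len) | len < 0))
  if (length(bad)) {
    stop(sprintf("branch lengths must be finite and >= 0 (offending value %g)", len[bad[1]]),
         call. = FALSE)
  }

  tips <- which(!internal)
  ints <- which(internal)
  ntip <- length(tips)

  if (ntip >= 1L && !length(ints)) {
    ## bare leaf, e.g. "A:0;" -- represent as root + single tip
    if (ntip > 1L) perr(1L, "multiple top-level leaves without parentheses")
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = if (is.na(len[tips])) 0 else len[tips],
      tip.label = label[tips],
      Nnode = 1L), class = "phylo")
    return(tr)
  }
  if (ntip < 1L) stop("tree has no leaves", call. = FALSE)
  if (anyDuplicated(label[tips])) {
    stop(sprintf("duplicate leaf label '%s'", label[tips][duplicated(label[tips])][1]),
         call. = FALSE)
  }

  ## phylo numbering: tips 1..ntip in order of appearance, internals
  ## ntip+1.. in order of creation (root first)
  newid <- integer(nnode)
  newid[tips] <- seq_len(ntip)
  newid[ints] <- ntip + seq_along(ints)
  nonroot <- which(parent != 0L)
  edge <- cbind(newid[parent[nonroot]], newid[nonroot])
  elen <- len[nonroot]
  elen[is.na(elen)] <- 0

  tr <- list(edge = edge, edge.length = elen, tip.label = label[tips],
             Nnode = length(ints))
  int_lab <- label[ints]
  if (any(!is.na(int_lab))) {
    int_lab[is.na(int_lab)] <- ""
    tr$node.label <- int_lab
  }
  root_id <- which(parent == 0L)
  if (internal[root_id] && !is.na(len[root_id])) tr$root.edge <- len[root_id]
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Serialise a rooted tree to Newick
#'
#' Branch lengths are printed with at least 6 significant digits
#' (default 10); zero-length branches are written as `0`, never omitted.
#' Labels containing Newick metacharacters or whitespace are
#' single-quoted.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string (ending in `;`).
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"), digits >= 6)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  ntip <- length(tree$tip.label)
  if (ntip == 1L && tree$Nnode == 1L) {
    l <- if (!is.null(tree$edge.length)) tree$edge.length[1] else 0
    return(paste0(.quote_label(tree$tip.label), ":", fmt(l), ";"))
  }
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(tree$edge))
  po <- ape::reorder.phylo(tree, "postorder")
  ## map reordered edges back: reorder keeps edge/edge.length in sync
  edge <- po$edge
  elen <- po$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(edge))
  nlab <- tree$node.label
  str <- character(ntip + tree$Nnode)
  str[seq_len(ntip)] <- .quote_label(tree$tip.label)
  parents <- unique(edge[, 1])          # postorder: children complete first
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (p in parents) {
    rows <- kids[[as.character(p)]]
    parts <- paste0(str[edge[rows, 2]], ":", fmt(elen[rows]))
    lab <- if (!is.null(nlab)) .quote_label(nlab[p - ntip]) else ""
    if (identical(lab, "''")) lab <- ""
    str[p] <- paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  root <- ntip + 1L
  paste0(str[root], ";")
}

#' Read a Newick tree file
#'
#' @param path path to a file whose first non-empty line holds one
#'   Newick string.
#' @return a `phylo` object (see [parse_newick()]).
#' @export
read_newick <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty tree file: %s", path))
  parse_newick(paste(lines, collapse = ""))
}

#' Write a tree to a Newick file
#' @param tree a `phylo` object.
#' @param path output path.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick_file <- function(tree, path, digits = 10) {
  writeLines(write_newick(tree, digits), path)
  invisible(path)
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE)
  if (!nrow(df)) stop(sprintf("empty table: %s", path))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a genome-to-clade map
#'
#' @param path TSV with header columns `genome_id`, `clade_id`.
#' @return named character vector: `genome_id -> clade_id`.
#' @export
read_clade_map <- function(path) {
  df <- .read_tsv(path, c("genome_id", "clade_id"))
  if (anyDuplicated(df$genome_id)) {
    stop(sprintf("%s: genome mapped to more than one clade: %s", path,
                 df$genome_id[duplicated(df$genome_id)][1]))
  }
  stats::setNames(df$clade_id, df$genome_id)
}

#' Read an ortholog-cluster membership table
#'
#' Flat-file style: one row per gene, columns `genome_id`, `gene_id`,
#' `cluster_id`.  A gene may occur only once per genome; a genome may
#' contribute several genes (paralogs) to one cluster.
#'
#' @param path TSV path with header.
#' @return data frame with character columns genome_id, gene_id,
#'   cluster_id.
#' @export
read_membership <- function(path) {
  df <- .read_tsv(path, c("genome_id", "gene_id", "cluster_id"))
  key <- paste(df$genome_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("%s: duplicated (genome, gene) row: (%s, %s)", path,
                 d$genome_id, d$gene_id))
  }
  df[c("genome_id", "gene_id", "cluster_id")]
}

#' Read membership and clade tables together
#'
#' Genomes present in the membership table but absent from the clade map
#' are reported with a warning; downstream clade statistics exclude
#' them.
#'
#' @param membership_path TSV (genome_id, gene_id, cluster_id).
#' @param clade_path TSV (genome_id, clade_id).
#' @return list with elements `membership` (data frame) and `clades`
#'   (named character vector).
#' @export
read_tables <- function(membership_path, clade_path) {
  membership <- read_membership(membership_path)
  clades <- read_clade_map(clade_path)
  unmapped <- setdiff(unique(membership$genome_id), names(clades))
  if (length(unmapped)) {
    warning(sprintf("%d genome(s) in membership absent from clade map (excluded from clade statistics): %s",
                    length(unmapped), paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  list(membership = membership, clades = clades)
}

#' Genome identifiers of a tree's leaves
#'
#' Gene-tree leaves are labelled `genome_id|gene_id`; the prefix before
#' the first `|` keys into the clade map and weight table.  Labels
#' without `|` are taken as bare genome ids (species trees).
#'
#' @param tree a `phylo` object, or a character vector of labels.
#' @return character vector of genome ids, one per leaf/label.
#' @export
leaf_genomes <- function(tree) {
  labels <- if (inherits(tree, "phylo")) tree$tip.label else tree
  sub("\\|.*$", "", labels)
}

## coerce helpers shared by the statistics modules
.as_weights_vector <- function(weights) {
  if (inherits(weights, "genome_weights")) return(weights$weights)
  if (is.data.frame(weights)) {
    stopifnot(all(c("genome_id", "weight") %in% names(weights)))
    return(stats::setNames(as.numeric(weights$weight), weights$genome_id))
  }
  if (is.numeric(weights) && !is.null(names(weights))) return(weights)
  stop("weights must be a genome_weights object, a named numeric vector, or a (genome_id, weight) data frame")
}

.as_clade_map <- function(clades) {
  if (is.data.frame(clades)) {
    stopifnot(all(c("genome_id", "clade_id") %in% names(clades)))
    return(stats::setNames(as.character(clades$clade_id), clades$genome_id))
  }
  if (is.character(clades) && !is.null(names(clades))) return(clades)
  stop("clades must be a named character vector or a (genome_id, clade_id) data frame")
}
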