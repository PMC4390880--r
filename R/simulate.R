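## Synthetic data emulating an archaeal phylogenomic study: a
## clade-structured species tree (13 clades, 168 genomes by default,
## exponential branch lengths), gene trees drawn as perturbations of
## the species tree with a planted fraction placing the focal clade
## next to designated sister clades, and phyletic matrices with planted
## exclusively-shared gene sets over background presence noise.

.DEFAULT_CLADES <- c(
  "Halobacteria", "Methanomicrobia", "Sulfolobales", "Thermococci",
  "Methanococci", "Methanobacteria", "Thermoproteales",
  "Desulfurococcales", "Thermoplasmata", "Thaumarchaeota",
  "Archaeoglobi", "Nanoarchaeota", "Korarchaeota")

## genomes per clade; skewed like real sampling (dense Halobacteria,
## a single Korarchaeota genome), summing to 168
.DEFAULT_SIZES <- c(30, 25, 22, 18, 15, 13, 11, 9, 8, 7, 5, 4, 1)

.DEFAULT_EURY <- c("Thermococci", "Methanococci", "Methanobacteria",
                   "Methanomicrobia", "Halobacteria", "Thermoplasmata",
                   "Archaeoglobi")

#' Simulation configuration
#'
#' Defaults state the emulated world: 13 clades totalling 168 genomes
#' with realistic sampling skew, exponential branch lengths of mean 0.1
#' substitutions/site, a gene-tree class mixture matching the observed
#' core-gene breakdown (topology I ~0.215, topology II ~0.315, the
#' rest perturbed), and per-genome taxon sampling of 0.8 emulating
#' patchy cluster presence.
#'
#' @param seed integer seed; fixes every generated object bit-for-bit.
#' @param n_clades number of clades (>= 2).
#' @param clade_names clade labels (length `n_clades`).
#' @param genomes_per_clade integer vector of clade sizes.
#' @param target focal clade id.
#' @param sister_set topology-II sister clades.
#' @param enclosing enclosing-group clades (must include target and
#'   sister set); kept monophyletic in the species tree.
#' @param bl_mean mean of the exponential branch-length law
#'   (substitutions/site).
#' @param stem_factor multiplier applied to the target clade's stem
#'   branch (> 1 emulates the long-branch regime).
#' @param n_gene_trees number of gene trees to simulate.
#' @param p_topology_II,p_topology_I planted class probabilities (sum
#'   <= 1; the remainder are random-SPR "X" trees).
#' @param spr_moves subtree-prune-regraft moves applied to "X" trees.
#' @param taxon_sampling per-genome retention probability per gene
#'   tree (1 = every genome in every tree).
#' @param background_p per-genome presence probability of background
#'   clusters in the phyletic matrix.
#' @param n_background number of background clusters.
#' @param planted_sets named list: `"CladeA+CladeB" = n` plants `n`
#'   clusters present single-copy in every genome of those clades and
#'   absent elsewhere.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clades = 13L,
                       clade_names = .DEFAULT_CLADES,
                       genomes_per_clade = .DEFAULT_SIZES,
                       target = "Thermococci",
                       sister_set = c("Methanococci", "Methanobacteria"),
                       enclosing = .DEFAULT_EURY,
                       bl_mean = 0.1,
                       stem_factor = 1,
                       n_gene_trees = 200L,
                       p_topology_II = 69 / 219,
                       p_topology_I = 47 / 219,
                       spr_moves = 3L,
                       taxon_sampling = 0.8,
                       background_p = 0.1,
                       n_background = 200L,
                       planted_sets = list(
                         "Thermococci+Methanococci" = 10L,
                         "Thermococci+Methanobacteria" = 5L,
                         "Thermococci+Methanococci+Methanobacteria" = 8L)) {
  if (n_clades < 2L) stop("n_clades must be >= 2")
  stopifnot(length(clade_names) == n_clades,
            length(genomes_per_clade) == n_clades,
            all(genomes_per_clade >= 1))
  probs <- c(p_topology_II, p_topology_I, taxon_sampling, background_p)
  if (any(probs < 0 | probs > 1) || p_topology_II + p_topology_I > 1) {
    stop("probabilities must lie in [0, 1] and p_topology_I + p_topology_II <= 1")
  }
  stopifnot(bl_mean > 0, stem_factor > 0, seed == as.integer(seed))
  if (!(target %in% clade_names)) stop("target must be one of clade_names")
  if (!all(c(target, sister_set) %in% c(enclosing, target))) {
    stop("sister_set must lie inside the enclosing group")
  }
  structure(list(seed = as.integer(seed), n_clades = as.integer(n_clades),
                 clade_names = clade_names,
                 genomes_per_clade = as.integer(genomes_per_clade),
                 target = target, sister_set = sister_set,
                 enclosing = intersect(c(enclosing, target), clade_names),
                 bl_mean = bl_mean, stem_factor = stem_factor,
                 n_gene_trees = as.integer(n_gene_trees),
                 p_topology_II = p_topology_II, p_topology_I = p_topology_I,
                 spr_moves = as.integer(spr_moves),
                 taxon_sampling = taxon_sampling,
                 background_p = background_p,
                 n_background = as.integer(n_background),
                 planted_sets = planted_sets),
            class = "sim_config")
}

## random binary newick over a set of pre-built subtree strings,
## coalescent-style joins, exponential branch lengths
.rand_join_nwk <- function(parts, bl_mean) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    merged <- sprintf("(%s:%.10g,%s:%.10g)",
                      parts[i[1]], stats::rexp(1, 1 / bl_mean),
                      parts[i[2]], stats::rexp(1, 1 / bl_mean))
    parts <- c(parts[-i], merged)
  }
  parts
}

#' Generate a clade-structured species tree
#'
#' Builds a rooted, clade-monophyletic species tree: the enclosing
#' group's clades form one monophyletic block, the remaining clades the
#' other; within-block and within-clade topologies are random with
#' exponential branch lengths.  Genome ids are `<Clade>_gNN`, so the
#' clade map is recoverable from the id prefix.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (`phylo`), `clades` (named character
#'   vector), `weights` (`genome_weights`, root weight = number of
#'   genomes) and `config`.
#' @export
make_species_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  clades <- config$clade_names
  sizes <- config$genomes_per_clade
  genome_ids <- mapply(function(cl, n) paste0(cl, "_g", sprintf("%02d", seq_len(n))),
                       clades, sizes, SIMPLIFY = FALSE)
  clade_nwk <- vapply(seq_along(clades), function(i) {
    ids <- genome_ids[[i]]
    if (length(ids) == 1L) ids else .rand_join_nwk(ids, config$bl_mean)
  }, character(1))
  names(clade_nwk) <- clades

  inner <- intersect(config$enclosing, clades)
  outer <- setdiff(clades, inner)
  stem <- function(x, fac = 1) sprintf("%s:%.10g", x, fac * stats::rexp(1, 1 / config$bl_mean))
  block <- function(members) {
    parts <- vapply(members, function(cl) {
      fac <- if (cl == config$target) config$stem_factor else 1
      stem(clade_nwk[[cl]], fac)
    }, character(1))
    if (length(parts) == 1L) return(sub(":[0-9.eE+-]+$", "", parts))
    joined <- parts
    while (length(joined) > 1L) {
      i <- sample.int(length(joined), 2L)
      merged <- sprintf("(%s,%s):%.10g", joined[i[1]], joined[i[2]],
                        stats::rexp(1, 1 / config$bl_mean))
      joined <- c(joined[-i], merged)
    }
    sub(":[0-9.eE+-]+$", "", joined)
  }
  nwk <- if (length(outer)) {
    sprintf("(%s:%.10g,%s:%.10g);", block(outer), stats::rexp(1, 1 / config$bl_mean),
            block(inner), stats::rexp(1, 1 / config$bl_mean))
  } else {
    sprintf("%s;", block(inner))
  }
  tree <- parse_newick(nwk)
  ids <- unlist(genome_ids, use.names = FALSE)
  cl_map <- stats::setNames(rep(clades, sizes), ids)
  weights <- distribute_weights(tree, root_weight = length(ids))
  list(tree = tree, clades = cl_map, weights = weights, config = config)
}

## prune a clade's leaves and regraft them (as a subtree with a fresh
## stem) onto the edge above the MRCA of `attach_tips`
.regraft_clade <- function(tree, clade_tips, attach_tips, stem_length) {
  sub <- ape::keep.tip(tree, clade_tips)
  rest <- ape::drop.tip(tree, clade_tips)
  at <- if (length(attach_tips) == 1L) {
    which(rest$tip.label == attach_tips)
  } else {
    ape::getMRCA(rest, attach_tips)
  }
  sub$root.edge <- stem_length
  ## split the attachment edge at its midpoint
  erow <- which(rest$edge[, 2] == at)
  pos <- if (length(erow)) rest$edge.length[erow] / 2 else 0
  ape::bind.tree(rest, sub, where = at, position = pos)
}

## one random SPR move preserving leaf set; fresh exponential lengths
## on the two edges touched
.spr_once <- function(tree, bl_mean) {
  ntip <- length(tree$tip.label)
  tu <- .tips_under(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  candidates <- setdiff(seq_len(nn), root)
  for (attempt in 1:20) {
    prune <- sample(candidates, 1)
    moved_tips <- tree$tip.label[tu[[prune]]]
    if (length(moved_tips) >= ntip - 2L) next
    rest_tips <- setdiff(tree$tip.label, moved_tips)
    attach_tip <- sample(rest_tips, 1)
    out <- tryCatch(.regraft_clade(tree, moved_tips, attach_tip,
                                   stats::rexp(1, 1 / bl_mean)),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  tree
}

#' Simulate gene trees with planted topology signal
#'
#' Each tree draws a class label: "II" (probability `p_topology_II`)
#' regrafts the target clade as sister to one randomly chosen
#' sister-set clade; "I" (`p_topology_I`) regrafts it as sister to the
#' rest of the enclosing group (basal position); "X" (remainder)
#' applies `spr_moves` random SPR moves to the species tree.  Genomes
#' are then subsampled independently with probability `taxon_sampling`.
#' Trees are returned rooted as built; the true class labels are
#' recorded.
#'
#' @param species output of [make_species_tree()] (or a compatible
#'   list with `tree`, `clades`, `config`).
#' @param config optional [sim_config()] overriding `species$config`.
#' @return list with `trees` (named list of `phylo`), `classes` (named
#'   character vector of true labels) and `config`.
#' @export
simulate_gene_trees <- function(species, config = species$config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- species$tree
  cl <- species$clades
  if (!any(cl == config$target)) stop("target clade absent from species tree")
  set.seed(config$seed + 1000L)
  n <- config$n_gene_trees
  pX <- 1 - config$p_topology_II - config$p_topology_I
  classes <- sample(c("II", "I", "X"), n, replace = TRUE,
                    prob = c(config$p_topology_II, config$p_topology_I, pX))
  target_tips <- names(cl)[cl == config$target]
  trees <- vector("list", n)
  for (j in seq_len(n)) {
    gt <- switch(classes[j],
      II = {
        sis <- sample(config$sister_set, 1)
        .regraft_clade(tree, target_tips, names(cl)[cl == sis],
                       stats::rexp(1, 1 / config$bl_mean))
      },
      I = {
        rest_enc <- setdiff(config$enclosing, config$target)
        .regraft_clade(tree, target_tips,
                       names(cl)[cl %in% rest_enc],
                       stats::rexp(1, 1 / config$bl_mean))
      },
      X = {
        out <- tree
        if (config$spr_moves > 0) {
          for (k in seq_len(config$spr_moves)) out <- .spr_once(out, config$bl_mean)
        }
        out
      })
    if (config$taxon_sampling < 1) {
      keep <- gt$tip.label[stats::runif(length(gt$tip.label)) <= config$taxon_sampling]
      if (length(keep) < 3L) keep <- sample(gt$tip.label, 3L)
      gt <- ape::keep.tip(gt, keep)
    }
    trees[[j]] <- gt
  }
  ids <- sprintf("gt%04d", seq_len(n))
  names(trees) <- ids
  list(trees = trees, classes = stats::setNames(classes, ids), config = config)
}

#' Simulate a phyletic matrix with planted exclusive gene sets
#'
#' Planted clusters are present single-copy in every genome of their
#' designated clade subset and absent elsewhere; background clusters
#' are present per genome independently with probability
#' `background_p`.
#'
#' @param clades genome -> clade map (e.g. from [make_species_tree()]).
#' @param config a [sim_config()].
#' @return list with `membership` (data frame genome_id, gene_id,
#'   cluster_id) and `truth` (data frame cluster_id, clade_set for the
#'   planted clusters).
#' @export
simulate_phyletic_matrix <- function(clades, config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- .as_clade_map(clades)
  set.seed(config$seed + 2000L)
  rows <- list()
  truth <- list()
  for (set_name in names(config$planted_sets)) {
    set_clades <- strsplit(set_name, "+", fixed = TRUE)[[1]]
    if (!all(set_clades %in% cl)) {
      stop(sprintf("planted set '%s' names unknown clades", set_name))
    }
    genomes <- names(cl)[cl %in% set_clades]
    for (k in seq_len(config$planted_sets[[set_name]])) {
      cid <- sprintf("planted_%s_%02d", gsub("+", "-", set_name, fixed = TRUE), k)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genomes,
        gene_id = paste0(cid, "@", genomes),
        cluster_id = cid, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        cluster_id = cid, clade_set = set_name, stringsAsFactors = FALSE)
    }
  }
  all_genomes <- names(cl)
  if (config$n_background > 0) {
    for (k in seq_len(config$n_background)) {
      cid <- sprintf("bg_%04d", k)
      hit <- all_genomes[stats::runif(length(all_genomes)) <= config$background_p]
      if (!length(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = hit, gene_id = paste0(cid, "@", hit),
        cluster_id = cid, stringsAsFactors = FALSE)
    }
  }
  membership <- do.call(rbind, rows)
  rownames(membership) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cluster_id = character(0), clade_set = character(0))
  list(membership = membership, truth = truth)
}

#' Write a full synthetic fixture set to disk
#'
#' Emits `species.nwk`, `clades.tsv`, `weights.tsv`, `trees/*.nwk`,
#' `tree_classes.tsv`, `membership.tsv` and `truth.tsv` under `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(config, outdir) {
  sp <- make_species_tree(config)
  gt <- simulate_gene_trees(sp)
  pm <- simulate_phyletic_matrix(sp$clades, config)
  dir.create(file.path(outdir, "trees"), recursive = TRUE, showWarnings = FALSE)
  write_newick_file(sp$tree, file.path(outdir, "species.nwk"))
  utils::write.table(data.frame(genome_id = names(sp$clades),
                                clade_id = as.character(sp$clades)),
                     file.path(outdir, "clades.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_weights(sp$weights, file.path(outdir, "weights.tsv"))
  for (id in names(gt$trees)) {
    write_newick_file(gt$trees[[id]], file.path(outdir, "trees", paste0(id, ".nwk")))
  }
  utils::write.table(data.frame(tree_id = names(gt$classes),
                                true_class = as.character(gt$classes)),
                     file.path(outdir, "tree_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pm$membership, file.path(outdir, "membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pm$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
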