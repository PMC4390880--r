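## End-to-end orchestration: weights -> phyletic statistics ->
## alignment cleaning -> gene-tree affinity, with TSV reports.

.ARCOGKIT_VERSION <- function() as.character(utils::packageVersion("arcogkit"))

#' Pipeline configuration
#'
#' @param species_tree path to the rooted species tree (Newick).
#' @param clade_map path to the genome -> clade TSV.
#' @param membership optional path to the membership TSV (phyletic
#'   stages skipped when `NULL`).
#' @param tree_dir optional directory of per-cluster gene trees
#'   (`*.nwk`; affinity stages skipped when `NULL`).
#' @param alignment_dir optional directory of aligned FASTA files
#'   (cleaning stage skipped when `NULL`).
#' @param out_dir output directory.
#' @param target focal clade id.
#' @param sister_set,enclosing topology-classification clade sets (see
#'   [topology_config()]).
#' @param exclusive_in clade set for the exclusivity screen; defaults
#'   to `c(target, sister_set)`.
#' @param core_threshold core representation cut-off (default 0.75).
#' @param core_exclude clades excluded from the core test.
#' @param candidate_threshold,candidate_min_clades gene-tree candidate
#'   rule (strict > 0.5 in at least 4 clades).
#' @param affinity_threshold coverage threshold for affinity nodes.
#' @param exclusivity_cutoff strict R_E cut-off (default 10).
#' @param max_gap,min_hom,max_row_gap alignment-cleaning thresholds.
#' @param root_weight `"auto"` (number of leaves) or a positive number.
#' @param midpoint midpoint-root gene trees before analysis.
#' @param seed seed for any stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(species_tree, clade_map, membership = NULL,
                            tree_dir = NULL, alignment_dir = NULL,
                            out_dir = "arcogkit_out",
                            target = "Thermococci",
                            sister_set = c("Methanococci", "Methanobacteria"),
                            enclosing = .DEFAULT_EURY,
                            exclusive_in = NULL,
                            core_threshold = 0.75,
                            core_exclude = "Nanoarchaeota",
                            candidate_threshold = 0.5,
                            candidate_min_clades = 4,
                            affinity_threshold = 0.75,
                            exclusivity_cutoff = 10,
                            max_gap = 0.5, min_hom = 0.1, max_row_gap = 2 / 3,
                            root_weight = "auto", midpoint = TRUE,
                            seed = 1L) {
  for (p in c(species_tree, clade_map, membership, tree_dir, alignment_dir)) {
    if (!is.null(p) && !file.exists(p)) stop(sprintf("input path does not exist: %s", p))
  }
  stopifnot(core_threshold > 0, core_threshold <= 1,
            candidate_threshold >= 0, candidate_threshold < 1,
            affinity_threshold > 0, affinity_threshold <= 1,
            exclusivity_cutoff > 0)
  if (is.null(exclusive_in)) exclusive_in <- c(target, sister_set)
  structure(list(species_tree = species_tree, clade_map = clade_map,
                 membership = membership, tree_dir = tree_dir,
                 alignment_dir = alignment_dir, out_dir = out_dir,
                 target = target, sister_set = sister_set,
                 enclosing = enclosing, exclusive_in = exclusive_in,
                 core_threshold = core_threshold, core_exclude = core_exclude,
                 candidate_threshold = candidate_threshold,
                 candidate_min_clades = candidate_min_clades,
                 affinity_threshold = affinity_threshold,
                 exclusivity_cutoff = exclusivity_cutoff,
                 max_gap = max_gap, min_hom = min_hom,
                 max_row_gap = max_row_gap,
                 root_weight = root_weight, midpoint = midpoint,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.report_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arcogkit %s; seed=%d", .ARCOGKIT_VERSION(), config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages (each skipped with a message when its inputs are absent):
#' genome weighting; phyletic statistics (representation, core
#' selection, tree-candidate selection, exclusivity screen);
#' alignment cleaning; per-gene-tree affinity analysis with topology
#' classification; aggregation.  Reports are TSVs under
#' `config$out_dir`, each headed by a version/seed comment line, plus a
#' `manifest.json`-style run record; identical config and seed give
#' byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- list()

  tree <- .stage("read_species_tree", read_newick(config$species_tree))
  clades <- .stage("read_clade_map", read_clade_map(config$clade_map))
  rw <- if (identical(config$root_weight, "auto")) length(tree$tip.label)
        else as.numeric(config$root_weight)
  weights <- .stage("genome_weighting", distribute_weights(tree, root_weight = rw))
  w <- weights$weights
  .report_tsv(data.frame(genome_id = names(w), weight = format(w, digits = 12)),
              file.path(config$out_dir, "weights.tsv"), config)
  out$weights <- weights

  if (!is.null(config$membership)) {
    membership <- .stage("read_membership", read_membership(config$membership))
    mat <- .stage("phyletic_matrix", phyletic_matrix(membership))
    profile <- .stage("clade_representation",
                      clade_representation(mat, weights, clades))
    .report_tsv(data.frame(cluster_id = rownames(profile),
                           round(profile, 6), check.names = FALSE),
                file.path(config$out_dir, "representation.tsv"), config)
    core <- .stage("select_core",
                   select_core(profile,
                               excluded_clades = intersect(config$core_exclude,
                                                           colnames(profile)),
                               threshold = config$core_threshold))
    .report_tsv(data.frame(cluster_id = core),
                file.path(config$out_dir, "core_arcogs.tsv"), config)
    cand <- .stage("select_tree_candidates",
                   select_tree_candidates(profile,
                                          min_clades = config$candidate_min_clades,
                                          threshold = config$candidate_threshold))
    .report_tsv(data.frame(cluster_id = cand),
                file.path(config$out_dir, "tree_candidates.tsv"), config)
    scr <- .stage("exclusive_screen",
                  exclusive_screen(mat, clades, config$exclusive_in,
                                   cutoff = config$exclusivity_cutoff))
    scr$units <- if (nrow(scr)) contribution_units(scr$R_E, config$exclusivity_cutoff)
                 else integer(0)
    .report_tsv(scr, file.path(config$out_dir, "exclusive_genes.tsv"), config)
    out$profile <- profile; out$core <- core
    out$tree_candidates <- cand; out$exclusive <- scr
  } else {
    message("pipeline: membership table absent -- phyletic stages skipped")
  }

  if (!is.null(config$alignment_dir)) {
    aln_files <- sort(list.files(config$alignment_dir,
                                 pattern = "\\.(fa|fasta|faa)$", full.names = TRUE))
    clean_dir <- file.path(config$out_dir, "cleaned")
    dir.create(clean_dir, showWarnings = FALSE)
    clean_report <- list()
    for (f in aln_files) {
      id <- sub("\\.[^.]*$", "", basename(f))
      res <- .stage(paste0("clean:", id), {
        aln <- read_alignment(f)
        fs <- filter_sites(aln, config$max_gap, config$min_hom)
        kept <- drop_fragmented(fs$alignment, config$max_row_gap)
        rq <- requalify_clades(kept, clades, weights)
        list(fs = fs, rq = rq)
      })
      write_alignment(res$rq$alignment, file.path(clean_dir, paste0(id, ".fasta")))
      clean_report[[id]] <- data.frame(
        cluster_id = id,
        sites_in = nrow(res$fs$stats), sites_kept = sum(!res$fs$stats$removed),
        rows_kept = nrow(res$rq$alignment),
        clades_kept = length(res$rq$clades),
        stringsAsFactors = FALSE)
    }
    if (length(clean_report)) {
      .report_tsv(do.call(rbind, clean_report),
                  file.path(config$out_dir, "cleaning_report.tsv"), config)
    }
    out$cleaning <- clean_report
  } else {
    message("pipeline: alignment directory absent -- cleaning stage skipped")
  }

  if (!is.null(config$tree_dir)) {
    tcfg <- topology_config(config$target, config$sister_set, config$enclosing)
    tree_files <- sort(list.files(config$tree_dir, pattern = "\\.nwk$",
                                  full.names = TRUE))
    results <- list()
    rows <- list()
    for (f in tree_files) {
      id <- sub("\\.nwk$", "", basename(f))
      res <- .stage(paste0("affinity:", id), {
        gt <- read_newick(f)
        analyze_gene_tree(gt, weights, clades, tcfg,
                          threshold = config$affinity_threshold,
                          midpoint = config$midpoint, tree_id = id)
      })
      if (is.null(res)) next
      results[[id]] <- res
      rows[[id]] <- data.frame(tree_id = id, clade = names(res$R_star),
                               W_star = round(res$W_star, 6),
                               R_star = round(res$R_star, 6),
                               class = res$class, stringsAsFactors = FALSE)
    }
    if (!length(results)) {
      message("pipeline: no gene tree contained the target clade -- affinity skipped")
    } else {
      .report_tsv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                  file.path(config$out_dir, "affinity.tsv"), config)
      summ <- aggregate_affinity(results)
      sdf <- rbind(
        data.frame(key = paste0("mean_R_", names(summ$mean_R)),
                   value = format(round(summ$mean_R, 6), trim = TRUE)),
        data.frame(key = paste0("n_class_", names(summ$class_counts)),
                   value = as.character(summ$class_counts)),
        data.frame(key = "n_trees_with_target", value = as.character(summ$n_trees)))
      .report_tsv(sdf, file.path(config$out_dir, "summary.tsv"), config)
      out$affinity <- results
      out$summary <- summ
    }
  } else {
    message("pipeline: gene-tree directory absent -- affinity stage skipped")
  }

  manifest <- c(
    sprintf("arcogkit_version\t%s", .ARCOGKIT_VERSION()),
    sprintf("seed\t%d", config$seed),
    vapply(names(unclass(config)), function(k) {
      v <- config[[k]]
      sprintf("%s\t%s", k, paste(format(v), collapse = ","))
    }, character(1)))
  writeLines(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(out)
}
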