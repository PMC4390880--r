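# Generator checks use reduced sizes where the default scale is not the
# point; the acceptance suite exercises the full 168-genome world.

small_cfg <- function(seed = 1, n_gene_trees = 20, taxon_sampling = 1, ...) {
  sim_config(seed = seed, n_clades = 5,
             clade_names = c("T", "S1", "S2", "E1", "O1"),
             genomes_per_clade = c(4, 4, 4, 4, 4),
             target = "T", sister_set = c("S1", "S2"),
             enclosing = c("T", "S1", "S2", "E1"),
             n_gene_trees = n_gene_trees, taxon_sampling = taxon_sampling,
             planted_sets = list("T+S1" = 3), n_background = 20, ...)
}

test_that("sim_config validates its stated world", {
  expect_error(sim_config(n_clades = 1), "n_clades")
  expect_error(sim_config(p_topology_II = 0.8, p_topology_I = 0.5), "<= 1")
  expect_error(sim_config(taxon_sampling = 1.2), "probabilities")
  expect_error(sim_config(target = "NotAClade"), "clade_names")
  cfg <- sim_config()
  expect_equal(cfg$n_clades, 13L)
  expect_equal(sum(cfg$genomes_per_clade), 168L)
})

test_that("make_species_tree emits a clade-monophyletic weighted world", {
  cfg <- small_cfg(seed = 5)
  sp <- make_species_tree(cfg)
  expect_equal(length(sp$tree$tip.label), 20)
  expect_equal(sum(sp$weights$weights), 20, tolerance = 1e-9)
  for (cl in cfg$clade_names) {
    tips <- names(sp$clades)[sp$clades == cl]
    expect_true(ape::is.monophyletic(sp$tree, tips))
  }
  # the enclosing group is itself monophyletic (needed for topology I)
  enc_tips <- names(sp$clades)[sp$clades %in% cfg$enclosing]
  expect_true(ape::is.monophyletic(sp$tree, enc_tips))
})

test_that("generators are pure functions of (config, seed)", {
  a <- make_species_tree(small_cfg(seed = 9))
  b <- make_species_tree(small_cfg(seed = 9))
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  c2 <- make_species_tree(small_cfg(seed = 10))
  expect_false(identical(write_newick(a$tree), write_newick(c2$tree)))

  g1 <- simulate_gene_trees(a)
  g2 <- simulate_gene_trees(b)
  expect_identical(vapply(g1$trees, write_newick, character(1)),
                   vapply(g2$trees, write_newick, character(1)))
  expect_identical(g1$classes, g2$classes)

  m1 <- simulate_phyletic_matrix(a$clades, a$config)
  m2 <- simulate_phyletic_matrix(b$clades, b$config)
  expect_identical(m1$membership, m2$membership)
})

test_that("planted gene-tree classes are recovered without noise", {
  for (p in list(c(1, 0), c(0, 1))) {
    cfg <- small_cfg(seed = 31, p_topology_II = p[1], p_topology_I = p[2])
    sp <- make_species_tree(cfg)
    gt <- simulate_gene_trees(sp)
    tc <- topology_config(cfg$target, cfg$sister_set, cfg$enclosing)
    cls <- vapply(gt$trees, function(tr) {
      analyze_gene_tree(tr, sp$weights, sp$clades, tc, midpoint = FALSE)$class
    }, character(1))
    expect_true(all(cls == if (p[1] == 1) "II" else "I"))
    expect_true(all(gt$classes == if (p[1] == 1) "II" else "I"))
  }
})

test_that("taxon subsampling keeps trees analysable", {
  cfg <- small_cfg(seed = 13, taxon_sampling = 0.6)
  sp <- make_species_tree(cfg)
  gt <- simulate_gene_trees(sp)
  sizes <- vapply(gt$trees, function(t) length(t$tip.label), numeric(1))
  expect_true(all(sizes >= 3))
  expect_true(any(sizes < 20))
})

test_that("simulate_phyletic_matrix plants recoverable exclusive sets", {
  cfg <- small_cfg(seed = 2, background_p = 0)
  sp <- make_species_tree(cfg)
  pm <- simulate_phyletic_matrix(sp$clades, cfg)
  # planted clusters cover exactly their designated clades, single copy
  mat <- phyletic_matrix(pm$membership)
  expect_true(all(mat %in% 0:1))
  scr <- exclusive_screen(mat, sp$clades, c("T", "S1"))
  expect_setequal(scr$cluster_id, pm$truth$cluster_id)
  # membership invariants: one gene id per genome
  key <- paste(pm$membership$genome_id, pm$membership$gene_id)
  expect_false(anyDuplicated(key) > 0)

  # with background on, planted single-copy exclusives stay >= 1e4
  cfg2 <- small_cfg(seed = 2, background_p = 0.15)
  pm2 <- simulate_phyletic_matrix(sp$clades, cfg2)
  mat2 <- phyletic_matrix(pm2$membership)
  re <- exclusivity_index(mat2, sp$clades, c("T", "S1"))
  planted_pair <- pm2$truth$cluster_id[pm2$truth$clade_set == "T+S1"]
  expect_true(all(re[planted_pair] >= 1e4))
})

test_that("write_simulation emits the complete fixture set", {
  dir <- withr::local_tempdir()
  write_simulation(small_cfg(seed = 4, n_gene_trees = 3), dir)
  expect_true(file.exists(file.path(dir, "species.nwk")))
  expect_true(file.exists(file.path(dir, "clades.tsv")))
  expect_true(file.exists(file.path(dir, "weights.tsv")))
  expect_length(list.files(file.path(dir, "trees"), pattern = "\\.nwk$"), 3)
  expect_true(file.exists(file.path(dir, "membership.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  # files are mutually consistent
  cl <- read_clade_map(file.path(dir, "clades.tsv"))
  tr <- read_newick(file.path(dir, "species.nwk"))
  expect_setequal(names(cl), tr$tip.label)
})
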