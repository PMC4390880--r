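test_that("phyletic_matrix aggregates membership with paralog counts", {
  mat <- phyletic_matrix(toy_membership())
  expect_equal(mat["cogA", "g1"], 1L)
  expect_equal(mat["cogB", "g1"], 2L)   # paralogs counted
  expect_equal(mat["cogB", "g3"], 0L)   # absence = 0
})

test_that("clade representation follows the weighted-presence formula", {
  # clade genomes with weights {0.5, 1.5}, only the first has the gene
  m <- matrix(c(1L, 0L), 1, 2, dimnames = list("cog1", c("g1", "g2")))
  w <- c(g1 = 0.5, g2 = 1.5)
  cl <- c(g1 = "K", g2 = "K")
  prof <- clade_representation(m, w, cl)
  expect_equal(prof["cog1", "K"], 0.25)

  mat <- phyletic_matrix(toy_membership())
  w2 <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)
  prof2 <- clade_representation(mat, w2, toy_clades())
  expect_equal(prof2["cogA", "X"], 1.0)   # present in every clade-X genome
  expect_equal(prof2["cogB", "Y"], 0.0)   # absent from clade Y
  # presence only: paralog multiplicity does not raise representation
  expect_equal(prof2["cogB", "X"], 0.5)
})

test_that("representation requires positive clade weight", {
  m <- matrix(1L, 1, 1, dimnames = list("c", "g1"))
  expect_error(clade_representation(m, c(g1 = 0), c(g1 = "K")), "zero total weight")
})

test_that("core selection applies the non-strict 0.75 rule with exclusions", {
  prof <- rbind(
    all_high = c(1, 1, 1),
    boundary = c(0.75, 0.75, 0.75),
    one_low = c(1, 0.74, 1),
    nano_gap = c(0.9, 0.8, 0))
  colnames(prof) <- c("A", "B", "Nano")
  expect_true("all_high" %in% select_core(prof))
  expect_true("boundary" %in% select_core(prof))          # >= is non-strict
  expect_false("one_low" %in% select_core(prof))
  expect_false("nano_gap" %in% select_core(prof))
  expect_true("nano_gap" %in% select_core(prof, excluded_clades = "Nano"))
  expect_error(select_core(prof, excluded_clades = c("A", "B", "Nano")),
               "all clades excluded")
})

test_that("tree-candidate selection is strict in > threshold", {
  prof <- rbind(
    four_over = c(0.51, 0.51, 0.51, 0.51, 0),
    three_full = c(1, 1, 1, 0, 0),
    all_half = rep(0.5, 5))
  colnames(prof) <- paste0("c", 1:5)
  sel <- select_tree_candidates(prof, min_clades = 4, threshold = 0.5)
  expect_equal(sel, "four_over")          # 0.5 exactly fails the strict rule
})

test_that("exclusivity index reproduces the closed-form values", {
  # genomes: two in-set clades (I1: counts 5, I2: 3), two out-set empty
  cl <- c(a = "I1", b = "I2", c = "O1", d = "O2")
  m <- rbind(
    excl = c(5L, 3L, 0L, 0L),
    dead = c(0L, 0L, 0L, 0L),
    weak = c(2L, 2L, 1L, 0L))
  colnames(m) <- names(cl)
  re <- exclusivity_index(m, cl, in_set = c("I1", "I2"))
  expect_equal(unname(re["excl"]), (3 + 1e-4) / 1e-4)      # 30001
  expect_equal(unname(re["dead"]), 1.0)                    # 0.0001/0.0001
  expect_equal(unname(re["weak"]), 2.0001 / 1.0001)        # ~1.9999, fails >10

  expect_error(exclusivity_index(m, cl, character(0)), "empty")
  expect_error(exclusivity_index(m, cl, c("I1", "I2", "O1", "O2")), "proper subset")
})

test_that("exclusivity is count-based and immune to reweighting", {
  cl <- toy_clades()
  mat <- phyletic_matrix(toy_membership())
  re1 <- exclusivity_index(mat, cl, "X")
  # representation responds to non-uniform reweighting, R_E does not
  w1 <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)
  w2 <- c(g1 = 5, g2 = 0.2, g3 = 1, g4 = 3)
  p1 <- clade_representation(mat, w1, cl)
  p2 <- clade_representation(mat, w2, cl)
  expect_false(isTRUE(all.equal(p1, p2)))
  expect_equal(exclusivity_index(mat, cl, "X"), re1)
})

test_that("union of genome sets dominates clade representation", {
  set.seed(7)
  genomes <- paste0("g", 1:12)
  cl <- stats::setNames(rep(c("A", "B", "C"), each = 4), genomes)
  w <- stats::setNames(stats::runif(12, 0.2, 2), genomes)
  for (rep in 1:20) {
    s1 <- sample(genomes, 5)
    s2 <- sample(genomes, 5)
    m <- matrix(0L, 3, 12, dimnames = list(c("u", "c1", "c2"), genomes))
    m["c1", s1] <- 1L; m["c2", s2] <- 1L; m["u", union(s1, s2)] <- 1L
    p <- clade_representation(m, w, cl)
    expect_true(all(p["u", ] >= p["c1", ] - 1e-12))
    expect_true(all(p["u", ] >= p["c2", ] - 1e-12))
  }
})

test_that("exclusive_screen keeps strictly > cutoff, sorted descending", {
  cl <- c(a = "I", b = "O1", c = "O2")
  m <- rbind(hi = c(9L, 0L, 0L), mid = c(2L, 0L, 0L), ten = c(1L, 0L, 0L))
  colnames(m) <- names(cl)
  # force an R_E of exactly 10 via pseudocount-free counts: use cutoff at
  # the computed value instead
  scr <- exclusive_screen(m, cl, "I", cutoff = 10)
  expect_equal(scr$cluster_id, c("hi", "mid", "ten"))
  expect_true(all(diff(scr$R_E) <= 0))
  re_ten <- exclusivity_index(m, cl, "I")[["ten"]]
  scr2 <- exclusive_screen(m, cl, "I", cutoff = re_ten)   # boundary is strict
  expect_false("ten" %in% scr2$cluster_id)

  empty <- matrix(integer(0), 0, 3, dimnames = list(NULL, names(cl)))
  expect_equal(nrow(exclusive_screen(empty, cl, "I")), 0)
})

test_that("contribution units tier monotonically and reject unscreened input", {
  expect_equal(contribution_units(c(10.5, 100, 101, 1e4, 10001, 30001)),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(contribution_units(10), "R_E > 10")
  expect_error(contribution_units(c(50, 9)), "R_E > 10")
  set.seed(5)
  r <- sort(stats::runif(50, 10.01, 1e6))
  expect_true(all(diff(contribution_units(r)) >= 0))
})
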