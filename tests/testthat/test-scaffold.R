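test_that("majority vote accepts strict majorities and rejects ties", {
  genes <- c("LIG1", "REC1")
  cells <- c("tcell", "fibro")
  # dataset medians sit at ~1 (values 0.1/100 around filler-free medians);
  # construct three datasets where LIG1 in tcell is high in 2 of 3
  mk <- function(tcell_val) make_ref(paste0("d", tcell_val),
    genes, cells, c(tcell_val, 0.1, 0.1, 0.1))
  refs <- list(mk(100), mk(90), mk(0.05))
  v <- vote_expressed(refs, "tcell", "LIG1")
  expect_equal(v$votes, 2L)
  expect_equal(v$possible, 3L)
  expect_true(v$expressed)

  # 1 of 2 datasets: a tie is not a majority
  v2 <- vote_expressed(refs[c(1, 3)], "tcell", "LIG1")
  expect_equal(v2$votes, 1L)
  expect_false(v2$expressed)
})

test_that("no-evidence genes are flagged distinctly from 0/n losses", {
  refs <- list(make_ref("d1", c("LIG1", "REC1"), c("tcell", "fibro"),
                        c(100, 0.1, 0.1, 100)))
  v <- vote_expressed(refs, "tcell", "ABSENT")
  expect_true(v$no_evidence)
  expect_false(v$expressed)
  expect_equal(v$possible, 0L)

  v2 <- vote_expressed(refs, "fibro", "LIG1")
  expect_false(v2$no_evidence)
  expect_equal(v2$possible, 1L)
  expect_equal(v2$votes, 0L)
})

test_that("vote tally matches a hand recount on a constructed 3-dataset fixture", {
  set.seed(101)
  genes <- sprintf("G%02d", 1:6)
  cells <- c("a", "b", "c")
  refs <- lapply(1:3, function(d)
    make_ref(paste0("d", d), genes, cells,
             stats::rlnorm(18, meanlog = 0, sdlog = 1.5), reps_per_cell = 2L))
  for (g in genes) for (cl in cells) {
    v <- vote_expressed(refs, cl, g)
    hand_votes <- 0L
    for (ref in refs) {
      reps <- names(ref$cellmap)[ref$cellmap == cl]
      agg <- stats::median(ref$expr[g, reps])
      if (agg > stats::median(as.vector(ref$expr))) hand_votes <- hand_votes + 1L
    }
    expect_equal(v$votes, hand_votes)
    expect_equal(v$possible, 3L)
    expect_equal(v$expressed, hand_votes > 1.5)
  }
})

test_that("per-gene median mode compares against the gene's own median", {
  genes <- c("G1", "G2")
  cells <- c("a", "b", "c")
  # G1 in cell a: 5 vs per-gene median of (5,1,1)=1 -> vote; vs global
  # median of all six values (52.5) -> no vote
  refs <- list(make_ref("d1", genes, cells, c(5, 100, 1, 200, 1, 300)))
  expect_true(vote_expressed(refs, "a", "G1", median_mode = "per-gene")$expressed)
  expect_false(vote_expressed(refs, "a", "G1", median_mode = "global")$expressed)
})

test_that("toy scaffold has the full bipartite + autocrine structure", {
  pairs <- data.frame(ligand = "L1", receptor = "R1")
  expressed <- expand.grid(cell = c("a", "b"), gene = c("L1", "R1"),
                           stringsAsFactors = FALSE)
  expressed$expressed <- TRUE
  sc <- build_scaffold(pairs, expressed)
  expect_equal(nrow(sc), 4L)
  expect_equal(sum(sc$lcell == sc$rcell), 2L)
  sc2 <- build_scaffold(pairs, expressed, include_self_loops = FALSE)
  expect_equal(nrow(sc2), 2L)
  expect_true(all(sc2$lcell != sc2$rcell))
})

test_that("scaffold equals the exhaustive triple-loop oracle on random maps", {
  set.seed(202)
  for (rep in 1:5) {
    setup <- random_expressed_setup(n_cells = sample(2:10, 1),
                                    n_pairs = sample(1:50, 1))
    for (loops in c(TRUE, FALSE)) {
      oracle <- brute_scaffold(setup$pairs, setup$expressed, loops)
      got <- tryCatch(build_scaffold(setup$pairs, setup$expressed, loops),
                      error = function(e) NULL)
      if (nrow(oracle) == 0L) next
      expect_false(is.null(got))
      expect_equal(nrow(got), nrow(oracle))
      expect_equal(got[, .(lcell, ligand, receptor, rcell)],
                   data.table::as.data.table(oracle),
                   ignore_attr = TRUE)
    }
  }
})

test_that("edge set is invariant to input row order", {
  set.seed(303)
  setup <- random_expressed_setup(5, 12, p_expressed = 0.6)
  sc1 <- build_scaffold(setup$pairs, setup$expressed)
  perm_pairs <- setup$pairs[sample(nrow(setup$pairs)), ]
  perm_exp <- setup$expressed[sample(nrow(setup$expressed)), ]
  sc2 <- build_scaffold(perm_pairs, perm_exp)
  expect_identical(sc1, sc2)
})

test_that("removing a gene from a cell's expressed set never adds edges", {
  set.seed(404)
  setup <- random_expressed_setup(4, 10, p_expressed = 0.7)
  sc_full <- build_scaffold(setup$pairs, setup$expressed)
  on_rows <- which(setup$expressed$expressed)
  drop <- sample(on_rows, 1)
  reduced <- setup$expressed
  reduced$expressed[drop] <- FALSE
  sc_red <- build_scaffold(setup$pairs, reduced)
  expect_lte(nrow(sc_red), nrow(sc_full))
  key <- function(s) paste(s$lcell, s$ligand, s$receptor, s$rcell)
  expect_true(all(key(sc_red) %in% key(sc_full)))
})

test_that("degree summary conserves edge counts and matches an adjacency recount", {
  set.seed(505)
  setup <- random_expressed_setup(6, 15, p_expressed = 0.5)
  sc <- build_scaffold(setup$pairs, setup$expressed)
  ds <- scaffold_degree_summary(sc)
  expect_equal(sum(ds$ligand_side), nrow(sc))
  expect_equal(sum(ds$receptor_side), nrow(sc))
  for (cl in ds$cell) {
    recount <- sum(sc$lcell == cl | sc$rcell == cl)
    expect_equal(ds$degree[ds$cell == cl], recount)
  }
})

test_that("empty inputs raise explicit errors", {
  expect_error(build_scaffold(data.frame(ligand = character(),
                                         receptor = character()),
                              data.frame(cell = "a", gene = "L1",
                                         expressed = TRUE)),
               "empty")
  expect_error(build_scaffold(data.frame(ligand = "L1", receptor = "R1"),
                              data.frame(cell = "a", gene = "L1",
                                         expressed = FALSE)),
               "empty")
})
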