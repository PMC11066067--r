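test_that("score propagation is the mean over descendant leaves", {
  cherry <- ape::read.tree(text = "(A,B);")
  ps <- propagate_scores(scored_tree(cherry, c(A = 10, B = 20), queries = "A"))
  expect_equal(ps$score[ps$node == 3], 15)

  tr <- ape::read.tree(text = "((A,B),C);")
  ps <- propagate_scores(scored_tree(tr, c(A = 10, B = 20, C = 30), queries = "A"))
  expect_equal(ps$score[!ps$is_leaf], c(20, 15))  # root, then (A,B)

  expect_error(scored_tree(tr, c(A = 10, B = 20), queries = "A"), "C")
})

test_that("propagated scores match the brute-force leaf means on random trees", {
  for (seed in 1:5) {
    set.seed(seed)
    phy <- ape::rtree(50, br = NULL)
    scores <- stats::setNames(stats::runif(50, 0, 500), phy$tip.label)
    st <- scored_tree(phy, scores, queries = phy$tip.label[1])
    ps <- propagate_scores(st)
    expect_equal(ps$score, unname(brute_mean_scores(phy, scores)), tolerance = 1e-12)
    # invariant under child reordering
    rot <- ape::read.tree(text = ape::write.tree(ape::rotate(phy, ape::Ntip(phy) + 1L)))
    ps2 <- propagate_scores(scored_tree(rot, scores, queries = phy$tip.label[1]))
    root <- ape::Ntip(phy) + 1L
    expect_equal(ps2$score[root], ps$score[root], tolerance = 1e-12)
  }
})

test_that("clade retention keeps all leaves under MRCA(queries + passers)", {
  tr <- ape::read.tree(text = "(((Q1,Q2),(H1,N1)),N2);")
  scores <- c(Q1 = 100, Q2 = 95, H1 = 80, N1 = 10, N2 = 5)
  # queries confined to one cherry, nothing else passes
  st <- scored_tree(tr, scores, queries = c("Q1", "Q2"), threshold = 90)
  expect_setequal(select_retained_clade(st), c("Q1", "Q2"))
  # H1 passes at 75: MRCA expands, pulling the low-scoring N1 along
  st <- scored_tree(tr, scores, queries = c("Q1", "Q2"), threshold = 75)
  expect_setequal(select_retained_clade(st), c("Q1", "Q2", "H1", "N1"))
  # everything passes: the whole tree is retained
  st <- scored_tree(tr, scores, queries = c("Q1", "Q2"), threshold = 0)
  expect_setequal(select_retained_clade(st), tr$tip.label)
})

test_that("retention matches brute force and shrinks monotonically in the threshold", {
  for (seed in 1:20) {
    set.seed(seed)
    phy <- ape::rtree(20, br = NULL)
    scores <- stats::setNames(stats::runif(20, 0, 100), phy$tip.label)
    queries <- sample(phy$tip.label, 2)
    prev <- NULL
    for (thr in c(0, 25, 50, 75, 101)) {
      st <- scored_tree(phy, scores, queries, threshold = thr)
      got <- select_retained_clade(st)
      expect_setequal(got, brute_retained(phy, scores, queries, thr))
      if (!is.null(prev)) expect_true(all(got %in% prev))
      prev <- got
    }
  }
})

test_that("default threshold falls back to the minimum query score", {
  tr <- ape::read.tree(text = "((A,B),C);")
  st <- scored_tree(tr, c(A = 40, B = 60, C = 90), queries = c("A", "B"))
  expect_equal(st$threshold, 40)
})

test_that("presence matrix records binary presence and counts co-occurrence", {
  m <- build_presence_matrix(list(f1 = "x_G1"), c("G1", "G2", "G3"))
  expect_equal(unname(colSums(m)), 1)
  # duplicate leaves from one genome still one presence
  m <- build_presence_matrix(list(f1 = c("x_G1", "y_G1")), c("G1", "G2"))
  expect_equal(m["G1", "f1"], 1L)
  expect_error(build_presence_matrix(list(f1 = "x_G9"), c("G1")), "G9")

  m <- matrix(c(1L, 1L, 0L, 1L, 0L, 0L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("f1", "f2")))
  expect_equal(count_presence(m, c("f1", "f2"), "all"), 1)
  expect_equal(count_presence(m, c("f1", "f2"), "any"), 2)
  expect_equal(count_presence(m, "f1", "all"), sum(m[, "f1"]))
  expect_equal(count_presence(m, "f1", "any"), sum(m[, "f1"]))
  expect_error(count_presence(m, "f9"), "f9")
})

test_that("presence counts equal brute-force row scans on random matrices", {
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rbinom(60, 1, 0.4), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("f", 1:6)))
    fams <- sample(colnames(m), 3)
    expect_equal(count_presence(m, fams, "all"),
                 sum(apply(m[, fams] == 1, 1, all)))
    expect_equal(count_presence(m, fams, "any"),
                 sum(apply(m[, fams] == 1, 1, any)))
    expect_lte(count_presence(m, fams, "all"), count_presence(m, fams, "any"))
  }
})

test_that("simulated families yield the ground-truth presence matrix", {
  spt <- simulate_dated_tree(8, 4, seed = 21)
  genomes <- spt$phy$tip.label
  fams <- list()
  for (k in 1:3) {
    fam <- simulate_gene_family(spt, 0.3, 0.2, 0.2, seed = 30 + k)
    labs <- if (fam$n_leaves >= 2) fam$gene_tree$tip.label else
      fam$leaf_label[!is.na(fam$leaf_label)]
    fams[[paste0("fam", k)]] <- if (is.null(labs)) character(0) else labs
  }
  m <- build_presence_matrix(fams, genomes)
  for (k in seq_along(fams)) {
    truth <- as.integer(genomes %in% leaf_genome(fams[[k]]))
    expect_equal(unname(m[, k]), truth)
  }
})

test_that("score tables parse in the simplified tblout shape", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# target  profile  evalue  bitscore",
    "seq1_G1  phnJ  1e-30  210.5",
    "seq2_G2  phnJ  0.05   22.1"
  ), path)
  tb <- read_score_table(path)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$bitscore, c(210.5, 22.1))
  expect_equal(tb$target[1], "seq1_G1")
})
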