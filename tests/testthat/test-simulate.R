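test_that("simulated species trees are reproducible, dated and well-formed", {
  t1 <- simulate_dated_tree(20, 4, seed = 10)
  t2 <- simulate_dated_tree(20, 4, seed = 10)
  expect_equal(write_dated_newick(t1), write_dated_newick(t2))
  expect_equal(root_age(t1), 4)
  expect_silent(validate_dated_tree(t1))
  expect_silent(compute_time_slices(t1))
  tiny <- simulate_dated_tree(2, 1.5, seed = 1)
  expect_equal(root_age(tiny), 1.5)
  expect_equal(n_tips(tiny), 2)
  expect_error(simulate_dated_tree(1, 4), "at least 2")
})

test_that("zero rates give a congruent gene tree with speciations only", {
  spt <- simulate_dated_tree(10, 4, seed = 20)
  fam <- simulate_gene_family(spt, 0, 0, 0, seed = 21)
  expect_equal(fam$n_leaves, 10)
  expect_equal(sort(unique(fam$history$event)), c("origination", "speciation"))
  expect_equal(sum(fam$history$event == "speciation"), 9)
  expect_setequal(leaf_genome(fam$gene_tree$tip.label), spt$phy$tip.label)
  expect_equal(true_history_cost(fam), 0)
})

test_that("duplication-only families obey the copy-count identity", {
  # with no loss and no transfer, a duplication on branch x adds one extra
  # copy in every species leaf below x, so
  #   gene leaves = species leaves + sum over duplications of leaves below
  for (seed in 1:5) {
    spt <- simulate_dated_tree(8, 4, seed = 30 + seed)
    fam <- simulate_gene_family(spt, dup_rate = 0.3, seed = 40 + seed)
    n <- n_tips(spt)
    tips_below <- vapply(fam$history$branch[fam$history$event == "duplication"],
                         function(b) {
                           if (b <= n) 1L
                           else ape::Ntip(ape::extract.clade(spt$phy, b))
                         }, 0L)
    expect_equal(fam$n_leaves, n + sum(tips_below))
    expect_gte(fam$n_leaves, n)  # every genome keeps >= 1 copy
    # copy counts per genome are all >= 1
    expect_true(all(table(leaf_genome(fam$gene_tree$tip.label)) >= 1))
  }
})

test_that("simulated transfers connect branches alive at the event date", {
  for (seed in 1:5) {
    spt <- simulate_dated_tree(15, 4, seed = 50 + seed)
    fam <- simulate_gene_family(spt, 0.1, 0.4, 0.1, seed = 60 + seed)
    tr <- fam$history[fam$history$event == "transfer", ]
    br <- branches(spt)
    for (i in seq_len(nrow(tr))) {
      recv <- br[br$branch == tr$branch[i], ]
      don <- br[br$branch == tr$donor[i], ]
      expect_true(recv$t_child <= tr$date[i] && tr$date[i] <= recv$t_parent)
      expect_true(don$t_child <= tr$date[i] && tr$date[i] <= don$t_parent)
    }
  }
})

test_that("the true visible history is a feasible reconciliation (cost bound)", {
  n_checked <- 0
  for (seed in 1:25) {
    spt <- simulate_dated_tree(12, 4, seed = 1000 + seed)
    fam <- simulate_gene_family(spt, 0.2, 0.2, 0.2, seed = 2000 + seed)
    if (fam$n_leaves < 2) next
    n_checked <- n_checked + 1
    expect_lte(optimal_cost(fam$gene_tree, spt), true_history_cost(fam) + 1e-9)
  }
  expect_gte(n_checked, 10)
})

test_that("identical seeds reproduce gene families exactly", {
  spt <- simulate_dated_tree(10, 4, seed = 70)
  f1 <- simulate_gene_family(spt, 0.3, 0.2, 0.2, seed = 71)
  f2 <- simulate_gene_family(spt, 0.3, 0.2, 0.2, seed = 71)
  expect_equal(f1$history, f2$history)
  if (f1$n_leaves >= 2) {
    expect_equal(ape::write.tree(f1$gene_tree), ape::write.tree(f2$gene_tree))
  }
})

test_that("tree samples perturb by NNI and strength 0 is the identity", {
  spt <- simulate_dated_tree(8, 4, seed = 80)
  fam <- simulate_gene_family(spt, 0.3, 0.1, 0, seed = 81)
  smp0 <- simulate_tree_sample(fam$gene_tree, strength = 0, n = 10, seed = 82)
  ccp0 <- build_ccp(smp0)
  tb0 <- tibble::as_tibble(ccp0)
  expect_true(all(tb0$clade_freq == 1))  # all true clades at frequency 1
  expect_equal(nrow(dplyr::distinct(tb0, clade)),
               2L * ape::Ntip(fam$gene_tree) - 1L)
  smp <- simulate_tree_sample(fam$gene_tree, strength = 4, n = 30, seed = 83)
  ccp <- build_ccp(smp)
  # strong perturbation introduces clades absent from the true tree
  expect_gt(nrow(dplyr::distinct(tibble::as_tibble(ccp), clade)),
            nrow(dplyr::distinct(tb0, clade)))
  # leaves are preserved by every move
  for (tr in smp) expect_setequal(tr$tip.label, fam$gene_tree$tip.label)
})

test_that("simulated abundance tables honour their generating model", {
  genes <- tibble::tibble(gene = "g", form = "linear", slope = -0.5,
                          intercept = 2, noise_sd = 0)
  tb <- simulate_abundance(genes, n = 30, seed = 90)
  expect_equal(tb$g, pmax(2 - 0.5 * tb$phosphate_uM, 0), tolerance = 1e-12)
  expect_true(all(tb$phosphate_uM >= 0 & tb$phosphate_uM <= 3.29))
  tb2 <- simulate_abundance(genes, n = 30, seed = 90)
  expect_equal(tb, tb2)
})
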