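test_that("a congruent gene tree reconciles at zero cost with speciations only", {
  sp2 <- parse_dated_newick("(A:2,B:2);")
  rec <- reconcile("(a_A,b_B);", sp2)
  expect_equal(rec$total_cost, 0)
  expect_equal(sort(unique(rec$events$event)), c("origination", "speciation"))
  expect_equal(sum(rec$events$event == "speciation"), 1)

  spt <- simulate_dated_tree(12, 4, seed = 71)
  fam <- simulate_gene_family(spt, 0, 0, 0, seed = 72)
  rec <- reconcile(fam$gene_tree, spt)
  expect_equal(rec$total_cost, 0)
  expect_equal(sum(rec$events$event %in% c("duplication", "transfer", "loss")), 0)
})

test_that("default costs are transfer 3, duplication 2, loss 1, speciation 0", {
  cs <- cost_scheme()
  expect_equal(unlist(cs[c("transfer", "duplication", "loss", "speciation")]),
               c(transfer = 3, duplication = 2, loss = 1, speciation = 0))
  expect_error(cost_scheme(loss = -1), "non-negative")
})

test_that("the DP matches the exhaustive oracle on the worked 3-leaf example", {
  spt <- abc_tree()
  rec <- reconcile("((a_A,c_C),b_B);", spt)
  bf <- brute_force_reconcile("((a_A,c_C),b_B);", spt)
  expect_equal(rec$total_cost, bf$total_cost)
  expect_equal(rec$total_cost, 3)  # speciation at (A,B) node + one transfer into C
})

test_that("event cost contributions always sum to the total cost", {
  for (seed in 1:10) {
    set.seed(seed)
    inst <- random_small_instance(300 + seed)
    cs <- cost_scheme(transfer = 3, duplication = 2, loss = 1, speciation = 0.5)
    rec <- reconcile(inst$gene, inst$species, cs)
    expect_equal(sum(rec$events$cost), rec$total_cost, tolerance = 1e-9)
    validate_reconciliation(rec)
    # observed leaves never map to the dead channel: every gene leaf's genome
    # branch hosts it by construction (spot-checked via contemporaneity pass)
    expect_true(all(!is.na(rec$events$branch[rec$events$event == "speciation"])))
  }
})

test_that("scaling every cost by k > 0 scales the optimum by k", {
  inst <- random_small_instance(411)
  base <- optimal_cost(inst$gene, inst$species,
                       cost_scheme(3, 2, 1, 0.5))
  scaled <- optimal_cost(inst$gene, inst$species,
                         cost_scheme(3 * 2.5, 2 * 2.5, 1 * 2.5, 0.5 * 2.5))
  expect_equal(scaled, base * 2.5, tolerance = 1e-9)
})

test_that("optimal cost is non-decreasing in each event cost separately", {
  set.seed(5)
  for (i in 1:5) {
    inst <- random_small_instance(500 + i)
    for (which in c("transfer", "duplication", "loss", "speciation")) {
      vals <- c(0.5, 1.5, 3, 6)
      costs <- lapply(vals, function(v) {
        args <- list(transfer = 3, duplication = 2, loss = 1, speciation = 0)
        args[[which]] <- v
        do.call(cost_scheme, args)
      })
      opt <- vapply(costs, function(cs) optimal_cost(inst$gene, inst$species, cs), 0)
      expect_true(all(diff(opt) >= -1e-9))
    }
  }
})

test_that("with transfers priced out, duplication-only instances use no transfers", {
  spt <- abc_tree()
  # two copies in every genome: explainable by one ancestral duplication
  gt <- "(((a1_A,b1_B),c1_C),((a2_A,b2_B),c2_C));"
  cs <- cost_scheme(transfer = 100)
  rec <- reconcile(gt, spt, cs)
  expect_equal(sum(rec$events$event == "transfer"), 0)
  expect_equal(rec$total_cost, 2)  # one duplication above the root
})

test_that("transfer cost sensitivity includes the base cost and is monotone", {
  spt <- abc_tree()
  sens <- cost_sensitivity("((a_A,c_C),b_B);", spt, hgt_grid = c(2, 4, 6))
  expect_equal(sens$tau, c(2, 3, 4, 6))
  expect_true(all(diff(sens$total_cost) >= -1e-9))
  # congruent input: identical zero-event output for every tau
  sp2 <- parse_dated_newick("(A:2,B:2);")
  sens0 <- cost_sensitivity("(a_A,b_B);", sp2, hgt_grid = c(2, 4, 6))
  expect_true(all(sens0$total_cost == 0))
  expect_error(cost_sensitivity("(a_A,b_B);", sp2, hgt_grid = numeric(0)), "one value")
})

test_that("amalgamated reconciliation never exceeds the cheapest sampled tree", {
  spt <- simulate_dated_tree(10, 4, seed = 81)
  fam <- simulate_gene_family(spt, 0.2, 0.2, 0.1, seed = 82)
  smp <- simulate_tree_sample(fam$gene_tree, strength = 2, n = 25, seed = 83)
  ccp <- build_ccp(smp)
  am <- optimal_cost(ccp, spt)
  per <- vapply(smp, function(tr) optimal_cost(tr, spt), 0)
  expect_lte(am, min(per) + 1e-9)
  rec <- reconcile(ccp, spt)
  expect_equal(rec$total_cost, am)
  validate_reconciliation(rec)
})

test_that("an unperturbed sample amalgamates to the single-tree optimum", {
  spt <- simulate_dated_tree(8, 4, seed = 91)
  fam <- simulate_gene_family(spt, 0.2, 0.1, 0.1, seed = 92)
  smp <- simulate_tree_sample(fam$gene_tree, strength = 0, n = 5, seed = 93)
  ccp <- build_ccp(smp)
  expect_equal(optimal_cost(ccp, spt), optimal_cost(fam$gene_tree, spt))
})

test_that("unknown genomes are rejected", {
  sp2 <- parse_dated_newick("(A:2,B:2);")
  expect_error(reconcile("(a_A,z_Z);", sp2), "Z")
})

test_that("root search over an unrooted gene tree is at least as cheap as the given rooting", {
  for (seed in 1:5) {
    inst <- random_small_instance(600 + seed)
    rooted_cost <- optimal_cost(inst$gene, inst$species)
    searched <- optimal_cost(inst$gene, inst$species, unrooted = TRUE)
    expect_lte(searched, rooted_cost + 1e-9)
  }
})

test_that("brute force refuses oversized instances", {
  spt <- simulate_dated_tree(5, 3, seed = 3)
  gt <- ape::rtree(3, tip.label = paste0("x", 1:3, "_", spt$phy$tip.label[1:3]), br = NULL)
  expect_error(brute_force_reconcile(gt, spt), "restricted")
})
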