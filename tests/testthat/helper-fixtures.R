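# Shared fixture builders.  Everything is generated in code; no data files.

# The 3-leaf example tree used throughout: ((A,B) at 1 Ga, C) rooted at 3 Ga.
abc_tree <- function() parse_dated_newick("((A:1,B:1):2,C:3);")

# A random small reconciliation instance within the brute-force oracle bounds.
random_small_instance <- function(seed) {
  spt <- simulate_dated_tree(sample(2:4, 1), root_age = 3, seed = seed)
  ng <- sample(2:4, 1)
  genomes <- sample(spt$phy$tip.label, ng, replace = TRUE)
  labs <- paste0("x", seq_len(ng), "_", genomes)
  gt <- ape::rtree(ng, tip.label = labs, br = NULL)
  list(species = spt, gene = gt)
}

# Brute-force mean bit score over the descendant leaves of every node.
brute_mean_scores <- function(phy, scores) {
  n <- ape::Ntip(phy)
  vapply(seq_len(n + phy$Nnode), function(v) {
    tips <- if (v <= n) phy$tip.label[v] else ape::extract.clade(phy, v)$tip.label
    mean(scores[tips])
  }, 0)
}

# Brute-force retained set: all leaves under the MRCA of queries + passers.
brute_retained <- function(phy, scores, queries, threshold) {
  anchors <- union(queries, names(scores)[scores >= threshold])
  if (length(anchors) <= 1) return(anchors)
  ape::extract.clade(phy, ape::getMRCA(phy, anchors))$tip.label
}
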