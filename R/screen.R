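#' Scored gene trees for homolog screening
#'
#' Bundles a rooted gene tree with per-leaf HMM bit scores (and optionally
#' e-values), the designated query leaves (the experimentally characterised
#' sequences the profile was built from), and the bit-score threshold
#' ("trusted cutoff") of the profile.  The e-value prefilter (0.1 in this
#' pipeline) is assumed to have been applied upstream when the score table was
#' produced; it is documented, not enforced.
#'
#' @param tree A rooted [ape::phylo] gene tree; leaves are sequence ids.
#' @param scores Named numeric vector of bit scores, one per leaf.
#' @param queries Character vector of query leaf labels (non-empty).
#' @param threshold Bit-score threshold; defaults to the minimum query score
#'   (conservative) when the profile's trusted cutoff is not supplied.
#' @param evalues Optional named numeric vector of e-values (>= 0).
#' @return A `scored_tree` object.
#' @export
scored_tree <- function(tree, scores, queries, threshold = NULL, evalues = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(scores))
  if (length(missing)) {
    abort(sprintf("Leaf '%s' has no bit score.", missing[1]))
  }
  if (length(queries) == 0 || !all(queries %in% tips)) {
    abort("`queries` must be a non-empty subset of the leaf labels.")
  }
  if (!is.null(evalues) && any(evalues < 0, na.rm = TRUE)) {
    abort("E-values must be non-negative.")
  }
  threshold <- threshold %||% min(scores[queries])
  structure(list(tree = tree, scores = scores[tips], queries = queries,
                 threshold = threshold, evalues = evalues),
            class = "scored_tree")
}

#' @export
print.scored_tree <- function(x, ...) {
  cat(sprintf("<scored_tree> %d leaves, %d queries, threshold %.4g bits\n",
              ape::Ntip(x$tree), length(x$queries), x$threshold))
  invisible(x)
}

#' Propagate bit scores to internal nodes
#'
#' Assigns each internal node the arithmetic mean of the bit scores of all
#' its descendant leaves (leaf scores are left untouched).  The
#' descendant-leaf mean is used rather than the mean of immediate children
#' because it is independent of how the subtree happens to be resolved.
#'
#' @param x A [scored_tree()].
#' @return A tibble with columns `node` (ape node id), `label` (leaf label or
#'   `NA`), `is_leaf` and `score`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' propagate_scores(scored_tree(tr, c(A = 10, B = 20, C = 30), queries = "A"))
#' @export
propagate_scores <- function(x) {
  stopifnot(inherits(x, "scored_tree"))
  phy <- x$tree
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  total <- numeric(nn)
  count <- integer(nn)
  total[seq_len(n)] <- x$scores[phy$tip.label]
  count[seq_len(n)] <- 1L
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]; ch <- po[k, 2]
    total[p] <- total[p] + total[ch]
    count[p] <- count[p] + count[ch]
  }
  tibble(
    node = seq_len(nn),
    label = c(phy$tip.label, rep(NA_character_, phy$Nnode)),
    is_leaf = seq_len(nn) <= n,
    score = total / count
  )
}

#' Select the retained homolog clade
#'
#' Implements the monophyletic-clade retention rule: leaves that pass the
#' bit-score threshold, together with the query sequences, define a most
#' recent common ancestor; every leaf under that ancestor is retained and all
#' leaves outside it are discarded, regardless of score.
#'
#' @param x A [scored_tree()].
#' @return Character vector of retained leaf labels.
#' @export
select_retained_clade <- function(x) {
  stopifnot(inherits(x, "scored_tree"))
  phy <- x$tree
  passers <- names(x$scores)[x$scores >= x$threshold]
  anchors <- union(x$queries, passers)
  if (length(anchors) == 0) abort("No query leaves and no leaves pass the threshold.")
  if (length(anchors) == 1) return(anchors)
  mrca <- ape::getMRCA(phy, anchors)
  ape::extract.clade(phy, mrca)$tip.label
}

#' Presence matrix across genomes
#'
#' @param retained Named list: one character vector of retained leaf labels
#'   per gene family.
#' @param genomes Character vector of all genome ids (matrix rows).
#' @param genome_of Function mapping leaf labels to genome ids
#'   (default [leaf_genome()]).
#' @return A 0/1 integer matrix, genomes x families.
#' @export
build_presence_matrix <- function(retained, genomes, genome_of = leaf_genome) {
  fams <- names(retained)
  if (is.null(fams)) abort("`retained` must be a named list (one entry per family).")
  m <- matrix(0L, nrow = length(genomes), ncol = length(fams),
              dimnames = list(genomes, fams))
  for (f in fams) {
    gs <- genome_of(retained[[f]])
    unknown <- setdiff(gs, genomes)
    if (length(unknown)) {
      abort(sprintf("Leaf maps to unknown genome '%s' (family %s).", unknown[1], f))
    }
    m[unique(gs), f] <- 1L
  }
  m
}

#' Count genomes by family presence
#'
#' `mode = "all"` counts genomes carrying every listed family (co-occurrence,
#' e.g. both CP-lyase subunits); `mode = "any"` counts genomes carrying at
#' least one.
#'
#' @param presence A presence matrix from [build_presence_matrix()].
#' @param families Character vector of family (column) names.
#' @param mode `"all"` or `"any"`.
#' @return Integer genome count.
#' @examples
#' m <- matrix(c(1, 1, 0, 1, 0, 0), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("f1", "f2")))
#' count_presence(m, c("f1", "f2"), "all")
#' @export
count_presence <- function(presence, families, mode = c("all", "any")) {
  mode <- match.arg(mode)
  unknown <- setdiff(families, colnames(presence))
  if (length(unknown)) abort(sprintf("Unknown family '%s'.", unknown[1]))
  sub <- presence[, families, drop = FALSE]
  hits <- if (mode == "all") rowSums(sub) == length(families) else rowSums(sub) > 0
  sum(hits)
}

#' Read a simplified HMMER tblout-style score table
#'
#' Whitespace-delimited with four columns: target sequence id, query/profile
#' id, e-value, bit score.  Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return A tibble with columns `target`, `profile`, `evalue`, `bitscore`.
#' @export
read_score_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 4)
  if (length(bad)) abort(sprintf("Line %d has fewer than 4 columns.", bad[1]))
  tibble(
    target = vapply(parts, `[[`, "", 1),
    profile = vapply(parts, `[[`, "", 2),
    evalue = as.numeric(vapply(parts, `[[`, "", 3)),
    bitscore = as.numeric(vapply(parts, `[[`, "", 4))
  )
}
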