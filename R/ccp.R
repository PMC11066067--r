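#' Read a gene-tree sample
#'
#' Reads a Bayesian gene-tree posterior sample, either as a plain multi-tree
#' Newick file (one rooted tree per line, the shape of MrBayes `.t` output
#' once translated) or as a Nexus file with a `trees` block.
#'
#' @param path Path to the file.
#' @return An [ape::multiPhylo] list of rooted trees.
#' @export
read_tree_sample <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  trees <- if (grepl("^#NEXUS", toupper(trimws(first)))) {
    ape::read.nexus(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    ape::read.tree(text = paste(lines, collapse = "\n"))
  }
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (length(trees) == 0) abort("No trees found in the sample file.")
  trees
}

#' Discard burn-in from a tree sample
#'
#' Removes the first `floor(fraction * N)` trees of the sample, the standard
#' treatment of the early, non-converged portion of an MCMC run (25% by
#' default in this pipeline).
#'
#' @param sample An [ape::multiPhylo] list (or plain list) of trees.
#' @param fraction Proportion in `[0, 1)` to discard from the start.
#' @return The retained trees, order preserved.
#' @examples
#' trs <- ape::rmtree(8, 4)
#' length(discard_burnin(trs, 0.25))
#' @export
discard_burnin <- function(sample, fraction = 0.25) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1).")
  n <- length(sample)
  drop <- floor(fraction * n)
  if (n - drop < 1) abort("Burn-in would discard every tree in the sample.")
  out <- sample[(drop + 1L):n]
  class(out) <- "multiPhylo"
  out
}

# Canonical clade keys: a clade is the sorted set of leaf indices under a fixed
# leaf ordering, encoded as a 0/1 bitmask string ("0110...").
clade_key <- function(idx, n_leaves) {
  mask <- integer(n_leaves)
  mask[idx] <- 1L
  paste(mask, collapse = "")
}

clade_key_to_idx <- function(key) {
  which(strsplit(key, "", fixed = TRUE)[[1]] == "1")
}

# List the clades of one rooted tree as index sets keyed to `leaf_order`,
# with, for each internal node, the unordered pair of child clades.
tree_clades <- function(phy, leaf_order) {
  n <- ape::Ntip(phy)
  idx_of_tip <- match(phy$tip.label, leaf_order)
  nn <- n + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- idx_of_tip[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  kids <- vector("list", nn)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[k, 2])
  }
  lapply(seq_len(nn), function(v) {
    idx <- sort(sets[[v]])
    list(
      node = v,
      key = clade_key(idx, length(leaf_order)),
      size = length(idx),
      children = if (v > n) {
        vapply(kids[[v]], function(c2) clade_key(sort(sets[[c2]]), length(leaf_order)), "")
      } else {
        character(0)
      }
    )
  })
}

#' Conditional clade table of a tree sample
#'
#' Summarizes a (post burn-in) sample of rooted gene trees over a common leaf
#' set into clade and split observation frequencies: the combinatorial object
#' over which amalgamated reconciliation searches, instead of committing to a
#' single topology.
#'
#' @param sample A list / [ape::multiPhylo] of rooted binary trees with
#'   identical leaf label sets.
#' @return A `ccp_table` tibble with one row per observed (clade, split) pair:
#'   columns `clade` (bitmask string under the canonical, alphabetical leaf
#'   order), `size`, `clade_freq`, `split1`, `split2` (child bitmasks, `NA`
#'   for singleton clades) and `split_freq`.  The leaf order is stored in
#'   attribute `leaf_order`.
#' @examples
#' trs <- ape::rmtree(5, 4)
#' build_ccp(trs)
#' @export
build_ccp <- function(sample) {
  if (length(sample) < 1) abort("The tree sample is empty.")
  leaf_order <- sort(sample[[1]]$tip.label)
  n_leaves <- length(leaf_order)
  clade_count <- new.env(parent = emptyenv())
  split_count <- new.env(parent = emptyenv())
  split_of <- new.env(parent = emptyenv())
  for (ti in seq_along(sample)) {
    phy <- sample[[ti]]
    if (!setequal(phy$tip.label, leaf_order) ||
        length(phy$tip.label) != n_leaves) {
      abort(sprintf("Tree %d has a different leaf label set from tree 1.", ti))
    }
    for (cl in tree_clades(phy, leaf_order)) {
      k <- cl$key
      clade_count[[k]] <- (clade_count[[k]] %||% 0L) + 1L
      if (length(cl$children)) {
        ch <- sort(cl$children)
        sk <- paste(k, ch[1], ch[2], sep = "|")
        split_count[[sk]] <- (split_count[[sk]] %||% 0L) + 1L
        split_of[[sk]] <- c(k, ch)
      }
    }
  }
  n_trees <- length(sample)
  skeys <- ls(split_count)
  rows <- purrr::map_dfr(skeys, function(sk) {
    info <- split_of[[sk]]
    tibble(
      clade = info[1],
      split1 = info[2],
      split2 = info[3],
      split_freq = split_count[[sk]] / n_trees
    )
  })
  singles <- tibble(
    clade = vapply(seq_len(n_leaves), clade_key, "", n_leaves = n_leaves),
    split1 = NA_character_, split2 = NA_character_, split_freq = NA_real_
  )
  out <- dplyr::bind_rows(rows, singles) %>%
    dplyr::mutate(
      size = unname(vapply(.data$clade, function(k) length(clade_key_to_idx(k)), 0L)),
      clade_freq = unname(vapply(.data$clade, function(k) clade_count[[k]] / n_trees, 0))
    ) %>%
    dplyr::select("clade", "size", "clade_freq", "split1", "split2", "split_freq") %>%
    dplyr::arrange(.data$size, .data$clade, .data$split1)
  attr(out, "leaf_order") <- leaf_order
  attr(out, "n_trees") <- n_trees
  class(out) <- c("ccp_table", class(out))
  out
}

#' @rdname build_ccp
#' @param ccp A `ccp_table`.
#' @param path Output TSV path.
#' @export
write_ccp <- function(ccp, path) {
  readr::write_tsv(as_tibble(ccp), path)
  invisible(path)
}
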