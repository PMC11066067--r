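#' Dated species trees
#'
#' A `dated_tree` is a rooted, strictly binary species tree whose every node
#' carries an age in Ga (giga-annum, billions of years before present; larger
#' values are older).  Leaves sit at the present (age 0) and every branch has a
#' strictly positive duration.  It is the backbone on which gene families are
#' simulated, reconciled, and dated.
#'
#' Internally the object wraps an [ape::phylo] tree (edge lengths equal to
#' branch durations in Ga) together with a vector of node ages indexed by ape
#' node number (tips `1..n`, internal nodes `n+1..2n-1`, root `n+1`).
#'
#' @param phy An [ape::phylo] object, rooted and binary.
#' @param ages Optional numeric vector of node ages (Ga) indexed by ape node
#'   number.  If omitted, ages are accumulated from the branch lengths, which
#'   must then be ultrametric.
#' @return A `dated_tree` object.
#' @examples
#' tr <- parse_dated_newick("((A:1,B:1):2,C:3);")
#' root_age(tr)
#' @export
dated_tree <- function(phy, ages = NULL) {
  if (!inherits(phy, "phylo")) abort("`phy` must be an ape 'phylo' object.")
  if (!ape::is.rooted(phy)) abort("The species tree must be rooted.")
  if (!ape::is.binary(phy)) {
    abort("Polytomies are not supported: the species tree must be strictly binary.")
  }
  n <- length(phy$tip.label)
  if (n < 2) abort("A dated tree needs at least 2 leaves.")
  if (anyDuplicated(phy$tip.label)) {
    abort("Leaf labels must be unique.")
  }
  if (is.null(ages)) {
    if (is.null(phy$edge.length)) {
      abort("Either node ages or branch lengths must be supplied.")
    }
    depth <- ape::node.depth.edgelength(phy)
    tipd <- depth[seq_len(n)]
    height <- max(tipd)
    rel_tol <- 1e-8 * max(height, 1)
    if (max(tipd) - min(tipd) > rel_tol) {
      i <- which.max(tipd); j <- which.min(tipd)
      abort(sprintf(
        "Branch lengths are not ultrametric: leaves '%s' and '%s' imply root-to-tip depths %.6g and %.6g.",
        phy$tip.label[i], phy$tip.label[j], tipd[i], tipd[j]
      ))
    }
    ages <- height - depth
    ages[seq_len(n)] <- 0
  }
  ages <- as.numeric(ages)
  if (length(ages) != n + phy$Nnode) {
    abort("`ages` must have one entry per node (tips first, ape numbering).")
  }
  if (any(ages < 0)) abort("Node ages must be non-negative.")
  if (any(abs(ages[seq_len(n)]) > 1e-12)) {
    abort("All leaf ages must equal 0 (extant sampling only).")
  }
  ages[seq_len(n)] <- 0
  # enforce strictly positive branch durations
  par <- phy$edge[, 1]; chi <- phy$edge[, 2]
  if (any(ages[par] <= ages[chi])) {
    k <- which(ages[par] <= ages[chi])[1]
    abort(sprintf(
      "Branch above node %d has non-positive duration (parent age %.6g <= child age %.6g).",
      chi[k], ages[par[k]], ages[chi[k]]
    ))
  }
  phy$edge.length <- ages[par] - ages[chi]
  structure(list(phy = phy, ages = ages), class = "dated_tree")
}

#' @rdname dated_tree
#' @param x,tree A `dated_tree`.
#' @export
is_dated_tree <- function(x) inherits(x, "dated_tree")

#' @rdname dated_tree
#' @export
root_age <- function(tree) {
  stopifnot(is_dated_tree(tree))
  unname(tree$ages[ape::Ntip(tree$phy) + 1L])
}

#' @rdname dated_tree
#' @export
n_tips <- function(tree) ape::Ntip(tree$phy)

#' @rdname dated_tree
#' @export
node_ages <- function(tree) tree$ages

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf(
    "<dated_tree> %d leaves, root age %.4g Ga, %d internal nodes\n",
    n_tips(x), root_age(x), x$phy$Nnode
  ))
  invisible(x)
}

#' Branch table of a dated tree
#'
#' Every branch is identified by the ape number of the node it leads to
#' (its child end).  The root's stem is not listed; it exists only as internal
#' plumbing for originations above the root.
#'
#' @param tree A [dated_tree].
#' @return A tibble with columns `branch` (child node id), `parent`,
#'   `label` (leaf label or internal node id as character), `t_child`,
#'   `t_parent` (ages in Ga) and `terminal`.
#' @export
branches <- function(tree) {
  stopifnot(is_dated_tree(tree))
  phy <- tree$phy
  n <- ape::Ntip(phy)
  chi <- phy$edge[, 2]
  par <- phy$edge[, 1]
  lab <- ifelse(chi <= n, phy$tip.label[chi], as.character(chi))
  tibble(
    branch = chi,
    parent = par,
    label = lab,
    t_child = tree$ages[chi],
    t_parent = tree$ages[par],
    terminal = chi <= n
  ) %>% dplyr::arrange(.data$branch)
}

#' Read and write dated Newick
#'
#' Ages are accepted either as ultrametric branch lengths or as node comments
#' of the form `[&age=x]` placed directly after the node's label; the writer
#' always emits both.  Trees with explicit age comments need not carry branch
#' lengths.  Polytomies and non-ultrametric length-only trees are rejected.
#'
#' @param text A Newick string, or the path of a file containing one tree.
#' @return `parse_dated_newick()` returns a [dated_tree];
#'   `write_dated_newick()` returns the Newick string (invisibly when writing
#'   to a file).
#' @examples
#' tr <- parse_dated_newick("((A:1,B:1):2,C:3);")
#' write_dated_newick(tr)
#' @export
parse_dated_newick <- function(text) {
  if (length(text) == 1 && !grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(paste(text, collapse = ""))
  has_ages <- grepl("\\[&age=", text)
  if (has_ages) {
    txt2 <- gsub("\\[&age=([0-9.eE+-]+)\\]", "@@\\1", text)
    if (grepl("\\[", txt2)) abort("Malformed [&age=...] annotation in Newick input.")
    phy <- ape::read.tree(text = txt2)
    if (is.null(phy)) abort("Could not parse Newick input.")
    n <- ape::Ntip(phy)
    ages <- rep(NA_real_, n + phy$Nnode)
    split_lab <- function(lab) {
      m <- regmatches(lab, regexpr("@@[0-9.eE+-]+$", lab))
      list(
        label = sub("@@[0-9.eE+-]+$", "", lab),
        age = if (length(m) && nzchar(m)) as.numeric(sub("^@@", "", m)) else NA_real_
      )
    }
    for (i in seq_len(n)) {
      p <- split_lab(phy$tip.label[i])
      phy$tip.label[i] <- p$label
      ages[i] <- if (is.na(p$age)) 0 else p$age
    }
    nl <- phy$node.label %||% rep("", phy$Nnode)
    for (j in seq_len(phy$Nnode)) {
      p <- split_lab(nl[j])
      nl[j] <- p$label
      ages[n + j] <- p$age
    }
    phy$node.label <- NULL
    if (anyNA(ages)) {
      abort("With [&age=...] annotations, every internal node must carry an age.")
    }
    if (any(ages < 0)) abort("Negative node ages are not allowed.")
    dated_tree(phy, ages)
  } else {
    phy <- ape::read.tree(text = text)
    if (is.null(phy)) abort("Could not parse Newick input.")
    dated_tree(phy)
  }
}

#' @rdname parse_dated_newick
#' @param tree A [dated_tree].
#' @param file Optional path; when given the Newick string is written there.
#' @param digits Significant digits used for ages and branch lengths.
#' @export
write_dated_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(is_dated_tree(tree))
  phy <- tree$phy
  ages <- tree$ages
  n <- ape::Ntip(phy)
  kids <- vector("list", n + phy$Nnode)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[k, 2])
  }
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(v, parent_age) {
    core <- if (v <= n) {
      sprintf("%s[&age=%s]", phy$tip.label[v], fmt(ages[v]))
    } else {
      sprintf("(%s)[&age=%s]",
              paste(vapply(kids[[v]], rec, "", parent_age = ages[v]), collapse = ","),
              fmt(ages[v]))
    }
    if (is.na(parent_age)) core else sprintf("%s:%s", core, fmt(parent_age - ages[v]))
  }
  out <- paste0(rec(n + 1L, NA_real_), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Validate the dated-tree invariants
#'
#' Checks the full invariant set (single root, unique leaf labels, leaf ages 0,
#' strictly positive branch durations) and aborts with an informative message
#' on the first violation.  Mostly useful in tests and on freshly parsed input.
#'
#' @param tree A [dated_tree].
#' @return `tree`, invisibly.
#' @export
validate_dated_tree <- function(tree) {
  stopifnot(is_dated_tree(tree))
  # reconstruction through the constructor re-runs every check
  dated_tree(tree$phy, tree$ages)
  invisible(tree)
}
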