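#' Simulate a dated species tree
#'
#' Draws a binary ultrametric species tree under a pure-birth process and
#' rescales node ages so the root sits at `root_age` Ga.  Deterministic given
#' `seed`.
#'
#' @param n_tips Number of extant leaves (>= 2).
#' @param root_age Root age in Ga.
#' @param seed Optional integer seed.
#' @return A [dated_tree] with tip labels `t1..tn`.
#' @examples
#' simulate_dated_tree(10, 4, seed = 1)
#' @export
simulate_dated_tree <- function(n_tips, root_age = 4, seed = NULL) {
  if (n_tips < 2) abort("`n_tips` must be at least 2.")
  if (root_age <= 0) abort("`root_age` must be positive.")
  phy <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr <- dated_tree(phy)
  ages <- tr$ages * (root_age / root_age(tr))
  dated_tree(tr$phy, ages)
}

#' Simulate a gene family on a dated tree
#'
#' Forward-in-time birth/transfer/death simulation of a single gene family.
#' A gene lineage travelling down a species branch duplicates in place at rate
#' `dup_rate`, copies itself into a uniformly chosen contemporaneous species
#' branch at rate `transfer_rate`, and dies at rate `loss_rate` (all in events
#' per lineage per Ga); it splits for free at every speciation node it
#' reaches.  Copies surviving to the present become gene leaves labelled
#' `x<k>_<genome>`.
#'
#' The returned history lists the *visible* events: those with at least one
#' surviving descendant, with extinct side-branches collapsed into single loss
#' records (dated at the first event of the lost subtree), exactly the event
#' set a parsimony reconciliation of the pruned gene tree can recover.  Every
#' visible history is a feasible reconciliation, so [optimal_cost()] of the
#' pruned tree can never exceed [true_history_cost()].
#'
#' @param tree A [dated_tree].
#' @param dup_rate,transfer_rate,loss_rate Event rates per lineage per Ga.
#' @param origin Species branch (node id) on which the family originates, or
#'   `"root"` to start at the root node.
#' @param seed Optional integer seed.
#' @return A `gene_family_sim`: list with `gene_tree` (pruned [ape::phylo], or
#'   `NULL` if fewer than 2 copies survive), `history` (tibble of visible
#'   events: `event`, `branch`, `branch_label`, `donor`, `date`), `origin_date`,
#'   `origin_branch` and `n_leaves`.
#' @export
simulate_gene_family <- function(tree, dup_rate = 0, transfer_rate = 0,
                                 loss_rate = 0, origin = "root", seed = NULL) {
  stopifnot(is_dated_tree(tree))
  if (any(c(dup_rate, transfer_rate, loss_rate) < 0)) {
    abort("Rates must be non-negative.")
  }
  sp <- recon_species(tree)
  rate <- dup_rate + transfer_rate + loss_rate
  n_events <- 0L
  leaf_n <- 0L
  with_seed(seed, {
    sim <- function(b, t0) {
      n_events <<- n_events + 1L
      if (n_events > 50000L) abort("Simulation exploded; lower the event rates.")
      t_end <- sp$t_child[b]
      t_ev <- if (rate > 0) t0 - stats::rexp(1, rate) else -Inf
      if (t_ev > t_end) {
        type <- sample(c("duplication", "transfer", "loss"), 1,
                       prob = c(dup_rate, transfer_rate, loss_rate))
        if (type == "duplication") {
          kids <- list(sim(b, t_ev), sim(b, t_ev))
          return(list(type = "duplication", date = t_ev, branch = b,
                      children = kids,
                      surv = kids[[1]]$surv || kids[[2]]$surv))
        }
        if (type == "transfer") {
          alive <- which(sp$t_child <= t_ev & sp$t_parent >= t_ev &
                           seq_len(sp$nn) != sp$root)
          recv <- setdiff(alive, b)
          if (length(recv) == 0) {
            # no contemporaneous partner (only near the root boundary):
            # the event fizzles, lineage continues
            return(sim_continue(b, t_ev))
          }
          y <- recv[sample.int(length(recv), 1)]
          kids <- list(sim(b, t_ev), sim(y, t_ev))
          return(list(type = "transfer", date = t_ev, branch = b, recipient = y,
                      children = kids,
                      surv = kids[[1]]$surv || kids[[2]]$surv))
        }
        return(list(type = "loss", date = t_ev, branch = b, surv = FALSE))
      }
      if (b <= sp$n_tip) {
        leaf_n <<- leaf_n + 1L
        return(list(type = "leaf", date = 0, branch = b,
                    genome = sp$phy$tip.label[b],
                    label = sprintf("x%d_%s", leaf_n, sp$phy$tip.label[b]),
                    surv = TRUE))
      }
      fg <- sp$kids[[b]]
      kids <- list(sim(fg[1], t_end), sim(fg[2], t_end))
      list(type = "speciation", date = t_end, branch = b, children = kids,
           surv = kids[[1]]$surv || kids[[2]]$surv)
    }
    sim_continue <- function(b, t0) sim(b, t0)
    origin_branch <- if (identical(origin, "root")) sp$root else as.integer(origin)
    origin_date <- sp$t_parent[origin_branch]
    root_node <- sim(origin_branch, origin_date)

    ev <- list()
    emit <- function(event, branch, date, donor = NA_integer_) {
      ev[[length(ev) + 1L]] <<- tibble(
        event = event, branch = as.integer(branch),
        branch_label = sp$label[branch],
        donor = if (is.na(donor)) NA_integer_ else as.integer(donor),
        date = date
      )
    }
    vis <- function(node) {
      # returns list(nwk, date) for the collapsed visible subtree
      if (node$type == "leaf") {
        return(list(nwk = node$label, date = 0))
      }
      ks <- node$children
      sv <- c(ks[[1]]$surv, ks[[2]]$surv)
      if (all(sv)) {
        if (node$type == "speciation") {
          emit("speciation", node$branch, node$date)
        } else if (node$type == "duplication") {
          emit("duplication", node$branch, node$date)
        } else {
          emit("transfer", node$recipient, node$date, donor = node$branch)
        }
        a <- vis(ks[[1]]); b <- vis(ks[[2]])
        return(list(
          nwk = sprintf("(%s:%.10g,%s:%.10g)",
                        a$nwk, node$date - a$date, b$nwk, node$date - b$date),
          date = node$date
        ))
      }
      keep <- which(sv); lost <- which(!sv)
      if (node$type == "speciation") {
        lost_branch <- ks[[lost]]$branch
        emit("loss", lost_branch, ks[[lost]]$date)
      } else if (node$type == "transfer") {
        if (keep == 2L) {  # only the transferred copy survives: transfer-loss
          emit("transfer", node$recipient, node$date, donor = node$branch)
          emit("loss", node$branch, ks[[1]]$date)
        }
        # donor-only survival: the transfer is invisible
      }
      # invisible duplication / pass-through
      vis(ks[[keep]])
    }

    if (!root_node$surv) {
      structure(list(
        gene_tree = NULL, history = tibble(), origin_date = origin_date,
        origin_branch = origin_branch, n_leaves = 0L,
        leaf_label = NA_character_, tree = tree
      ), class = "gene_family_sim")
    } else {
      emit("origination", origin_branch, origin_date)
      top <- vis(root_node)
      n_surv <- leaf_n_surviving(root_node)
      gene_tree <- if (n_surv >= 2L) {
        ape::read.tree(text = paste0(top$nwk, ";"))
      } else {
        NULL
      }
      structure(list(
        gene_tree = gene_tree,
        history = dplyr::bind_rows(ev),
        origin_date = origin_date,
        origin_branch = origin_branch,
        n_leaves = n_surv,
        leaf_label = if (n_surv == 1L) top$nwk else NA_character_,
        tree = tree
      ), class = "gene_family_sim")
    }
  })
}

leaf_n_surviving <- function(node) {
  if (node$type == "leaf") return(1L)
  if (node$type == "loss") return(0L)
  sum(vapply(node$children, leaf_n_surviving, 0L))
}

#' @export
print.gene_family_sim <- function(x, ...) {
  cat(sprintf("<gene_family_sim> %d surviving copies, origin %.3g Ga; %d visible events\n",
              x$n_leaves, x$origin_date, nrow(x$history)))
  invisible(x)
}

#' Parsimony cost of a simulated true history
#'
#' Prices the visible events of a [simulate_gene_family()] run under a
#' [cost_scheme()].  Because the visible history is itself a feasible dated
#' reconciliation of the pruned gene tree, this is an upper bound on
#' [optimal_cost()].
#'
#' @param sim A `gene_family_sim`.
#' @param costs A [cost_scheme()].
#' @return Total cost (numeric scalar).
#' @export
true_history_cost <- function(sim, costs = cost_scheme()) {
  stopifnot(inherits(sim, "gene_family_sim"))
  if (nrow(sim$history) == 0) return(0)
  price <- c(origination = 0, speciation = costs$speciation,
             duplication = costs$duplication, transfer = costs$transfer,
             loss = costs$loss)
  sum(price[sim$history$event])
}

#' Perturbed gene-tree samples
#'
#' Emulates a Bayesian posterior sample by applying random rooted
#' nearest-neighbour-interchange (NNI) moves to a true gene tree; per-tree
#' move counts are Poisson with mean `strength` (strength 0 reproduces the
#' input `n` times).
#'
#' @param gene_tree A rooted binary [ape::phylo].
#' @param strength Mean number of NNI moves per sampled tree.
#' @param n Number of trees in the sample.
#' @param seed Optional integer seed.
#' @return An [ape::multiPhylo] list of `n` rooted trees.
#' @export
simulate_tree_sample <- function(gene_tree, strength = 1, n = 50, seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), n >= 1)
  base <- gene_tree
  base$edge.length <- NULL
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      k <- stats::rpois(1, strength)
      tr <- base
      for (j in seq_len(k)) tr <- rooted_nni(tr)
      tr
    })
    class(out) <- "multiPhylo"
    out
  })
}

# One random rooted NNI move: pick an internal edge (u, v), swap one child of
# v with v's sibling.  Preserves rootedness and binarity.
rooted_nni <- function(phy) {
  ntip <- ape::Ntip(phy)
  internal_child <- which(phy$edge[, 2] > ntip)
  if (length(internal_child) == 0) return(phy)
  k <- internal_child[sample.int(length(internal_child), 1)]
  u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
  vkids_rows <- which(phy$edge[, 1] == v)
  sib_row <- setdiff(which(phy$edge[, 1] == u), k)
  c_row <- vkids_rows[sample.int(2, 1)]
  tmp <- phy$edge[c_row, 2]
  phy$edge[c_row, 2] <- phy$edge[sib_row, 2]
  phy$edge[sib_row, 2] <- tmp
  phy <- ape::read.tree(text = ape::write.tree(phy))  # renumber canonically
  phy
}

#' Simulate an abundance-vs-phosphate table
#'
#' Emulates per-sample relative gene abundances with a specified dependence on
#' phosphate concentration: phosphate is drawn uniformly on `phosphate_range`
#' (default the 0-3.29 uM span observed across Tara Oceans surface samples)
#' and each gene follows either `intercept + slope * x` plus Gaussian noise
#' (linear) or `exp(intercept + slope * x)` times lognormal noise
#' (log-linear), floored at zero.
#'
#' @param genes A tibble with columns `gene`, `form` (`"linear"` or
#'   `"log-linear"`), `slope`, `intercept`, `noise_sd`.
#' @param n Number of samples (default 139, the Tara surface-sample count).
#' @param phosphate_range Length-2 numeric, micromolar.
#' @param seed Optional integer seed.
#' @return An abundance tibble: `sample`, `phosphate_uM`, one column per gene.
#' @examples
#' simulate_abundance(tibble::tibble(gene = "pstS", form = "linear",
#'                    slope = -0.79, intercept = 3, noise_sd = 0.5), seed = 1)
#' @export
simulate_abundance <- function(genes, n = 139, phosphate_range = c(0, 3.29),
                               seed = NULL) {
  if (n < 3) abort("At least 3 samples are required.")
  if (any(genes$noise_sd < 0)) abort("`noise_sd` must be non-negative.")
  with_seed(seed, {
    x <- stats::runif(n, phosphate_range[1], phosphate_range[2])
    out <- tibble(sample = sprintf("S%03d", seq_len(n)), phosphate_uM = x)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      y <- if (g$form == "linear") {
        g$intercept + g$slope * x + stats::rnorm(n, 0, g$noise_sd)
      } else if (g$form == "log-linear") {
        exp(g$intercept + g$slope * x) * exp(stats::rnorm(n, 0, g$noise_sd))
      } else {
        abort("`form` must be 'linear' or 'log-linear'.")
      }
      out[[g$gene]] <- pmax(y, 0)
    }
    out
  })
}
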