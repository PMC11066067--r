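#' Parsimony event costs
#'
#' The relative costs of the four reconciliation events.  The defaults,
#' transfer : duplication : loss : speciation = 3 : 2 : 1 : 0, are the
#' standard choice for dated DTL parsimony (they minimise implied genome-size
#' variation between parent and daughter lineages).
#'
#' @param transfer,duplication,loss,speciation Non-negative event costs.
#' @return A `cost_scheme` object.
#' @examples
#' cost_scheme()            # 3, 2, 1, 0
#' cost_scheme(transfer = 6)
#' @export
cost_scheme <- function(transfer = 3, duplication = 2, loss = 1, speciation = 0) {
  vals <- c(transfer = transfer, duplication = duplication,
            loss = loss, speciation = speciation)
  if (any(vals < 0, na.rm = TRUE)) abort("Event costs must be non-negative.")
  structure(as.list(vals), class = "cost_scheme")
}

#' @export
print.cost_scheme <- function(x, ...) {
  cat(sprintf("<cost_scheme> transfer=%g duplication=%g loss=%g speciation=%g\n",
              x$transfer, x$duplication, x$loss, x$speciation))
  invisible(x)
}

#' Map gene-tree leaves to genomes
#'
#' Gene leaves are sequence ids tagged with their source genome.  The default
#' convention takes the genome as the text after the last underscore
#' (`"seq1_A"` belongs to genome `"A"`); labels without an underscore are
#' treated as bare genome names.
#'
#' @param labels Character vector of gene leaf labels.
#' @return Character vector of genome ids.
#' @export
leaf_genome <- function(labels) {
  ifelse(grepl("_", labels), sub(".*_", "", labels), labels)
}

# ---------------------------------------------------------------------------
# Gene input normalisation: both a single rooted gene tree and an amalgamated
# CCP table reduce to the same clade structure the DP ranges over.
# ---------------------------------------------------------------------------

gene_clades_from_phylo <- function(phy, genome_of = leaf_genome) {
  n <- ape::Ntip(phy)
  if (!ape::is.binary(phy)) abort("Gene trees must be binary.")
  nn <- n + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  kids <- vector("list", nn)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
    kids[[p]] <- c(kids[[p]], ch)
  }
  size <- vapply(sets, length, 0L)
  splits <- lapply(seq_len(nn), function(v) {
    if (v <= n) NULL else matrix(kids[[v]], ncol = 2)
  })
  list(
    n = nn,
    size = size,
    key = vapply(sets, function(s) paste(sort(s), collapse = "+"), ""),
    genome = c(genome_of(phy$tip.label), rep(NA_character_, phy$Nnode)),
    splits = splits,
    root = n + 1L,
    order = order(size),
    leaf_labels = phy$tip.label
  )
}

gene_clades_from_ccp <- function(ccp, genome_of = leaf_genome) {
  leaf_order <- attr(ccp, "leaf_order")
  tb <- as_tibble(ccp)
  keys <- unique(tb$clade)
  idx <- stats::setNames(seq_along(keys), keys)
  size <- vapply(keys, function(k) length(clade_key_to_idx(k)), 0L)
  genome <- rep(NA_character_, length(keys))
  label <- character(length(keys))
  for (i in seq_along(keys)) {
    leaves <- leaf_order[clade_key_to_idx(keys[i])]
    label[i] <- paste(sort(leaves), collapse = "+")
    if (size[i] == 1L) genome[i] <- genome_of(leaves)
  }
  splits <- vector("list", length(keys))
  sp_rows <- tb[!is.na(tb$split1), ]
  for (r in seq_len(nrow(sp_rows))) {
    i <- idx[[sp_rows$clade[r]]]
    splits[[i]] <- rbind(splits[[i]],
                         c(idx[[sp_rows$split1[r]]], idx[[sp_rows$split2[r]]]))
  }
  root <- idx[[clade_key(seq_along(leaf_order), length(leaf_order))]]
  list(
    n = length(keys), size = unname(size), key = label, genome = genome,
    splits = splits, root = unname(root), order = order(size),
    leaf_labels = leaf_order
  )
}

as_gene_clades <- function(gene, genome_of = leaf_genome) {
  if (inherits(gene, "ccp_table")) {
    gene_clades_from_ccp(gene, genome_of)
  } else if (inherits(gene, "phylo")) {
    gene_clades_from_phylo(gene, genome_of)
  } else if (is.character(gene) && length(gene) == 1) {
    gene_clades_from_phylo(ape::read.tree(text = gene), genome_of)
  } else {
    abort("`gene` must be a rooted gene tree (phylo / Newick) or a ccp_table.")
  }
}

# ---------------------------------------------------------------------------
# Species-side pre-processing for the slice DP.  Branch x is the edge above
# node x (ape numbering); the root's zero-length stem lives alone in a virtual
# slice above the oldest real slice, and one extra column represents the
# unsampled ("dead") lineage channel.
# ---------------------------------------------------------------------------

recon_species <- function(tree) {
  stopifnot(is_dated_tree(tree))
  phy <- tree$phy
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  ages <- tree$ages
  kids <- vector("list", nn)
  parent <- integer(nn)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    kids[[p]] <- sort(c(kids[[p]], ch))
    parent[ch] <- p
  }
  root <- n + 1L
  parent[root] <- root
  t_child <- ages
  t_parent <- ages[parent]
  bnd <- sort(unique(c(0, ages[(n + 1L):nn])))
  K <- length(bnd) - 1L
  tol <- 1e-12 * max(1, ages[root])
  alive <- lapply(seq_len(K), function(s) {
    which(t_child <= bnd[s] + tol & t_parent >= bnd[s + 1L] - tol &
            seq_len(nn) != root)
  })
  enders <- lapply(seq_len(K + 1L), function(s) {
    if (s == 1L) return(integer(0))
    if (s == K + 1L) return(root)
    b <- alive[[s]]
    b[b > n & abs(t_child[b] - bnd[s]) <= tol]
  })
  list(
    phy = phy, n_tip = n, nn = nn, root = root, ages = ages,
    kids = kids, t_child = t_child, t_parent = t_parent,
    bnd = bnd, K = K, alive = alive, enders = enders,
    dead = nn + 1L, ncol = nn + 1L,
    tip_of = stats::setNames(seq_len(n), phy$tip.label),
    label = c(phy$tip.label, as.character((n + 1L):nn), "dead")
  )
}

sp_alive_cols <- function(sp, s) {
  if (s == sp$K + 1L) sp$root else sp$alive[[s]]
}

# ---------------------------------------------------------------------------
# Forward DP.  V[[s]][u, x] is the minimum cost of embedding gene clade u
# given its lineage sits at location x (species branch or dead channel) at the
# top of slice s.  Within a slice: duplication, transfer (receiver any other
# contemporaneous branch or the dead channel), transfer-loss, and dead-channel
# re-emission; at slice bottoms: speciation, speciation-loss, null passage,
# leaf termination.  Origination is free on any location in any slice.
# ---------------------------------------------------------------------------

top2 <- function(v) {
  i1 <- which.min(v)
  m1 <- v[i1]
  v2 <- v
  v2[i1] <- Inf
  m2 <- min(v2)
  list(m1 = m1, i1 = i1, m2 = m2)
}

compute_B <- function(g, sp, costs, s, Vprev) {
  B <- matrix(Inf, g$n, sp$ncol)
  if (s == 1L) {
    leafs <- which(!is.na(g$genome))
    for (u in leafs) {
      tip <- sp$tip_of[[g$genome[u]]]
      B[u, tip] <- 0
    }
    return(B)
  }
  lam <- costs$loss; sig <- costs$speciation
  cols <- sp_alive_cols(sp, s)
  ender <- sp$enders[[s]]
  for (b in cols) {
    if (b %in% ender) {
      fg <- sp$kids[[b]]
      f <- fg[1]; g2 <- fg[2]
      for (u in seq_len(g$n)) {
        sl <- lam + min(Vprev[u, f], Vprev[u, g2])
        spv <- Inf
        S <- g$splits[[u]]
        if (!is.null(S)) {
          v1 <- Vprev[S[, 1], f] + Vprev[S[, 2], g2]
          v2 <- Vprev[S[, 1], g2] + Vprev[S[, 2], f]
          spv <- sig + min(v1, v2)
        }
        B[u, b] <- min(spv, sl)
      }
    } else {
      B[, b] <- Vprev[, b]
    }
  }
  B[, sp$dead] <- Vprev[, sp$dead]
  B
}

compute_W_row <- function(g, sp, costs, s, B, V, u) {
  cols <- sp_alive_cols(sp, s)
  all_cols <- c(cols, sp$dead)
  tau <- costs$transfer; del <- costs$duplication
  W <- rep(Inf, sp$ncol)
  W[all_cols] <- B[u, all_cols]
  S <- g$splits[[u]]
  if (!is.null(S)) {
    for (r in seq_len(nrow(S))) {
      u1 <- S[r, 1]; u2 <- S[r, 2]
      # duplication on a sampled branch
      W[cols] <- pmin(W[cols], del + V[u1, cols] + V[u2, cols])
      # transfer: one child stays, the other is received elsewhere (or dead)
      t1 <- top2(V[u1, all_cols]); t2 <- top2(V[u2, all_cols])
      bo1 <- ifelse(seq_along(all_cols) == t1$i1, t1$m2, t1$m1)
      bo2 <- ifelse(seq_along(all_cols) == t2$i1, t2$m2, t2$m1)
      names(bo1) <- names(bo2) <- NULL
      idx <- match(cols, all_cols)
      W[cols] <- pmin(W[cols],
                      tau + V[u1, cols] + bo2[idx],
                      tau + V[u2, cols] + bo1[idx])
      # transfer with the dead channel as donor: one child stays dead,
      # the other is emitted into a sampled branch
      ms <- min(V[u1, cols]); ms2 <- min(V[u2, cols])
      W[sp$dead] <- min(W[sp$dead],
                        tau + V[u1, sp$dead] + ms2,
                        tau + V[u2, sp$dead] + ms)
    }
  }
  W
}

closure_row <- function(sp, costs, s, W) {
  cols <- sp_alive_cols(sp, s)
  all_cols <- c(cols, sp$dead)
  tau <- costs$transfer; lam <- costs$loss
  t <- top2(W[all_cols])
  other <- ifelse(seq_along(all_cols) == t$i1, t$m2, t$m1)
  out <- rep(Inf, sp$ncol)
  idx <- match(cols, all_cols)
  out[cols] <- pmin(W[cols], tau + lam + other[idx])
  out[sp$dead] <- min(W[sp$dead], tau + min(W[cols]))
  out
}

recon_forward <- function(g, sp, costs) {
  miss <- setdiff(unique(stats::na.omit(g$genome)), names(sp$tip_of))
  if (length(miss)) {
    abort(sprintf("Gene leaves map to genomes absent from the species tree: %s",
                  paste(miss, collapse = ", ")))
  }
  Vs <- vector("list", sp$K + 1L)
  Bs <- vector("list", sp$K + 1L)
  Vprev <- NULL
  for (s in seq_len(sp$K + 1L)) {
    B <- compute_B(g, sp, costs, s, Vprev)
    V <- matrix(Inf, g$n, sp$ncol)
    for (u in g$order) {
      W <- compute_W_row(g, sp, costs, s, B, V, u)
      V[u, ] <- closure_row(sp, costs, s, W)
    }
    Vs[[s]] <- V
    Bs[[s]] <- B
    Vprev <- V
  }
  # origination: free on any location in any slice; deterministic tie-break by
  # lower species-branch index, then younger slice
  best <- list(v = Inf, x = .Machine$integer.max, s = .Machine$integer.max)
  for (s in seq_len(sp$K + 1L)) {
    for (x in c(sp_alive_cols(sp, s), sp$dead)) {
      v <- Vs[[s]][g$root, x]
      if (!is.finite(v)) next
      if (v < best$v - COST_TOL ||
          (near(v, best$v) && (x < best$x || (x == best$x && s < best$s)))) {
        best <- list(v = v, x = x, s = s)
      }
    }
  }
  if (!is.finite(best$v)) abort("No feasible reconciliation found (internal error).")
  list(Vs = Vs, Bs = Bs, opt = best$v, opt_x = best$x, opt_s = best$s)
}

# ---------------------------------------------------------------------------
# Backtracking: deterministic event-list reconstruction.  Option preference:
# slice-bottom moves (leaf / speciation / speciation-loss / null) before
# duplication before transfer, transfer-loss last; receiver and survivor ties
# broken by lower branch index, origination ties by younger slice.
# ---------------------------------------------------------------------------

recon_backtrack <- function(g, sp, costs, dp) {
  tau <- costs$transfer; del <- costs$duplication
  lam <- costs$loss; sig <- costs$speciation
  rows <- list()
  emit <- function(event, clade, branch, slice, donor = NA_integer_, cost = 0) {
    rows[[length(rows) + 1L]] <<- tibble(
      event = event, clade = g$key[clade],
      branch = if (is.na(branch)) NA_integer_ else as.integer(branch),
      branch_label = if (is.na(branch)) NA_character_ else sp$label[branch],
      slice = as.integer(slice),
      donor = if (is.na(donor)) NA_integer_ else as.integer(donor),
      donor_label = if (is.na(donor)) NA_character_ else sp$label[donor],
      cost = cost
    )
  }

  bt_V <- function(u, x, s) {
    v <- dp$Vs[[s]][u, x]
    W <- compute_W_row(g, sp, costs, s, dp$Bs[[s]], dp$Vs[[s]], u)
    if (near(W[x], v)) return(bt_W(u, x, s, W))
    all_cols <- c(sp_alive_cols(sp, s), sp$dead)
    if (x != sp$dead) {
      for (y in sort(all_cols)) {
        if (y != x && near(tau + lam + W[y], v)) {
          emit("transfer", u, if (y == sp$dead) NA else y, s, donor = x, cost = tau)
          if (y == sp$dead) rows[[length(rows)]]$branch_label <<- "dead"
          emit("loss", u, x, s, cost = lam)
          return(bt_W(u, y, s, W))
        }
      }
    } else {
      for (y in sort(sp_alive_cols(sp, s))) {
        if (near(tau + W[y], v)) {
          emit("transfer", u, y, s, donor = sp$dead, cost = tau)
          return(bt_W(u, y, s, W))
        }
      }
    }
    abort("Backtracking failed at the transfer-loss closure (internal error).")
  }

  bt_W <- function(u, x, s, W) {
    if (near(dp$Bs[[s]][u, x], W[x])) return(bt_B(u, x, s))
    S <- g$splits[[u]]
    cols <- sp_alive_cols(sp, s)
    all_cols <- c(cols, sp$dead)
    V <- dp$Vs[[s]]
    if (!is.null(S) && x != sp$dead) {
      for (r in seq_len(nrow(S))) {
        u1 <- S[r, 1]; u2 <- S[r, 2]
        if (near(del + V[u1, x] + V[u2, x], W[x])) {
          emit("duplication", u, x, s, cost = del)
          bt_V(u1, x, s); bt_V(u2, x, s)
          return(invisible())
        }
      }
    }
    if (!is.null(S)) {
      for (r in seq_len(nrow(S))) {
        u1 <- S[r, 1]; u2 <- S[r, 2]
        recv <- if (x == sp$dead) sort(cols) else sort(all_cols)
        for (pair in list(c(u1, u2), c(u2, u1))) {
          stay <- pair[1]; move <- pair[2]
          for (y in recv) {
            if (y != x && near(tau + V[stay, x] + V[move, y], W[x])) {
              emit("transfer", move, if (y == sp$dead) NA else y, s,
                   donor = x, cost = tau)
              if (y == sp$dead) rows[[length(rows)]]$branch_label <<- "dead"
              if (x == sp$dead) rows[[length(rows)]]$donor_label <<- "dead"
              bt_V(stay, x, s); bt_V(move, y, s)
              return(invisible())
            }
          }
        }
      }
    }
    abort("Backtracking failed at an in-slice event (internal error).")
  }

  bt_B <- function(u, x, s) {
    B <- dp$Bs[[s]]
    if (s == 1L) {
      if (!is.na(g$genome[u]) && x == sp$tip_of[[g$genome[u]]] &&
          near(B[u, x], 0)) {
        return(invisible())  # observed leaf reached its genome
      }
      abort("Backtracking failed at the present-day boundary (internal error).")
    }
    Vprev <- dp$Vs[[s - 1L]]
    if (x == sp$dead) return(bt_V(u, sp$dead, s - 1L))
    if (x %in% sp$enders[[s]]) {
      fg <- sp$kids[[x]]
      f <- fg[1]; g2 <- fg[2]
      S <- g$splits[[u]]
      if (!is.null(S)) {
        for (r in seq_len(nrow(S))) {
          u1 <- S[r, 1]; u2 <- S[r, 2]
          if (near(sig + Vprev[u1, f] + Vprev[u2, g2], B[u, x])) {
            emit("speciation", u, x, s, cost = sig)
            bt_V(u1, f, s - 1L); bt_V(u2, g2, s - 1L)
            return(invisible())
          }
          if (near(sig + Vprev[u1, g2] + Vprev[u2, f], B[u, x])) {
            emit("speciation", u, x, s, cost = sig)
            bt_V(u1, g2, s - 1L); bt_V(u2, f, s - 1L)
            return(invisible())
          }
        }
      }
      for (surv in c(f, g2)) {
        lost <- setdiff(c(f, g2), surv)
        if (near(lam + Vprev[u, surv], B[u, x])) {
          emit("loss", u, lost, s - 1L, cost = lam)
          return(bt_V(u, surv, s - 1L))
        }
      }
      abort("Backtracking failed at a speciation node (internal error).")
    }
    bt_V(u, x, s - 1L)  # null passage
  }

  emit("origination", g$root,
       if (dp$opt_x == sp$dead) NA else dp$opt_x, dp$opt_s, cost = 0)
  if (dp$opt_x == sp$dead) rows[[length(rows)]]$branch_label <- "dead"
  bt_V(g$root, dp$opt_x, dp$opt_s)
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# User-facing surface
# ---------------------------------------------------------------------------

#' Most-parsimonious dated DTL reconciliation
#'
#' Embeds a rooted gene tree (or an amalgamated clade set summarised in a
#' [build_ccp()] table) into a time-calibrated species tree, minimising the
#' total cost of duplication, transfer, loss and speciation events under a
#' [cost_scheme()].  Transfers are only allowed between species branches alive
#' in the same time slice; a "transfer to the dead" channel lets genes travel
#' through unsampled lineages (enter at transfer cost, persist free, re-emerge
#' at transfer cost).  Backtracking is deterministic, so one optimum among
#' possible co-optima is returned reproducibly.
#'
#' @param gene A rooted binary gene tree ([ape::phylo] or Newick string) whose
#'   leaf labels carry genome tags (see [leaf_genome()]), or a `ccp_table` for
#'   amalgamated reconciliation over observed clades and splits.
#' @param species A [dated_tree].
#' @param costs A [cost_scheme()].
#' @param genome_of Function mapping gene leaf labels to genome ids.
#' @param unrooted If `TRUE` (gene tree input only), every root position of
#'   the gene tree is tried and the cheapest kept (ties: lowest edge index).
#' @return A `dtl_reconciliation`: list with `total_cost`, the `events` tibble
#'   (`event`, `clade`, `branch`, `branch_label`, `slice`, `donor`, `cost`;
#'   transfers are recorded at their reception), the `costs` used, and the
#'   number of events routed through the dead channel (`n_dead`).
#' @examples
#' sp <- parse_dated_newick("((A:1,B:1):2,C:3);")
#' reconcile("((a_A,c_C),b_B);", sp)
#' @export
reconcile <- function(gene, species, costs = cost_scheme(),
                      genome_of = leaf_genome, unrooted = FALSE) {
  sp <- recon_species(species)
  if (unrooted && !inherits(gene, "ccp_table")) {
    gene <- best_rooting(gene, species, costs, genome_of)
  }
  g <- as_gene_clades(gene, genome_of)
  dp <- recon_forward(g, sp, costs)
  events <- recon_backtrack(g, sp, costs, dp)
  total_check <- sum(events$cost)
  if (!near(total_check, dp$opt)) {
    abort(sprintf("Internal inconsistency: event costs sum to %g but DP optimum is %g.",
                  total_check, dp$opt))
  }
  structure(list(
    total_cost = dp$opt,
    events = events,
    costs = costs,
    n_dead = sum(is.na(events$branch)),
    species = species,
    gene_input = if (inherits(gene, "ccp_table")) "ccp" else "tree"
  ), class = "dtl_reconciliation")
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  tab <- table(x$events$event)
  cat(sprintf("<dtl_reconciliation> total cost %g\n", x$total_cost))
  cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (x$n_dead > 0) cat("  (", x$n_dead, "event(s) routed through the dead channel )\n")
  invisible(x)
}

#' @rdname reconcile
#' @return `optimal_cost()` returns just the minimum total cost (forward pass
#'   only, no event list).
#' @export
optimal_cost <- function(gene, species, costs = cost_scheme(),
                         genome_of = leaf_genome, unrooted = FALSE) {
  sp <- recon_species(species)
  if (unrooted && !inherits(gene, "ccp_table")) {
    gene <- best_rooting(gene, species, costs, genome_of)
  }
  g <- as_gene_clades(gene, genome_of)
  recon_forward(g, sp, costs)$opt
}

# Try every root position of an unrooted gene tree, keeping the cheapest
# (ties broken by lowest edge index).
best_rooting <- function(gene, species, costs, genome_of) {
  if (is.character(gene)) gene <- ape::read.tree(text = gene)
  if (ape::Ntip(gene) <= 2) return(gene)  # a cherry has a single rooted shape
  un <- if (ape::is.rooted(gene)) ape::unroot(gene) else gene
  sp <- recon_species(species)
  best <- NULL; best_cost <- Inf
  for (k in seq_len(nrow(un$edge))) {
    ch <- un$edge[k, 2]
    out_tips <- if (ch <= ape::Ntip(un)) {
      un$tip.label[ch]
    } else {
      ape::extract.clade(un, ch)$tip.label
    }
    if (length(out_tips) == ape::Ntip(un)) next
    rooted <- tryCatch(
      ape::root(un, outgroup = out_tips, resolve.root = TRUE),
      error = function(e) NULL
    )
    if (is.null(rooted) || !ape::is.binary(rooted)) next
    g <- as_gene_clades(rooted, genome_of)
    cost <- recon_forward(g, sp, costs)$opt
    if (cost < best_cost - COST_TOL) {
      best <- rooted; best_cost <- cost
    }
  }
  if (is.null(best)) abort("No valid rooting found for the gene tree.")
  best
}

#' Sensitivity of a reconciliation to the transfer cost
#'
#' Re-runs the reconciliation across a grid of horizontal-transfer costs
#' (holding duplication, loss and speciation at their base values), the
#' standard robustness check for dated DTL analyses; the base transfer cost is
#' always included in the grid.
#'
#' @inheritParams reconcile
#' @param base Base [cost_scheme()].
#' @param hgt_grid Numeric vector of transfer costs to try (default
#'   `c(2, 4, 6)`, the conventional spread around the default of 3).
#' @return A tibble with one row per transfer cost: `tau`, `total_cost`, and a
#'   `reconciliation` list-column.
#' @export
cost_sensitivity <- function(gene, species, base = cost_scheme(),
                             hgt_grid = c(2, 4, 6), genome_of = leaf_genome) {
  if (length(hgt_grid) == 0) abort("`hgt_grid` must contain at least one value.")
  if (any(hgt_grid < 0)) abort("Transfer costs must be non-negative.")
  taus <- sort(unique(c(base$transfer, hgt_grid)))
  recs <- lapply(taus, function(tv) {
    cs <- cost_scheme(transfer = tv, duplication = base$duplication,
                      loss = base$loss, speciation = base$speciation)
    reconcile(gene, species, cs, genome_of = genome_of)
  })
  tibble(
    tau = taus,
    total_cost = vapply(recs, function(r) r$total_cost, 0),
    reconciliation = recs
  )
}

#' Re-validate a reconciliation against the slice structure
#'
#' Independent post-hoc check of the contemporaneity invariant: every
#' transfer's donor and reception branches must both be alive in the event's
#' time slice, and the event costs must sum to the reported total.
#'
#' @param rec A `dtl_reconciliation`.
#' @param slices Optional [compute_time_slices()] index (recomputed if absent).
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_reconciliation <- function(rec, slices = NULL) {
  stopifnot(inherits(rec, "dtl_reconciliation"))
  slices <- slices %||% compute_time_slices(rec$species)
  ev <- rec$events
  tr <- ev[ev$event == "transfer", ]
  for (i in seq_len(nrow(tr))) {
    s <- tr$slice[i]
    if (s > nrow(slices)) next  # virtual stem slice
    alive <- slices$branches[[s]]
    ok_recv <- is.na(tr$branch[i]) || tr$branch[i] %in% alive
    ok_donor <- is.na(tr$donor[i]) || tr$donor[i] %in% alive ||
      tr$donor_label[i] %in% "dead"
    if (!ok_recv || !ok_donor) {
      abort(sprintf("Transfer %d violates contemporaneity in slice %d.", i, s))
    }
  }
  if (!near(sum(ev$cost), rec$total_cost)) {
    abort("Event cost contributions do not sum to the total cost.")
  }
  invisible(TRUE)
}
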