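# ---------------------------------------------------------------------------
# Exhaustive reconciliation oracle for tiny instances.  Independent of the
# slice-sweep DP: every internal gene node is assigned an explicit event
# (speciation at a species node, duplication on a branch-slice, or transfer
# with an explicit receiver), and the gene lineages between events move
# through an explicit (branch, slice) location graph whose loss-type moves
# (speciation-loss, transfer-loss, dead-channel passage) are charged by
# all-pairs shortest paths.  Used solely to certify the DP on small instances.
# ---------------------------------------------------------------------------

# Location table: every (branch, slice) pair the branch is alive in, the
# virtual stem location, and one dead-channel location per slice.
bf_locations <- function(sp) {
  rows <- list()
  for (s in seq_len(sp$K)) {
    for (b in sp$alive[[s]]) rows[[length(rows) + 1L]] <- c(b, s)
  }
  rows[[length(rows) + 1L]] <- c(sp$root, sp$K + 1L)  # stem
  for (s in seq_len(sp$K + 1L)) rows[[length(rows) + 1L]] <- c(0L, s)  # dead
  loc <- do.call(rbind, rows)
  colnames(loc) <- c("branch", "slice")
  loc
}

# Move graph between locations (forward in time = toward the present):
# null passage, speciation-loss, transfer-loss, dead persistence/re-emission.
bf_move_graph <- function(sp, loc, costs) {
  L <- nrow(loc)
  d <- matrix(Inf, L, L)
  diag(d) <- 0
  lam <- costs$loss; tau <- costs$transfer
  find <- function(b, s) which(loc[, "branch"] == b & loc[, "slice"] == s)
  for (i in seq_len(L)) {
    b <- loc[i, "branch"]; s <- loc[i, "slice"]
    if (b == 0L) {                       # dead channel
      if (s > 1L) d[i, find(0L, s - 1L)] <- pmin(d[i, find(0L, s - 1L)], 0)
      if (s <= sp$K) {
        for (y in sp$alive[[s]]) d[i, find(y, s)] <- pmin(d[i, find(y, s)], tau)
      }
      next
    }
    alive_here <- if (s == sp$K + 1L) sp$root else sp$alive[[s]]
    # transfer-loss to any contemporaneous branch or into the dead channel
    if (s <= sp$K) {
      for (y in setdiff(alive_here, b)) {
        d[i, find(y, s)] <- pmin(d[i, find(y, s)], tau + lam)
      }
    }
    d[i, find(0L, s)] <- pmin(d[i, find(0L, s)], tau + lam)
    if (s > 1L) {
      ends <- b %in% sp$enders[[s]] || (s == sp$K + 1L)
      if (ends && b > sp$n_tip) {        # speciation-loss through the node
        for (f in sp$kids[[b]]) {
          d[i, find(f, s - 1L)] <- pmin(d[i, find(f, s - 1L)], lam)
        }
      } else if (!ends) {                # null passage
        d[i, find(b, s - 1L)] <- pmin(d[i, find(b, s - 1L)], 0)
      }
    }
  }
  # Floyd-Warshall with path reconstruction
  nxt <- matrix(NA_integer_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) if (is.finite(d[i, j]) && i != j) nxt[i, j] <- j
  for (k in seq_len(L)) {
    for (i in seq_len(L)) {
      if (!is.finite(d[i, k])) next
      upd <- d[i, k] + d[k, ] < d[i, ]
      if (any(upd)) {
        d[i, upd] <- d[i, k] + d[k, upd]
        nxt[i, upd] <- nxt[i, k]
      }
    }
  }
  list(d = d, nxt = nxt)
}

#' Exhaustive reconciliation of tiny instances
#'
#' Enumerates all valid dated event histories of a small gene tree on a small
#' dated species tree and returns the cheapest, as an independent certificate
#' for [reconcile()].  `max_events` caps the number of duplication and
#' transfer events; loss-type events along lineage paths are optimised
#' exactly, so with at most 3 internal gene nodes a cap of 4 makes the
#' enumeration exhaustive over all histories.
#'
#' @inheritParams reconcile
#' @param max_events Cap on duplication + transfer events (at most 4).
#' @return A list with `total_cost` and an `events` tibble.
#' @export
brute_force_reconcile <- function(gene, species, costs = cost_scheme(),
                                  max_events = 4L, genome_of = leaf_genome) {
  if (is.character(gene)) gene <- ape::read.tree(text = gene)
  if (ape::Ntip(gene) > 4L || n_tips(species) > 4L || max_events > 4L) {
    abort("brute_force_reconcile is restricted to <=4 gene leaves, <=4 species leaves, max_events <= 4.")
  }
  g <- as_gene_clades(gene, genome_of)
  sp <- recon_species(species)
  loc <- bf_locations(sp)
  mg <- bf_move_graph(sp, loc, costs)
  L <- nrow(loc)
  tau <- costs$transfer; del <- costs$duplication; sig <- costs$speciation
  find <- function(b, s) which(loc[, "branch"] == b & loc[, "slice"] == s)
  leaf_loc <- vapply(seq_len(g$n), function(u) {
    if (is.na(g$genome[u])) NA_integer_ else find(sp$tip_of[[g$genome[u]]], 1L)
  }, 0L)
  # slice whose bottom boundary is a given internal species node
  node_bottom_slice <- function(b) {
    if (b == sp$root) return(sp$K + 1L)
    which(vapply(seq_len(sp$K + 1L), function(s) b %in% sp$enders[[s]], TRUE))[1]
  }
  sampled_locs <- which(loc[, "branch"] != 0L)
  dead_locs <- which(loc[, "branch"] == 0L)

  memo <- new.env(parent = emptyenv())
  # h(u, i, k): min cost of clade u's subtree with its lineage entering at
  # location i, using at most k duplication+transfer events; also stores the
  # chosen event for reconstruction.
  h <- function(u, i, k) {
    key <- paste(u, i, k, sep = ":")
    if (!is.null(memo[[key]])) return(memo[[key]]$v)
    best <- Inf; choice <- NULL
    if (!is.na(g$genome[u])) {
      best <- mg$d[i, leaf_loc[u]]
      choice <- list(type = "leaf", to = leaf_loc[u])
    } else {
      S <- g$splits[[u]]
      for (r in seq_len(nrow(S))) {
        u1 <- S[r, 1]; u2 <- S[r, 2]
        # speciation at any internal species node (incl. the root)
        for (b in (sp$n_tip + 1L):sp$nn) {
          s <- node_bottom_slice(b)
          ei <- find(b, s)
          if (!is.finite(mg$d[i, ei])) next
          fg <- sp$kids[[b]]
          f1 <- find(fg[1], s - 1L); f2 <- find(fg[2], s - 1L)
          for (asg in list(c(u1, u2), c(u2, u1))) {
            for (k1 in 0:k) {
              v <- mg$d[i, ei] + sig + h(asg[1], f1, k1) + h(asg[2], f2, k - k1)
              if (v < best - COST_TOL) {
                best <- v
                choice <- list(type = "speciation", at = ei, branch = b, slice = s,
                               c1 = asg[1], l1 = f1, k1 = k1,
                               c2 = asg[2], l2 = f2, k2 = k - k1)
              }
            }
          }
        }
        if (k >= 1L) {
          for (ei in sampled_locs) {
            if (!is.finite(mg$d[i, ei])) next
            b <- loc[ei, "branch"]; s <- loc[ei, "slice"]
            # duplication on a sampled branch
            for (k1 in 0:(k - 1L)) {
              v <- mg$d[i, ei] + del + h(u1, ei, k1) + h(u2, ei, k - 1L - k1)
              if (v < best - COST_TOL) {
                best <- v
                choice <- list(type = "duplication", at = ei, branch = b, slice = s,
                               c1 = u1, l1 = ei, k1 = k1,
                               c2 = u2, l2 = ei, k2 = k - 1L - k1)
              }
            }
            # transfer: one child stays, the other is received elsewhere
            alive_here <- if (s == sp$K + 1L) integer(0) else sp$alive[[s]]
            recv <- c(setdiff(alive_here, b), 0L)
            for (y in recv) {
              yi <- find(y, s)
              for (asg in list(c(u1, u2), c(u2, u1))) {
                for (k1 in 0:(k - 1L)) {
                  v <- mg$d[i, ei] + tau + h(asg[1], ei, k1) + h(asg[2], yi, k - 1L - k1)
                  if (v < best - COST_TOL) {
                    best <- v
                    choice <- list(type = "transfer", at = ei, branch = y, slice = s,
                                   donor = b, c1 = asg[1], l1 = ei, k1 = k1,
                                   c2 = asg[2], l2 = yi, k2 = k - 1L - k1)
                  }
                }
              }
            }
          }
          # transfer out of the dead channel
          for (s in seq_len(sp$K)) {
            ei <- find(0L, s)
            if (!is.finite(mg$d[i, ei])) next
            for (y in sp$alive[[s]]) {
              yi <- find(y, s)
              for (asg in list(c(u1, u2), c(u2, u1))) {
                for (k1 in 0:(k - 1L)) {
                  v <- mg$d[i, ei] + tau + h(asg[1], ei, k1) + h(asg[2], yi, k - 1L - k1)
                  if (v < best - COST_TOL) {
                    best <- v
                    choice <- list(type = "transfer", at = ei, branch = y, slice = s,
                                   donor = 0L, c1 = asg[1], l1 = ei, k1 = k1,
                                   c2 = asg[2], l2 = yi, k2 = k - 1L - k1)
                  }
                }
              }
            }
          }
        }
      }
    }
    memo[[key]] <- list(v = best, choice = choice)
    best
  }

  # free origination: try every location for the gene root
  best <- Inf; best_loc <- NA_integer_
  for (i in c(sampled_locs, dead_locs)) {
    v <- h(g$root, i, max_events)
    if (v < best - COST_TOL) { best <- v; best_loc <- i }
  }
  if (!is.finite(best)) {
    abort("No history within the event budget; raise `max_events`.")
  }

  # ---- reconstruct the event list -------------------------------------
  rows <- list()
  lam <- costs$loss
  emit <- function(event, clade, branch, slice, cost) {
    rows[[length(rows) + 1L]] <<- tibble(
      event = event, clade = g$key[clade],
      branch = if (branch == 0L) NA_integer_ else as.integer(branch),
      branch_label = if (branch == 0L) "dead" else sp$label[branch],
      slice = as.integer(slice), cost = cost
    )
  }
  emit_path <- function(u, i, j) {
    while (i != j) {
      nx <- mg$nxt[i, j]
      step <- mg$d[i, nx]
      bi <- loc[i, "branch"]; si <- loc[i, "slice"]
      bn <- loc[nx, "branch"]; sn <- loc[nx, "slice"]
      if (near(step, 0)) {
        # null passage / dead persistence
      } else if (si == sn && bi != 0L) {
        emit("transfer", u, bn, sn, tau)        # transfer-loss jump
        emit("loss", u, bi, si, lam)
      } else if (si == sn && bi == 0L) {
        emit("transfer", u, bn, sn, tau)        # dead re-emission
      } else {
        lost <- setdiff(sp$kids[[bi]], bn)      # speciation-loss
        emit("loss", u, lost, sn, lam)
      }
      i <- nx
    }
  }
  rebuild <- function(u, i, k) {
    ch <- memo[[paste(u, i, k, sep = ":")]]$choice
    if (ch$type == "leaf") {
      emit_path(u, i, ch$to)
      return(invisible())
    }
    emit_path(u, i, ch$at)
    emit(ch$type, u, ch$branch, ch$slice,
         switch(ch$type, speciation = sig, duplication = del, transfer = tau))
    rebuild(ch$c1, ch$l1, ch$k1)
    rebuild(ch$c2, ch$l2, ch$k2)
  }
  emit("origination", g$root, loc[best_loc, "branch"], loc[best_loc, "slice"], 0)
  rebuild(g$root, best_loc, max_events)
  list(total_cost = best, events = dplyr::bind_rows(rows))
}

#' Classical duplication-loss cost by LCA mapping
#'
#' Closed-form minimum duplication-loss reconciliation cost (transfers
#' disabled): each gene node maps to the most recent common ancestor of its
#' leaves' genomes; duplications are nodes mapping to the same species node as
#' a child, and losses count skipped species edges.  The limit of the dated
#' DTL model as the transfer cost goes to infinity.
#'
#' @inheritParams reconcile
#' @return The total cost `duplication * D + loss * L + speciation * S`.
#' @export
dl_lca_cost <- function(gene, species, costs = cost_scheme(),
                        genome_of = leaf_genome) {
  if (is.character(gene)) gene <- ape::read.tree(text = gene)
  phy <- species$phy
  n <- ape::Ntip(phy)
  parent <- integer(n + phy$Nnode)
  for (k in seq_len(nrow(phy$edge))) parent[phy$edge[k, 2]] <- phy$edge[k, 1]
  depth <- integer(n + phy$Nnode)
  ord <- ape::reorder.phylo(phy, "cladewise")$edge
  for (k in seq_len(nrow(ord))) depth[ord[k, 2]] <- depth[ord[k, 1]] + 1L
  anc_path <- function(v) {
    out <- v
    while (v != n + 1L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  lca <- function(a, b) {
    pa <- anc_path(a)
    pb <- anc_path(b)
    pa[pa %in% pb][1]
  }
  gn <- ape::Ntip(gene)
  kids <- vector("list", gn + gene$Nnode)
  for (k in seq_len(nrow(gene$edge))) {
    kids[[gene$edge[k, 1]]] <- c(kids[[gene$edge[k, 1]]], gene$edge[k, 2])
  }
  M <- integer(gn + gene$Nnode)
  tip_of <- stats::setNames(seq_len(n), phy$tip.label)
  for (i in seq_len(gn)) {
    gm <- genome_of(gene$tip.label[i])
    if (is.na(tip_of[gm])) abort(sprintf("Gene leaf '%s' has no genome in the species tree.", gene$tip.label[i]))
    M[i] <- tip_of[[gm]]
  }
  D <- 0L; Lc <- 0L; S <- 0L
  for (v in unique(ape::reorder.phylo(gene, "postorder")$edge[, 1])) {
    c1 <- kids[[v]][1]; c2 <- kids[[v]][2]
    M[v] <- lca(M[c1], M[c2])
    isdup <- M[v] == M[c1] || M[v] == M[c2]
    if (isdup) {
      D <- D + 1L
      Lc <- Lc + (depth[M[c1]] - depth[M[v]]) + (depth[M[c2]] - depth[M[v]])
    } else {
      S <- S + 1L
      Lc <- Lc + (depth[M[c1]] - depth[M[v]] - 1L) + (depth[M[c2]] - depth[M[v]] - 1L)
    }
  }
  costs$duplication * D + costs$loss * Lc + costs$speciation * S
}
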