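#' Date the events of a reconciliation
#'
#' Converts a reconciliation's event list into dated records: speciations are
#' dated at the age of the species node where they occur; duplications,
#' losses and transfer receptions are dated at the midpoint of their species
#' branch (the reconciliation constrains them to the branch, not to a point,
#' so the midpoint is the natural summary).  Transfers appear once, at their
#' reception; events routed through the dead (unsampled) channel carry no
#' date on the sampled tree and are excluded from the output but tallied in
#' the `n_dead` attribute.  An optional slice-midpoint mode dates in-branch
#' events at the midpoint of their DP time slice instead of the whole branch.
#'
#' @param rec A [reconcile()] result.
#' @param tree The [dated_tree] the reconciliation was computed against
#'   (defaults to the tree stored in `rec`).
#' @param periods A period table (default [default_periods()]).
#' @param family Gene family id attached to each record.
#' @param slice_midpoint If `TRUE`, date in-branch events at their slice
#'   midpoint rather than the branch midpoint.
#' @return A tibble of dated events: `family`, `event`, `branch`,
#'   `branch_parent`, `branch_child` (labels), `date_Ga`, `branch_class`
#'   (`"internal"`/`"terminal"`), `period`.  Originations are bookkeeping, not
#'   phylogenetic evidence, and are not dated.
#' @export
date_events <- function(rec, tree = rec$species, periods = default_periods(),
                        family = "family", slice_midpoint = FALSE) {
  stopifnot(inherits(rec, "dtl_reconciliation"), is_dated_tree(tree))
  br <- branches(tree)
  slices <- compute_time_slices(tree)
  ev <- rec$events[rec$events$event != "origination", ]
  n_dead <- sum(is.na(ev$branch))
  ev <- ev[!is.na(ev$branch), ]
  n_sp <- n_tips(tree)
  root_id <- n_sp + 1L
  rows <- purrr::pmap_dfr(ev, function(event, clade, branch, branch_label,
                                       slice, donor, donor_label, cost) {
    if (branch == root_id && event != "speciation") {
      # in-branch event on the zero-length stem: dated at the root age
      lo <- root_age(tree); hi <- root_age(tree)
      parent_label <- "stem"
      child_label <- as.character(root_id)
      terminal <- FALSE
    } else if (branch == root_id) {
      lo <- root_age(tree); hi <- root_age(tree)
      parent_label <- "stem"
      child_label <- as.character(root_id)
      terminal <- FALSE
    } else {
      row <- br[br$branch == branch, ]
      if (nrow(row) == 0) abort(sprintf("Event references unknown branch %d.", branch))
      lo <- row$t_child; hi <- row$t_parent
      parent_label <- if (row$parent == root_id) as.character(root_id) else {
        br$label[br$branch == row$parent]
      }
      child_label <- row$label
      terminal <- row$terminal
    }
    date <- if (event == "speciation") {
      node_ages(tree)[branch]
    } else if (slice_midpoint && slice <= nrow(slices)) {
      (slices$lower[slice] + slices$upper[slice]) / 2
    } else {
      (lo + hi) / 2
    }
    tibble(
      family = family, event = event, branch = as.integer(branch),
      branch_parent = parent_label, branch_child = child_label,
      date_Ga = date,
      branch_class = if (terminal) "terminal" else "internal"
    )
  })
  if (nrow(rows) > 0) {
    rows$period <- assign_geological_period(rows$date_Ga, periods)
  } else {
    rows <- tibble(family = character(), event = character(),
                   branch = integer(), branch_parent = character(),
                   branch_child = character(), date_Ga = numeric(),
                   branch_class = character(), period = character())
  }
  attr(rows, "n_dead") <- n_dead
  rows
}

#' First appearance of a gene family
#'
#' The oldest dated event of a family is the first phylogenetic evidence of
#' the gene's presence; earlier presence in unsampled or extinct lineages
#' cannot be excluded, so the estimate is a lower bound on the true origin.
#' Losses count by default (a loss implies the gene was already there);
#' restrict to gain-type events (speciation, duplication, transfer) with
#' `include_losses = FALSE`.
#'
#' @param events A [date_events()] tibble (one or more families).
#' @param family Family id to summarise.
#' @param include_losses Whether losses may carry the earliest evidence.
#' @return A one-row tibble: `family`, `origin_Ga`, `event`, `qualifier`
#'   (always `"lower bound"`).
#' @export
first_appearance <- function(events, family = NULL, include_losses = TRUE) {
  fam <- family %||% unique(events$family)[1]
  sub <- events[events$family == fam, ]
  if (!include_losses) sub <- sub[sub$event != "loss", ]
  if (nrow(sub) == 0) abort(sprintf("No dated events for family '%s'.", fam))
  i <- which.max(sub$date_Ga)
  tibble(
    family = fam,
    origin_Ga = sub$date_Ga[i],
    event = sub$event[i],
    qualifier = "lower bound"
  )
}

#' Bin dated events into geological periods
#'
#' @param events A [date_events()] tibble.
#' @param periods A period table (default [default_periods()]).
#' @return A contingency tibble: `period`, `event`, `n`, with every
#'   (period, event type) combination present (zero-filled); periods ordered
#'   oldest first.
#' @export
bin_events_by_period <- function(events, periods = default_periods()) {
  validate_period_table(periods)
  types <- c("speciation", "duplication", "transfer", "loss")
  grid <- tidyr::expand_grid(
    period = periods$period[order(-periods$older_Ga)],
    event = types
  )
  if (nrow(events) == 0) {
    return(dplyr::mutate(grid, n = 0L))
  }
  oldest <- max(periods$older_Ga)
  bad <- which(events$date_Ga < 0 | events$date_Ga > oldest)
  if (length(bad)) {
    abort(sprintf("Event %d (%s at %.4g Ga) is outside the period table range.",
                  bad[1], events$event[bad[1]], events$date_Ga[bad[1]]))
  }
  counts <- events %>%
    dplyr::mutate(period = assign_geological_period(.data$date_Ga, periods)) %>%
    dplyr::count(.data$period, .data$event)
  grid %>%
    dplyr::left_join(counts, by = c("period", "event")) %>%
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}
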