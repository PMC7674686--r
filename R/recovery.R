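#' Compare an inferred event history against simulated truth
#'
#' Computes per-node repertoire precision/recall (on presence of a group
#' at a node), per-branch event precision/recall (on
#' branch-group-event-type tuples) and origin-placement accuracy (the
#' fraction of truth groups with at least one surviving copy whose
#' inferred origin branch matches the true one).
#'
#' @param truth,inferred `event_history` objects over the same species
#'   tree and group universe.
#' @return A `recovery_report` list: `summary` (one-row tibble) plus
#'   `by_node` and `by_branch` detail tibbles.
#' @export
recovery_report <- function(truth, inferred) {
  tn <- tree_node_names(truth$tree)
  if (!setequal(tn, tree_node_names(inferred$tree))) {
    plg_validation_error("truth and inferred histories are on different trees")
  }
  keyify <- function(df, cols) do.call(paste, c(as_tibble(df)[cols], sep = "\r"))
  pr <- function(truth_keys, inf_keys) {
    tp <- length(intersect(truth_keys, inf_keys))
    c(precision = if (length(inf_keys) == 0) NA_real_ else tp / length(inf_keys),
      recall = if (length(truth_keys) == 0) NA_real_ else tp / length(truth_keys))
  }
  rep_t <- keyify(truth$repertoires[truth$repertoires$count > 0, ], c("node", "group"))
  rep_i <- keyify(inferred$repertoires[inferred$repertoires$count > 0, ], c("node", "group"))
  rep_pr <- pr(rep_t, rep_i)
  ev_t <- keyify(truth$events, c("branch", "group", "event"))
  ev_i <- keyify(inferred$events, c("branch", "group", "event"))
  ev_pr <- pr(ev_t, ev_i)
  # origin accuracy over truth groups that survive somewhere
  leaves <- tree_leaves(truth$tree)
  surviving <- unique(truth$repertoires$group[truth$repertoires$node %in% leaves &
                                                truth$repertoires$count > 0])
  t_or <- truth$origins[truth$origins$group %in% surviving, ]
  i_or <- setNames(inferred$origins$branch, inferred$origins$group)
  acc <- if (nrow(t_or) == 0) NA_real_ else {
    mean(!is.na(i_or[t_or$group]) & i_or[t_or$group] == t_or$branch)
  }
  by_node <- truth$repertoires |>
    filter(.data$count > 0) |>
    group_by(.data$node) |>
    summarise(n_truth = dplyr::n(), .groups = "drop")
  summary <- tibble(repertoire_precision = rep_pr[["precision"]],
                    repertoire_recall = rep_pr[["recall"]],
                    event_precision = ev_pr[["precision"]],
                    event_recall = ev_pr[["recall"]],
                    origin_accuracy = acc,
                    n_groups_truth = length(unique(truth$origins$group)),
                    n_groups_surviving = length(surviving))
  structure(list(summary = summary, by_node = by_node),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary)
  invisible(x)
}
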