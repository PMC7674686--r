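#' Configuration for the gene-family birth-death simulator
#'
#' The simulator emulates the generative assumptions of the analysis:
#' single-origin families, WGD-correlated gains, lineage losses, tandem
#' duplicates adjacent to their parents, and locally conserved gene
#' neighbourhoods.  Defaults describe a near-complete retention of
#' WGD-derived genes with slow background turnover on an undisturbed
#' genome of 20,000 genes.
#'
#' @param seed integer seed; identical configurations yield identical
#'   outputs, byte for byte.
#' @param wgd_retention_prob probability that a gene copy is retained in
#'   duplicate through a WGD (default 0.8).
#' @param loss_rate expected losses per gene copy per unit branch length
#'   (default 0.05).
#' @param tandem_rate expected tandem duplications per gene copy per unit
#'   branch length (default 0.02).
#' @param rearrangement_rate expected neighbour shuffles per gene per unit
#'   branch length on the simulated gene order (default 0).
#' @param support_noise standard deviation (percent) of the half-normal
#'   perturbation subtracted from bootstrap supports (default 0).
#' @param n_progenitors number of gene lineages present before any event
#'   (default 3).
#' @param genome_gene_count background genes per simulated genome
#'   (default 20000).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, wgd_retention_prob = 0.8,
                              loss_rate = 0.05, tandem_rate = 0.02,
                              rearrangement_rate = 0, support_noise = 0,
                              n_progenitors = 3L, genome_gene_count = 20000L) {
  if (wgd_retention_prob < 0 || wgd_retention_prob > 1) {
    plg_validation_error("wgd_retention_prob must lie in [0, 1]")
  }
  if (loss_rate < 0 || tandem_rate < 0 || rearrangement_rate < 0 || support_noise < 0) {
    plg_validation_error("rates and noise must be non-negative")
  }
  if (n_progenitors < 1) plg_validation_error("n_progenitors must be >= 1")
  structure(list(seed = as.integer(seed), wgd_retention_prob = wgd_retention_prob,
                 loss_rate = loss_rate, tandem_rate = tandem_rate,
                 rearrangement_rate = rearrangement_rate,
                 support_noise = support_noise,
                 n_progenitors = as.integer(n_progenitors),
                 genome_gene_count = as.integer(genome_gene_count)),
            class = "simulation_config")
}

# Branch length lookup; unit length where the tree carries none, zero on
# the root stem (whose events are instantaneous WGDs).
branch_length <- function(ix, v) {
  if (v == ix$root) return(0)
  l <- ix$edge_length[v]
  if (is.na(l)) 1 else l
}

#' Simulate a gene-family event history on a species tree
#'
#' Starts with `n_progenitors` gene lineages entering the root stem.  At
#' every WGD event each extant copy duplicates independently with
#' probability `wgd_retention_prob`, founding a new orthology group whose
#' true progenitor and origin event are recorded.  Along each branch,
#' copies are lost by Poisson thinning at `loss_rate` and spawn
#' same-group tandem duplicates at `tandem_rate` (WGD duplications are
#' applied at the start of a branch, then losses, then tandem gains).
#'
#' @param config a [simulation_config()].
#' @param tree a `species_tree`.
#' @return A `gene_family_sim` list: `truth` (the realised
#'   `event_history`), `matrix` (leaf `count_matrix`), `copies` (leaf copy
#'   table), `constraints` (true origin constraints), `evlog` (the raw
#'   per-branch event log that [simulate_tracks()] and
#'   [simulate_gene_tree()] replay), and `config`.
#' @export
simulate_history <- function(config, tree) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ix <- tree_index(tree)
  counter <- new.env(parent = emptyenv())
  counter$copy <- 0L
  counter$group <- 0L
  new_copy <- function() {
    counter$copy <- counter$copy + 1L
    sprintf("c%04d", counter$copy)
  }
  evlog <- list()
  log_event <- function(branch, type, copy, group, new_copy = NA_character_,
                        new_group = NA_character_, wgd = NA_character_) {
    evlog[[length(evlog) + 1L]] <<- tibble(
      branch = branch, ord = length(evlog) + 1L, type = type, copy = copy,
      group = group, new_copy = new_copy, new_group = new_group, wgd = wgd)
  }
  origins <- list()
  rep_rows <- list()
  copies_at_leaf <- list()

  # state: tibble(copy, group, progenitor)
  run_branch <- function(state, branch_name, length_) {
    evs <- st_branch_events(tree, branch_name)
    for (w in evs) {
      if (nrow(state) == 0) break
      keep <- runif(nrow(state)) < config$wgd_retention_prob
      for (i in which(keep)) {
        nc <- new_copy()
        if (w %in% c("WGD1", "WGD2")) {
          # the 2R WGDs found new orthology groups (ohnologs)
          counter$group <- counter$group + 1L
          ng <- sprintf("%s.%s.%02d", state$group[i], w, counter$group)
          log_event(branch_name, "wgd_dup", state$copy[i], state$group[i], nc, ng, w)
          origins[[ng]] <<- tibble(group = ng, branch = branch_name, event = w,
                                   parent_group = state$group[i],
                                   progenitor = state$progenitor[i])
          state <- bind_rows(state, tibble(copy = nc, group = ng,
                                           progenitor = state$progenitor[i]))
        } else {
          # the teleost-specific WGD adds copies within existing groups
          log_event(branch_name, "wgd_copy", state$copy[i], state$group[i], nc,
                    state$group[i], w)
          state <- bind_rows(state, tibble(copy = nc, group = state$group[i],
                                           progenitor = state$progenitor[i]))
        }
      }
    }
    if (length_ > 0 && nrow(state) > 0) {
      surv <- runif(nrow(state)) < exp(-config$loss_rate * length_)
      for (i in which(!surv)) {
        log_event(branch_name, "loss", state$copy[i], state$group[i])
      }
      state <- state[surv, , drop = FALSE]
      if (nrow(state) > 0) {
        ndup <- rpois(nrow(state), config$tandem_rate * length_)
        for (i in seq_len(nrow(state))) {
          for (k in seq_len(ndup[i])) {
            nc <- new_copy()
            log_event(branch_name, "tandem_dup", state$copy[i], state$group[i], nc,
                      state$group[i])
            state <- bind_rows(state, tibble(copy = nc, group = state$group[i],
                                             progenitor = state$progenitor[i]))
          }
        }
      }
    }
    state
  }

  descend <- function(state, node_id) {
    node <- ix$names[node_id]
    if (nrow(state) > 0) {
      rep_rows[[node]] <<- state |> count(.data$group, name = "count") |>
        mutate(node = node) |> select("node", "group", "count")
    }
    if (node_id <= ix$n_tip) {
      copies_at_leaf[[node]] <<- state |> mutate(species = node) |>
        select("species", "copy", "group")
      return(invisible(NULL))
    }
    for (child in ix$children[[node_id]]) {
      child_state <- run_branch(state, ix$names[child], branch_length(ix, child))
      descend(child_state, child)
    }
  }

  init <- tibble(copy = vapply(seq_len(config$n_progenitors), function(i) new_copy(),
                               character(1)),
                 group = sprintf("G%d", seq_len(config$n_progenitors)))
  init$progenitor <- init$group
  for (g in init$group) {
    origins[[g]] <- tibble(group = g, branch = ix$names[ix$root], event = "pre_WGD",
                           parent_group = NA_character_, progenitor = g)
  }
  root_state <- run_branch(init, ix$names[ix$root], 0)
  descend(root_state, ix$root)

  evlog <- if (length(evlog) > 0) bind_rows(evlog) else
    tibble(branch = character(), ord = integer(), type = character(),
           copy = character(), group = character(), new_copy = character(),
           new_group = character(), wgd = character())
  origins <- bind_rows(origins)
  repertoires <- if (length(rep_rows) > 0) bind_rows(rep_rows) |>
    arrange(.data$node, .data$group) else
    tibble(node = character(), group = character(), count = integer())
  copies <- if (length(copies_at_leaf) > 0) bind_rows(copies_at_leaf) else
    tibble(species = character(), copy = character(), group = character())

  # leaf count matrix over all groups ever observed at a leaf
  leaf_groups <- sort(unique(copies$group))
  mat <- tibble(species = ix$names[seq_len(ix$n_tip)])
  for (g in leaf_groups) {
    mat[[g]] <- vapply(mat$species, function(s) {
      sum(copies$species == s & copies$group == g)
    }, integer(1))
  }
  mat$Other <- 0L
  matrix <- as_count_matrix(mat, leaf_groups)

  truth <- structure(list(tree = tree,
                          origins = origins |>
                            select("group", "branch", "event", "parent_group") |>
                            mutate(after_event = NA_character_),
                          events = truth_events(tree, origins, repertoires),
                          repertoires = repertoires),
                     class = "event_history")
  constraints <- truth_constraints(origins)
  structure(list(truth = truth, matrix = matrix, copies = copies,
                 constraints = constraints, evlog = evlog, config = config,
                 progenitors = origins |> select("group", "progenitor")),
            class = "gene_family_sim")
}

# events on a branch of a species_tree, in recorded order
st_branch_events <- function(tree, branch_name) {
  ev <- tree$events[tree$events$branch == branch_name, ]
  ev$event[order(ev$order)]
}

# Collapse the realised history into per-branch, per-group net event rows
# in the same vocabulary the reconstruction uses (origin, loss, copy_loss,
# tandem_duplication, wgd_retention).  Within-branch churn that cancels out
# (a gain followed by a loss of the same copy) is unobservable to any
# parsimony method and is deliberately collapsed.
truth_events <- function(tree, origins, repertoires) {
  ix <- tree_index(tree)
  ts_branches <- event_branches(tree, "TS_WGD")
  cnt <- function(node, g) {
    i <- repertoires$node == node & repertoires$group == g
    if (any(i)) repertoires$count[i][[1]] else 0L
  }
  rows <- list()
  all_groups <- unique(c(origins$group, repertoires$group))
  for (v in seq_along(ix$names)) {
    b <- ix$names[v]
    p <- ix$parent[v]
    born_here <- origins$group[origins$branch == b]
    for (g in all_groups) {
      base <- if (g %in% born_here) 1L else if (is.na(p)) 0L else cnt(ix$names[p], g)
      here <- cnt(b, g)
      if (g %in% born_here) {
        rows[[length(rows) + 1L]] <- tibble(branch = b, group = g,
                                            event = "origin", n = 1L)
      } else if (base == 0L) next
      d <- here - base
      if (d > 0) {
        lab <- if (b %in% ts_branches && !(g %in% born_here)) "wgd_retention"
               else "tandem_duplication"
        rows[[length(rows) + 1L]] <- tibble(branch = b, group = g, event = lab, n = d)
      } else if (d < 0) {
        lab <- if (here == 0L) "loss" else "copy_loss"
        n <- if (here == 0L) base else base - here
        rows[[length(rows) + 1L]] <- tibble(branch = b, group = g, event = lab, n = n)
      }
    }
  }
  ev <- bind_rows(rows)
  if (is.null(ev) || nrow(ev) == 0) {
    return(tibble(branch = character(), group = character(), event = character(),
                  n = integer()))
  }
  ev |> arrange(.data$branch, .data$group, .data$event)
}

truth_constraints <- function(origins) {
  tbl <- tibble(group = origins$group,
                cluster = "unassigned",
                origin = ifelse(origins$event %in% c("WGD1", "WGD2"), origins$event,
                         ifelse(origins$event == "pre_WGD", "pre_WGD", "unconstrained")),
                parent_group = origins$parent_group,
                branch = origins$branch,
                after_event = NA_character_,
                progenitor = origins$progenitor,
                quartet = NA_character_,
                paralogon = "unknown")
  tbl$quartet <- tbl$progenitor
  read_constraints(tbl)
}
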