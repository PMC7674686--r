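#' Place the origin of an orthology group on the species tree
#'
#' Unconstrained groups originate, under Dollo parsimony, on the branch
#' above the most recent common ancestor of the species that carry them
#' (one gain, losses minimised).  A constrained group originates at its
#' stated event instead: on the branch carrying `WGD1`/`WGD2` (or, for
#' `pre_WGD`, the branch carrying `WGD1`, before it), or on the stated
#' branch for a tandem duplication.  Constrained origins may force losses
#' that plain Dollo would avoid; an origin that is not ancestral to every
#' species carrying the group is infeasible.
#'
#' @param group group id.
#' @param matrix a `count_matrix`.
#' @param tree a `species_tree`.
#' @param constraint optional one-row constraint (see [read_constraints()]).
#' @return A one-row tibble: `group`, `branch` (child node of the origin
#'   branch), `event` (`origin` class: `dollo`, `pre_WGD`, `WGD1`, `WGD2`
#'   or `tandem`), `parent_group`, `after_event`.
#' @export
place_origin <- function(group, matrix, tree, constraint = NULL) {
  ix <- tree_index(tree)
  if (!group %in% count_groups(matrix)) {
    if (is.null(constraint) || constraint$origin == "unconstrained") {
      plg_validation_error(sprintf("group '%s' not in matrix and unconstrained", group))
    }
  }
  counts <- group_leaf_counts(matrix, tree, group)
  presence <- which(!is.na(counts) & counts > 0)
  cons <- constraint %||% constraint_for(NULL, group)
  origin <- cons$origin[[1]]
  if (origin == "unconstrained") {
    if (length(presence) == 0) {
      plg_validation_error(sprintf(
        "group '%s' has no presence and no constraint forcing existence", group))
    }
    node <- mrca_id(ix, presence)
    return(tibble(group = group, branch = ix$names[node], event = "dollo",
                  parent_group = NA_character_, after_event = NA_character_))
  }
  if (origin %in% c("pre_WGD", "WGD1", "WGD2")) {
    ev <- if (origin == "pre_WGD") "WGD1" else origin
    branches <- event_branches(tree, ev)
    if (length(branches) == 0) {
      if (origin == "pre_WGD") {
        # pre-WGD means "before any WGD": on a tree without WGD events that
        # is simply the root stem
        branches <- ix$names[ix$root]
      } else {
        plg_infeasible_error(sprintf(
          "group '%s' is constrained to %s but no branch carries that event", group, origin))
      }
    }
    ok <- branches[vapply(branches, function(b) {
      all(vapply(presence, function(t) is_ancestor(ix, ix$id[[b]], t), logical(1)))
    }, logical(1))]
    if (length(ok) == 0) {
      plg_infeasible_error(sprintf(
        "constraint %s for group '%s' is not ancestral to all its presences", origin, group))
    }
    return(tibble(group = group, branch = ok[[1]], event = origin,
                  parent_group = NA_character_, after_event = NA_character_))
  }
  # tandem
  b <- cons$branch[[1]]
  if (is.na(b) || !b %in% ix$names) {
    plg_validation_error(sprintf("tandem origin of '%s' names unknown branch '%s'", group, b))
  }
  feasible <- all(vapply(presence, function(t) is_ancestor(ix, ix$id[[b]], t), logical(1)))
  if (!feasible) {
    plg_infeasible_error(sprintf(
      "tandem origin of group '%s' on branch '%s' is not ancestral to all its presences",
      group, b))
  }
  tibble(group = group, branch = b, event = "tandem",
         parent_group = cons$parent_group[[1]], after_event = cons$after_event[[1]])
}

# Leaf copy counts for one group, aligned with tree tip ids.
# Species present in the tree but absent from the matrix are missing data (NA).
group_leaf_counts <- function(matrix, tree, group) {
  ix <- tree_index(tree)
  m <- as_tibble(matrix)
  v <- rep(NA_integer_, ix$n_tip)
  hit <- match(m$species, ix$names[seq_len(ix$n_tip)])
  if (any(is.na(hit))) {
    plg_validation_error(sprintf("matrix species not in tree: %s",
                                 paste(m$species[is.na(hit)], collapse = ", ")))
  }
  if (group %in% names(m)) v[hit] <- m[[group]]
  else v[hit] <- 0L
  v
}

# Sankoff DP over integer copy-number states with Dollo's no-regain rule:
# transition cost |parent - child|, parent 0 -> child > 0 forbidden; entry
# cost |s - 1| at the origin point (the origin event deposits one copy).
# Ties break towards the smallest ancestral count.  Returns states by node id.
wagner_dollo_states <- function(ix, origin_id, counts, max_state = NULL) {
  S <- max_state %||% min(32L, max(c(counts, 1L), na.rm = TRUE) + 2L)
  ns <- S + 1L
  trans <- abs(outer(0:S, 0:S, "-"))
  trans[1, 2:ns] <- Inf  # Dollo: no regain after loss
  # postorder over the subtree rooted at origin_id
  order_nodes <- integer()
  stack <- origin_id
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_nodes <- c(order_nodes, v)
    stack <- c(stack, ix$children[[v]])
  }
  order_nodes <- rev(order_nodes)  # children before parents
  cost <- matrix(NA_real_, nrow = length(ix$names), ncol = ns)
  for (v in order_nodes) {
    if (v <= ix$n_tip) {
      cv <- counts[v]
      if (is.na(cv)) {
        cost[v, ] <- 0
      } else {
        cost[v, ] <- Inf
        if (cv <= S) cost[v, cv + 1L] <- 0
      }
    } else {
      acc <- rep(0, ns)
      for (c in ix$children[[v]]) {
        childmin <- vapply(seq_len(ns), function(ps) min(trans[ps, ] + cost[c, ]),
                           numeric(1))
        acc <- acc + childmin
      }
      cost[v, ] <- acc
    }
  }
  entry <- abs(0:S - 1L)
  total <- entry + cost[origin_id, ]
  if (all(!is.finite(total))) {
    plg_infeasible_error("no feasible copy-number history (state bound too small?)")
  }
  states <- rep(NA_integer_, length(ix$names))
  states[origin_id] <- which.min(total) - 1L  # which.min takes the smallest index
  # top-down backtrack, children after parents
  for (v in rev(order_nodes)) {
    if (v == origin_id || is.na(states[v])) {
      if (v != origin_id) next
    }
    ps <- states[v]
    for (c in ix$children[[v]]) {
      states[c] <- which.min(trans[ps + 1L, ] + cost[c, ]) - 1L
    }
  }
  list(states = states, cost = min(total), max_state = S)
}

#' Infer the full event history of every orthology group
#'
#' For each group the origin is placed with [place_origin()], then copy
#' numbers are reconstructed over the subtree below the origin by Wagner
#' parsimony (integer states, cost the absolute change per branch, one
#' copy at the origin) under Dollo's single-gain rule (no regain after
#' loss).  Presence-level losses are branches where the copy number falls
#' to zero; smaller decreases are copy losses.  Copy gains on a branch
#' carrying the teleost-specific WGD are labelled `wgd_retention` when the
#' group predates that branch; all other gains are tandem duplications.
#' Ties break towards the smallest ancestral count (conservative
#' duplication calls).
#'
#' @param matrix a `count_matrix`.
#' @param tree a `species_tree`.
#' @param constraints optional `origin_constraints`.
#' @return An `event_history` object: a list with `tree`, `origins` (one
#'   row per group), `events` (tibble `branch`, `group`, `event`, `n`) and
#'   `repertoires` (tibble `node`, `group`, `count`, presence only).
#' @export
infer_history <- function(matrix, tree, constraints = NULL) {
  ix <- tree_index(tree)
  groups <- count_groups(matrix)
  extra <- if (!is.null(constraints)) setdiff(constraints$group, groups) else character()
  all_groups <- c(groups, extra)
  origin_rows <- list()
  event_rows <- list()
  rep_rows <- list()
  for (g in all_groups) {
    cons <- constraint_for(constraints, g)
    counts <- group_leaf_counts(matrix, tree, g)
    if (all(is.na(counts) | counts == 0) && cons$origin == "unconstrained") next
    og <- place_origin(g, matrix, tree, cons)
    oid <- ix$id[[og$branch]]
    fit <- wagner_dollo_states(ix, oid, counts)
    st <- fit$states
    origin_rows[[g]] <- og
    # origin branch events
    ev <- list(tibble(branch = og$branch, group = g, event = "origin", n = 1L))
    s0 <- st[oid]
    if (s0 > 1L) {
      lab <- if (og$branch %in% event_branches(tree, "TS_WGD")) "tandem_duplication"
             else "tandem_duplication"
      ev <- c(ev, list(tibble(branch = og$branch, group = g, event = lab,
                              n = s0 - 1L)))
    } else if (s0 == 0L) {
      ev <- c(ev, list(tibble(branch = og$branch, group = g, event = "loss", n = 1L)))
    }
    # events below the origin
    ts_branches <- event_branches(tree, "TS_WGD")
    below <- which(!is.na(st))
    for (v in below) {
      if (v == oid) next
      p <- ix$parent[v]
      ps <- st[p]
      cs <- st[v]
      if (is.na(ps) || cs == ps) next
      b <- ix$names[v]
      if (cs > ps) {
        lab <- if (b %in% ts_branches && ps >= 1L) "wgd_retention" else "tandem_duplication"
        ev <- c(ev, list(tibble(branch = b, group = g, event = lab, n = cs - ps)))
      } else if (cs == 0L) {
        ev <- c(ev, list(tibble(branch = b, group = g, event = "loss", n = ps)))
      } else {
        ev <- c(ev, list(tibble(branch = b, group = g, event = "copy_loss", n = ps - cs)))
      }
    }
    event_rows[[g]] <- bind_rows(ev)
    pres <- which(!is.na(st) & st > 0)
    if (length(pres) > 0) {
      rep_rows[[g]] <- tibble(node = ix$names[pres], group = g, count = st[pres])
    }
  }
  origins <- if (length(origin_rows) > 0) bind_rows(origin_rows) else
    tibble(group = character(), branch = character(), event = character(),
           parent_group = character(), after_event = character())
  events <- if (length(event_rows) > 0) bind_rows(event_rows) |>
    arrange(.data$branch, .data$group, .data$event) else
    tibble(branch = character(), group = character(), event = character(), n = integer())
  repertoires <- if (length(rep_rows) > 0) bind_rows(rep_rows) |>
    arrange(.data$node, .data$group) else
    tibble(node = character(), group = character(), count = integer())
  structure(list(tree = tree, origins = origins, events = events,
                 repertoires = repertoires),
            class = "event_history")
}

#' @export
print.event_history <- function(x, ...) {
  cat(sprintf("<event_history> %d groups, %d events across %d branches\n",
              nrow(x$origins), sum(x$events$n), length(unique(x$events$branch))))
  invisible(x)
}

#' Ancestral gene repertoire at a named node
#'
#' @param history an `event_history`.
#' @param node node name (leaf or ancestor).
#' @return A tibble `group`, `count` for groups present (count >= 1) at
#'   the node; its row count is the repertoire size.
#' @export
ancestral_repertoire <- function(history, node) {
  nm <- tree_node_names(history$tree)
  if (!node %in% nm) plg_lookup_error(sprintf("unknown node '%s'", node))
  history$repertoires |> filter(.data$node == !!node) |> select("group", "count")
}

#' Number of distinct pre-WGD gene lineages
#'
#' Counts the distinct progenitor ids among WGD- or pre-WGD-originated
#' groups; tandem-duplicate groups collapse onto their parent's lineage
#' and add nothing.  Without WGD constraints this reduces to the number of
#' groups whose Dollo origin sits on the root stem.
#'
#' @param history an `event_history`.
#' @param constraints an `origin_constraints` table.
#' @return An integer count.
#' @export
progenitor_count <- function(history, constraints = NULL) {
  root <- tree_root(history$tree)
  lineage_of <- function(g, seen = character()) {
    if (g %in% seen) plg_validation_error(sprintf("tandem parent cycle at '%s'", g))
    cons <- constraint_for(constraints, g)
    if (cons$origin %in% c("pre_WGD", "WGD1", "WGD2")) {
      if (is.na(cons$progenitor)) {
        plg_validation_error(sprintf("WGD-originated group '%s' lacks a progenitor id", g))
      }
      return(cons$progenitor)
    }
    if (cons$origin == "tandem") return(lineage_of(cons$parent_group, c(seen, g)))
    o <- history$origins[history$origins$group == g, ]
    if (nrow(o) == 1 && o$branch == root) return(g)
    NA_character_
  }
  lin <- vapply(history$origins$group, lineage_of, character(1))
  length(unique(lin[!is.na(lin)]))
}

#' Gene count immediately after the second whole-genome duplication
#'
#' The number of genes existing just after WGD2: the repertoire at the
#' node below the WGD2-carrying branch, excluding tandem duplicates placed
#' after WGD2 on that branch.  Without tandem constraints this equals the
#' repertoire size at that node.
#'
#' @param history an `event_history`.
#' @param constraints an `origin_constraints` table.
#' @return An integer gene count.
#' @export
post_wgd_gene_count <- function(history, constraints = NULL) {
  b <- event_branches(history$tree, "WGD2")
  node <- if (length(b) > 0) b[[1]] else tree_root(history$tree)
  rep <- ancestral_repertoire(history, node)
  excluded <- character()
  if (!is.null(constraints)) {
    tand <- as_tibble(constraints) |>
      filter(.data$origin == "tandem", !is.na(.data$after_event),
             .data$after_event == "WGD2")
    excluded <- tand$group
  }
  sum(rep$count[!rep$group %in% excluded])
}

#' Conservation summary of a count matrix
#'
#' Partitions the species into the two clades on either side of the root
#' (named after their ancestral nodes) and classifies orthology groups by
#' their phylogenetic span: present in every species; present on both
#' sides of the root but not universal; restricted to the reference
#' species' side; restricted to the other side.  Also tallies per-species
#' group counts and totals and lists groups absent from a designated
#' reference species.
#'
#' @param matrix a `count_matrix`.
#' @param tree a `species_tree` covering the matrix species.
#' @param reference_species the reference species (default
#'   `"Homo_sapiens"`); its side of the root is the "ingroup".
#' @return A `conservation_summary` list with elements `universal`,
#'   `shared_not_universal`, `ingroup_only`, `outgroup_only`,
#'   `absent_in_reference` (character vectors of group ids), `per_species`
#'   (tibble `species`, `n_groups`, `n_genes`, `n_other`), `n_groups`,
#'   `ingroup`, `outgroup` (species sets).
#' @export
conservation_summary <- function(matrix, tree, reference_species = "Homo_sapiens") {
  ix <- tree_index(tree)
  m <- as_tibble(matrix)
  groups <- count_groups(matrix)
  kids <- ix$children[[ix$root]]
  sides <- lapply(kids, function(k) ix$names[tips_below(ix, k)])
  names(sides) <- ix$names[kids]
  in_side <- vapply(sides, function(s) reference_species %in% s, logical(1))
  if (!any(in_side)) {
    plg_validation_error(sprintf("reference species '%s' not in tree", reference_species))
  }
  ingroup <- intersect(unlist(sides[in_side]), m$species)
  outgroup <- intersect(unlist(sides[!in_side]), m$species)
  present <- function(g, sp) any(m[[g]][m$species %in% sp] > 0)
  pres_all <- vapply(groups, function(g) all(m[[g]] > 0), logical(1))
  pres_in <- vapply(groups, function(g) present(g, ingroup), logical(1))
  pres_out <- vapply(groups, function(g) present(g, outgroup), logical(1))
  universal <- groups[pres_all]
  shared <- groups[pres_in & pres_out & !pres_all]
  ingroup_only <- groups[pres_in & !pres_out]
  outgroup_only <- groups[pres_out & !pres_in]
  ref_row <- m[m$species == reference_species, ]
  absent_ref <- if (nrow(ref_row) == 1) {
    groups[vapply(groups, function(g) ref_row[[g]] == 0, logical(1))]
  } else groups
  per_species <- tibble(
    species = m$species,
    n_groups = vapply(seq_len(nrow(m)), function(i) {
      sum(vapply(groups, function(g) m[[g]][i] > 0, logical(1)))
    }, integer(1)),
    n_genes = count_totals(matrix, include_other = TRUE)$total,
    n_other = m$Other)
  structure(list(universal = universal, shared_not_universal = shared,
                 ingroup_only = ingroup_only, outgroup_only = outgroup_only,
                 absent_in_reference = absent_ref, per_species = per_species,
                 n_groups = length(groups),
                 ingroup = ingroup, outgroup = outgroup,
                 reference_species = reference_species),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation_summary> %d groups across %d species\n",
              x$n_groups, nrow(x$per_species)))
  cat(sprintf(" universal: %s\n", paste(x$universal, collapse = ", ")))
  cat(sprintf(" shared (both sides, not universal): %d\n",
              length(x$shared_not_universal)))
  cat(sprintf(" %s-side only: %d; absent in %s: %d\n",
              x$reference_species, length(x$ingroup_only),
              x$reference_species, length(x$absent_in_reference)))
  invisible(x)
}
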