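#' Read a species tree with branch-attached whole-genome duplication events
#'
#' Parses a rooted newick tree whose internal nodes are named ancestors and
#' attaches whole-genome duplication (WGD) events to branches.  Events are
#' carried in a separate two-column table rather than in newick comments,
#' keyed by the *child* node of the branch that carries them; the root
#' node's own name keys the stem branch above the root, which is where the
#' two ancestral vertebrate WGDs live in the packaged fixture.
#'
#' @param newick path to a newick file, or a literal newick string.
#' @param events optional branch-event table: a path, TSV text, or a data
#'   frame with columns `branch` (child node name), `event` (one of
#'   `"WGD1"`, `"WGD2"`, `"TS_WGD"`) and optionally `order` (position of
#'   the event along its branch, earliest first).
#' @return A `species_tree` object: a list with elements `phylo` (an
#'   [ape::read.tree()] tree with named internal nodes) and `events`
#'   (a tibble of branch events).
#' @details Invariants enforced: the tree is rooted with unique leaf names;
#'   on any one branch `WGD1` precedes `WGD2`; `TS_WGD` never shares a
#'   branch with `WGD1` or `WGD2`.  Unnamed internal nodes are auto-named
#'   `N<id>` so every branch is addressable.
#' @export
#' @examples
#' st <- read_species_tree("((A,B)ab,C)root;",
#'                         data.frame(branch = "root", event = c("WGD1", "WGD2")))
#' tree_node_names(st)
read_species_tree <- function(newick, events = NULL) {
  text <- as_text_source(newick, "newick")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) plg_parse_error("malformed newick: could not parse tree")
  if (!ape::is.rooted(phy)) plg_validation_error("species tree must be rooted")
  if (anyDuplicated(phy$tip.label)) {
    plg_validation_error("species tree leaf names must be unique")
  }
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  blank <- is.na(phy$node.label) | phy$node.label == ""
  phy$node.label[blank] <- paste0("N", ape::Ntip(phy) + which(blank))
  nm <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(nm)) {
    plg_validation_error("species tree node names must be unique across leaves and ancestors")
  }
  ev <- normalise_branch_events(events, nm)
  structure(list(phylo = phy, events = ev), class = "species_tree")
}

normalise_branch_events <- function(events, node_names) {
  if (is.null(events)) {
    return(tibble(branch = character(), event = character(), order = integer()))
  }
  ev <- if (is.data.frame(events)) {
    as_tibble(events)
  } else {
    read_tsv_quiet(as_text_source(events, "events table"))
  }
  if (!all(c("branch", "event") %in% names(ev))) {
    plg_validation_error("events table needs columns 'branch' and 'event'")
  }
  if (!"order" %in% names(ev)) ev$order <- seq_len(nrow(ev))
  ev <- ev |>
    mutate(branch = as.character(.data$branch),
           event = as.character(.data$event),
           order = as.integer(.data$order)) |>
    select("branch", "event", "order") |>
    arrange(.data$branch, .data$order)
  known <- c("WGD1", "WGD2", "TS_WGD")
  bad <- setdiff(unique(ev$event), known)
  if (length(bad) > 0) {
    plg_validation_error(sprintf("unknown event name(s): %s", paste(bad, collapse = ", ")))
  }
  missing <- setdiff(unique(ev$branch), node_names)
  if (length(missing) > 0) {
    plg_validation_error(sprintf("event on nonexistent branch: %s",
                                 paste(missing, collapse = ", ")))
  }
  for (b in unique(ev$branch)) {
    e <- ev$event[ev$branch == b]
    if (anyDuplicated(e)) {
      plg_validation_error(sprintf("duplicate event on branch '%s'", b))
    }
    if (all(c("WGD1", "WGD2") %in% e) &&
        which(e == "WGD1") > which(e == "WGD2")) {
      plg_validation_error(sprintf("WGD1 must precede WGD2 on branch '%s'", b))
    }
    if ("TS_WGD" %in% e && any(c("WGD1", "WGD2") %in% e)) {
      plg_validation_error(sprintf("TS_WGD cannot share branch '%s' with WGD1/WGD2", b))
    }
  }
  ev
}

#' Write a species tree back to newick and a branch-event TSV
#'
#' @param st a `species_tree`.
#' @param newick_path file to write the newick string to.
#' @param events_path optional file to write the branch-event table to.
#' @return `st`, invisibly.
#' @export
write_species_tree <- function(st, newick_path, events_path = NULL) {
  stopifnot(inherits(st, "species_tree"))
  ape::write.tree(st$phylo, file = newick_path)
  if (!is.null(events_path)) {
    readr::write_tsv(st$events, events_path, progress = FALSE)
  }
  invisible(st)
}

# Internal index of a species_tree / phylo: id <-> name maps, parent and
# children by ape node id (tips 1..n, internals n+1..n+m, root n+1).
tree_index <- function(st) {
  phy <- if (inherits(st, "species_tree")) st$phylo else st
  n <- ape::Ntip(phy)
  m <- phy$Nnode
  nm <- c(phy$tip.label, if (is.null(phy$node.label)) paste0("N", n + seq_len(m)) else phy$node.label)
  parent <- rep(NA_integer_, n + m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- vector("list", n + m)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[[p]] <- c(children[[p]], phy$edge[i, 2])
  }
  children <- lapply(children, function(x) if (is.null(x)) integer() else sort(x))
  elen <- rep(NA_real_, n + m)
  if (!is.null(phy$edge.length)) elen[phy$edge[, 2]] <- phy$edge.length
  list(phylo = phy, n_tip = n, names = nm, id = setNames(seq_along(nm), nm),
       parent = parent, children = children, root = n + 1L, edge_length = elen)
}

# All tip ids below (and including) a node id.
tips_below <- function(ix, node) {
  if (node <= ix$n_tip) return(node)
  out <- integer()
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    kids <- ix$children[[v]]
    out <- c(out, kids[kids <= ix$n_tip])
    stack <- c(stack, kids[kids > ix$n_tip])
  }
  sort(out)
}

# Is `anc` an ancestor of (or equal to) node `v`?
is_ancestor <- function(ix, anc, v) {
  while (!is.na(v)) {
    if (v == anc) return(TRUE)
    v <- ix$parent[v]
  }
  FALSE
}

mrca_id <- function(ix, tip_ids) {
  if (length(tip_ids) == 1L) return(tip_ids)
  paths <- lapply(tip_ids, function(t) {
    p <- t
    while (!is.na(ix$parent[p[length(p)]])) p <- c(p, ix$parent[p[length(p)]])
    p
  })
  common <- Reduce(intersect, paths)
  common[[1]]  # first common node on the path from a tip upward = MRCA
}

#' Node, leaf and root names of a species tree
#' @param st a `species_tree`.
#' @return A character vector of names.
#' @export
tree_node_names <- function(st) tree_index(st)$names

#' @rdname tree_node_names
#' @export
tree_leaves <- function(st) st$phylo$tip.label

#' @rdname tree_node_names
#' @export
tree_root <- function(st) {
  ix <- tree_index(st)
  ix$names[ix$root]
}

#' Branches carrying a given WGD event
#' @param st a `species_tree`.
#' @param event event name (`"WGD1"`, `"WGD2"` or `"TS_WGD"`).
#' @return Character vector of child-node names keying the branches.
#' @export
event_branches <- function(st, event) {
  st$events$branch[st$events$event == event]
}

#' Leaf species descending from a named node
#' @param st a `species_tree`.
#' @param node a node name.
#' @return Character vector of leaf names.
#' @export
descendant_species <- function(st, node) {
  ix <- tree_index(st)
  if (!node %in% ix$names) plg_lookup_error(sprintf("unknown node '%s'", node))
  ix$names[tips_below(ix, ix$id[[node]])]
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d species, %d internal nodes, %d branch events\n",
              ape::Ntip(x$phylo), x$phylo$Nnode, nrow(x$events)))
  if (nrow(x$events) > 0) {
    ev <- paste(sprintf("%s@%s", x$events$event, x$events$branch), collapse = ", ")
    cat(" events:", ev, "\n")
  }
  invisible(x)
}

#' Read a gene tree with integer bootstrap supports
#'
#' Gene trees are consumed, never estimated: internal-node labels are read
#' as integer percent bootstrap supports (0-100); missing labels are kept
#' and treated as unsupported (0) by downstream clade extraction.  Leaves
#' are labelled `"<species>|<accession>"`.
#'
#' @param newick path to a newick file or a literal newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_gene_tree <- function(newick) {
  text <- as_text_source(newick, "newick")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) plg_parse_error("malformed newick: could not parse gene tree")
  if (anyDuplicated(phy$tip.label)) {
    plg_validation_error("gene tree leaf labels must be unique")
  }
  sup <- node_supports(phy)
  if (any(!is.na(sup) & (sup < 0 | sup > 100))) {
    plg_validation_error("bootstrap supports must lie in [0, 100]")
  }
  phy
}

# Integer supports per internal node; NA where absent/non-numeric.
node_supports <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_integer_, phy$Nnode))
  suppressWarnings(as.integer(round(as.numeric(phy$node.label))))
}

# Split "<species>|<accession>" leaf labels.
split_leaf_labels <- function(labels) {
  has_sep <- grepl("|", labels, fixed = TRUE)
  sp <- ifelse(has_sep, sub("\\|.*$", "", labels), NA_character_)
  acc <- ifelse(has_sep, sub("^[^|]*\\|", "", labels), labels)
  tibble(label = labels, species = sp, accession = acc)
}
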