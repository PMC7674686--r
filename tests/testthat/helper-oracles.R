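# Independent oracles used across the suite.  These deliberately take
# different code paths from the package (ape/phangorn traversals, explicit
# enumeration) so they can serve as ground truth.

# tip labels below each node, by ape node id
oracle_tipsets <- function(phy) {
  n <- ape::Ntip(phy)
  desc <- phangorn::Descendants(phy, seq_len(n + phy$Nnode), type = "tips")
  lapply(desc, function(i) sort(phy$tip.label[i]))
}

oracle_parent <- function(phy) {
  pa <- rep(NA_integer_, ape::Ntip(phy) + phy$Nnode)
  pa[phy$edge[, 2]] <- phy$edge[, 1]
  pa
}

oracle_is_anc <- function(pa, anc, v) {
  while (!is.na(v)) {
    if (v == anc) return(TRUE)
    v <- pa[v]
  }
  FALSE
}

# Brute-force Dollo: minimum number of presence-level losses over every
# feasible origin placement, by direct enumeration.
bf_dollo <- function(phy, presence_tips) {
  n <- ape::Ntip(phy)
  tipsets <- oracle_tipsets(phy)
  pa <- oracle_parent(phy)
  feasible <- which(vapply(tipsets, function(s) all(presence_tips %in% s), logical(1)))
  best <- Inf
  best_nodes <- integer()
  for (v in feasible) {
    loss <- 0L
    for (e in seq_len(nrow(phy$edge))) {
      a <- phy$edge[e, 1]
      b <- phy$edge[e, 2]
      if (!oracle_is_anc(pa, v, a)) next
      a_has <- length(intersect(tipsets[[a]], presence_tips)) > 0
      b_has <- length(intersect(tipsets[[b]], presence_tips)) > 0
      if (a_has && !b_has) loss <- loss + 1L
    }
    if (loss < best) {
      best <- loss
      best_nodes <- v
    } else if (loss == best) best_nodes <- c(best_nodes, v)
  }
  list(min_losses = best, argmin = best_nodes)
}

# Exhaustive Wagner-Dollo cost: enumerate every internal-state assignment
# on a small rooted tree, origin at the root with entry cost |s - 1|,
# transition cost |parent - child|, parent 0 -> child > 0 forbidden.
bf_wagner_cost <- function(phy, tip_counts, max_state) {
  n <- ape::Ntip(phy)
  m <- phy$Nnode
  states <- 0:max_state
  grids <- rev(expand.grid(rep(list(states), m)))
  pa <- oracle_parent(phy)
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    assign <- c(tip_counts, as.integer(grids[r, m:1]))
    root_state <- assign[n + 1L]
    cost <- abs(root_state - 1L)
    ok <- TRUE
    for (e in seq_len(nrow(phy$edge))) {
      ps <- assign[phy$edge[e, 1]]
      cs <- assign[phy$edge[e, 2]]
      if (ps == 0L && cs > 0L) { ok <- FALSE; break }
      cost <- cost + abs(ps - cs)
    }
    if (ok) best <- min(best, cost)
  }
  best
}

# A random rooted tree with tip labels sp1..spk (deterministic per seed).
random_species_tree <- function(n_tips, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  phy$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  phy$node.label <- sprintf("anc%02d", seq_len(phy$Nnode))
  read_species_tree(ape::write.tree(phy))
}

# One-group presence/absence matrix over the given species.
presence_matrix <- function(species, present) {
  df <- tibble::tibble(species = species, grp = as.integer(species %in% present))
  as_count_matrix(df)
}

# Compare two leaf partitions (named membership vectors) up to label names.
same_partition <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  b <- b[names(a)]
  canon <- function(x) {
    blocks <- split(names(x), x)
    sort(vapply(blocks, function(g) paste(sort(g), collapse = ","), character(1)),
         method = "radix")
  }
  identical(unname(canon(a)), unname(canon(b)))
}

# An empty event history on a tree (for recall-0 checks).
empty_history <- function(tree) {
  structure(list(tree = tree,
                 origins = tibble::tibble(group = character(), branch = character(),
                                          event = character(),
                                          parent_group = character(),
                                          after_event = character()),
                 events = tibble::tibble(branch = character(), group = character(),
                                         event = character(), n = integer()),
                 repertoires = tibble::tibble(node = character(), group = character(),
                                              count = integer())),
            class = "event_history")
}

fixture_totals <- c(Petromyzon_marinus = 7L, Lethenteron_camtschaticum = 8L,
                    Eptatretus_burgeri = 8L, Callorhinchus_milii = 20L,
                    Rhincodon_typus = 29L, Danio_rerio = 19L,
                    Takifugu_rubripes = 14L, Lepisosteus_oculatus = 20L,
                    Latimeria_chalumnae = 25L, Homo_sapiens = 18L)

agnathan_species <- c("Petromyzon_marinus", "Lethenteron_camtschaticum",
                      "Eptatretus_burgeri")
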