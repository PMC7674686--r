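#' Simulate gene-order tracks for a realised history
#'
#' Builds an ancestral gene order of `genome_gene_count` background genes
#' with the progenitor family genes inserted at random positions, then
#' replays the event log down the species tree: tandem duplicates are
#' inserted immediately adjacent to their parent copy, WGD duplicates at a
#' random position (a new genomic context), lost copies are removed, and
#' each branch applies Poisson(`rearrangement_rate` x length x genes)
#' neighbour shuffles (a random gene moved to a random position).  Each
#' species ends up with one scaffold of 1-kb genes spaced 1 kb apart, so
#' the default 200-kb neighbourhood window spans about 100 genes.
#' Background genes keep their own id as family label, giving a ready-made
#' cross-species orthology map.
#'
#' @param sim a `gene_family_sim` from [simulate_history()].
#' @param config the same [simulation_config()] (`seed + 1` drives the
#'   placement and shuffling randomness, so tracks are reproducible
#'   independently of the other emitters).
#' @return A `gene_track` covering every species in the tree.
#' @export
simulate_tracks <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  ix <- tree_index(sim$truth$tree)
  n_bg <- config$genome_gene_count
  bg <- sprintf("BG%06d", seq_len(n_bg))
  order0 <- bg
  # insert the initial progenitor copies at random positions, then replay
  first_copies <- sprintf("c%04d", seq_len(config$n_progenitors))
  for (cp in first_copies) {
    pos <- sample.int(length(order0) + 1L, 1L)
    order0 <- append(order0, cp, after = pos - 1L)
  }
  copy_group <- copy_group_map(sim)

  apply_branch <- function(ord, branch_name, length_) {
    evs <- sim$evlog[sim$evlog$branch == branch_name, ]
    evs <- evs[order(evs$ord), ]
    for (i in seq_len(nrow(evs))) {
      e <- evs[i, ]
      if (e$type %in% c("wgd_dup", "wgd_copy")) {
        if (!e$copy %in% ord) next
        pos <- sample.int(length(ord) + 1L, 1L)
        ord <- append(ord, e$new_copy, after = pos - 1L)
      } else if (e$type == "tandem_dup") {
        at <- match(e$copy, ord)
        if (is.na(at)) next
        ord <- append(ord, e$new_copy, after = at)
      } else if (e$type == "loss") {
        ord <- setdiff(ord, e$copy)
      }
    }
    if (config$rearrangement_rate > 0 && length_ > 0) {
      n_moves <- rpois(1L, config$rearrangement_rate * length_ * length(ord))
      n_moves <- min(n_moves, 10L * length(ord))
      for (k in seq_len(n_moves)) {
        from <- sample.int(length(ord), 1L)
        gid <- ord[from]
        ord <- ord[-from]
        to <- sample.int(length(ord) + 1L, 1L)
        ord <- append(ord, gid, after = to - 1L)
      }
    }
    ord
  }

  tracks <- list()
  descend <- function(ord, node_id) {
    node <- ix$names[node_id]
    if (node_id <= ix$n_tip) {
      fam <- ifelse(ord %in% names(copy_group), copy_group[ord], ord)
      n <- length(ord)
      tracks[[node]] <<- tibble(
        species = node, scaffold = "chr1",
        start = (seq_len(n) - 1L) * 2000L, end = (seq_len(n) - 1L) * 2000L + 1000L,
        strand = "+", gene_id = ord, family = unname(fam))
      return(invisible(NULL))
    }
    for (child in ix$children[[node_id]]) {
      descend(apply_branch(ord, ix$names[child], branch_length(ix, child)), child)
    }
  }
  ord_root <- apply_branch(order0, ix$names[ix$root], 0)
  descend(ord_root, ix$root)
  as_gene_track(bind_rows(tracks))
}

# copy id -> group id over the whole realised history; the initial copies
# c0001..c000p carry the progenitor groups G1..Gp in order by construction
copy_group_map <- function(sim) {
  born <- sim$evlog[sim$evlog$type %in% c("wgd_dup", "wgd_copy", "tandem_dup"), ]
  first <- sprintf("c%04d", seq_len(sim$config$n_progenitors))
  c(setNames(sprintf("G%d", seq_along(first)), first),
    setNames(born$new_group, born$new_copy))
}

#' Simulate a gene tree concordant with a realised history
#'
#' Replays the event log into a gene tree: duplication events create
#' paralog clades, losses prune leaves, and lineages that never duplicate
#' collapse to polytomies (speciation order is not resolved).  Supports
#' mirror the signature of real single-domain trees, where only
#' within-orthology-group branches are statistically supported: a clade
#' whose leaves all belong to one orthology group gets an integer
#' bootstrap support of 100 minus half-normal noise of standard deviation
#' `support_noise` (clamped to `[0, 100]`), whereas nodes joining
#' different groups — ancient WGD splits and the root joining unrelated
#' families — get support 0.  Leaves are labelled `"<species>|<copy>"`.
#'
#' @param sim a `gene_family_sim` from [simulate_history()].
#' @param config the same [simulation_config()] (`seed + 2` drives the
#'   support noise).
#' @return A `phylo` gene tree.
#' @export
simulate_gene_tree <- function(sim, config = sim$config) {
  set.seed(config$seed + 2L)
  ix <- tree_index(sim$truth$tree)
  cg <- copy_group_map(sim)
  draw_support <- function(groups) {
    if (length(groups) > 1) return(0L)
    s <- 100 - abs(rnorm(1L, 0, config$support_noise))
    max(0L, min(100L, as.integer(round(s))))
  }
  # subtrees are lists: str (newick fragment) + groups (leaf group set)
  sub <- function(str, groups) list(str = str, groups = groups)
  wrap <- function(parts) {
    if (length(parts) == 1) return(parts[[1]])
    gs <- sort(unique(unlist(lapply(parts, `[[`, "groups"))))
    sub(sprintf("(%s)%d", paste(vapply(parts, `[[`, "", "str"), collapse = ","),
                draw_support(gs)), gs)
  }
  branch_evs <- split(sim$evlog, sim$evlog$branch)

  node_set <- function(copy, node_id) {
    if (node_id <= ix$n_tip) {
      return(list(sub(sprintf("%s|%s", ix$names[node_id], copy), cg[[copy]])))
    }
    parts <- list()
    for (child in ix$children[[node_id]]) {
      evs <- branch_evs[[ix$names[child]]]
      if (!is.null(evs)) evs <- evs[order(evs$ord), ]
      parts <- c(parts, branch_set(copy, evs, child))
    }
    parts
  }
  branch_set <- function(copy, evs, child_id) {
    if (!is.null(evs) && nrow(evs) > 0) {
      mine <- which(evs$copy == copy)
      if (length(mine) > 0) {
        e <- evs[mine[[1]], ]
        rest <- evs[-seq_len(mine[[1]]), , drop = FALSE]
        if (e$type == "loss") return(list())
        a <- branch_set(copy, rest, child_id)
        b <- branch_set(e$new_copy, rest, child_id)
        if (length(a) == 0) return(b)
        if (length(b) == 0) return(a)
        wa <- wrap(a)
        wb <- wrap(b)
        gs <- sort(unique(c(wa$groups, wb$groups)))
        return(list(sub(sprintf("(%s,%s)%d", wa$str, wb$str, draw_support(gs)), gs)))
      }
    }
    node_set(copy, child_id)
  }

  root_evs <- branch_evs[[ix$names[ix$root]]]
  if (!is.null(root_evs)) root_evs <- root_evs[order(root_evs$ord), ]
  first_copies <- sprintf("c%04d", seq_len(config$n_progenitors))
  fams <- character()
  n_leaves <- 0L
  for (cp in first_copies) {
    res <- branch_set(cp, root_evs, ix$root)
    if (length(res) == 0) next
    w <- wrap(res)
    fams <- c(fams, w$str)
    n_leaves <- n_leaves + 1L  # at least one leaf per surviving progenitor
  }
  if (length(fams) == 0) plg_validation_error("no surviving gene copies to build a tree from")
  newick <- if (length(fams) == 1) paste0(fams, ";") else
    sprintf("(%s)0;", paste(fams, collapse = ","))
  phy <- ape::read.tree(text = newick)
  if (is.null(phy)) {
    # a single surviving leaf: build the one-tip tree by hand
    lab <- gsub("[();]|;", "", newick)
    phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab,
                          Nnode = 1L, node.label = "0"),
                     class = "phylo")
  }
  phy
}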