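#' Classification settings for orthology grouping
#'
#' @param min_support minimum integer bootstrap percent for a branch to be
#'   considered statistically supported (default 95, the conventional
#'   ultrafast-bootstrap significance threshold).
#' @param reference_species species whose gene labels seed orthology-group
#'   names (default `"Homo_sapiens"`).
#' @param allow_synteny_rescue rescue leaves left outside supported clades
#'   using microsynteny evidence?
#' @return A `classification_config` list.
#' @export
classification_config <- function(min_support = 95L,
                                  reference_species = "Homo_sapiens",
                                  allow_synteny_rescue = TRUE) {
  min_support <- as.integer(min_support)
  if (is.na(min_support) || min_support < 0L || min_support > 100L) {
    plg_validation_error("min_support must lie in [0, 100]")
  }
  structure(list(min_support = min_support,
                 reference_species = reference_species,
                 allow_synteny_rescue = isTRUE(allow_synteny_rescue)),
            class = "classification_config")
}

#' Extract bootstrap-supported clades from a gene tree
#'
#' Returns every clade (maximal and nested) whose subtending branch has
#' bootstrap support of at least `min_support` percent, plus every leaf as
#' a singleton clade.  Missing supports count as 0 (an unsupported branch
#' is uninformative, never evidence).
#'
#' @param tree a rooted `phylo` gene tree with integer supports as
#'   internal-node labels.
#' @param min_support minimum support percent (default 95).
#' @return A list of character vectors of leaf labels.  Internal clades
#'   come first (largest first, ties broken by the smallest member label),
#'   then singletons in sorted label order.
#' @export
supported_clades <- function(tree, min_support = 95L) {
  ix <- tree_index(tree)
  sup <- node_supports(ix$phylo)
  sup[is.na(sup)] <- 0L
  internal <- ix$n_tip + seq_len(ix$phylo$Nnode)
  keep <- internal[sup >= min_support]
  clades <- lapply(keep, function(v) sort(ix$names[tips_below(ix, v)]))
  clades <- clades[lengths(clades) >= 2]  # internal clades proper
  if (length(clades) > 0) {
    key <- vapply(clades, function(x) x[[1]], character(1))
    clades <- clades[order(-lengths(clades), key)]
    clades <- unique(clades)
  }
  c(clades, as.list(sort(ix$names[seq_len(ix$n_tip)])))
}

# Merged group name from >= 2 inseparable reference labels: slash-joined,
# compressing the longest common prefix ("TNFSF1" + "TNFSF2" -> "TNFSF1/2").
merge_name <- function(labels) {
  labels <- sort(unique(labels))
  if (length(labels) == 1) return(labels)
  first <- labels[[1]]
  rest <- vapply(labels[-1], function(x) {
    chars_a <- strsplit(first, "")[[1]]
    chars_b <- strsplit(x, "")[[1]]
    k <- 0L
    while (k < min(length(chars_a), length(chars_b)) - 1L &&
           chars_a[k + 1L] == chars_b[k + 1L]) k <- k + 1L
    substr(x, k + 1L, nchar(x))
  }, character(1))
  paste(c(first, rest), collapse = "/")
}

#' Classify gene-tree leaves into orthology groups
#'
#' Combines bootstrap-supported clades with microsynteny corroboration.
#' Rules, applied in order:
#' \enumerate{
#' \item a supported clade containing at least one reference leaf, with no
#'   supported internal branch separating its reference genes
#'   species-consistently, defines one group named after its reference
#'   gene(s) (two or more inseparable reference genes yield a merged,
#'   slash-joined name);
#' \item a supported clade with no reference leaf spanning at least two
#'   species defines a novel group, auto-named `GRP-` plus its
#'   lexicographically smallest accession;
#' \item a leaf outside any qualifying clade is rescued into a group it
#'   shares `same_position` or `same_chromosome` synteny evidence with;
#'   equal-class evidence towards two groups is a conflict and the leaf
#'   stays unassigned;
#' \item anything else is `UNASSIGNED`.
#' }
#'
#' A supported branch "separates the reference genes species-consistently"
#' when each side of the split holds at most one reference gene and every
#' non-reference species' leaves fall entirely on one side; only then can
#' orthology be read off the tree, otherwise the references merge.
#'
#' @param tree a rooted `phylo` gene tree, leaves labelled
#'   `"<species>|<accession>"`.
#' @param config a [classification_config()].
#' @param synteny optional synteny-evidence tibble (see
#'   [shared_neighbor_evidence()]) used for rescue.
#' @param reference_labels optional tibble with columns `accession` and
#'   `group` naming known genes; defaults to the reference species' leaves,
#'   each seeding a group named after its accession.  May be empty for
#'   fully de novo grouping.
#' @return A tibble of sequence assignments: `accession`, `species`,
#'   `group` (`"UNASSIGNED"` when none), and the evidence flags
#'   `clade_support`, `synteny_same_position`, `synteny_same_chromosome`,
#'   `conflict`.
#' @export
classify <- function(tree, config = classification_config(), synteny = NULL,
                     reference_labels = NULL) {
  leaves <- split_leaf_labels(tree$tip.label)
  if (is.null(reference_labels)) {
    ref_leaves <- leaves[!is.na(leaves$species) &
                           leaves$species == config$reference_species, ]
    reference_labels <- tibble(accession = ref_leaves$accession,
                               group = ref_leaves$accession)
  } else {
    reference_labels <- as_tibble(reference_labels)[, c("accession", "group")]
  }
  ref_group <- setNames(reference_labels$group, reference_labels$accession)
  is_ref <- leaves$accession %in% reference_labels$accession
  ref_labels_in_tree <- leaves$label[is_ref]

  all_clades <- supported_clades(tree, config$min_support)
  clades <- all_clades[lengths(all_clades) >= 2]

  refs_in <- lapply(clades, intersect, y = ref_labels_in_tree)
  nref <- lengths(refs_in)

  # species-consistent separation test for rule 1
  separable <- function(ci) {
    C <- clades[[ci]]
    refs <- refs_in[[ci]]
    if (length(refs) < 2) return(FALSE)
    leaf_sp <- setNames(leaves$species, leaves$label)
    for (dj in seq_along(clades)) {
      D <- clades[[dj]]
      if (length(D) >= length(C) || !all(D %in% C)) next
      inD <- sum(refs %in% D)
      if (inD == 0 || inD == length(refs)) next      # does not separate refs
      outD <- length(refs) - inD
      if (inD > 1 || outD > 1) next                   # both sides must hold <= 1 ref
      nonref <- setdiff(C, ref_labels_in_tree)
      sp <- leaf_sp[nonref]
      split_side <- nonref %in% D
      ok <- TRUE
      for (s in unique(sp[!is.na(sp)])) {
        sides <- unique(split_side[!is.na(sp) & sp == s])
        if (length(sides) > 1) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }

  qualifies <- vapply(seq_along(clades), function(ci) {
    nref[ci] >= 1 && !separable(ci)
  }, logical(1))

  assignment <- setNames(rep(NA_character_, nrow(leaves)), leaves$label)
  flag_clade <- setNames(rep(FALSE, nrow(leaves)), leaves$label)

  # rule 1: nearest (smallest) qualifying reference clade
  qual_idx <- which(qualifies)
  if (length(qual_idx) > 0) {
    qual_sizes <- lengths(clades[qual_idx])
    for (l in leaves$label) {
      containing <- qual_idx[vapply(clades[qual_idx], function(C) l %in% C, logical(1))]
      if (length(containing) == 0) next
      best <- containing[which.min(lengths(clades[containing]))]
      refs <- refs_in[[best]]
      assignment[[l]] <- merge_name(unname(ref_group[split_leaf_labels(refs)$accession]))
      flag_clade[[l]] <- TRUE
    }
  }

  # rule 2: maximal supported no-reference clades spanning >= 2 species
  noref_idx <- which(nref == 0)
  if (length(noref_idx) > 0) {
    ord <- noref_idx[order(-lengths(clades[noref_idx]))]
    for (ci in ord) {
      C <- clades[[ci]]
      sp <- unique(split_leaf_labels(C)$species)
      if (length(sp[!is.na(sp)]) < 2) next
      if (any(!is.na(assignment[C]))) next  # nested inside an assigned clade
      accs <- sort(split_leaf_labels(C)$accession)
      assignment[C] <- paste0("GRP-", accs[[1]])
      flag_clade[C] <- TRUE
    }
  }

  # rule 3: synteny rescue of leftover leaves
  flag_pos <- setNames(rep(FALSE, nrow(leaves)), leaves$label)
  flag_chr <- setNames(rep(FALSE, nrow(leaves)), leaves$label)
  flag_conflict <- setNames(rep(FALSE, nrow(leaves)), leaves$label)
  if (config$allow_synteny_rescue && !is.null(synteny) && nrow(synteny) > 0) {
    syn <- as_tibble(synteny)
    acc_group <- setNames(assignment, leaves$accession)  # assigned so far, by accession
    for (l in leaves$label[is.na(assignment)]) {
      acc <- split_leaf_labels(l)$accession
      hits <- bind_rows(
        syn[syn$gene_a == acc, c("gene_b", "class")] |> rename(partner = "gene_b"),
        syn[syn$gene_b == acc, c("gene_a", "class")] |> rename(partner = "gene_a"))
      hits <- hits[hits$class %in% c("same_position", "same_chromosome"), ]
      if (nrow(hits) == 0) next
      hits$group <- unname(acc_group[hits$partner])
      hits <- hits[!is.na(hits$group), ]
      if (nrow(hits) == 0) next
      hits$rank <- ifelse(hits$class == "same_position", 2L, 1L)
      best <- hits[hits$rank == max(hits$rank), ]
      cand <- unique(best$group)
      if (length(cand) > 1) {
        flag_conflict[[l]] <- TRUE
        next
      }
      assignment[[l]] <- cand
      if (best$class[[1]] == "same_position") flag_pos[[l]] <- TRUE else flag_chr[[l]] <- TRUE
    }
  }

  tibble(accession = leaves$accession,
         species = leaves$species,
         group = unname(ifelse(is.na(assignment[leaves$label]), "UNASSIGNED",
                               assignment[leaves$label])),
         clade_support = unname(flag_clade[leaves$label]),
         synteny_same_position = unname(flag_pos[leaves$label]),
         synteny_same_chromosome = unname(flag_chr[leaves$label]),
         conflict = unname(flag_conflict[leaves$label]))
}

#' Tally sequence assignments into a count matrix
#'
#' @param assignments a tibble as returned by [classify()] (columns
#'   `accession`, `species`, `group`).
#' @param species optional species universe (rows), so species with no
#'   assigned sequence still appear with zero counts.
#' @param groups optional group ordering for the columns.
#' @return A `count_matrix`; `UNASSIGNED` sequences are tallied into
#'   `Other`.
#' @export
assignments_to_matrix <- function(assignments, species = NULL, groups = NULL) {
  a <- as_tibble(assignments)
  species <- species %||% unique(a$species)
  groups <- groups %||% sort(setdiff(unique(a$group), "UNASSIGNED"))
  wide <- tibble(species = species)
  for (g in groups) {
    wide[[g]] <- vapply(species, function(s) {
      sum(a$species == s & a$group == g, na.rm = TRUE)
    }, integer(1))
  }
  wide$Other <- vapply(species, function(s) {
    sum(a$species == s & a$group == "UNASSIGNED", na.rm = TRUE)
  }, integer(1))
  as_count_matrix(wide, groups)
}
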