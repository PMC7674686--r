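evidence_levels <- c("same_position", "same_chromosome", "none", "undetermined")
evidence_rank <- c(same_position = 3L, same_chromosome = 2L, none = 1L,
                   undetermined = 0L)

#' Extract the gene neighbourhood around a focal gene
#'
#' Collects up to `k_genes` neighbours on each side of the focal gene,
#' within `window_bp` of it (defaults: about 200 kb per side, expanding up
#' to 1 Mb in gene-poor regions).  If a side has no gene within
#' `window_bp` the window expands towards `max_window_bp` until at least
#' one neighbour is found or the scaffold ends; a neighbourhood with an
#' empty side is flagged one-sided.  Adjacency is rank-based: the bp
#' windows only bound how far the extraction looks.
#'
#' @param track a `gene_track`.
#' @param gene focal `gene_id` (must be on the track).
#' @param k_genes neighbours per side (default 2).
#' @param window_bp base window per side in bp (default 200000).
#' @param max_window_bp expanded window bound in bp (default 1000000).
#' @return A tibble of neighbours (`gene_id`, `family`, `side`,
#'   `rank_distance`, `distance_bp`), with attributes `focal` and
#'   `one_sided`.
#' @export
neighborhood <- function(track, gene, k_genes = 2L, window_bp = 200000L,
                         max_window_bp = 1000000L) {
  hit <- as_tibble(track)[track$gene_id == gene, ]
  if (nrow(hit) == 0) plg_lookup_error(sprintf("gene '%s' not on track", gene))
  hit <- hit[1, ]
  scaf <- as_tibble(track) |>
    filter(.data$species == hit$species, .data$scaffold == hit$scaffold) |>
    arrange(.data$rank)
  r <- hit$rank
  one_side <- function(side) {
    cand <- if (side == "left") scaf[scaf$rank < r, ] else scaf[scaf$rank > r, ]
    if (nrow(cand) == 0) return(cand[0, ])
    gap <- if (side == "left") pmax(0L, hit$start - cand$end) else pmax(0L, cand$start - hit$end)
    cand$distance_bp <- gap
    cand$rank_distance <- abs(cand$rank - r)
    cand <- cand[order(cand$rank_distance), ]
    within <- cand[cand$distance_bp <= window_bp, ]
    if (nrow(within) >= 1) return(head(within, k_genes))
    expanded <- cand[cand$distance_bp <= max_window_bp, ]
    head(expanded, 1L)
  }
  left <- one_side("left")
  right <- one_side("right")
  fmt <- function(x, side) {
    if (nrow(x) == 0) return(tibble(gene_id = character(), family = character(),
                                    side = character(), rank_distance = integer(),
                                    distance_bp = integer()))
    tibble(gene_id = x$gene_id, family = x$family, side = side,
           rank_distance = as.integer(x$rank_distance),
           distance_bp = as.integer(x$distance_bp))
  }
  out <- bind_rows(fmt(left, "left"), fmt(right, "right"))
  attr(out, "focal") <- gene
  attr(out, "one_sided") <- xor(nrow(left) == 0, nrow(right) == 0)
  out
}

#' Probability that a shared flanking gene is a chance collision
#'
#' The chance that, in a genome of `genome_gene_count` genes, a random
#' gene lands in one of the `neighbor_slots` positions flanking a focal
#' gene: `neighbor_slots / genome_gene_count`, capped at 1.  With the
#' default four slots (two immediately flanking genes per side) and a
#' 20,000-gene genome this is 1/5,000, which is why a single shared
#' immediately-adjacent ortholog is accepted as proof of synteny.
#'
#' @param genome_gene_count number of genes in the genome (> 0).
#' @param neighbor_slots number of candidate flanking slots (>= 0).
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' chance_probability(20000, 4)  # 1/5000
chance_probability <- function(genome_gene_count, neighbor_slots = 4L) {
  if (!is.numeric(genome_gene_count) || length(genome_gene_count) != 1 ||
      is.na(genome_gene_count) || genome_gene_count <= 0) {
    plg_domain_error("genome_gene_count must be a positive number")
  }
  if (!is.numeric(neighbor_slots) || length(neighbor_slots) != 1 ||
      is.na(neighbor_slots) || neighbor_slots < 0) {
    plg_domain_error("neighbor_slots must be non-negative")
  }
  min(neighbor_slots / genome_gene_count, 1)
}

#' Shared-neighbour synteny evidence between two genes
#'
#' Compares the neighbourhoods of a focal gene pair across two species.
#' Evidence classes, strongest first: `same_position` when at least one
#' immediately adjacent (rank distance 1) neighbour is orthologous on both
#' sides of the comparison; `same_chromosome` when no adjacent neighbour
#' is shared but some neighbour's ortholog lies on the second gene's
#' scaffold (intrachromosomal rearrangement); `none` otherwise;
#' `undetermined` when either neighbourhood is empty (isolated contigs are
#' missing data, never evidence of absence).
#'
#' @param track_a,track_b `gene_track`s for the two species.
#' @param gene_a,gene_b focal gene ids.
#' @param orthology_map optional tibble (`gene_id`, `family`) relating
#'   genes across species; defaults to the tracks' `family` column.
#' @param k_genes,window_bp,max_window_bp see [neighborhood()].
#' @param genome_gene_count genome size used for the collision probability.
#' @return A one-row tibble: `species_a`, `gene_a`, `species_b`, `gene_b`,
#'   `class`, `shared_neighbors` (comma-joined family ids), `p` (collision
#'   probability of the observed evidence; `NA` for none/undetermined).
#' @export
shared_neighbor_evidence <- function(track_a, track_b, gene_a, gene_b,
                                     orthology_map = NULL, k_genes = 2L,
                                     window_bp = 200000L, max_window_bp = 1000000L,
                                     genome_gene_count = 20000L) {
  fam_of <- function(track, genes) {
    if (!is.null(orthology_map)) {
      m <- setNames(orthology_map$family, orthology_map$gene_id)
      unname(m[genes])
    } else {
      m <- setNames(track$family, track$gene_id)
      unname(m[genes])
    }
  }
  row_a <- as_tibble(track_a)[track_a$gene_id == gene_a, ][1, ]
  row_b <- as_tibble(track_b)[track_b$gene_id == gene_b, ][1, ]
  na <- neighborhood(track_a, gene_a, k_genes, window_bp, max_window_bp)
  nb <- neighborhood(track_b, gene_b, k_genes, window_bp, max_window_bp)
  base <- tibble(species_a = row_a$species, gene_a = gene_a,
                 species_b = row_b$species, gene_b = gene_b,
                 class = "undetermined", shared_neighbors = "", p = NA_real_)
  if (nrow(na) == 0 || nrow(nb) == 0) return(base)
  fam_a_adj <- fam_of(track_a, na$gene_id[na$rank_distance == 1L])
  fam_b_adj <- fam_of(track_b, nb$gene_id[nb$rank_distance == 1L])
  shared <- sort(intersect(fam_a_adj[!is.na(fam_a_adj)], fam_b_adj[!is.na(fam_b_adj)]))
  if (length(shared) > 0) {
    base$class <- "same_position"
    base$shared_neighbors <- paste(shared, collapse = ",")
    base$p <- chance_probability(genome_gene_count, 2L * k_genes)
    return(base)
  }
  scaf_b <- as_tibble(track_b) |>
    filter(.data$species == row_b$species, .data$scaffold == row_b$scaffold,
           .data$gene_id != gene_b)
  fam_scaf_b <- fam_of(track_b, scaf_b$gene_id)
  fam_a_all <- fam_of(track_a, na$gene_id)
  on_chr <- sort(intersect(fam_a_all[!is.na(fam_a_all)],
                           fam_scaf_b[!is.na(fam_scaf_b)]))
  if (length(on_chr) > 0) {
    base$class <- "same_chromosome"
    base$shared_neighbors <- paste(on_chr, collapse = ",")
    base$p <- min(nrow(scaf_b) / genome_gene_count, 1)
    return(base)
  }
  base$class <- "none"
  base
}

#' Group-level synteny verdicts across comparator species
#'
#' Aggregates per-pair evidence into one verdict per (group, focal
#' species): the best evidence class across comparators, and a combined
#' chance-collision probability (the product of the per-comparison
#' probabilities of the informative comparisons, assuming independence)
#' tested against `alpha`.  Congruent evidence from several species
#' therefore compounds: two independent same-position hits at p = 2e-4
#' combine to 4e-8.
#'
#' @param evidence a tibble with columns `group`, `species` (the focal
#'   species), `class` and `p` — typically per-pair rows from
#'   [shared_neighbor_evidence()] joined to group membership.
#' @param alpha significance level for the combined probability
#'   (default 1e-3).
#' @return A tibble: `group`, `species`, `verdict`, `n_comparisons`,
#'   `combined_p`, `corroborated`.
#' @export
corroborate <- function(evidence, alpha = 1e-3) {
  ev <- as_tibble(evidence)
  need <- c("group", "species", "class", "p")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0) {
    plg_validation_error(sprintf("corroborate() needs column(s): %s",
                                 paste(miss, collapse = ", ")))
  }
  ev |>
    group_by(.data$group, .data$species) |>
    summarise(
      verdict = evidence_levels[[4 - max(evidence_rank[.data$class])]],
      n_comparisons = dplyr::n(),
      combined_p = {
        inf <- .data$class %in% c("same_position", "same_chromosome")
        if (any(inf)) prod(.data$p[inf]) else NA_real_
      },
      .groups = "drop") |>
    mutate(corroborated = !is.na(.data$combined_p) & .data$combined_p < alpha)
}
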