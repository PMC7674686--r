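#' Read a BED-like gene-order track
#'
#' A gene track records the physical order of genes along scaffolds:
#' columns `species`, `scaffold`, `start`, `end`, `strand`, `gene_id`,
#' `family` (orthology/family label, blank when unknown).  Coordinates are
#' 0-based half-open base pairs.  Records are sorted by start then end
#' within each scaffold and a 0-based `rank` is assigned; rank order (gene
#' order), not bp distance, defines adjacency downstream, while bp windows
#' only bound neighbourhood extraction.  Strand is recorded but ignored by
#' the neighbourhood logic.
#'
#' @param x path to a TSV file, literal TSV text, or a data frame.
#' @return A `gene_track` tibble with an added `rank` column.
#' @export
read_gene_track <- function(x) {
  tbl <- if (is.data.frame(x)) as_tibble(x) else {
    read_tsv_quiet(as_text_source(x, "gene track"),
                   col_types = readr::cols(
                     species = readr::col_character(),
                     scaffold = readr::col_character(),
                     start = readr::col_double(),
                     end = readr::col_double(),
                     strand = readr::col_character(),
                     gene_id = readr::col_character(),
                     family = readr::col_character()))
  }
  need <- c("species", "scaffold", "start", "end", "strand", "gene_id", "family")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    plg_validation_error(sprintf("gene track missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  }
  if (!all(is_whole(tbl$start)) || !all(is_whole(tbl$end)) ||
      any(tbl$start < 0)) {
    plg_validation_error("track coordinates must be non-negative integers")
  }
  if (any(tbl$start >= tbl$end)) {
    bad <- tbl$gene_id[which(tbl$start >= tbl$end)[1]]
    plg_validation_error(sprintf("gene '%s' has start >= end (0-based half-open intervals required)", bad))
  }
  as_gene_track(tbl[, need])
}

as_gene_track <- function(tbl) {
  tbl <- as_tibble(tbl) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$species, .data$scaffold, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$species, .data$scaffold) |>
    mutate(rank = row_number() - 1L) |>
    ungroup()
  structure(tbl, class = c("gene_track", class(as_tibble(tbl))))
}

#' Write a gene track as TSV
#'
#' The `rank` column is derived, so it is dropped on write; a write/read
#' cycle is byte-identical for tracks produced by the package.
#'
#' @param track a `gene_track`.
#' @param path output file.
#' @return `track`, invisibly.
#' @export
write_gene_track <- function(track, path) {
  out <- as_tibble(track)
  out$rank <- NULL
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(track)
}
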