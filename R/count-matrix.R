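#' Read a species-by-orthology-group count matrix
#'
#' The matrix is a wide, tab-delimited table: one row per species, one
#' integer column per orthology group, an `Other` column holding sequences
#' not assigned to any group, and optionally a `No.` column stating the
#' per-species total.  Blank cells are zeros.  When `No.` is present each
#' row total is recomputed and checked against it; a mismatch is a
#' validation error naming the offending species.
#'
#' @param x path to a TSV file, or literal TSV text.
#' @return A `count_matrix`: a tibble with a `species` column, one integer
#'   column per group, and an `Other` column; the group ordering is kept in
#'   `attr(, "groups")`.
#' @export
#' @examples
#' m <- read_count_matrix("species\tgrpA\tOther\nsp1\t1\t\n")
#' count_groups(m)
read_count_matrix <- function(x) {
  text <- as_text_source(x, "count matrix")
  raw <- read_tsv_quiet(text, col_types = readr::cols(.default = readr::col_character()))
  # first column is the species id regardless of its header
  names(raw)[1] <- "species"
  num_cols <- setdiff(names(raw), "species")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(ifelse(is.na(raw[[col]]), "0", raw[[col]])))
    if (any(is.na(v)) || any(v < 0) || !all(is_whole(v))) {
      plg_validation_error(sprintf("column '%s' contains negative or non-integer counts", col))
    }
    raw[[col]] <- as.integer(round(v))
  }
  stated <- NULL
  if ("No." %in% names(raw)) {
    stated <- raw[["No."]]
    raw[["No."]] <- NULL
  }
  if (!"Other" %in% names(raw)) raw$Other <- 0L
  groups <- setdiff(names(raw), c("species", "Other"))
  raw <- raw[, c("species", groups, "Other")]
  if (!is.null(stated)) {
    totals <- rowSums(raw[, c(groups, "Other"), drop = FALSE])
    bad <- which(totals != stated)
    if (length(bad) > 0) {
      plg_validation_error(sprintf(
        "row total mismatch for species '%s': stated %d, computed %d",
        raw$species[bad[1]], stated[bad[1]], as.integer(totals[bad[1]])))
    }
  }
  new_count_matrix(raw, groups)
}

new_count_matrix <- function(tbl, groups = NULL) {
  tbl <- as_tibble(tbl)
  groups <- groups %||% setdiff(names(tbl), c("species", "Other"))
  structure(tbl, groups = groups,
            class = c("count_matrix", class(as_tibble(tbl))))
}

#' Coerce a data frame to a count matrix
#'
#' @param df a data frame with a `species` column and integer group columns;
#'   an `Other` column is added (all zero) if absent.
#' @param groups optional group ordering; defaults to the column order.
#' @return A `count_matrix`.
#' @export
as_count_matrix <- function(df, groups = NULL) {
  df <- as_tibble(df)
  if (!"species" %in% names(df)) plg_validation_error("need a 'species' column")
  if (!"Other" %in% names(df)) df$Other <- 0L
  num_cols <- setdiff(names(df), "species")
  for (col in num_cols) {
    v <- df[[col]]
    if (any(v < 0) || !all(is_whole(v))) {
      plg_validation_error(sprintf("column '%s' contains negative or non-integer counts", col))
    }
    df[[col]] <- as.integer(round(v))
  }
  groups <- groups %||% setdiff(names(df), c("species", "Other"))
  new_count_matrix(df[, c("species", groups, "Other")], groups)
}

#' Group columns of a count matrix (excluding `Other`)
#' @param m a `count_matrix`.
#' @return Character vector of group ids in matrix order.
#' @export
count_groups <- function(m) attr(m, "groups") %||% setdiff(names(m), c("species", "Other"))

#' Long (tidy) form of a count matrix
#'
#' @param m a `count_matrix`.
#' @param keep_other include the `Other` tally as a pseudo-group row?
#' @return A tibble with columns `species`, `group`, `count`.
#' @export
counts_long <- function(m, keep_other = FALSE) {
  cols <- count_groups(m)
  if (keep_other) cols <- c(cols, "Other")
  as_tibble(m)[, c("species", cols)] |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "group", values_to = "count")
}

#' Per-species totals of a count matrix
#' @param m a `count_matrix`.
#' @param include_other include the `Other` column in the total?
#' @return A tibble with columns `species` and `total`.
#' @export
count_totals <- function(m, include_other = TRUE) {
  cols <- count_groups(m)
  if (include_other) cols <- c(cols, "Other")
  tibble(species = m$species,
         total = as.integer(rowSums(as_tibble(m)[, cols, drop = FALSE])))
}

#' Write a count matrix as TSV
#' @param m a `count_matrix`.
#' @param path output file.
#' @param total_column append a `No.` column of row totals?
#' @return `m`, invisibly.
#' @export
write_count_matrix <- function(m, path, total_column = FALSE) {
  out <- as_tibble(m)
  if (total_column) out[["No."]] <- count_totals(m)$total
  readr::write_tsv(out, path, progress = FALSE)
  invisible(m)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d species x %d groups (+Other)\n",
              nrow(x), length(count_groups(x))))
  NextMethod()
}
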