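origin_levels <- c("pre_WGD", "WGD1", "WGD2", "tandem", "unconstrained")
cluster_levels <- c("TNF", "EDA", "FASL", "CD40L", "4-1BBL", "unassigned")

#' Read origin constraints for orthology groups
#'
#' An origin constraint pins the birth of an orthology group to a specific
#' event: one of the two ancestral whole-genome duplications (`WGD1`,
#' `WGD2`), the pre-WGD era (`pre_WGD`), or a tandem duplication of a named
#' parent group on a named branch (`tandem`).  Groups absent from the table
#' default to `unconstrained` and are placed by plain Dollo parsimony.
#'
#' Columns: `group`, `cluster`, `origin`, `parent_group`, `branch`,
#' `after_event`, `progenitor`, `quartet`, `paralogon`.  `progenitor`
#' labels the pre-WGD gene lineage a WGD-born group descends from;
#' `quartet` (defaulting to the progenitor) identifies the post-WGD1
#' lineage whose WGD2 ohnolog set may hold at most four members;
#' `paralogon` records the ancestral chromosome (`9`, `16` or `unknown`).
#' `after_event` orders a tandem duplication relative to a WGD on the same
#' branch (e.g. a tandem on the vertebrate stem *after* WGD2).
#'
#' @param x path to a TSV file, literal TSV text, or a data frame.
#' @param groups optional universe of known group ids; tandem parents may
#'   reference these even if they carry no constraint row themselves.
#' @return An `origin_constraints` tibble.
#' @export
read_constraints <- function(x, groups = NULL) {
  tbl <- if (is.data.frame(x)) as_tibble(x) else {
    read_tsv_quiet(as_text_source(x, "constraints"),
                   col_types = readr::cols(.default = readr::col_character()))
  }
  wanted <- c("group", "cluster", "origin", "parent_group", "branch",
              "after_event", "progenitor", "quartet", "paralogon")
  if (nrow(tbl) == 0 && !"group" %in% names(tbl)) tbl <- tibble(group = character())
  for (col in setdiff(wanted, names(tbl))) tbl[[col]] <- NA_character_
  tbl <- tbl[, wanted]
  tbl <- tbl |> mutate(across(all_of(wanted), as.character))
  tbl$cluster[is.na(tbl$cluster)] <- "unassigned"
  tbl$origin[is.na(tbl$origin)] <- "unconstrained"
  tbl$quartet <- ifelse(is.na(tbl$quartet), tbl$progenitor, tbl$quartet)
  tbl$paralogon[is.na(tbl$paralogon)] <- "unknown"
  validate_constraints(tbl, groups)
  structure(tbl, class = c("origin_constraints", class(as_tibble(tbl))))
}

validate_constraints <- function(tbl, groups = NULL) {
  if (anyDuplicated(tbl$group)) {
    plg_validation_error("constraint group ids must be unique")
  }
  bad <- setdiff(unique(tbl$origin), origin_levels)
  if (length(bad) > 0) {
    plg_validation_error(sprintf("unknown origin value(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$cluster), cluster_levels)
  if (length(bad) > 0) {
    plg_validation_error(sprintf("unknown cluster value(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$paralogon), c("9", "16", "unknown"))
  if (length(bad) > 0) {
    plg_validation_error(sprintf("paralogon must be 9, 16 or unknown; got %s",
                                 paste(bad, collapse = ", ")))
  }
  universe <- union(tbl$group, groups %||% character())
  tand <- tbl[tbl$origin == "tandem", ]
  if (nrow(tand) > 0) {
    if (any(is.na(tand$parent_group))) {
      plg_validation_error("tandem origins must name a parent_group")
    }
    dangling <- setdiff(tand$parent_group, universe)
    if (length(dangling) > 0) {
      plg_validation_error(sprintf("tandem parent group(s) not found: %s",
                                   paste(dangling, collapse = ", ")))
    }
    if (any(is.na(tand$branch))) {
      plg_validation_error("tandem origins must name a branch (child node)")
    }
  }
  wgd <- tbl[tbl$origin %in% c("WGD1", "WGD2"), ]
  if (any(is.na(wgd$progenitor))) {
    plg_validation_error("every WGD-originated group needs a progenitor id")
  }
  w2 <- wgd[wgd$origin == "WGD2" & !is.na(wgd$quartet), ]
  if (nrow(w2) > 0) {
    toomany <- table(w2$quartet)
    toomany <- names(toomany)[toomany > 4]
    if (length(toomany) > 0) {
      plg_validation_error(sprintf(
        "more than 4 WGD2 ohnologs in quartet(s): %s", paste(toomany, collapse = ", ")))
    }
  }
  invisible(tbl)
}

# Constraint row for one group, defaulting to unconstrained.
constraint_for <- function(constraints, group) {
  if (!is.null(constraints)) {
    hit <- as_tibble(constraints)[constraints$group == group, ]
    if (nrow(hit) == 1) return(hit)
  }
  tibble(group = group, cluster = "unassigned", origin = "unconstrained",
         parent_group = NA_character_, branch = NA_character_,
         after_event = NA_character_, progenitor = NA_character_,
         quartet = NA_character_, paralogon = "unknown")
}
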