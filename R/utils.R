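#' @importFrom rlang %||% .data
#' @importFrom dplyr arrange bind_rows count distinct filter group_by left_join
#'   mutate n pull rename row_number select summarise ungroup across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rpois runif setNames
#' @importFrom utils head tail
NULL

# Condition helpers: every user-facing failure is a classed condition so
# callers (and tests) can distinguish parse, validation, lookup, domain and
# infeasibility errors.
plg_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "paralogon_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

plg_parse_error <- function(msg) plg_abort(msg, "paralogon_parse_error")
plg_validation_error <- function(msg) plg_abort(msg, "paralogon_validation_error")
plg_lookup_error <- function(msg) plg_abort(msg, "paralogon_lookup_error")
plg_domain_error <- function(msg) plg_abort(msg, "paralogon_domain_error")
plg_infeasible_error <- function(msg) plg_abort(msg, "paralogon_infeasible_error")

# Accept either a file path or literal text for the text-format readers.
as_text_source <- function(x, what = "input") {
  if (!is.character(x) || length(x) != 1L) {
    plg_validation_error(sprintf("%s must be a single path or text string", what))
  }
  if (!grepl("\n", x) && !grepl("\t", x) && file.exists(x)) {
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  x
}

read_tsv_quiet <- function(text, ...) {
  readr::read_tsv(I(text), comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = c("", "NA"), ...)
}

is_whole <- function(x) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < 1e-8
}
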