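#' Run the full reconstruction pipeline from a flat configuration
#'
#' Orchestrates the stages (read inputs, optional simulation, event
#' reconstruction, conservation summary) and writes a self-describing run
#' directory: the configuration echoed with all defaults filled in, the
#' per-branch events and per-node repertoires as TSV, a machine-readable
#' `summary.json`, and a log of versions, seed and per-stage counts.
#' Identical inputs and seed produce a byte-identical `summary.json`.
#'
#' @param config a named list, or path to a flat `key = value` text file
#'   (`#` comments allowed).  Recognised keys: `species_tree`,
#'   `wgd_events`, `count_matrix`, `constraints` (file paths),
#'   `reference_species`, `seed`, `simulate` (`true`/`false`), and the
#'   [simulation_config()] fields when simulating.
#' @param out_dir output directory (created; defaults to `config$out_dir`
#'   or a `paralogon-run` folder under the session temp dir).
#' @return The summary list, invisibly, with attribute `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config) && length(config) == 1) {
    read_flat_config(config)
  } else if (is.list(config)) config
  else plg_validation_error("config must be a path or a named list")
  defaults <- list(reference_species = "Homo_sapiens", seed = 1L,
                   simulate = FALSE, constraints = NA_character_)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  out_dir <- out_dir %||% cfg$out_dir %||% file.path(tempdir(), "paralogon-run")
  # validate inputs before any stage runs
  if (is.null(cfg$species_tree)) plg_validation_error("config lacks 'species_tree'")
  paths <- c(species_tree = cfg$species_tree, wgd_events = cfg$wgd_events,
             count_matrix = if (!isTRUE(cfg$simulate)) cfg$count_matrix,
             constraints = if (!is.na(cfg$constraints)) cfg$constraints)
  missing <- paths[!is.na(paths) & !file.exists(paths)]
  if (length(missing) > 0) {
    plg_validation_error(sprintf("missing input file(s): %s",
                                 paste(missing, collapse = ", ")))
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$count_matrix)) {
    plg_validation_error("config lacks 'count_matrix' (and simulate is off)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("paralogon %s", as.character(utils::packageVersion("paralogon"))),
                 sprintf("seed: %s", cfg$seed))

  tree <- read_species_tree(cfg$species_tree, cfg$wgd_events)
  recovery <- NULL
  if (isTRUE(cfg$simulate)) {
    sim_cfg <- simulation_config(
      seed = as.integer(cfg$seed),
      wgd_retention_prob = as.numeric(cfg$wgd_retention_prob %||% 0.8),
      loss_rate = as.numeric(cfg$loss_rate %||% 0.05),
      tandem_rate = as.numeric(cfg$tandem_rate %||% 0.02),
      rearrangement_rate = as.numeric(cfg$rearrangement_rate %||% 0),
      support_noise = as.numeric(cfg$support_noise %||% 0),
      n_progenitors = as.integer(cfg$n_progenitors %||% 3L),
      genome_gene_count = as.integer(cfg$genome_gene_count %||% 20000L))
    sim <- simulate_history(sim_cfg, tree)
    matrix <- sim$matrix
    constraints <- sim$constraints
    log_lines <- c(log_lines, sprintf("simulated %d groups, %d leaf genes",
                                      nrow(sim$truth$origins),
                                      sum(count_totals(matrix)$total)))
  } else {
    matrix <- read_count_matrix(cfg$count_matrix)
    constraints <- if (!is.na(cfg$constraints)) read_constraints(cfg$constraints) else NULL
  }
  history <- infer_history(matrix, tree, constraints)
  log_lines <- c(log_lines, sprintf("reconstructed %d groups, %d events",
                                    nrow(history$origins), sum(history$events$n)))
  if (isTRUE(cfg$simulate)) {
    recovery <- recovery_report(sim$truth, history)
  }
  cons_sum <- conservation_summary(matrix, tree, cfg$reference_species)

  internal <- setdiff(tree_node_names(tree), tree_leaves(tree))
  anc_sizes <- lapply(setNames(internal, internal), function(nd) {
    nrow(ancestral_repertoire(history, nd))
  })
  losses <- history$events |> filter(.data$event == "loss") |>
    count(.data$branch, wt = NULL, name = "n_losses")
  per_branch_losses <- setNames(as.list(losses$n_losses), losses$branch)

  summary <- list(
    n_species = nrow(as_tibble(matrix)),
    n_groups = length(count_groups(matrix)),
    ancestral_repertoire_sizes = anc_sizes,
    per_branch_losses = per_branch_losses,
    progenitor_count = if (!is.null(constraints)) progenitor_count(history, constraints) else NULL,
    post_wgd_gene_count = post_wgd_gene_count(history, constraints),
    conservation = list(
      universal = as.list(cons_sum$universal),
      n_universal = length(cons_sum$universal),
      n_absent_in_reference = length(cons_sum$absent_in_reference),
      per_species_totals = setNames(as.list(cons_sum$per_species$n_genes),
                                    cons_sum$per_species$species)),
    recovery = if (!is.null(recovery)) as.list(recovery$summary) else NULL)
  summary <- summary[!vapply(summary, is.null, logical(1))]

  readr::write_tsv(history$events, file.path(out_dir, "events.tsv"), progress = FALSE)
  readr::write_tsv(history$repertoires, file.path(out_dir, "repertoires.tsv"),
                   progress = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(flat_config_lines(cfg), file.path(out_dir, "config.txt"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  attr(summary, "out_dir") <- out_dir
  invisible(summary)
}

read_flat_config <- function(path) {
  if (!file.exists(path)) plg_validation_error(sprintf("config file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) plg_validation_error(sprintf("malformed config line: '%s'", lines[bad][1]))
  vals <- lapply(kv, function(x) {
    v <- x[[2]]
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    v
  })
  setNames(vals, vapply(kv, function(x) x[[1]], character(1)))
}

flat_config_lines <- function(cfg) {
  vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.logical(v)) tolower(as.character(v)) else as.character(v))
  }, character(1))
}

#' Render a count matrix as a publication-style table
#'
#' Appends a `No.` column of per-species totals (groups plus `Other`) and
#' keeps the matrix's own group ordering.
#'
#' @param matrix a `count_matrix`.
#' @param format `"tibble"` (default) or `"markdown"` (a character vector
#'   of pipe-table lines, zeros shown as blanks).
#' @return A tibble, or a character vector for markdown.
#' @export
render_count_table <- function(matrix, format = c("tibble", "markdown")) {
  format <- match.arg(format)
  out <- as_tibble(matrix)
  out[["No."]] <- count_totals(matrix)$total
  if (format == "tibble") return(out)
  cells <- out
  for (col in setdiff(names(cells), "species")) {
    v <- as.character(cells[[col]])
    if (col != "No.") v[cells[[col]] == 0] <- ""
    cells[[col]] <- v
  }
  header <- paste0("| ", paste(names(cells), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(cells)), function(i) {
    paste0("| ", paste(unlist(cells[i, ]), collapse = " | "), " |")
  }, character(1))
  c(header, rule, rows)
}
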