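#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an event history into its per-branch event table
#'
#' @param x an `event_history`.
#' @param ... unused.
#' @return A tibble with columns `branch`, `group`, `event`, `n`.
#' @exportS3Method generics::tidy
tidy.event_history <- function(x, ...) x$events

#' One-row summary of an event history
#'
#' @param x an `event_history`.
#' @param ... unused.
#' @return A one-row tibble: group and event tallies plus the root
#'   repertoire size.
#' @exportS3Method generics::glance
glance.event_history <- function(x, ...) {
  ev <- x$events
  root <- tree_root(x$tree)
  tibble(n_groups = nrow(x$origins),
         n_origins = sum(ev$n[ev$event == "origin"]),
         n_losses = sum(ev$n[ev$event == "loss"]),
         n_copy_losses = sum(ev$n[ev$event == "copy_loss"]),
         n_duplications = sum(ev$n[ev$event == "tandem_duplication"]),
         n_wgd_retentions = sum(ev$n[ev$event == "wgd_retention"]),
         root_repertoire = nrow(ancestral_repertoire(x, root)))
}

#' @rdname tidy.event_history
#' @exportS3Method generics::tidy
tidy.conservation_summary <- function(x, ...) {
  bind_rows(
    tibble(category = "universal", group = x$universal),
    tibble(category = "shared_not_universal", group = x$shared_not_universal),
    tibble(category = "ingroup_only", group = x$ingroup_only),
    tibble(category = "outgroup_only", group = x$outgroup_only))
}

#' @rdname glance.event_history
#' @exportS3Method generics::glance
glance.conservation_summary <- function(x, ...) {
  tibble(n_groups = x$n_groups,
         n_universal = length(x$universal),
         n_shared_not_universal = length(x$shared_not_universal),
         n_ingroup_only = length(x$ingroup_only),
         n_outgroup_only = length(x$outgroup_only),
         n_absent_in_reference = length(x$absent_in_reference))
}

#' @rdname glance.event_history
#' @exportS3Method generics::glance
glance.recovery_report <- function(x, ...) x$summary

#' Plot per-branch event counts of an event history
#'
#' @param object an `event_history`.
#' @param ... unused.
#' @return A ggplot: stacked event counts per branch.
#' @exportS3Method ggplot2::autoplot
autoplot.event_history <- function(object, ...) {
  ev <- object$events |>
    group_by(.data$branch, .data$event) |>
    summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$branch, y = .data$n,
                                   fill = .data$event)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "events",
                  title = "Gene-family events per branch") +
    ggplot2::theme_minimal()
}

#' Heatmap of a species-by-group count matrix
#'
#' @param object a `count_matrix`.
#' @param ... unused.
#' @return A ggplot tile map of copy numbers.
#' @exportS3Method ggplot2::autoplot
autoplot.count_matrix <- function(object, ...) {
  long <- counts_long(object) |>
    mutate(species = factor(.data$species, levels = rev(object$species)),
           group = factor(.data$group, levels = count_groups(object)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$species,
                                     fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0, .data$count, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "copies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
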