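#' Tidy a concentration report
#'
#' @param x A `concentration_report` from [concentration_test()].
#' @param ... Unused.
#' @return Per-chromosome tibble with counts, expected fractions, and raw
#'   and Holm-adjusted p-values.
#' @method tidy concentration_report
#' @export
tidy.concentration_report <- function(x, ...) {
  x$table
}

#' @rdname tidy.concentration_report
#' @return `glance()` returns a one-row tibble with the totals, the
#'   fraction of unassigned markers, and the number of chromosomes
#'   significant after adjustment.
#' @method glance concentration_report
#' @export
glance.concentration_report <- function(x, ...) {
  tibble(
    n_markers = x$n_markers, n_assigned = x$n_assigned,
    fraction_unassigned = x$fraction_unassigned,
    n_significant = if (x$tested) {
      sum(x$table$p_adjusted < x$alpha, na.rm = TRUE)
    } else NA_integer_,
    alpha = x$alpha, tested = x$tested
  )
}

#' Plot observed versus expected marker counts per chromosome
#'
#' @param object A `concentration_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concentration_report
#' @export
autoplot.concentration_report <- function(object, ...) {
  df <- object$table %>%
    mutate(expected = .data$expected_frac * object$n_assigned,
           significant = !is.na(.data$p_adjusted) &
             .data$p_adjusted < object$alpha)
  ggplot(df, aes(x = .data$chromosome)) +
    geom_col(aes(y = .data$n_assigned, fill = .data$significant)) +
    geom_point(aes(y = .data$expected), shape = 95, size = 8) +
    scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                      guide = "none") +
    labs(x = NULL, y = "assigned markers",
         title = "Marker concentration by chromosome",
         subtitle = "dashes: expectation proportional to chromosome length") +
    theme_minimal()
}

#' Tidy a gene-tree result
#'
#' @param x A `gene_tree_result` from [build_gene_tree()].
#' @param ... Unused.
#' @return Tip-level tibble (label, species, allele class).
#' @method tidy gene_tree_result
#' @export
tidy.gene_tree_result <- function(x, ...) {
  x$labels
}

#' @rdname tidy.gene_tree_result
#' @method glance gene_tree_result
#' @export
glance.gene_tree_result <- function(x, ...) {
  tibble(
    classification = x$classification,
    method = x$method,
    n_tips = length(x$tree$tip.label),
    n_species = n_distinct(x$labels$species_id),
    y_clade_support = x$detail$y_clade_support,
    min_species_support = suppressWarnings(min(x$detail$species_supports)),
    support_threshold = x$support_threshold
  )
}

#' Plot a classified gene tree
#'
#' Base-graphics phylogram with tips coloured by allele class and bootstrap
#' supports as node labels.
#'
#' @param x A `gene_tree_result`.
#' @param ... Passed to `ape::plot.phylo`.
#' @export
plot.gene_tree_result <- function(x, ...) {
  cls <- setNames(x$labels$allele_class, x$labels$label)
  col <- c(X = "firebrick", Y = "steelblue", unphased = "grey40")
  ape::plot.phylo(x$tree,
                  tip.color = col[cls[x$tree$tip.label]], ...)
  if (!is.null(x$tree$node.label)) {
    ape::nodelabels(x$tree$node.label, frame = "none", cex = 0.7,
                    adj = c(1.2, -0.3))
  }
  invisible(x)
}

#' Tidy a parsimony fit
#'
#' @param x A `parsimony_fit` from [fitch_min_changes()].
#' @param ... Unused.
#' @return Tibble of mandatory-change branches.
#' @method tidy parsimony_fit
#' @export
tidy.parsimony_fit <- function(x, ...) {
  x$change_branches
}

#' @rdname tidy.parsimony_fit
#' @method glance parsimony_fit
#' @export
glance.parsimony_fit <- function(x, ...) {
  tibble(
    min_changes = x$min_changes,
    n_mandatory_branches = nrow(x$change_branches),
    n_possible_branches = nrow(x$possible_branches),
    n_states = length(x$states),
    n_tips = length(x$tree$tip.label)
  )
}

#' Plot tip states and inferred changes on the tree
#'
#' @param x A `parsimony_fit`.
#' @param ... Passed to `ape::plot.phylo`.
#' @export
plot.parsimony_fit <- function(x, ...) {
  states <- x$tip_states[x$tree$tip.label]
  pal <- setNames(
    grDevices::hcl.colors(max(2, length(x$states)), "Dark 3")[
      seq_along(x$states)],
    x$states
  )
  ape::plot.phylo(x$tree, tip.color = pal[states], ...)
  if (nrow(x$change_branches)) {
    ape::edgelabels(
      "*",
      which(x$tree$edge[, 2] %in% x$change_branches$node),
      frame = "circle", bg = "gold"
    )
  }
  invisible(x)
}
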