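#' Lineages-through-time plot
#'
#' Step plot of the number of lineages extant at each time horizon,
#' optionally within a clade.
#'
#' @param dtree A `dated_tree` or `genealogy`.
#' @param clade Optional internal node restricting the count.
#' @return A ggplot.
#' @export
plot_ltt <- function(dtree, clade = NULL) {
  phy <- tree_phylo(dtree)
  root_age <- if (is.null(clade)) dtree$ages[length(phy$tip.label) + 1L]
              else dtree$ages[clade]
  times <- sort(unique(c(0, dtree$ages[dtree$ages <= root_age], root_age)))
  df <- tibble(
    time = times,
    lineages = vapply(times, function(t)
      lineages_through_time(dtree, t, clade), integer(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$lineages)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Years before present", y = "Lineages") +
    ggplot2::theme_minimal()
}

#' Plot a mutation tree
#'
#' Thin wrapper over [ape::plot.phylo()] with mutation-count edge lengths.
#'
#' @param x A `mutation_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.mutation_tree <- function(x, ...) {
  ape::plot.phylo(x$phy, ...)
  invisible(x)
}
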