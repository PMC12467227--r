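## ggplot2 views of the pipeline's result tables.

tier_palette <- c(H = "#b5651d", M = "#1b5e20", L = "#8bc34a",
                  P = "#d2b48c", ABS = "white")

arch_palette <- c(both = "#e6c229", TORC1_only = "#1f8a8a",
                  TORC2_only = "#c0392b", neither = "#9e9e9e")

#' Heat-map of detection tiers (species x component)
#'
#' @param tiers Tier tibble from [call_tiers()].
#' @return A ggplot object.
#' @export
plot_tier_matrix <- function(tiers) {
  ggplot2::ggplot(tiers, ggplot2::aes(
    x = factor(.data$component, TORC_COMPONENTS),
    y = .data$species, fill = factor(.data$tier, TIER_LEVELS))) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = tier_palette, name = "tier",
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked architecture composition per clade
#'
#' @param summary Output of [architecture_proportions()].
#' @return A ggplot object.
#' @export
plot_architecture_proportions <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$clade, y = .data$prop,
    fill = factor(.data$architecture, ARCHITECTURE_LEVELS))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = arch_palette, name = "architecture") +
    ggplot2::labs(x = NULL, y = "proportion of species") +
    ggplot2::theme_minimal()
}

#' Stacked trophic-strategy composition by architecture class
#'
#' @param summary Output of [strategy_by_architecture()].
#' @return A ggplot object.
#' @export
plot_strategy_composition <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = factor(.data$architecture, ARCHITECTURE_LEVELS),
    y = .data$prop, fill = .data$strategy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of species") +
    ggplot2::theme_minimal()
}

## simple cladogram layout: tips evenly spaced, internal nodes at child mean
tree_layout <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- children_of(tree)
  root <- root_of(tree)
  y <- rep(NA_real_, ntip + tree$Nnode)
  y[seq_len(ntip)] <- seq_len(ntip)
  depth <- rep(0, ntip + tree$Nnode)
  fill <- function(v, d) {
    depth[v] <<- d
    for (w in ch[[v]]) fill(w, d + 1)
    if (length(ch[[v]])) y[v] <<- mean(y[ch[[v]]])
  }
  fill(root, 0)
  maxd <- max(depth)
  x <- ifelse(seq_along(y) <= ntip, maxd, depth)
  list(x = x, y = y, depth = depth, root = root, ch = ch)
}

#' Plot a Dollo reconstruction as an annotated cladogram
#'
#' Nodes are coloured by reconstructed state; loss edges are drawn in red.
#'
#' @param object A `dollo_loss` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dollo_loss
#' @export
autoplot.dollo_loss <- function(object, ...) {
  tr <- object$tree
  lay <- tree_layout(tr)
  labs <- node_labels(tr)
  seg <- purrr::map(seq_len(nrow(tr$edge)), function(k) {
    a <- tr$edge[k, 1]; b <- tr$edge[k, 2]
    tibble(x = lay$depth[a], xend = lay$x[b], y = lay$y[a], yend = lay$y[b],
           loss = labs[b] %in% object$loss_edges)
  }) |> bind_rows()
  nodes <- tibble(x = lay$x, y = lay$y, label = labs,
                  state = unname(object$node_state),
                  is_tip = seq_along(labs) <= length(tr$tip.label))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg, ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend,
      colour = .data$loss), linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#c0392b"),
                                 name = "loss edge") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(
      x = .data$x, y = .data$y, shape = .data$state), size = 2) +
    ggplot2::scale_shape_manual(values = c(present = 16, absent = 1)) +
    ggplot2::geom_text(data = nodes[nodes$is_tip, ], ggplot2::aes(
      x = .data$x + 0.1, y = .data$y, label = .data$label), hjust = 0,
      size = 3) +
    ggplot2::expand_limits(x = max(lay$x) + 1.5) +
    ggplot2::labs(title = sprintf("%s: %d independent loss event(s)",
                                  object$trait, object$n_losses),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}
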