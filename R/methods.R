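#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a supported tree into an edge table
#'
#' @param x A `gh2_tree`.
#' @param ... Unused.
#' @return Tibble with one row per edge: `parent`, `child`, `length`,
#'   `support` (`NA` on terminal and root edges), `is_tip`, `label`.
#' @export
tidy.gh2_tree <- function(x, ...) {
  phy <- x$phylo
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  support <- rep(NA_real_, length(child))
  support[child > ntip] <- x$supports[child[child > ntip] - ntip]
  label <- rep(NA_character_, length(child))
  label[child <= ntip] <- phy$tip.label[child[child <= ntip]]
  tibble(
    parent = phy$edge[, 1], child = child,
    length = if (!is.null(phy$edge.length)) phy$edge.length else NA_real_,
    support = support,
    is_tip = child <= ntip,
    label = label
  )
}

#' One-row tree summary
#'
#' @param x A `gh2_tree`.
#' @param ... Unused.
#' @return Tibble: tip count, internal edges, mean/min support, replicates.
#' @export
glance.gh2_tree <- function(x, ...) {
  s <- x$supports[!is.na(x$supports)]
  tibble(n_tips = length(x$phylo$tip.label),
         n_internal_edges = sum(x$phylo$edge[, 2] >
                                  length(x$phylo$tip.label)),
         mean_support = if (length(s)) mean(s) else NA_real_,
         min_support = if (length(s)) min(s) else NA_real_,
         n_replicates = x$meta$n_replicates %||% NA_integer_)
}

#' Tidy a concordance report
#'
#' @param x A `gh2_concordance`.
#' @param ... Unused.
#' @return The per-label tibble.
#' @export
tidy.gh2_concordance <- function(x, ...) x$per_label

#' One-row concordance summary
#'
#' @param x A `gh2_concordance`.
#' @param ... Unused.
#' @return Tibble: label count, monophyletic labels, mean purity.
#' @export
glance.gh2_concordance <- function(x, ...) {
  tibble(n_labels = nrow(x$per_label),
         n_monophyletic = sum(x$per_label$monophyletic),
         mean_purity = mean(x$per_label$purity))
}

#' Plot a supported tree
#'
#' Simple rectangular layout with edges drawn as segments, tips labeled,
#' internal edges colored by bootstrap support.
#'
#' @param object A `gh2_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gh2_tree <- function(object, ...) {
  phy <- object$phylo
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  depth <- numeric(nn)
  po <- ape::reorder.phylo(phy, "postorder")
  # preorder depths
  for (k in rev(seq_len(nrow(po$edge)))) {
    depth[po$edge[k, 2]] <- depth[po$edge[k, 1]] +
      (po$edge.length[k] %||% 1)
  }
  y <- numeric(nn)
  y[seq_len(ntip)] <- seq_len(ntip)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    kids <- po$edge[po$edge[, 1] == p, 2]
    y[p] <- mean(y[kids])
  }
  ed <- tidy(object)
  seg <- ed |>
    mutate(x = depth[.data$parent], xend = depth[.data$child],
           yy = y[.data$child], y_parent = y[.data$parent])
  tips <- tibble(x = depth[seq_len(ntip)], y = y[seq_len(ntip)],
                 label = phy$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$yy, yend = .data$yy,
                                       color = .data$support)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$y_parent, yend = .data$yy,
                                       color = .data$support)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 2.5) +
    ggplot2::scale_color_gradient(low = "grey80", high = "black",
                                  na.value = "steelblue",
                                  limits = c(0, 1), name = "support") +
    ggplot2::expand_limits(x = max(depth) * 1.15) +
    ggplot2::theme_void()
}

#' Plot DA-type counts
#'
#' @param object A `gh2_calls` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of sequences per DA type.
#' @export
autoplot.gh2_calls <- function(object, ...) {
  tally_da_types(as_tibble(object), drop_rejected = FALSE) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$da_type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "DA type", y = "sequences") +
    ggplot2::theme_minimal()
}

#' Plot an active-site conservation profile
#'
#' Per-anchor identity percentage colored by band, faceting the full set
#' against the designated subset when present.
#'
#' @param object A `gh2_conservation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gh2_conservation <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::any_of(c("percent", "subset_percent",
                                        "rest_percent")),
                        names_to = "scope", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$value, fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$scope) +
    ggplot2::scale_fill_manual(values = c("100" = "#08306b",
                                          ">=50" = "#6baed6",
                                          "<50" = "grey70")) +
    ggplot2::labs(x = "reference position", y = "% identity") +
    ggplot2::theme_minimal()
}
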