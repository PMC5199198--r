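#' Tidy a pipeline result
#'
#' One row per proteome: id, species group, status and semicolon-joined
#' representatives.
#'
#' @param x A `prm_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.prm_result <- function(x, ...) {
  out <- x$statuses
  out$representatives <- vapply(out$representatives,
                                function(r) paste(r, collapse = ";"),
                                character(1))
  tibble::as_tibble(out)
}

#' Summarize a pipeline result
#'
#' @param x A `prm_result`.
#' @param ... Unused.
#' @return A one-row tibble: proteome, group, comparison and edge counts,
#'   and the redundant/non-redundant split.
#' @export
glance.prm_result <- function(x, ...) {
  tibble::tibble(
    n_proteomes = nrow(x$statuses),
    n_groups = length(x$graphs),
    n_comparisons = nrow(x$comparisons),
    n_performed = sum(x$comparisons$performed),
    n_edges = sum(vapply(x$graphs, function(g) nrow(g$edges), integer(1))),
    n_non_redundant = sum(x$statuses$status == "non-redundant"),
    n_redundant = sum(x$statuses$status == "redundant")
  )
}

#' Tidy a graph reduction
#'
#' @param x A `prm_reduction`.
#' @param ... Unused.
#' @return A tibble with `proteome_id`, `status` and semicolon-joined
#'   `representatives`.
#' @export
tidy.prm_reduction <- function(x, ...) {
  ids <- c(x$surviving, x$removed)
  tibble::tibble(
    proteome_id = ids,
    status = ifelse(ids %in% x$surviving, "non-redundant", "redundant"),
    representatives = vapply(ids, function(id) {
      if (id %in% x$surviving) ""
      else paste(x$surviving_neighbours[[id]], collapse = ";")
    }, character(1))
  )[order(ids), ]
}

#' Summarize a graph reduction
#'
#' @param x A `prm_reduction`.
#' @param ... Unused.
#' @return A one-row tibble with surviving/removed/protected counts.
#' @export
glance.prm_reduction <- function(x, ...) {
  tibble::tibble(
    n_surviving = length(x$surviving),
    n_removed = length(x$removed),
    n_protected = length(x$protected),
    seed = x$seed
  )
}

#' Plot status counts per species group
#'
#' Stacked bars of redundant vs non-redundant proteomes in each species
#' group — the at-a-glance view of how much each group collapsed.
#'
#' @param object A `prm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prm_result <- function(object, ...) {
  d <- dplyr::count(object$statuses, .data$species_group_id, .data$status)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species_group_id,
                                  y = .data$n, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c("non-redundant" = "#2c7fb8", "redundant" = "#bdbdbd")) +
    ggplot2::labs(x = "species group", y = "proteomes", fill = NULL,
                  title = "Proteome redundancy by species group") +
    ggplot2::theme_minimal()
}

#' Plot a redundancy graph
#'
#' Nodes are proteomes, arrows point from a redundant proteome to the
#' proteome it is redundant to. When a reduction is supplied, survivors are
#' highlighted. Uses igraph's Fruchterman-Reingold layout when igraph is
#' available, otherwise a circular layout.
#'
#' @param object A `redundancy_graph`.
#' @param reduction Optional `prm_reduction` used to colour survivors.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.redundancy_graph <- function(object, reduction = NULL, ...) {
  ids <- object$nodes$proteome_id
  if (requireNamespace("igraph", quietly = TRUE) && nrow(object$edges) > 0) {
    g <- igraph::graph_from_data_frame(
      object$edges[, c("from", "to")], directed = TRUE,
      vertices = data.frame(name = ids))
    xy <- igraph::layout_with_fr(g)
    rownames(xy) <- igraph::V(g)$name
    xy <- xy[ids, , drop = FALSE]
  } else {
    theta <- seq(0, 2 * pi, length.out = length(ids) + 1)[seq_along(ids)]
    xy <- cbind(cos(theta), sin(theta))
    rownames(xy) <- ids
  }
  nodes <- tibble::tibble(proteome_id = ids, x = xy[, 1], y = xy[, 2])
  nodes$status <- if (is.null(reduction)) "proteome" else {
    ifelse(ids %in% reduction$surviving, "non-redundant", "redundant")
  }
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, ids)]
  edges$y <- nodes$y[match(edges$from, ids)]
  edges$xend <- nodes$x[match(edges$to, ids)]
  edges$yend <- nodes$y[match(edges$to, ids)]
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey60")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$status), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$proteome_id),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, title = "Redundancy graph")
}
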