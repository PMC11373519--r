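# simple layered layout: y = time (or topological depth), x = samples evenly
# spaced, ancestors at the mean x of the nodes inheriting from them
garg_layout <- function(g) {
  ord <- node_order(g)
  depth <- stats::setNames(rep(0, length(ord)), ord)
  for (u in ord) {
    pa <- g$edges$parent[g$edges$child == u]
    for (p in pa) {
      depth[as.character(p)] <- max(depth[as.character(p)],
                                    depth[as.character(u)] + 1)
    }
  }
  y <- g$nodes$time
  if (any(is.na(y))) y <- unname(depth[as.character(g$nodes$id)])
  x <- rep(NA_real_, nrow(g$nodes))
  names(x) <- g$nodes$id
  leaves <- ord[!ord %in% g$edges$parent]
  x[as.character(leaves)] <- seq_along(leaves)
  for (u in ord) {
    if (is.na(x[as.character(u)])) {
      ch <- g$edges$child[g$edges$parent == u]
      x[as.character(u)] <- mean(x[as.character(unique(ch))], na.rm = TRUE)
    }
  }
  x[is.na(x)] <- seq_len(sum(is.na(x))) + max(x, na.rm = TRUE)
  tibble::tibble(id = g$nodes$id, x = unname(x[as.character(g$nodes$id)]),
                 y = y)
}

#' Plot a gARG
#'
#' Draws the inheritance graph with nodes positioned by time (pastwards up)
#' and edges labelled, via line width, by the genomic span they transmit.
#'
#' @param object A [garg()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(example_garg_pedigree())
#' @exportS3Method ggplot2::autoplot
autoplot.garg <- function(object, ...) {
  lay <- garg_layout(object)
  e <- dplyr::group_by(object$edges, .data$child, .data$parent)
  e <- dplyr::summarise(e, span = sum(.data$right - .data$left),
                        .groups = "drop")
  seg <- tibble::tibble(
    x = lay$x[match(e$child, lay$id)], y = lay$y[match(e$child, lay$id)],
    xend = lay$x[match(e$parent, lay$id)],
    yend = lay$y[match(e$parent, lay$id)],
    span = e$span)
  lab <- ifelse(is.na(object$nodes$metadata), as.character(object$nodes$id),
                sub("\\s.*", "", object$nodes$metadata))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$span),
      colour = "grey55") +
    ggplot2::scale_linewidth(range = c(0.2, 1.6),
                             name = "genomic span") +
    ggplot2::geom_point(
      data = cbind(lay, sample = object$nodes$is_sample),
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$sample),
      size = 6, colour = "white") +
    ggplot2::geom_text(
      data = cbind(lay, label = lab),
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 15, `FALSE` = 16),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "time (pastwards)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot the local trees of a gARG along the genome
#'
#' One panel per breakpoint region, each showing the sample-restricted local
#' tree with locally unary nodes suppressed.
#'
#' @param g A [garg()].
#' @param suppress_unary Passed to [local_trees()].
#' @return A ggplot object.
#' @examples
#' plot_local_trees(example_garg_pedigree())
#' @export
plot_local_trees <- function(g, suppress_unary = TRUE) {
  lt <- local_trees(g, suppress_unary = suppress_unary)
  forests <- attr(lt, "forests")
  rows <- list()
  for (f in forests) {
    lay <- forest_layout(f)
    lab <- ifelse(is.na(g$nodes$metadata[match(lay$id, g$nodes$id)]),
                  as.character(lay$id),
                  sub("\\s.*", "", g$nodes$metadata[match(lay$id, g$nodes$id)]))
    region <- sprintf("[%g,%g)", f$left, f$right)
    p <- f$parent_of[as.character(lay$id)]
    rows[[length(rows) + 1]] <- tibble::tibble(
      region = region, id = lay$id, x = lay$x, y = lay$y, label = lab,
      px = lay$x[match(p, lay$id)], py = lay$y[match(p, lay$id)])
  }
  d <- dplyr::bind_rows(rows)
  d$region <- factor(d$region, levels = unique(d$region))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$px,
                   yend = .data$py),
      na.rm = TRUE, colour = "grey55") +
    ggplot2::geom_label(
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3, label.size = 0) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

forest_layout <- function(f) {
  ids <- f$nodes
  depth <- stats::setNames(rep(0, length(ids)), ids)
  # depth = distance above leaves
  repeat {
    changed <- FALSE
    for (u in ids) {
      p <- f$parent_of[as.character(u)]
      if (!is.na(p) && depth[as.character(p)] < depth[as.character(u)] + 1) {
        depth[as.character(p)] <- depth[as.character(u)] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  leaves <- ids[!ids %in% f$parent_of]
  x <- stats::setNames(rep(NA_real_, length(ids)), ids)
  x[as.character(sort(leaves))] <- seq_along(leaves)
  for (d in sort(unique(depth[depth > 0]))) {
    for (u in ids[depth[as.character(ids)] == d]) {
      ch <- ids[!is.na(f$parent_of[as.character(ids)]) &
                  f$parent_of[as.character(ids)] == u]
      if (length(ch) > 0) x[as.character(u)] <- mean(x[as.character(ch)],
                                                     na.rm = TRUE)
    }
  }
  x[is.na(x)] <- seq_len(sum(is.na(x)))
  tibble::tibble(id = ids, x = unname(x[as.character(ids)]),
                 y = unname(depth[as.character(ids)]))
}
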