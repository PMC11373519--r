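# -- segment bookkeeping -----------------------------------------------------

# Decompose possibly-overlapping weighted segments (left, right, count) into
# disjoint cells with summed counts, merging adjacent cells of equal count.
flatten_counts <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(fast_tbl(left = numeric(), right = numeric(), count = integer()))
  }
  cuts <- sort(unique(c(df$left, df$right)))
  l <- cuts[-length(cuts)]
  r <- cuts[-1]
  cnt <- vapply(seq_along(l), function(i) {
    sum(df$count[df$left <= l[i] & df$right >= r[i]])
  }, numeric(1))
  keep <- cnt > 0
  l <- l[keep]; r <- r[keep]; cnt <- cnt[keep]
  if (length(l) > 1) {   # merge adjacent equal-count cells
    brk <- c(TRUE, !(l[-1] == r[-length(r)] & cnt[-1] == cnt[-length(cnt)]))
    grp <- factor(cumsum(brk), levels = unique(cumsum(brk)))
    l <- as.numeric(tapply(l, grp, min))
    r <- as.numeric(tapply(r, grp, max))
    cnt <- as.numeric(tapply(cnt, grp, function(x) x[1]))
  }
  fast_tbl(left = as.numeric(l), right = as.numeric(r),
           count = as.integer(cnt))
}

# clip weighted segments against one interval [cl, cr)
clip_counts <- function(seg, cl, cr) {
  l <- pmax(seg$left, cl)
  r <- pmin(seg$right, cr)
  keep <- l < r
  fast_tbl(left = l[keep], right = r[keep], count = seg$count[keep])
}

# Hudson-style pastward propagation of ancestral material.
#
# Processes nodes children-first (time order when dated). Each sample seeds
# one segment [0, L) x 1. At every node the arriving segments are merged
# (counts add, since each sample inherits each position along a single
# path). When stop_at_mrca is TRUE, positions at which all samples have
# coalesced at or below the node are recorded at the node but not propagated
# to its parents — this is the convention under which structure above each
# position's full coalescence carries no tracked material.
propagate_material <- function(g, samples = g$samples, stop_at_mrca = FALSE) {
  samples <- sort(unique(as.integer(samples)))
  if (!all(samples %in% g$nodes$id)) {
    stop("samples must be node ids present in the graph", call. = FALSE)
  }
  n <- length(samples)
  ord <- node_order(g)
  incoming <- new.env(parent = emptyenv())
  push <- function(id, seg) {
    key <- as.character(id)
    cur <- incoming[[key]]
    incoming[[key]] <- if (is.null(cur)) list(seg) else c(cur, list(seg))
  }
  edges_by_child <- split(seq_len(nrow(g$edges)), g$edges$child)

  node_segs <- vector("list", length(ord))
  names(node_segs) <- as.character(ord)
  res_rows <- list()

  for (u in ord) {
    key <- as.character(u)
    arriving <- incoming[[key]]
    arriving <- if (is.null(arriving)) list() else arriving
    if (u %in% samples) {
      arriving <- c(arriving, list(fast_tbl(
        left = 0, right = g$sequence_length, count = 1L)))
    }
    seg <- flatten_counts(dplyr::bind_rows(arriving))
    node_segs[[key]] <- seg
    if (nrow(seg) == 0) next
    out <- if (stop_at_mrca) seg[seg$count < n, , drop = FALSE] else seg
    if (nrow(out) == 0) next
    for (i in edges_by_child[[key]] %||% integer(0)) {
      piece <- clip_counts(out, g$edges$left[i], g$edges$right[i])
      if (nrow(piece) == 0) next
      push(g$edges$parent[i], piece)
      res_rows[[length(res_rows) + 1]] <-
        fast_tbl(child = rep(g$edges$child[i], nrow(piece)),
                 parent = rep(g$edges$parent[i], nrow(piece)),
                 left = piece$left, right = piece$right)
    }
  }

  segments <- dplyr::bind_rows(lapply(names(node_segs), function(k) {
    s <- node_segs[[k]]
    if (is.null(s) || nrow(s) == 0) return(NULL)
    fast_tbl(node = rep(as.integer(k), nrow(s)), left = s$left,
             right = s$right, sample_count = s$count)
  }))
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- tibble::tibble(node = integer(), left = numeric(),
                               right = numeric(), sample_count = integer())
  }
  resolved <- if (length(res_rows) > 0) dplyr::bind_rows(res_rows) else
    tibble::tibble(child = integer(), parent = integer(),
                   left = numeric(), right = numeric())
  list(segments = segments[order(segments$node, segments$left), ],
       resolved_edges = resolved, n_samples = n)
}

#' Ancestral material of a sample set
#'
#' Computes, for every node, the genomic intervals through which at least
#' one of the given samples inherits, together with the number of samples
#' whose ancestry passes through the node there (`sample_count`). Segments
#' are propagated pastwards from the samples and merged at each node,
#' processing nodes in time (or topological) order.
#'
#' With `stop_at_mrca = TRUE`, a position is not propagated above the node
#' at which all samples have coalesced: ancestry of entirely coalesced
#' regions is omitted, as in Hudson-style simulation bookkeeping. The
#' default (`FALSE`) is the plain definition, under which the material also
#' covers ancestors above the position's MRCA.
#'
#' @param g A valid [garg()].
#' @param samples Node ids (default: the graph's sample set).
#' @param stop_at_mrca Stop tracking a position above its full coalescence
#'   (default `FALSE`).
#' @return A tibble `node`, `left`, `right`, `sample_count` (disjoint rows
#'   per node; `1 <= sample_count <= length(samples)`). Nodes carrying no
#'   ancestral material are absent.
#' @examples
#' am <- ancestral_material(example_garg_pedigree())
#' # in [2,7) nodes F, G, H (ids 6-8) carry material; E (id 5) is blank
#' subset(am, node %in% 5:8 & left < 7 & right > 2)
#' @export
ancestral_material <- function(g, samples = g$samples, stop_at_mrca = FALSE) {
  propagate_material(g, samples, stop_at_mrca = stop_at_mrca)$segments
}

#' Resolve a gARG with respect to a sample set
#'
#' Produces the sample-resolved gARG: every edge's inheritance intervals are
#' intersected with the ancestral material its child propagates, so the
#' annotations contain no nonancestral material; positions are not tracked
#' above their full coalescence, so structure ancestral to every local root
#' is dropped as well. Edges left empty are removed, and nodes left with no
#' edges (other than samples) are removed. The samples' local genealogies
#' are unchanged at every position.
#'
#' @inheritParams ancestral_material
#' @return A [garg()] with the same node ids (a subset) and updated edges.
#' @examples
#' g <- earg_to_garg(example_earg_trapped())
#' r <- garg_resolve(g)
#' setdiff(g$nodes$id, r$nodes$id)  # the grand MRCA is gone
#' @export
garg_resolve <- function(g, samples = g$samples) {
  pr <- propagate_material(g, samples, stop_at_mrca = TRUE)
  e <- pr$resolved_edges
  keep_nodes <- union(unique(c(e$child, e$parent)), samples)
  nodes <- g$nodes[g$nodes$id %in% keep_nodes, ]
  garg(nodes = nodes, edges = e, sequence_length = g$sequence_length,
       samples = intersect(samples, nodes$id))
}

#' Coalescence span of every node
#'
#' The coalescence span of a node is the fraction of the genome over which
#' it is *locally coalescent*: at least two distinct child edges carry
#' ancestral material of the samples there. Nodes with span strictly
#' between 0 and 1 are coalescent in some local trees and unary in others.
#'
#' @inheritParams ancestral_material
#' @return A tibble `node`, `span` (fraction of `L` in `[0, 1]`, one row per
#'   node of `g`). The coalescent intervals themselves are attached as
#'   attribute `"intervals"` (tibble `node`, `left`, `right`).
#' @examples
#' cs <- coalescence_span(example_garg_pedigree())
#' subset(cs, node == 6)  # node F: coalescent over [2,7), span 0.5
#' @export
coalescence_span <- function(g, samples = g$samples) {
  pr <- propagate_material(g, samples, stop_at_mrca = TRUE)
  e <- pr$resolved_edges
  span <- numeric(nrow(g$nodes))
  ivs <- list()
  by_parent <- split(seq_len(nrow(e)), e$parent)
  for (i in seq_along(g$nodes$id)) {
    u <- g$nodes$id[i]
    idx <- by_parent[[as.character(u)]]
    if (is.null(idx)) next
    # the resolved segments of any one child edge are disjoint, so the
    # per-position row coverage counts distinct child edges directly
    fl <- flatten_counts(fast_tbl(left = e$left[idx], right = e$right[idx],
                                  count = rep(1L, length(idx))))
    co <- fl[fl$count >= 2, , drop = FALSE]
    if (nrow(co) > 0) {
      co <- interval_canonical(co[c("left", "right")])
      span[i] <- sum(co$right - co$left) / g$sequence_length
      ivs[[length(ivs) + 1]] <- tibble::tibble(node = u, left = co$left,
                                               right = co$right)
    }
  }
  out <- tibble::tibble(node = g$nodes$id, span = span)
  attr(out, "intervals") <- if (length(ivs) > 0) dplyr::bind_rows(ivs) else
    tibble::tibble(node = integer(), left = numeric(), right = numeric())
  out
}

#' Simplification options
#'
#' The simplification ladder applies, in order of increasing strength:
#' (a) sample resolution (always on); (b) removal of singly connected path
#' bundles — non-sample nodes with exactly one local child and one local
#' parent at every position they cover, such as the interior of "diamonds";
#' (c) removal of nodes that never represent a coalescence (unary
#' everywhere), reconnecting children to grandparents; (d) region-by-region
#' bypassing of locally unary nodes, so surviving nodes appear in a local
#' tree only where coalescent ("fully simplified").
#'
#' @param level Convenience name: one of `"resolve"`, `"prune-diamonds"`,
#'   `"prune-unary"`, `"full"`; overrides the individual flags.
#' @param remove_singly_connected,remove_everywhere_unary,bypass_locally_unary
#'   Individual flags; `bypass_locally_unary` implies
#'   `remove_everywhere_unary`.
#' @return A list of class `simplify_options`.
#' @export
simplify_options <- function(level = NULL,
                             remove_singly_connected = FALSE,
                             remove_everywhere_unary = FALSE,
                             bypass_locally_unary = FALSE) {
  if (!is.null(level)) {
    level <- match.arg(level,
                       c("resolve", "prune-diamonds", "prune-unary", "full"))
    remove_singly_connected <- level != "resolve"
    remove_everywhere_unary <- level %in% c("prune-unary", "full")
    bypass_locally_unary <- level == "full"
  }
  if (bypass_locally_unary) remove_everywhere_unary <- TRUE
  structure(list(remove_nonancestral = TRUE,
                 remove_singly_connected = remove_singly_connected,
                 remove_everywhere_unary = remove_everywhere_unary,
                 bypass_locally_unary = bypass_locally_unary),
            class = "simplify_options")
}

# splice nodes out of g: each node's child edges are reconnected to its
# parents over the intersection of intervals; portions of a child edge not
# covered by any parent edge are dropped (the child becomes a local root
# there). Nodes are processed sequentially on a plain data frame so a chain
# of removals costs one graph rebuild.
splice_nodes <- function(g, us) {
  e <- as.data.frame(g$edges)
  for (u in us) {
    is_ch <- e$parent == u
    is_pa <- e$child == u
    ch <- e[is_ch, , drop = FALSE]
    pa <- e[is_pa, , drop = FALSE]
    e <- e[!is_ch & !is_pa, , drop = FALSE]
    if (nrow(ch) == 0 || nrow(pa) == 0) next
    grid <- expand.grid(i = seq_len(nrow(ch)), j = seq_len(nrow(pa)))
    l <- pmax(ch$left[grid$i], pa$left[grid$j])
    r <- pmin(ch$right[grid$i], pa$right[grid$j])
    keep <- l < r
    if (any(keep)) {
      e <- rbind(e, data.frame(child = ch$child[grid$i][keep],
                               parent = pa$parent[grid$j][keep],
                               left = l[keep], right = r[keep]))
    }
  }
  nodes <- g$nodes[!g$nodes$id %in% us, ]
  garg(nodes = nodes, edges = e, sequence_length = g$sequence_length,
       samples = setdiff(g$samples, us))
}

# non-sample nodes with exactly one local child and one local parent at
# every covered position (the singly connected class)
singly_connected_nodes <- function(g) {
  out <- integer(0)
  for (u in setdiff(g$nodes$id, g$samples)) {
    ch <- g$edges[g$edges$parent == u, , drop = FALSE]
    pa <- g$edges[g$edges$child == u, , drop = FALSE]
    if (nrow(ch) == 0 || nrow(pa) == 0) next
    chf <- flatten_counts(tibble::tibble(left = ch$left, right = ch$right,
                                         count = 1L))
    if (any(chf$count != 1)) next
    ch_set <- interval_canonical(chf[c("left", "right")])
    pa_set <- interval_canonical(pa[c("left", "right")])
    if (nrow(interval_subtract(ch_set, pa_set)) > 0) next
    if (nrow(interval_subtract(pa_set, ch_set)) > 0) next
    out <- c(out, u)
  }
  out
}

# non-sample nodes that are never locally coalescent
everywhere_unary_nodes <- function(g, samples) {
  cs <- coalescence_span(g, samples)
  has_child <- cs$node %in% g$edges$parent
  cs$node[cs$span == 0 & has_child & !cs$node %in% samples]
}

#' Simplify a gARG
#'
#' Applies sample resolution followed by the optional pruning levels of
#' [simplify_options()]. At every level the samples' local genealogies
#' (their pairwise MRCAs and coalescent structure at each position) are
#' preserved; node and edge counts are non-increasing with option strength.
#' Node ids of the result are reassigned densely in processing order
#' (samples first); `node_map` records the correspondence.
#'
#' @inheritParams ancestral_material
#' @param options A [simplify_options()] object, or a level name
#'   (`"resolve"`, `"prune-diamonds"`, `"prune-unary"`, `"full"`).
#' @return An object of class `garg_simplify`: list with `graph` (the
#'   simplified [garg()]), `node_map` (tibble `old_id`, `new_id`) and
#'   `coalescent_span` (tibble `node`, `left`, `right` over new ids, the
#'   intervals where each surviving node has two or more children carrying
#'   ancestral material).
#' @examples
#' s <- garg_simplify(example_garg_pedigree(), options = "full")
#' s$graph
#' s$node_map
#' @export
garg_simplify <- function(g, samples = g$samples, options = "resolve") {
  if (is.character(options)) options <- simplify_options(level = options)
  stopifnot(inherits(options, "simplify_options"))
  samples <- sort(unique(as.integer(samples)))
  h <- garg_resolve(g, samples)

  if (options$remove_singly_connected) {
    repeat {
      cand <- singly_connected_nodes(h)
      if (length(cand) == 0) break
      h <- splice_nodes(h, cand)
    }
  }
  if (options$remove_everywhere_unary) {
    repeat {
      cand <- everywhere_unary_nodes(h, samples)
      if (length(cand) == 0) break
      h <- splice_nodes(h, cand)
    }
  }
  if (options$bypass_locally_unary) {
    lt <- local_trees(h, suppress_unary = TRUE, samples = samples)
    e <- lt[!is.na(lt$parent), c("node", "parent", "left", "right")]
    names(e)[1] <- "child"
    keep <- union(unique(c(e$child, e$parent)), samples)
    h <- garg(nodes = h$nodes[h$nodes$id %in% keep, ], edges = e,
              sequence_length = h$sequence_length, samples = samples)
  }

  # dense renumbering in processing order: samples first, then by time/id
  ord <- node_order(h)
  ord <- c(intersect(ord, samples), setdiff(ord, samples))
  node_map <- tibble::tibble(old_id = ord, new_id = seq_along(ord))
  relabel <- function(x) node_map$new_id[match(x, node_map$old_id)]
  nodes <- h$nodes
  nodes$id <- relabel(nodes$id)
  edges <- h$edges
  edges$child <- relabel(edges$child)
  edges$parent <- relabel(edges$parent)
  out <- garg(nodes = nodes, edges = edges,
              sequence_length = h$sequence_length,
              samples = relabel(intersect(samples, h$nodes$id)))
  cs <- coalescence_span(out)
  structure(list(graph = out, node_map = node_map,
                 coalescent_span = attr(cs, "intervals"),
                 options = options),
            class = "garg_simplify")
}

#' @export
print.garg_simplify <- function(x, ...) {
  cat("<garg_simplify>\n")
  print(x$graph)
  cat(sprintf("  node_map: %d nodes retained\n", nrow(x$node_map)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.garg_simplify <- function(x, ...) {
  x$node_map
}

#' @exportS3Method generics::glance
glance.garg_simplify <- function(x, ...) {
  garg_stats(x$graph)
}
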