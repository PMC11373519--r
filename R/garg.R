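#' Construct a genome ARG (gARG)
#'
#' A gARG is a directed acyclic graph in which nodes are haploid genomes and
#' each edge records that a child genome inherited a set of genomic intervals
#' from a parent genome. This single annotation is enough to express any form
#' of homologous recombination (multiple crossovers, gene conversion, ...),
#' without modelling the events themselves.
#'
#' @param nodes A data frame with columns `id` (integer, unique), and
#'   optionally `time` (numeric, larger values are further in the past; `NA`
#'   when unknown), `is_sample` (logical or 0/1) and `metadata` (character,
#'   free-form; the shipped examples store letter labels here).
#' @param edges A data frame with columns `child`, `parent` (node ids) and
#'   either long-format columns `left`, `right` (one row per interval) or an
#'   `intervals` character column using the `"l1,r1;l2,r2"` serialization.
#' @param sequence_length Genome length `L`; all intervals must lie in
#'   `[0, L)`.
#' @param samples Integer vector of sample node ids. Defaults to the nodes
#'   flagged by `is_sample`.
#'
#' @return An object of class `garg`: a list with elements `sequence_length`
#'   (numeric), `nodes` (tibble `id`, `time`, `is_sample`, `metadata`),
#'   `edges` (tibble `child`, `parent`, `left`, `right`, canonical and sorted)
#'   and `samples` (integer vector).
#' @seealso [garg_validate()], [local_trees()], [garg_resolve()],
#'   [example_garg_pedigree()]
#' @examples
#' g <- garg(
#'   nodes = data.frame(id = 1:3, time = c(0, 0, 1),
#'                      is_sample = c(TRUE, TRUE, FALSE)),
#'   edges = data.frame(child = c(1, 2), parent = c(3, 3),
#'                      left = c(0, 0), right = c(10, 10)),
#'   sequence_length = 10
#' )
#' garg_breakpoints(g)
#' @export
garg <- function(nodes, edges, sequence_length, samples = NULL) {
  stopifnot(is.numeric(sequence_length), length(sequence_length) == 1,
            sequence_length > 0)
  nodes <- as_node_table(nodes)
  edges <- as_edge_table(edges)
  if (is.null(samples)) {
    samples <- nodes$id[nodes$is_sample]
  }
  samples <- sort(unique(as.integer(samples)))
  nodes$is_sample <- nodes$id %in% samples
  g <- structure(
    list(sequence_length = as.numeric(sequence_length),
         nodes = nodes, edges = edges, samples = samples),
    class = "garg"
  )
  g$edges <- canonical_edges(g$edges, nodes)
  g
}

as_node_table <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (!"id" %in% names(nodes)) stop("node table needs an 'id' column",
                                    call. = FALSE)
  if (!"time" %in% names(nodes)) nodes$time <- NA_real_
  if (!"is_sample" %in% names(nodes)) nodes$is_sample <- FALSE
  if (!"metadata" %in% names(nodes)) nodes$metadata <- NA_character_
  tibble::tibble(id = as.integer(nodes$id),
                 time = as.numeric(nodes$time),
                 is_sample = as.logical(as.integer(as.logical(nodes$is_sample))),
                 metadata = as.character(nodes$metadata))
}

as_edge_table <- function(edges) {
  edges <- tibble::as_tibble(edges)
  need <- c("child", "parent")
  if (!all(need %in% names(edges))) {
    stop("edge table needs 'child' and 'parent' columns", call. = FALSE)
  }
  if ("intervals" %in% names(edges) && !"left" %in% names(edges)) {
    sets <- lapply(seq_len(nrow(edges)), function(i) {
      s <- parse_interval_set(edges$intervals[i],
                              where = sprintf("edge %d->%d", edges$child[i],
                                              edges$parent[i]))
      tibble::tibble(child = edges$child[i], parent = edges$parent[i],
                     left = s$left, right = s$right)
    })
    edges <- dplyr::bind_rows(sets)
  }
  if (!all(c("left", "right") %in% names(edges))) {
    stop("edge table needs 'left'/'right' (or 'intervals') columns",
         call. = FALSE)
  }
  tibble::tibble(child = as.integer(edges$child),
                 parent = as.integer(edges$parent),
                 left = as.numeric(edges$left),
                 right = as.numeric(edges$right))
}

# merge intervals per (child, parent) and apply the canonical sort:
# (child time if present, child id, parent id, left endpoint)
canonical_edges <- function(edges, nodes) {
  if (nrow(edges) == 0) return(edges)
  edges <- edges |>
    dplyr::group_by(.data$child, .data$parent) |>
    dplyr::reframe(interval_canonical(dplyr::pick("left", "right")))
  ct <- nodes$time[match(edges$child, nodes$id)]
  key <- order(ifelse(is.na(ct), Inf, ct), edges$child, edges$parent,
               edges$left)
  edges[key, ]
}

#' @export
print.garg <- function(x, ...) {
  cat(sprintf("<garg> L = %g, %d nodes (%d samples), %d edges, %d intervals\n",
              x$sequence_length, nrow(x$nodes), length(x$samples),
              nrow(dplyr::distinct(x$edges, .data$child, .data$parent)),
              nrow(x$edges)))
  invisible(x)
}

#' Validate a gARG
#'
#' Checks the whole-graph invariants of the gARG data model and returns a
#' table of violations rather than throwing: unique node ids, samples and
#' edge endpoints referring to known nodes, `child != parent`, intervals
#' non-empty and bounded by `[0, L)`, acyclicity of the child-to-parent
#' relation (by node time when times are present on both ends of an edge,
#' and by topological sort overall), and *per-child functional inheritance*:
#' at any genome position a child inherits from at most one parent.
#'
#' @param g A [garg()] object (arbitrary tables are accepted; malformed
#'   content yields violations, not errors).
#' @return A tibble with columns `kind` (invariant violated), `ids`
#'   (offending node/edge ids, comma-separated) and `message`. Zero rows
#'   means the graph is valid.
#' @examples
#' garg_validate(example_garg_pedigree())  # 0 rows
#' @export
garg_validate <- function(g) {
  v <- list()
  add <- function(kind, ids, message) {
    v[[length(v) + 1]] <<- tibble::tibble(kind = kind,
                                          ids = paste(ids, collapse = ","),
                                          message = message)
  }
  nodes <- g$nodes
  edges <- g$edges
  L <- g$sequence_length

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    add("duplicate_node_id", unique(dup), "node ids must be unique")
  }
  missing_samples <- setdiff(g$samples, nodes$id)
  if (length(missing_samples) > 0) {
    add("unknown_sample", missing_samples, "sample ids not in node table")
  }
  unknown <- setdiff(unique(c(edges$child, edges$parent)), nodes$id)
  if (length(unknown) > 0) {
    add("unknown_edge_node", unknown, "edge endpoint not in node table")
  }
  self <- edges$child == edges$parent
  if (any(self)) {
    add("self_edge", unique(edges$child[self]), "edge with child == parent")
  }
  bad_iv <- !(edges$left < edges$right) | edges$left < 0 | edges$right > L
  if (any(bad_iv)) {
    add("bad_interval",
        unique(paste0(edges$child[bad_iv], "->", edges$parent[bad_iv])),
        sprintf("edge intervals must satisfy 0 <= left < right <= %g", L))
  }

  # time ordering on edges where both ends are dated
  tc <- nodes$time[match(edges$child, nodes$id)]
  tp <- nodes$time[match(edges$parent, nodes$id)]
  dated <- !is.na(tc) & !is.na(tp)
  bad_t <- dated & tc >= tp
  if (any(bad_t)) {
    add("time_order",
        unique(paste0(edges$child[bad_t], "->", edges$parent[bad_t])),
        "time(child) must be strictly less than time(parent)")
  }

  # acyclicity of the child->parent relation
  ok_nodes <- unique(nodes$id)
  e_ok <- edges[edges$child %in% ok_nodes & edges$parent %in% ok_nodes &
                  edges$child != edges$parent, ]
  ord <- topo_order(ok_nodes, e_ok$child, e_ok$parent)
  if (is.null(ord)) {
    add("cycle", character(0), "child->parent relation contains a cycle")
  }

  # per-child functional inheritance
  for (c_id in unique(edges$child)) {
    ivs <- edges[edges$child == c_id & edges$left < edges$right, ]
    if (nrow(ivs) < 2) next
    o <- order(ivs$left, ivs$right)
    l <- ivs$left[o]; r <- ivs$right[o]
    ov <- which(l[-1] < r[-length(r)])
    if (length(ov) > 0) {
      rng <- sprintf("[%g,%g)", l[ov + 1][1], min(r[ov][1], r[ov + 1][1]))
      add("multiple_parents", c_id,
          sprintf("child %d inherits from more than one parent over %s",
                  c_id, rng))
    }
  }

  if (length(v) == 0) {
    tibble::tibble(kind = character(), ids = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# Kahn's algorithm with smallest-id tie-break; edges point child -> parent so
# the returned order lists children before their parents (youngest first).
# A node is ready once all edges arriving from its children are consumed.
# Returns NULL when a cycle is present.
topo_order <- function(ids, child, parent) {
  ids <- sort(unique(ids))
  n <- length(ids)
  keep <- !duplicated(paste(child, parent))  # parallel edges count once
  child <- child[keep]; parent <- parent[keep]
  remaining <- tabulate(match(parent, ids), nbins = n)
  pars <- split(match(parent, ids), match(child, ids))
  ready <- ids[remaining == 0]
  out <- integer(0)
  while (length(ready) > 0) {
    u <- ready[1]
    ready <- ready[-1]
    out <- c(out, u)
    for (p in pars[[as.character(match(u, ids))]] %||% integer(0)) {
      remaining[p] <- remaining[p] - 1
      if (remaining[p] == 0) ready <- sort(c(ready, ids[p]))
    }
  }
  if (length(out) < n) NULL else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic processing order, children before parents: by time when all
# nodes are dated (ties and undated fall back to topological rank), id breaks
# remaining ties
node_order <- function(g) {
  ord <- topo_order(g$nodes$id, g$edges$child, g$edges$parent)
  if (is.null(ord)) stop("graph contains a cycle", call. = FALSE)
  rank_topo <- match(g$nodes$id, ord)
  t <- g$nodes$time
  if (all(!is.na(t))) {
    g$nodes$id[order(t, rank_topo, g$nodes$id)]
  } else {
    g$nodes$id[order(rank_topo, g$nodes$id)]
  }
}

#' Genome positions at which the local genealogy can change
#'
#' Returns the sorted union of `{0, L}` with every interval endpoint on any
#' edge. Consecutive positions delimit the regions within which the
#' child-to-parent mapping — and hence the local tree — is constant.
#'
#' @param g A valid [garg()].
#' @return Sorted numeric vector of positions, starting at 0 and ending at
#'   `L`.
#' @examples
#' garg_breakpoints(example_garg_pedigree())  # 0 2 7 10
#' @export
garg_breakpoints <- function(g) {
  sort(unique(c(0, g$sequence_length, g$edges$left, g$edges$right)))
}

#' @exportS3Method generics::tidy
tidy.garg <- function(x, ...) {
  lab <- x$nodes$metadata[match(x$edges$child, x$nodes$id)]
  plab <- x$nodes$metadata[match(x$edges$parent, x$nodes$id)]
  tibble::tibble(child = x$edges$child, parent = x$edges$parent,
                 left = x$edges$left, right = x$edges$right,
                 child_label = lab, parent_label = plab)
}

#' @exportS3Method generics::glance
glance.garg <- function(x, ...) {
  garg_stats(x)
}
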