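#' Construct an event ARG (eARG)
#'
#' The classical ARG encoding: internal nodes are historical *events* rather
#' than genomes. Common-ancestor nodes merge lineages; recombination nodes
#' split a lineage in two and carry a crossover breakpoint. Because the
#' breakpoint alone does not say which parent transmits the left-hand side,
#' every out-edge of a recombination node carries an explicit side label.
#'
#' @param nodes A data frame with columns `id` (integer), `kind` (one of
#'   `"sample"`, `"common_ancestor"`, `"recombination"`), `breakpoint`
#'   (numeric, required exactly when `kind == "recombination"`, strictly
#'   inside `(0, L)`), and optionally `time` and `metadata`.
#' @param edges A data frame with columns `child`, `parent` and `side`
#'   (`"L"`/`"R"` for the two out-edges of a recombination child, `"-"`
#'   otherwise).
#' @param sequence_length Genome length `L`.
#' @param samples Sample node ids; defaults to nodes with `kind == "sample"`.
#' @return An object of class `earg`: list with `sequence_length`, `nodes`,
#'   `edges` tibbles and `samples`.
#' @seealso [earg_validate()], [earg_to_garg()], [earg_tree_at()]
#' @export
earg <- function(nodes, edges, sequence_length, samples = NULL) {
  stopifnot(is.numeric(sequence_length), length(sequence_length) == 1,
            sequence_length > 0)
  nodes <- tibble::as_tibble(nodes)
  if (!"time" %in% names(nodes)) nodes$time <- NA_real_
  if (!"breakpoint" %in% names(nodes)) nodes$breakpoint <- NA_real_
  if (!"metadata" %in% names(nodes)) nodes$metadata <- NA_character_
  nodes <- tibble::tibble(id = as.integer(nodes$id),
                          kind = as.character(nodes$kind),
                          breakpoint = as.numeric(nodes$breakpoint),
                          time = as.numeric(nodes$time),
                          metadata = as.character(nodes$metadata))
  edges <- tibble::as_tibble(edges)
  if (!"side" %in% names(edges)) edges$side <- "-"
  edges <- tibble::tibble(child = as.integer(edges$child),
                          parent = as.integer(edges$parent),
                          side = as.character(edges$side))
  if (is.null(samples)) samples <- nodes$id[nodes$kind == "sample"]
  structure(
    list(sequence_length = as.numeric(sequence_length), nodes = nodes,
         edges = edges[order(edges$child, edges$parent, edges$side), ],
         samples = sort(unique(as.integer(samples)))),
    class = "earg"
  )
}

#' @export
print.earg <- function(x, ...) {
  cat(sprintf(
    "<earg> L = %g, %d nodes (%d samples, %d recombination), %d edges\n",
    x$sequence_length, nrow(x$nodes), length(x$samples),
    sum(x$nodes$kind == "recombination"), nrow(x$edges)))
  invisible(x)
}

#' Validate an eARG
#'
#' Checks the event-graph invariants: known node kinds; breakpoints present
#' exactly on recombination nodes and strictly inside `(0, L)`; side labels
#' `L`/`R` exactly on the out-edges of recombination nodes, with the two
#' sides distinct; each recombination node has exactly 2 parents; each
#' common-ancestor node has at least 2 children and at most 1 parent;
#' acyclicity. Multiple parentless internal nodes produce a `warning`-kind
#' row (the grand MRCA is usually unique, but this is not enforced).
#'
#' @param e An [earg()] object.
#' @return A tibble of violations (`kind`, `ids`, `message`); zero rows
#'   (ignoring `kind == "warning"` rows) means valid.
#' @export
earg_validate <- function(e) {
  v <- list()
  add <- function(kind, ids, message) {
    v[[length(v) + 1]] <<- tibble::tibble(kind = kind,
                                          ids = paste(ids, collapse = ","),
                                          message = message)
  }
  nodes <- e$nodes
  edges <- e$edges
  L <- e$sequence_length

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) add("duplicate_node_id", unique(dup),
                           "node ids must be unique")
  bad_kind <- !nodes$kind %in% c("sample", "common_ancestor", "recombination")
  if (any(bad_kind)) add("unknown_kind", nodes$id[bad_kind],
                         "kind must be sample/common_ancestor/recombination")
  rec <- nodes$id[nodes$kind == "recombination"]
  bp <- nodes$breakpoint[match(rec, nodes$id)]
  bad_bp <- is.na(bp) | bp <= 0 | bp >= L
  if (any(bad_bp)) add("bad_breakpoint", rec[bad_bp],
                       sprintf("breakpoint must lie strictly inside (0,%g)", L))
  stray <- nodes$kind != "recombination" & !is.na(nodes$breakpoint)
  if (any(stray)) add("stray_breakpoint", nodes$id[stray],
                      "only recombination nodes carry a breakpoint")

  unknown <- setdiff(unique(c(edges$child, edges$parent)), nodes$id)
  if (length(unknown) > 0) add("unknown_edge_node", unknown,
                               "edge endpoint not in node table")

  kind_of <- function(id) nodes$kind[match(id, nodes$id)]
  is_rec_child <- kind_of(edges$child) == "recombination"
  bad_side <- (is_rec_child & !edges$side %in% c("L", "R")) |
    (!is_rec_child & edges$side != "-") %in% TRUE
  bad_side[is.na(bad_side)] <- FALSE
  if (any(bad_side)) {
    add("bad_side", unique(edges$child[bad_side]),
        "side must be L/R exactly for out-edges of recombination nodes")
  }

  for (r in rec) {
    out <- edges[edges$child == r, ]
    if (nrow(out) != 2) {
      add("recombination_parents", r,
          sprintf("recombination node %d has %d parents (expected 2)",
                  r, nrow(out)))
    } else if (length(unique(out$side)) != 2 ||
               !setequal(out$side, c("L", "R"))) {
      add("side_uniqueness", r,
          sprintf("the two out-edges of recombination node %d must carry distinct sides L and R", r))
    }
  }
  for (ca in nodes$id[nodes$kind == "common_ancestor"]) {
    nch <- sum(edges$parent == ca)
    npar <- sum(edges$child == ca)
    if (nch < 2) add("common_ancestor_children", ca,
                     sprintf("common-ancestor node %d has %d children (expected >= 2)", ca, nch))
    if (npar > 1) add("common_ancestor_parents", ca,
                      sprintf("common-ancestor node %d has %d parents (expected <= 1)", ca, npar))
  }

  internal <- nodes$id[nodes$kind != "sample"]
  parentless <- internal[!internal %in% edges$child]
  if (length(parentless) > 1) {
    add("warning", parentless,
        "more than one parentless internal node (multiple grand MRCA candidates)")
  }

  if (is.null(topo_order(nodes$id, edges$child, edges$parent))) {
    add("cycle", character(0), "child->parent relation contains a cycle")
  }

  if (length(v) == 0) {
    tibble::tibble(kind = character(), ids = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

earg_assert_valid <- function(e) {
  rep <- earg_validate(e)
  rep <- rep[rep$kind != "warning", ]
  if (nrow(rep) > 0) {
    stop(sprintf("invalid eARG: %s", rep$message[1]), call. = FALSE)
  }
  invisible(e)
}

#' Convert an eARG to a gARG
#'
#' Duplicates the node set and topology and attaches inheritance intervals:
#' the single out-edge of a sample or common-ancestor node is annotated
#' `[0, L)`; the two out-edges of a recombination node with breakpoint `x`
#' are annotated `[0, x)` (left side) and `[x, L)` (right side). The
#' conversion is one-to-one with the information in the eARG; the result is
#' a valid gARG whose per-position genealogy equals the classical
#' breakpoint-based traversal ([earg_tree_at()]).
#'
#' @param e A valid [earg()].
#' @return A [garg()] with the same node ids, times, metadata and samples.
#' @examples
#' g <- earg_to_garg(example_earg_recombination())
#' garg_breakpoints(g)
#' @export
earg_to_garg <- function(e) {
  earg_assert_valid(e)
  L <- e$sequence_length
  kind <- e$nodes$kind[match(e$edges$child, e$nodes$id)]
  bp <- e$nodes$breakpoint[match(e$edges$child, e$nodes$id)]
  left <- ifelse(kind == "recombination" & e$edges$side == "R", bp, 0)
  right <- ifelse(kind == "recombination" & e$edges$side == "L", bp, L)
  garg(
    nodes = tibble::tibble(id = e$nodes$id, time = e$nodes$time,
                           is_sample = e$nodes$id %in% e$samples,
                           metadata = e$nodes$metadata),
    edges = tibble::tibble(child = e$edges$child, parent = e$edges$parent,
                           left = left, right = right),
    sequence_length = L,
    samples = e$samples
  )
}

#' Local tree of an eARG by breakpoint traversal
#'
#' Recovers the genealogy at position `x` directly from the event encoding,
#' by tracing pastwards from each sample and, at every recombination node
#' with breakpoint `b`, following the left parent when `x < b` and the right
#' parent otherwise (a position equal to the breakpoint belongs to the
#' right-hand interval `[b, L)`). This is the classical construction and is
#' used as an independent oracle for [earg_to_garg()] conversion.
#'
#' @param e A valid [earg()].
#' @param x Genome position, `0 <= x < L`.
#' @return A `local_forest` (see [tree_at()]) over the nodes on the samples'
#'   pastward paths at `x`.
#' @export
earg_tree_at <- function(e, x) {
  earg_assert_valid(e)
  stopifnot(x >= 0, x < e$sequence_length)
  parent_of <- integer(0)
  visit <- function(u) {
    while (!as.character(u) %in% names(parent_of)) {
      out <- e$edges[e$edges$child == u, ]
      if (nrow(out) == 0) {
        parent_of[as.character(u)] <<- NA_integer_
        break
      }
      kind <- e$nodes$kind[match(u, e$nodes$id)]
      if (kind == "recombination") {
        b <- e$nodes$breakpoint[match(u, e$nodes$id)]
        side <- if (x < b) "L" else "R"
        p <- out$parent[out$side == side]
      } else {
        p <- out$parent[1]
      }
      parent_of[as.character(u)] <<- p
      u <- p
    }
  }
  for (s in e$samples) visit(s)
  bps <- sort(unique(c(0, e$sequence_length,
                       e$nodes$breakpoint[!is.na(e$nodes$breakpoint)])))
  i <- findInterval(x, bps)
  new_local_forest(bps[i], bps[i + 1], parent_of)
}
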