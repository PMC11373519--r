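new_local_forest <- function(left, right, parent_of) {
  ids <- suppressWarnings(as.integer(names(parent_of)))
  o <- order(ids)
  parent_of <- parent_of[o]
  structure(list(left = left, right = right,
                 parent_of = parent_of,
                 nodes = ids[o]),
            class = "local_forest")
}

#' @export
print.local_forest <- function(x, ...) {
  roots <- x$nodes[is.na(x$parent_of)]
  cat(sprintf("<local_forest> region [%g,%g), %d nodes, %d root(s)\n",
              x$left, x$right, length(x$nodes), length(roots)))
  invisible(x)
}

#' @export
format.local_forest <- function(x, ...) {
  paste(forest_newick(x), collapse = " ")
}

forest_equal <- function(a, b) {
  identical(a$nodes, b$nodes) &&
    identical(unname(a$parent_of), unname(b$parent_of))
}

# iteratively drop non-sample leaves that subtend no sample, then splice
# non-sample nodes with exactly one child (re-attaching the child to the
# grandparent, or making it a root); sample nodes are never touched
suppress_unary_map <- function(parent_of, samples) {
  repeat {
    ids <- as.integer(names(parent_of))
    kids <- table(factor(parent_of[!is.na(parent_of)], levels = ids))
    nch <- as.integer(kids)
    names(nch) <- ids
    drop <- ids[nch == 0 & !ids %in% samples]
    if (length(drop) > 0) {
      parent_of <- parent_of[!ids %in% drop]
      next
    }
    unary <- ids[nch == 1 & !ids %in% samples]
    if (length(unary) == 0) break
    u <- unary[1]
    child <- as.integer(names(parent_of)[which(parent_of == u)])
    parent_of[as.character(child)] <- parent_of[as.character(u)]
    parent_of <- parent_of[names(parent_of) != as.character(u)]
  }
  parent_of
}

# restrict a parent map to nodes pastward-reachable from the samples; a
# sample with no covering edge is kept as an isolated local root
restrict_to_samples_map <- function(parent_of, samples) {
  for (s in samples) {
    if (!as.character(s) %in% names(parent_of)) {
      parent_of[as.character(s)] <- NA_integer_
    }
  }
  keep <- character(0)
  for (s in samples) {
    u <- as.character(s)
    while (u %in% names(parent_of) && !u %in% keep) {
      keep <- c(keep, u)
      p <- parent_of[[u]]
      if (is.na(p)) break
      u <- as.character(p)
    }
  }
  parent_of[names(parent_of) %in% keep]
}

#' Local tree (forest) at a single genome position
#'
#' Restricts the gARG to the edges whose inheritance intervals contain `x`:
#' each node's local parent is the unique parent from which it inherits at
#' that position. Regions of the genome where the samples have not fully
#' coalesced within the graph yield a forest with several local roots; no
#' virtual super-root is invented.
#'
#' With `suppress_unary = TRUE` the forest is reduced to the conventional
#' depiction: it is restricted to the ancestry of the samples and nodes that
#' are *locally unary* (exactly one child at this position) are bypassed, so
#' only samples and local coalescences remain.
#'
#' @param g A valid [garg()].
#' @param x Genome position, `0 <= x < L`.
#' @param suppress_unary Bypass locally-unary non-sample nodes
#'   (default `FALSE`).
#' @param samples Optional node ids; when given, the forest is restricted to
#'   nodes on the pastward paths of these samples (always implied by
#'   `suppress_unary`, using the graph's sample set unless overridden).
#' @return A `local_forest`: list with `left`/`right` (the enclosing
#'   breakpoint region), `parent_of` (named integer vector, `NA` for local
#'   roots) and `nodes`.
#' @examples
#' f <- tree_at(example_garg_pedigree(), 4)
#' f$parent_of[c("1", "3")]  # A and C share parent F in [2,7)
#' @export
tree_at <- function(g, x, suppress_unary = FALSE, samples = NULL) {
  stopifnot(x >= 0, x < g$sequence_length)
  covers <- g$edges$left <= x & x < g$edges$right
  e <- g$edges[covers, ]
  present <- unique(c(e$child, e$parent))
  parent_of <- rep(NA_integer_, length(present))
  names(parent_of) <- present
  parent_of[as.character(e$child)] <- e$parent
  if (suppress_unary && is.null(samples)) samples <- g$samples
  if (!is.null(samples)) {
    parent_of <- restrict_to_samples_map(parent_of, samples)
  }
  if (suppress_unary) {
    parent_of <- suppress_unary_map(parent_of, samples)
  }
  bps <- garg_breakpoints(g)
  i <- findInterval(x, bps)
  new_local_forest(bps[i], bps[i + 1], parent_of)
}

#' Local trees along the genome
#'
#' Recovers the full sequence of local trees with a single left-to-right
#' sweep: edge fragments are inserted and removed at breakpoints while an
#' active child-to-parent mapping is maintained, rather than rebuilding each
#' region independently. The regions tile `[0, L)` exactly.
#'
#' @inheritParams tree_at
#' @return A tibble with one row per (region, node): columns `tree` (region
#'   index), `left`, `right`, `node`, `parent` (`NA` for a local root). The
#'   list of `local_forest` objects is attached as attribute `"forests"`.
#' @examples
#' local_trees(example_garg_pedigree(), suppress_unary = TRUE)
#' @export
local_trees <- function(g, suppress_unary = FALSE, samples = NULL) {
  bps <- garg_breakpoints(g)
  nregion <- length(bps) - 1
  # every interval endpoint is a breakpoint, so each edge row is inserted
  # once at its left end and removed once at its right end
  frag <- g$edges
  ins <- split(seq_len(nrow(frag)), factor(frag$left, levels = bps))
  rem <- split(seq_len(nrow(frag)), factor(frag$right, levels = bps))

  active_parent <- integer(0)  # named by child id
  forests <- vector("list", nregion)
  rows <- vector("list", nregion)
  if (suppress_unary && is.null(samples)) samples <- g$samples
  for (r in seq_len(nregion)) {
    out_idx <- rem[[as.character(bps[r])]] %||% integer(0)
    in_idx <- ins[[as.character(bps[r])]] %||% integer(0)
    for (i in out_idx) {
      active_parent <- active_parent[names(active_parent) !=
                                       as.character(frag$child[i])]
    }
    for (i in in_idx) {
      active_parent[as.character(frag$child[i])] <- frag$parent[i]
    }
    # nodes present: endpoints of active edges
    present <- unique(c(as.integer(names(active_parent)),
                        unname(active_parent)))
    parent_of <- rep(NA_integer_, length(present))
    names(parent_of) <- present
    parent_of[names(active_parent)] <- active_parent
    if (!is.null(samples)) {
      parent_of <- restrict_to_samples_map(parent_of, samples)
    }
    if (suppress_unary) {
      parent_of <- suppress_unary_map(parent_of, samples)
    }
    f <- new_local_forest(bps[r], bps[r + 1], parent_of)
    forests[[r]] <- f
    rows[[r]] <- tibble::tibble(tree = r, left = f$left, right = f$right,
                                node = f$nodes, parent = unname(f$parent_of))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "forests") <- forests
  out
}

#' Number of distinct local trees
#'
#' Counts maximal runs of adjacent breakpoint regions whose local forests
#' (after restriction to the samples' ancestry and suppression of locally
#' unary nodes) are identical as child-to-parent mappings — node identity is
#' shared across local trees, so two regions count as one tree only when the
#' same nodes are connected the same way.
#'
#' @inheritParams tree_at
#' @return An integer count.
#' @examples
#' count_distinct_trees(example_garg_pedigree())  # 3
#' @export
count_distinct_trees <- function(g, samples = NULL) {
  forests <- attr(local_trees(g, suppress_unary = TRUE, samples = samples),
                  "forests")
  if (length(forests) == 0) return(0L)
  n <- 1L
  for (i in seq_along(forests)[-1]) {
    if (!forest_equal(forests[[i - 1]], forests[[i]])) n <- n + 1L
  }
  n
}

#' Newick strings for a local forest
#'
#' Serializes each local root of the forest as one Newick string. Leaf and
#' internal labels are node ids (or the node `metadata` labels of `g` when
#' supplied). Children are listed in increasing id order, so output is
#' deterministic.
#'
#' @param f A `local_forest` from [tree_at()] or [local_trees()].
#' @param g Optional [garg()] used to translate ids to metadata labels.
#' @return Character vector, one `;`-terminated Newick string per root.
#' @examples
#' f <- tree_at(example_garg_pedigree(), 4, suppress_unary = TRUE)
#' forest_newick(f, example_garg_pedigree())
#' @export
forest_newick <- function(f, g = NULL) {
  lab <- function(id) {
    if (!is.null(g)) {
      m <- g$nodes$metadata[match(id, g$nodes$id)]
      if (!is.na(m) && nzchar(m)) return(sub("\\s.*", "", m))
    }
    sprintf("n%d", id)
  }
  kids <- split(f$nodes[!is.na(f$parent_of)],
                unname(f$parent_of[!is.na(f$parent_of)]))
  build <- function(u) {
    ch <- kids[[as.character(u)]]
    if (is.null(ch) || length(ch) == 0) return(lab(u))
    paste0("(", paste(vapply(sort(ch), build, character(1)), collapse = ","),
           ")", lab(u))
  }
  roots <- sort(f$nodes[is.na(f$parent_of)])
  vapply(roots, function(r) paste0(build(r), ";"), character(1))
}

# minimal Newick parser used for round-trip tests; returns a parent map
# (named by label) sufficient to rebuild a forest, tolerating unary nodes
parse_newick <- function(s) {
  s <- gsub("\\s", "", s)
  s <- sub(";$", "", s)
  pos <- 1
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  read_label <- function() {
    start <- pos
    while (pos <= n && !substr(s, pos, pos) %in% c("(", ")", ",", ";")) {
      pos <<- pos + 1
    }
    substr(s, start, pos - 1)
  }
  parent_of <- character(0)
  node <- function() {
    children <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1
      repeat {
        children <- c(children, node())
        if (peek() == ",") { pos <<- pos + 1 } else break
      }
      stopifnot(peek() == ")")
      pos <<- pos + 1
    }
    me <- read_label()
    for (ch in children) parent_of[ch] <<- me
    me
  }
  root <- node()
  parent_of[root] <- NA_character_
  parent_of
}
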