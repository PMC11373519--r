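read_table_checked <- function(path, cols) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    stop(sprintf("%s: expected a '#'-prefixed header line", path),
         call. = FALSE)
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (!identical(header, cols)) {
    stop(sprintf("%s: header must be '#%s'", path, paste(cols, collapse = "\t")),
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    length(f) <- length(cols)   # pad trailing empty fields
    f[is.na(f)] <- ""
    if (length(f) != length(cols)) {
      stop(sprintf("%s: line %d: expected %d tab-separated fields",
                   path, i + 1, length(cols)), call. = FALSE)
    }
    f
  })
  m <- do.call(rbind, c(rows, list(matrix(character(), 0, length(cols)))))
  colnames(m) <- cols
  tibble::as_tibble(m)
}

num_or_na <- function(x, path, field) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & nzchar(x)
  if (any(bad)) {
    stop(sprintf("%s: line %d: field '%s' is not numeric: '%s'",
                 path, which(bad)[1] + 1, field, x[bad][1]), call. = FALSE)
  }
  out
}

#' Read and write gARG node/edge tables
#'
#' The gARG text format is two UTF-8 TSV tables with a `#`-prefixed header.
#' `nodes.tsv` has columns `id`, `time` (empty when unknown), `is_sample`
#' (0/1) and `metadata`; `edges.tsv` has `child`, `parent` and `intervals`,
#' the interval set serialized as semicolon-separated `left,right` pairs
#' (e.g. `0,2;7,10`). Writing a canonical graph and reading it back
#' round-trips bit-exact.
#'
#' @param nodes_path,edges_path File paths of the two tables.
#' @param sequence_length Genome length `L`; when `NULL` on read, the
#'   maximum right endpoint across edges is used.
#' @param g A [garg()].
#' @return `read_garg()` returns a [garg()]; `write_garg()` returns the two
#'   paths, invisibly.
#' @examples
#' td <- tempdir()
#' np <- file.path(td, "nodes.tsv"); ep <- file.path(td, "edges.tsv")
#' write_garg(example_garg_pedigree(), np, ep)
#' g <- read_garg(np, ep)
#' @export
read_garg <- function(nodes_path, edges_path, sequence_length = NULL) {
  nr <- read_table_checked(nodes_path, c("id", "time", "is_sample", "metadata"))
  nodes <- tibble::tibble(
    id = as.integer(num_or_na(nr$id, nodes_path, "id")),
    time = num_or_na(nr$time, nodes_path, "time"),
    is_sample = num_or_na(nr$is_sample, nodes_path, "is_sample") == 1,
    metadata = ifelse(nzchar(nr$metadata), nr$metadata, NA_character_))
  er <- read_table_checked(edges_path, c("child", "parent", "intervals"))
  sets <- lapply(seq_len(nrow(er)), function(i) {
    s <- tryCatch(
      parse_interval_set(er$intervals[i], where = ""),
      error = function(cnd) stop(sprintf("%s: line %d: %s", edges_path, i + 1,
                                         conditionMessage(cnd)),
                                 call. = FALSE))
    tibble::tibble(child = as.integer(er$child[i]),
                   parent = as.integer(er$parent[i]),
                   left = s$left, right = s$right)
  })
  edges <- dplyr::bind_rows(c(sets, list(tibble::tibble(
    child = integer(), parent = integer(),
    left = numeric(), right = numeric()))))
  if (is.null(sequence_length)) {
    sequence_length <- if (nrow(edges) > 0) max(edges$right) else 1
  }
  garg(nodes = nodes, edges = edges, sequence_length = sequence_length)
}

#' @rdname read_garg
#' @export
write_garg <- function(g, nodes_path, edges_path) {
  n <- g$nodes
  nl <- sprintf("%d\t%s\t%d\t%s", n$id,
                ifelse(is.na(n$time), "", format_coord(n$time)),
                as.integer(n$is_sample),
                ifelse(is.na(n$metadata), "", n$metadata))
  writeLines(c("#id\ttime\tis_sample\tmetadata", nl), nodes_path,
             useBytes = TRUE)
  e <- dplyr::group_by(g$edges, .data$child, .data$parent)
  e <- dplyr::summarise(
    e, intervals = format_interval_set(dplyr::pick("left", "right")),
    .groups = "drop")
  # restore the canonical edge sort of the graph
  key <- match(paste(e$child, e$parent),
               unique(paste(g$edges$child, g$edges$parent)))
  e <- e[order(key), ]
  el <- sprintf("%d\t%d\t%s", e$child, e$parent, e$intervals)
  writeLines(c("#child\tparent\tintervals", el), edges_path, useBytes = TRUE)
  invisible(c(nodes_path, edges_path))
}

#' Read and write eARG node/edge tables
#'
#' `enodes.tsv` has columns `id`, `kind`, `breakpoint` (empty except on
#' recombination nodes) and `time` (empty when unknown); `eedges.tsv` has
#' `child`, `parent`, `side` with side in `L`/`R`/`-`.
#'
#' @param nodes_path,edges_path File paths of the two tables.
#' @param sequence_length Genome length `L` (required on read: the tables do
#'   not store it).
#' @param e An [earg()].
#' @return `read_earg()` returns an [earg()]; `write_earg()` the two paths,
#'   invisibly.
#' @export
read_earg <- function(nodes_path, edges_path, sequence_length) {
  nr <- read_table_checked(nodes_path, c("id", "kind", "breakpoint", "time"))
  nodes <- tibble::tibble(
    id = as.integer(num_or_na(nr$id, nodes_path, "id")),
    kind = nr$kind,
    breakpoint = num_or_na(nr$breakpoint, nodes_path, "breakpoint"),
    time = num_or_na(nr$time, nodes_path, "time"))
  er <- read_table_checked(edges_path, c("child", "parent", "side"))
  edges <- tibble::tibble(
    child = as.integer(num_or_na(er$child, edges_path, "child")),
    parent = as.integer(num_or_na(er$parent, edges_path, "parent")),
    side = er$side)
  bad <- !edges$side %in% c("L", "R", "-")
  if (any(bad)) {
    stop(sprintf("%s: line %d: side must be L, R or -", edges_path,
                 which(bad)[1] + 1), call. = FALSE)
  }
  earg(nodes = nodes, edges = edges, sequence_length = sequence_length)
}

#' @rdname read_earg
#' @export
write_earg <- function(e, nodes_path, edges_path) {
  n <- e$nodes
  nl <- sprintf("%d\t%s\t%s\t%s", n$id, n$kind,
                ifelse(is.na(n$breakpoint), "", format_coord(n$breakpoint)),
                ifelse(is.na(n$time), "", format_coord(n$time)))
  writeLines(c("#id\tkind\tbreakpoint\ttime", nl), nodes_path,
             useBytes = TRUE)
  el <- sprintf("%d\t%d\t%s", e$edges$child, e$edges$parent, e$edges$side)
  writeLines(c("#child\tparent\tside", el), edges_path, useBytes = TRUE)
  invisible(c(nodes_path, edges_path))
}

#' Export a gARG in DOT format for visual inspection
#'
#' Node labels are ids (or metadata labels when present); edge labels are
#' the inheritance interval sets.
#'
#' @param g A [garg()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dot <- function(g, path) {
  lab <- ifelse(is.na(g$nodes$metadata), as.character(g$nodes$id),
                sub("\\s.*", "", g$nodes$metadata))
  shapes <- ifelse(g$nodes$is_sample, "box", "ellipse")
  nl <- sprintf('  n%d [label="%s", shape=%s];', g$nodes$id, lab, shapes)
  e <- dplyr::group_by(g$edges, .data$child, .data$parent)
  e <- dplyr::summarise(
    e, intervals = format_interval_set(dplyr::pick("left", "right")),
    .groups = "drop")
  el <- sprintf('  n%d -> n%d [label="%s"];', e$child, e$parent, e$intervals)
  writeLines(c("digraph garg {", "  rankdir=BT;", nl, el, "}"), path,
             useBytes = TRUE)
  invisible(path)
}

#' Summary statistics of a gARG
#'
#' One-row tibble with node/edge/sample counts, the number of internal
#' breakpoints, the number of distinct local trees, and quantiles of the
#' per-node coalescence span with respect to the samples. Also available as
#' `glance()` on a `garg`.
#'
#' @inheritParams ancestral_material
#' @return A one-row tibble.
#' @examples
#' garg_stats(example_garg_pedigree())
#' @export
garg_stats <- function(g, samples = g$samples) {
  bps <- garg_breakpoints(g)
  span <- if (length(samples) > 0 && nrow(g$edges) > 0) {
    coalescence_span(g, samples)$span
  } else {
    numeric(0)
  }
  q <- if (length(span) > 0) stats::quantile(span, c(0, .25, .5, .75, 1)) else
    rep(NA_real_, 5)
  tibble::tibble(
    sequence_length = g$sequence_length,
    n_nodes = nrow(g$nodes),
    n_edges = nrow(dplyr::distinct(g$edges, .data$child, .data$parent)),
    n_samples = length(samples),
    n_breakpoints = max(length(bps) - 2L, 0L),
    n_local_trees = if (nrow(g$edges) > 0) count_distinct_trees(g, samples)
      else as.integer(nrow(g$nodes) > 0),
    span_min = unname(q[1]), span_q25 = unname(q[2]),
    span_median = unname(q[3]), span_q75 = unname(q[4]),
    span_max = unname(q[5])
  )
}
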