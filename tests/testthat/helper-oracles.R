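# Brute-force oracles, deliberately independent of the package's sweep /
# segment algorithms: everything here works position by position by scanning
# the edge table and following parent chains.

# parent of `node` at position x, or NA
oracle_parent_at <- function(g, node, x) {
  e <- g$edges
  hit <- e$child == node & e$left <= x & x < e$right
  if (!any(hit)) NA_integer_ else e$parent[hit][1]
}

# full child -> parent map at x (named integer vector incl. parentless nodes)
oracle_forest_at <- function(g, x) {
  e <- g$edges[g$edges$left <= x & x < g$edges$right, ]
  present <- sort(unique(c(e$child, e$parent)))
  p <- rep(NA_integer_, length(present))
  names(p) <- present
  p[as.character(e$child)] <- e$parent
  p
}

# nodes visited by following each sample's parent chain at x
oracle_ancestral_nodes <- function(g, samples, x) {
  seen <- integer(0)
  for (s in samples) {
    u <- s
    while (!is.na(u) && !u %in% seen) {
      seen <- c(seen, u)
      u <- oracle_parent_at(g, u, x)
    }
  }
  sort(seen)
}

# chain of ancestors of s at x, starting at s
oracle_chain <- function(g, s, x) {
  out <- integer(0)
  u <- s
  while (!is.na(u) && !u %in% out) {
    out <- c(out, u)
    u <- oracle_parent_at(g, u, x)
  }
  out
}

# most recent common ancestor of two samples at x (first shared chain node),
# or NA when their lineages never meet within the graph
oracle_mrca <- function(g, a, b, x) {
  ca <- oracle_chain(g, a, x)
  cb <- oracle_chain(g, b, x)
  shared <- ca[ca %in% cb]
  if (length(shared) == 0) NA_integer_ else shared[1]
}

# signature of the sample-restricted genealogy at x: pairwise MRCAs
oracle_mrca_signature <- function(g, samples, x) {
  pairs <- utils::combn(sort(samples), 2)
  apply(pairs, 2, function(p) oracle_mrca(g, p[1], p[2], x))
}

# midpoints of the breakpoint regions of g
region_midpoints <- function(g) {
  bps <- garg_breakpoints(g)
  (bps[-1] + bps[-length(bps)]) / 2
}

# map new ids of a garg_simplify result back to the original ids
unmap_ids <- function(sim, ids) {
  sim$node_map$old_id[match(ids, sim$node_map$new_id)]
}

# forest signature robust to id renumbering: for each region midpoint the
# pairwise sample MRCAs, translated back to original ids when a node_map is
# given
mrca_profile <- function(g, samples, positions, node_map = NULL) {
  sig <- lapply(positions, function(x) oracle_mrca_signature(g, samples, x))
  if (!is.null(node_map)) {
    sig <- lapply(sig, function(v) node_map$old_id[match(v, node_map$new_id)])
  }
  sig
}

expect_valid_garg <- function(g) {
  expect_identical(nrow(garg_validate(g)), 0L)
}

expect_valid_earg <- function(e) {
  rep <- earg_validate(e)
  expect_identical(nrow(rep[rep$kind != "warning", ]), 0L)
}

# small random WF graphs used across tests
random_wf <- function(seed, N = 5, gens = 6, L = 10, rate = 1, gc = 0) {
  sim_wf_garg(population_size = N, generations = gens, sequence_length = L,
              crossover_rate = rate, gene_conversion_rate = gc,
              gc_tract_length = 2, seed = seed)
}

letter_id <- function(letter) match(letter, LETTERS)
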