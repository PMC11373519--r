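test_that("ancestral material in the pedigree example matches its documented facts", {
  g <- example_garg_pedigree()
  am <- ancestral_material(g)

  # samples carry their whole genome
  for (s in g$samples) {
    own <- am[am$node == s, ]
    expect_equal(own$left, 0)
    expect_equal(own$right, 10)
    expect_equal(own$sample_count, 1L)
  }

  # in [2,7): E blank, F/G/H carry material, i.e. 3 ancestral segments
  parental <- letter_id(c("E", "F", "G", "H"))
  in_region <- am[am$node %in% parental & am$left < 7 & am$right > 2, ]
  expect_setequal(unique(in_region$node), letter_id(c("F", "G", "H")))

  # F carries the local coalescence of A and C over exactly [2,7)
  f_two <- am[am$node == letter_id("F") & am$sample_count == 2, ]
  expect_equal(f_two$left, 2)
  expect_equal(f_two$right, 7)
})

test_that("segment propagation agrees with the per-position chain oracle", {
  for (seed in 1:6) {
    g <- random_wf(seed, gc = if (seed %% 3 == 0) 0.3 else 0)
    am <- ancestral_material(g)
    for (x in region_midpoints(g)) {
      expected <- oracle_ancestral_nodes(g, g$samples, x)
      got <- sort(unique(am$node[am$left <= x & x < am$right]))
      expect_equal(got, expected)
    }
  }
})

test_that("sample counts add along merging paths and respect bounds", {
  for (seed in 1:4) {
    g <- random_wf(seed)
    am <- ancestral_material(g)
    n <- length(g$samples)
    expect_true(all(am$sample_count >= 1 & am$sample_count <= n))
    # per-position: count at a node equals the number of samples whose chain
    # passes through it
    for (x in region_midpoints(g)[1:2]) {
      rows <- am[am$left <= x & x < am$right, ]
      for (i in sample(seq_len(nrow(rows)), min(5, nrow(rows)))) {
        through <- sum(vapply(g$samples, function(s)
          rows$node[i] %in% oracle_chain(g, s, x), logical(1)))
        expect_equal(rows$sample_count[i], through)
      }
    }
  }
})

test_that("lineage counts are non-increasing pastwards at every position", {
  for (seed in 1:4) {
    g <- random_wf(seed)
    am <- ancestral_material(g, stop_at_mrca = TRUE)
    times <- sort(unique(g$nodes$time))
    for (x in region_midpoints(g)) {
      carriers <- am[am$left <= x & x < am$right, ]
      counts <- vapply(times[-length(times)], function(t) {
        live <- carriers$node[g$nodes$time[match(carriers$node,
                                                 g$nodes$id)] <= t]
        sum(vapply(live, function(u) {
          p <- oracle_parent_at(g, u, x)
          is.na(p) || !p %in% carriers$node ||
            g$nodes$time[match(p, g$nodes$id)] > t
        }, logical(1)))
      }, numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  }
})

test_that("resolving the trapped example removes exactly the documented structure", {
  e <- example_earg_trapped()
  g <- earg_to_garg(e)
  r <- garg_resolve(g)
  expect_valid_garg(r)

  # the grand MRCA Q is gone; everything else survives
  expect_setequal(setdiff(g$nodes$id, r$nodes$id), letter_id("Q"))

  pair_of <- function(gr) unique(paste(gr$edges$child, gr$edges$parent))
  gone <- setdiff(pair_of(g), pair_of(r))
  gone_pairs <- do.call(rbind, strsplit(gone, " "))
  gone_child <- as.integer(gone_pairs[, 1])
  gone_parent <- as.integer(gone_pairs[, 2])

  # exactly one removed edge has a recombination-node child: G -> J, and G's
  # breakpoint is 5
  rec_ids <- e$nodes$id[e$nodes$kind == "recombination"]
  rec_gone <- gone_child %in% rec_ids
  expect_equal(sum(rec_gone), 1L)
  expect_equal(gone_child[rec_gone], letter_id("G"))
  expect_equal(gone_parent[rec_gone], letter_id("J"))
  expect_equal(e$nodes$breakpoint[e$nodes$id == letter_id("G")], 5)

  # full coalescence happens in K over [0,3) and P over [3,7)
  am <- ancestral_material(g, stop_at_mrca = TRUE)
  full <- am[am$sample_count == 3, ]
  expect_equal(full$node, letter_id(c("K", "P")))
  expect_equal(full$left, c(0, 3))
  expect_equal(full$right, c(3, 7))
})

test_that("resolution preserves the samples' genealogy at every position", {
  for (seed in 1:6) {
    g <- random_wf(seed)
    r <- garg_resolve(g)
    expect_valid_garg(r)
    for (x in region_midpoints(g)) {
      expect_equal(oracle_mrca_signature(r, g$samples, x),
                   oracle_mrca_signature(g, g$samples, x))
      expect_identical(tree_at(r, x, suppress_unary = TRUE)$parent_of,
                       tree_at(g, x, suppress_unary = TRUE)$parent_of)
    }
  }
})

test_that("resolve and simplify are idempotent", {
  targets <- list(earg_to_garg(example_earg_trapped()),
                  example_garg_pedigree(), random_wf(3))
  for (g in targets) {
    r1 <- garg_resolve(g)
    r2 <- garg_resolve(r1)
    expect_equal(as.data.frame(r1$edges), as.data.frame(r2$edges))
    expect_equal(r1$nodes$id, r2$nodes$id)
    for (lev in c("resolve", "prune-diamonds", "prune-unary", "full")) {
      s1 <- garg_simplify(g, options = lev)
      s2 <- garg_simplify(s1$graph, options = lev)
      expect_equal(as.data.frame(s2$graph$edges), as.data.frame(s1$graph$edges))
      expect_equal(s2$node_map$new_id, s2$node_map$old_id)
    }
  }
})

test_that("an already-binary single tree is a fixed point of all levels", {
  n <- data.frame(id = 1:7, time = c(0, 0, 0, 0, 1, 1, 2),
                  is_sample = c(rep(TRUE, 4), rep(FALSE, 3)))
  e <- data.frame(child = c(1, 2, 3, 4, 5, 6), parent = c(5, 5, 6, 6, 7, 7),
                  left = 0, right = 10)
  g <- garg(n, e, sequence_length = 10)
  for (lev in c("resolve", "prune-diamonds", "prune-unary", "full")) {
    s <- garg_simplify(g, options = lev)
    expect_equal(s$node_map$old_id, s$node_map$new_id)
    expect_equal(as.data.frame(s$graph$edges), as.data.frame(g$edges))
  }
})

test_that("simplification preserves sample genealogies and shrinks monotonically", {
  levels <- c("resolve", "prune-diamonds", "prune-unary", "full")
  for (seed in 1:6) {
    g <- random_wf(seed)
    positions <- region_midpoints(g)
    ref <- mrca_profile(g, g$samples, positions)
    n_nodes <- c()
    tot_len <- c()
    for (lev in levels) {
      s <- garg_simplify(g, options = lev)
      expect_valid_garg(s$graph)
      new_samples <- s$node_map$new_id[match(g$samples, s$node_map$old_id)]
      expect_false(any(is.na(new_samples)))     # samples always survive
      prof <- mrca_profile(s$graph, new_samples, positions,
                           node_map = s$node_map)
      expect_equal(prof, ref)
      n_nodes <- c(n_nodes, nrow(s$graph$nodes))
      tot_len <- c(tot_len, sum(s$graph$edges$right - s$graph$edges$left))
    }
    expect_true(all(diff(n_nodes) <= 0))
    expect_true(all(diff(tot_len) <= 1e-9))
  }
})

test_that("fully simplified graphs have no locally unary coverage", {
  for (seed in 1:4) {
    g <- random_wf(seed)
    s <- garg_simplify(g, options = "full")
    lt <- local_trees(s$graph, suppress_unary = FALSE,
                      samples = s$graph$samples)
    for (f in attr(lt, "forests")) {
      kids <- table(f$parent_of[!is.na(f$parent_of)])
      internal <- setdiff(f$nodes, s$graph$samples)
      present_internal <- intersect(internal, as.integer(names(kids)))
      expect_true(all(kids[as.character(present_internal)] >= 2))
    }
  }
})

test_that("coalescence span matches the worked examples and the unary ladder", {
  g <- example_garg_pedigree()
  cs <- coalescence_span(g)
  expect_equal(cs$span[cs$node == letter_id("F")], 0.5)
  expect_equal(cs$span[cs$node == letter_id("A")], 0)   # a sample leaf

  # nodes with zero span and children are exactly the ones pruned at the
  # unary-everywhere level (plus what diamond pruning already removed)
  r <- garg_resolve(random_wf(2))
  cs2 <- coalescence_span(r)
  zero <- cs2$node[cs2$span == 0 & cs2$node %in% r$edges$parent &
                     !cs2$node %in% r$samples]
  s <- garg_simplify(random_wf(2), options = "prune-unary")
  expect_true(all(!zero %in% s$node_map$old_id))
})
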