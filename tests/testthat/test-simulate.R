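test_that("WF simulation with no recombination gives single full-span edges", {
  g <- sim_wf_garg(4, 3, 10, crossover_rate = 0, seed = 1)
  expect_valid_garg(g)
  per_child <- split(seq_len(nrow(g$edges)), g$edges$child)
  for (idx in per_child) {
    expect_length(idx, 1)
    expect_equal(g$edges$left[idx], 0)
    expect_equal(g$edges$right[idx], 10)
  }
})

test_that("a fixed seed reproduces bit-identical tables", {
  a <- sim_wf_garg(5, 4, 10, crossover_rate = 1, gene_conversion_rate = 0.2,
                   gc_tract_length = 2, seed = 99)
  b <- sim_wf_garg(5, 4, 10, crossover_rate = 1, gene_conversion_rate = 0.2,
                   gc_tract_length = 2, seed = 99)
  expect_identical(a, b)
  e1 <- sim_coalescent_earg(4, 10, recombination_rate = 1, seed = 7)
  e2 <- sim_coalescent_earg(4, 10, recombination_rate = 1, seed = 7)
  expect_identical(e1, e2)
})

test_that("inbound edges of every non-founder genome partition [0, L)", {
  for (seed in 1:4) {
    g <- random_wf(seed, gc = if (seed %% 2) 0 else 0.5)
    expect_valid_garg(g)
    founders <- g$nodes$id[g$nodes$time == max(g$nodes$time)]
    for (child in setdiff(g$nodes$id, founders)) {
      iv <- g$edges[g$edges$child == child, c("left", "right")]
      expect_gt(nrow(iv), 0)
      u <- interval_canonical(iv)
      expect_equal(sum(u$right - u$left), g$sequence_length)  # covers L
      # disjointness: total row length equals union length
      expect_equal(sum(iv$right - iv$left), g$sequence_length)
    }
  }
})

test_that("crossovers per meiosis are Poisson with the requested mean", {
  # 2 * 100 * 10 = 2000 meioses at rate 1
  g <- sim_wf_garg(100, 10, 10, crossover_rate = 1, seed = 2024)
  founders <- g$nodes$id[g$nodes$time == max(g$nodes$time)]
  kids <- setdiff(g$nodes$id, founders)
  pieces <- table(factor(g$edges$child, levels = kids))
  crossovers <- as.numeric(pieces) - 1
  n <- length(crossovers)
  se <- stats::sd(crossovers) / sqrt(n)
  expect_lt(abs(mean(crossovers) - 1), 3 * se)
})

test_that("gene conversion produces multi-interval edges", {
  g <- sim_wf_garg(10, 6, 10, crossover_rate = 0, gene_conversion_rate = 1,
                   gc_tract_length = 2, seed = 5)
  per_edge <- dplyr::count(g$edges, child, parent)
  expect_gt(max(per_edge$n), 1)   # some edge carries >= 2 intervals
  expect_valid_garg(g)
})

test_that("mean number of distinct trees grows with the crossover rate", {
  mean_trees <- function(rate) {
    mean(vapply(1:12, function(seed) {
      g <- sim_wf_garg(5, 6, 10, crossover_rate = rate, seed = 1000 + seed)
      r <- garg_resolve(g)
      as.numeric(count_distinct_trees(r))
    }, numeric(1)))
  }
  m <- vapply(c(0, 0.5, 2), mean_trees, numeric(1))
  expect_true(all(diff(m) >= 0))
  expect_equal(m[1], 1)   # no recombination: a single tree
})

test_that("coalescent eARG simulation: structure and conversion conservation", {
  e0 <- sim_coalescent_earg(5, 10, recombination_rate = 0, seed = 11)
  expect_valid_earg(e0)
  expect_equal(sum(e0$nodes$kind == "recombination"), 0L)
  expect_equal(sum(e0$nodes$kind == "common_ancestor"), 4L)  # binary tree

  for (seed in 1:10) {
    e <- sim_coalescent_earg(3, 10, recombination_rate = 1, seed = seed)
    expect_valid_earg(e)
    g <- earg_to_garg(e)
    expect_valid_garg(g)
    # each recombination node whose two parents are distinct contributes its
    # breakpoint to the gARG edge table (when both sides lead to the same
    # parent the two intervals merge back to [0, L))
    rec_ids <- e$nodes$id[e$nodes$kind == "recombination"]
    two_parents <- vapply(rec_ids, function(u)
      length(unique(e$edges$parent[e$edges$child == u])) == 2, logical(1))
    splitters <- unique(g$edges$child[g$edges$left > 0 |
                                        g$edges$right < g$sequence_length])
    expect_setequal(splitters, rec_ids[two_parents])
    r <- garg_resolve(g)
    expect_valid_garg(r)
  }
})

test_that("some runs drop a recombination edge that fell in nonancestral material", {
  dropped <- 0
  for (seed in 1:40) {
    e <- sim_coalescent_earg(3, 10, recombination_rate = 1, seed = seed)
    g <- earg_to_garg(e)
    r <- garg_resolve(g)
    pair_of <- function(gr) unique(paste(gr$edges$child, gr$edges$parent))
    gone <- setdiff(pair_of(g), pair_of(r))
    rec_ids <- e$nodes$id[e$nodes$kind == "recombination"]
    gone_child <- as.integer(vapply(strsplit(gone, " "), `[[`, "", 1))
    if (any(gone_child %in% rec_ids)) dropped <- dropped + 1
  }
  expect_gt(dropped, 0)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(sim_wf_garg(0, 3, 10, seed = 1))
  expect_error(sim_wf_garg(5, 3, 10, crossover_rate = -1, seed = 1))
  expect_error(sim_coalescent_earg(1, 10, seed = 1))
})
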