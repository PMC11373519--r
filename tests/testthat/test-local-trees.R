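test_that("the pedigree example yields the three drawn local trees", {
  g <- example_garg_pedigree()
  lt <- local_trees(g, suppress_unary = TRUE)
  forests <- attr(lt, "forests")
  expect_length(forests, 3)
  expect_equal(vapply(forests, function(f) c(f$left, f$right), numeric(2)),
               matrix(c(0, 2, 2, 7, 7, 10), nrow = 2))
  nwk <- vapply(forests, function(f) forest_newick(f, g), character(1))
  expect_equal(nwk, c("((A,B)I,(C,D)K)N;",
                      "(B,(D,(A,C)F)K)N;",
                      "((B,C)I,(A,D)K)N;"))
})

test_that("A and C share parent F at position 4 without suppression", {
  g <- example_garg_pedigree()
  f <- tree_at(g, 4)
  expect_equal(unname(f$parent_of[as.character(letter_id(c("A", "C")))]),
               rep(letter_id("F"), 2))
})

test_that("a single-tree gARG gives the same forest everywhere", {
  n <- data.frame(id = 1:3, time = c(0, 0, 1),
                  is_sample = c(TRUE, TRUE, FALSE))
  g <- garg(n, data.frame(child = 1:2, parent = 3, left = 0, right = 10),
            sequence_length = 10)
  lt <- local_trees(g)
  expect_length(attr(lt, "forests"), 1)
  for (x in c(0, 3.3, 9.99)) {
    expect_identical(tree_at(g, x)$parent_of,
                     attr(lt, "forests")[[1]]$parent_of)
  }
  expect_equal(count_distinct_trees(g), 1L)
})

test_that("the sweep equals per-midpoint reconstruction on simulated ARGs", {
  for (seed in 1:8) {
    g <- random_wf(seed, gc = if (seed %% 2) 0 else 0.3)
    for (suppress in c(FALSE, TRUE)) {
      lt <- local_trees(g, suppress_unary = suppress)
      forests <- attr(lt, "forests")
      mids <- region_midpoints(g)
      expect_length(forests, length(mids))
      for (i in seq_along(mids)) {
        expect_identical(forests[[i]]$parent_of,
                         tree_at(g, mids[i], suppress_unary = suppress)$parent_of)
      }
    }
  }
})

test_that("regions tile [0, L) with no gaps or overlaps", {
  for (seed in 1:5) {
    g <- random_wf(seed)
    lt <- local_trees(g)
    forests <- attr(lt, "forests")
    lefts <- vapply(forests, `[[`, numeric(1), "left")
    rights <- vapply(forests, `[[`, numeric(1), "right")
    expect_equal(lefts[1], 0)
    expect_equal(rights[length(rights)], g$sequence_length)
    expect_equal(lefts[-1], rights[-length(rights)])
  }
})

test_that("distinct tree count collapses adjacent regions with identical forests", {
  expect_equal(count_distinct_trees(example_garg_pedigree()), 3L)

  # two breakpoint regions that induce the same suppressed forest: B switches
  # between two parents that are themselves spliced into the same chain
  n <- data.frame(id = 1:5, time = c(0, 0, 1, 1, 2),
                  is_sample = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  e <- data.frame(child = c(1, 2, 2, 3, 4),
                  parent = c(5, 3, 4, 5, 5),
                  left = c(0, 0, 5, 0, 5), right = c(10, 5, 10, 5, 10))
  g <- garg(n, e, sequence_length = 10)
  expect_length(attr(local_trees(g), "forests"), 2)  # two regions ...
  expect_equal(count_distinct_trees(g), 1L)          # ... one distinct tree
})

test_that("suppression never changes a pairwise MRCA that is locally coalescent", {
  for (seed in 1:5) {
    g <- random_wf(seed)
    samples <- g$samples
    for (x in region_midpoints(g)) {
      plain <- tree_at(g, x, samples = samples)
      supp <- tree_at(g, x, suppress_unary = TRUE)
      for (pair in utils::combn(samples[1:4], 2, simplify = FALSE)) {
        m <- oracle_mrca(g, pair[1], pair[2], x)
        if (is.na(m)) next
        # MRCA with >= 2 sample-bearing children locally must survive
        kids <- names(plain$parent_of)[!is.na(plain$parent_of) &
                                         plain$parent_of == m]
        if (length(kids) >= 2 && m %in% supp$nodes) {
          # in the suppressed forest the pair must still meet at m
          anc <- supp$parent_of
          walk <- function(s) {
            out <- s
            while (!is.na(anc[as.character(out[length(out)])])) {
              out <- c(out, anc[[as.character(out[length(out)])]])
            }
            out
          }
          shared <- intersect(walk(pair[1]), walk(pair[2]))
          expect_equal(shared[1], m)
        }
      }
    }
  }
})

test_that("newick export round-trips and matches ape on suppressed trees", {
  g <- example_garg_pedigree()
  f <- tree_at(g, 4, suppress_unary = TRUE)
  nwk <- forest_newick(f, g)
  expect_equal(nwk, "(B,(D,(A,C)F)K)N;")

  # round-trip through the internal parser: same parent relation
  pm <- gargkit:::parse_newick(nwk)
  expect_equal(pm[["A"]], "F")
  expect_equal(pm[["F"]], "K")
  expect_equal(unname(is.na(pm[["N"]])), TRUE)

  # unsuppressed forests include unary chains and still round-trip
  f2 <- tree_at(g, 4, samples = g$samples)
  nwk2 <- forest_newick(f2, g)
  pm2 <- gargkit:::parse_newick(nwk2[1])
  expect_equal(pm2[["A"]], "F")
  expect_equal(pm2[["F"]], "K")

  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # (A,C) must be a clade in ape's reading too
  mrca_ac <- ape::getMRCA(tr, c("A", "C"))
  expect_setequal(ape::extract.clade(tr, mrca_ac)$tip.label, c("A", "C"))
})

test_that("every sample appears in every region's forest", {
  for (seed in 1:3) {
    g <- random_wf(seed)
    lt <- local_trees(g, suppress_unary = TRUE)
    for (f in attr(lt, "forests")) {
      expect_true(all(g$samples %in% f$nodes))
    }
  }
})
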