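#' Forward-time diploid Wright-Fisher gARG simulator
#'
#' Records genetic inheritance exhaustively, generation by generation, in a
#' "prospective" gARG: every genome of every individual is a node, whether
#' or not it turns out to be ancestral to the final generation. Each
#' non-founder genome is produced by one meiosis: a parent individual is
#' chosen uniformly at random (with replacement; selfing is permitted), the
#' number of crossovers is Poisson(`crossover_rate`), breakpoints are
#' uniform on `(0, L)`, and the transmitted genome alternates between the
#' parent's two genomes at the breakpoints, giving 1 or 2 inheritance edges
#' whose interval sets partition `[0, L)`. Gene conversion events
#' (Poisson(`gene_conversion_rate`) per meiosis, tract start uniform, tract
#' length exponential with mean `gc_tract_length`) copy an interior tract
#' from the homologous genome, which can put 2 or more intervals on a
#' single edge. Final-generation genomes are the samples.
#'
#' All random draws come from a single stream seeded by `seed`, in a fixed
#' documented order (per meiosis: crossover count, breakpoints, starting
#' genome, gene-conversion count, then per tract its start and length), so
#' a given seed reproduces bit-identical tables.
#'
#' @param population_size Number of diploid individuals per generation.
#' @param generations Number of generations simulated after the founders.
#' @param sequence_length Genome length `L`.
#' @param crossover_rate Expected crossovers per transmitted genome.
#' @param gene_conversion_rate Expected gene-conversion events per meiosis.
#' @param gc_tract_length Mean gene-conversion tract length.
#' @param seed Integer seed.
#' @return A valid [garg()]. Node `time` is the number of generations before
#'   the present (founders oldest); `metadata` records `"<individual> g<generation>"`
#'   pedigree coordinates.
#' @examples
#' g <- sim_wf_garg(population_size = 4, generations = 3,
#'                  sequence_length = 10, crossover_rate = 1, seed = 1)
#' nrow(garg_validate(g)) == 0
#' @export
sim_wf_garg <- function(population_size, generations, sequence_length,
                        crossover_rate = 1, gene_conversion_rate = 0,
                        gc_tract_length = 1, seed = 1) {
  stopifnot(population_size >= 1, generations >= 1, sequence_length > 0,
            crossover_rate >= 0, gene_conversion_rate >= 0,
            gc_tract_length > 0)
  set.seed(as.integer(seed))
  L <- sequence_length
  N <- as.integer(population_size)

  node_rows <- list()
  edge_rows <- list()
  next_id <- 1L
  new_genomes <- function(gen_back, cohort) {
    ids <- next_id:(next_id + 2L * N - 1L)
    next_id <<- next_id + 2L * N
    node_rows[[length(node_rows) + 1]] <<- tibble::tibble(
      id = ids, time = gen_back,
      is_sample = gen_back == 0,
      metadata = sprintf("i%d g%d", rep(seq_len(N), each = 2), cohort))
    matrix(ids, nrow = 2)   # column j = the two genomes of individual j
  }

  prev <- new_genomes(generations, 0L)
  for (cohort in seq_len(generations)) {
    cur <- new_genomes(generations - cohort, cohort)
    for (j in seq_len(N)) {
      for (hap in 1:2) {
        parent_ind <- sample.int(N, 1)
        child <- cur[hap, j]
        # meiosis: which parts come from the parent's first genome
        k <- stats::rpois(1, crossover_rate)
        bps <- sort(stats::runif(k, 0, L))
        cuts <- c(0, bps, L)
        start_first <- sample.int(2, 1) == 1
        take_first <- rep(c(start_first, !start_first),
                          length.out = length(cuts) - 1)
        first_set <- fast_tbl(left = cuts[-length(cuts)][take_first],
                              right = cuts[-1][take_first])
        ngc <- stats::rpois(1, gene_conversion_rate)
        for (t in seq_len(ngc)) {
          s <- stats::runif(1, 0, L)
          len <- stats::rexp(1, rate = 1 / gc_tract_length)
          tract <- fast_tbl(left = s, right = min(s + len, L))
          if (tract$left >= tract$right) next
          first_set <- interval_union(
            interval_subtract(first_set, tract),
            interval_subtract(tract, first_set))
        }
        first_set <- interval_canonical(first_set)
        second_set <- interval_subtract(
          fast_tbl(left = 0, right = L), first_set)
        if (nrow(first_set) > 0) {
          edge_rows[[length(edge_rows) + 1]] <- fast_tbl(
            child = rep(child, nrow(first_set)),
            parent = rep(prev[1, parent_ind], nrow(first_set)),
            left = first_set$left, right = first_set$right)
        }
        if (nrow(second_set) > 0) {
          edge_rows[[length(edge_rows) + 1]] <- fast_tbl(
            child = rep(child, nrow(second_set)),
            parent = rep(prev[2, parent_ind], nrow(second_set)),
            left = second_set$left, right = second_set$right)
        }
      }
    }
    prev <- cur
  }
  garg(nodes = dplyr::bind_rows(node_rows),
       edges = dplyr::bind_rows(edge_rows),
       sequence_length = L)
}

#' Backwards coalescent-with-recombination eARG simulator
#'
#' Simulates the ancestry of `sample_size` genomes backwards in time as a
#' lineage process: pairs of lineages coalesce (common-ancestor nodes) at
#' rate `k(k-1)/2`, and single lineages split (recombination nodes) at a
#' rate proportional to the length of ancestral material they still carry
#' (`recombination_rate` per lineage carrying a full genome). Breakpoints
#' are uniform on `(0, L)` — not restricted to ancestral material — so a
#' breakpoint can fall in nonancestral material, in which case one side of
#' the recombination node carries nothing ancestral and the corresponding
#' edge disappears under [garg_resolve()]. Segments that have fully
#' coalesced stop contributing to the recombination rate, so the process
#' terminates at a grand MRCA almost surely.
#'
#' @param sample_size Number of sampled genomes (>= 2).
#' @param sequence_length Genome length `L`.
#' @param recombination_rate Recombination rate per fully-ancestral lineage.
#' @param seed Integer seed.
#' @return A valid [earg()].
#' @examples
#' e <- sim_coalescent_earg(3, sequence_length = 10,
#'                          recombination_rate = 0.5, seed = 7)
#' nrow(earg_validate(e)) == 0
#' @export
sim_coalescent_earg <- function(sample_size, sequence_length,
                                recombination_rate = 1, seed = 1) {
  stopifnot(sample_size >= 2, sequence_length > 0, recombination_rate >= 0)
  set.seed(as.integer(seed))
  L <- sequence_length
  n <- as.integer(sample_size)

  nodes <- tibble::tibble(id = seq_len(n), kind = "sample",
                          breakpoint = NA_real_, time = 0,
                          metadata = NA_character_)
  edges <- tibble::tibble(child = integer(), parent = integer(),
                          side = character())
  # a lineage: most recent node, side tag on the edge to its next parent,
  # and the (count-weighted, MRCA-capped) ancestral material it carries
  lineages <- lapply(seq_len(n), function(i) {
    list(node = i, side = "-",
         material = tibble::tibble(left = 0, right = L, count = 1L))
  })
  next_id <- n + 1L
  t_now <- 0

  while (length(lineages) > 1) {
    k <- length(lineages)
    w <- vapply(lineages, function(l) sum(l$material$right - l$material$left),
                numeric(1)) / L
    rate_rec <- recombination_rate * sum(w)
    rate_coal <- k * (k - 1) / 2
    t_now <- t_now + stats::rexp(1, rate_rec + rate_coal)
    if (stats::runif(1) < rate_rec / (rate_rec + rate_coal)) {
      i <- sample.int(k, 1, prob = w)
      bp <- stats::runif(1, 0, L)
      lin <- lineages[[i]]
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        id = next_id, kind = "recombination", breakpoint = bp, time = t_now,
        metadata = NA_character_))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = lin$node, parent = next_id, side = lin$side))
      lineages[[i]] <- list(node = next_id, side = "L",
                            material = clip_counts(lin$material, 0, bp))
      lineages[[k + 1]] <- list(node = next_id, side = "R",
                                material = clip_counts(lin$material, bp, L))
      next_id <- next_id + 1L
    } else {
      ij <- sample.int(k, 2)
      a <- lineages[[ij[1]]]; b <- lineages[[ij[2]]]
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        id = next_id, kind = "common_ancestor", breakpoint = NA_real_,
        time = t_now, metadata = NA_character_))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = c(a$node, b$node), parent = next_id, side = c(a$side, b$side)))
      merged <- flatten_counts(dplyr::bind_rows(a$material, b$material))
      merged <- merged[merged$count < n, , drop = FALSE]  # full MRCA: stop
      lineages[c(ij[1], ij[2])] <- NULL
      lineages[[length(lineages) + 1]] <-
        list(node = next_id, side = "-", material = merged)
      next_id <- next_id + 1L
    }
  }
  earg(nodes = nodes, edges = edges, sequence_length = L,
       samples = seq_len(n))
}
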