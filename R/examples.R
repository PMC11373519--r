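#' Worked-example ARGs
#'
#' Three small hand-constructed ARGs used throughout the documentation and
#' tests, plus a seeded Wright-Fisher example. Node `metadata` carries
#' letter labels (`A`, `B`, ...) matching ids `1, 2, ...`.
#'
#' `example_garg_pedigree()` is a gARG embedded in a highly inbred pedigree
#' of 8 diploid individuals (16 genomes `A`-`P`, four generations, genome
#' length 10). The four current-generation genomes `A`-`D` are the samples.
#' Genome `A` is the recombinant product of `E` and `F` crossing over at
#' position 2 (it inherits `[0,2)` from `E` and `[2,10)` from `F`); `C` is
#' an independent recombinant of the same two genomes with a crossover at
#' position 7; `B` and `D` were inherited without recombination from `G`
#' and `H`. In the region `[2,7)` samples `A` and `C` locally coalesce in
#' `F`, so only three parental-generation genomes (`F`, `G`, `H`) carry
#' ancestral material there while `E` carries none; all samples reach their
#' grand MRCA in node `N`. The two crossovers delimit three local trees.
#'
#' `example_earg_recombination()` is the minimal event ARG: samples `A`,
#' `B`, `C`, one recombination node `D` (breakpoint `x`, default 5, genome
#' length 10) that inherits left of `x` from `E` and right of `x` from `F`,
#' and common-ancestor nodes `E`, `F`, `G`. Its two local trees are
#' `((A,B),C)` and `((A,C),B)`.
#'
#' `example_earg_trapped()` is a classical-style event ARG (samples `A`,
#' `B`, `C`, genome length 7, nodes `A`-`Q`) in which a recombination node
#' `G` has its breakpoint (position 5) inside material that is nonancestral
#' to the samples, so on conversion and resolution the edge from `G` to `J`
#' vanishes; every genome position fully coalesces in `K` (over `[0,3)`) or
#' `P` (over `[3,7)`), so the grand MRCA `Q` is removed by resolution.
#'
#' `example_garg_wf()` regenerates a small diploid Wright-Fisher gARG from a
#' pinned seed via [sim_wf_garg()].
#'
#' @param x Breakpoint position of the recombination node in
#'   `example_earg_recombination()`.
#' @return A [garg()] or [earg()] object.
#' @name examples
NULL

label_ids <- function(labels) stats::setNames(seq_along(labels), labels)

#' @rdname examples
#' @export
example_garg_pedigree <- function() {
  id <- label_ids(LETTERS[1:16])
  labels <- names(id)
  gen <- rep(0:3, each = 4)  # A-D samples, E-H parents, I-L, M-P founders
  individual <- paste0("d", rep(1:8, each = 2))
  nodes <- tibble::tibble(
    id = unname(id),
    time = as.numeric(gen),
    is_sample = gen == 0,
    metadata = labels
  )
  ed <- function(child, parent, left, right) {
    tibble::tibble(child = id[[child]], parent = id[[parent]],
                   left = left, right = right)
  }
  edges <- dplyr::bind_rows(
    ed("A", "E", 0, 2), ed("A", "F", 2, 10),        # crossover at 2
    ed("B", "G", 0, 10),
    ed("C", "F", 0, 7), ed("C", "E", 7, 10),        # crossover at 7
    ed("D", "H", 0, 10),
    ed("E", "I", 0, 10), ed("F", "K", 0, 10),
    ed("G", "I", 0, 10), ed("H", "K", 0, 10),
    ed("I", "N", 0, 10), ed("K", "N", 0, 10),
    ed("J", "O", 0, 10), ed("L", "P", 0, 10)        # nonancestral lines
  )
  nodes$metadata <- paste0(nodes$metadata, " ", individual)  # "A d1", ...
  garg(nodes = nodes, edges = edges, sequence_length = 10)
}

#' @rdname examples
#' @export
example_earg_recombination <- function(x = 5) {
  stopifnot(x > 0, x < 10)
  id <- label_ids(LETTERS[1:7])
  labels <- names(id)
  nodes <- tibble::tibble(
    id = unname(id),
    kind = c("sample", "sample", "sample", "recombination",
             "common_ancestor", "common_ancestor", "common_ancestor"),
    breakpoint = c(NA, NA, NA, x, NA, NA, NA),
    time = c(0, 0, 0, 1, 2, 3, 4),
    metadata = labels
  )
  e <- function(child, parent, side = "-") {
    tibble::tibble(child = id[[child]], parent = id[[parent]], side = side)
  }
  edges <- dplyr::bind_rows(
    e("A", "D"),
    e("D", "E", "L"), e("D", "F", "R"),
    e("B", "E"), e("C", "F"),
    e("E", "G"), e("F", "G")
  )
  earg(nodes = nodes, edges = edges, sequence_length = 10)
}

#' @rdname examples
#' @export
example_earg_trapped <- function() {
  id <- label_ids(LETTERS[1:17])
  labels <- names(id)
  kind <- c(rep("sample", 3),
            "recombination",     # D: splits C at 2
            "common_ancestor",   # E: B + right part of C
            "recombination",     # F: splits E's lineage at 3
            "recombination",     # G: splits D's left lineage at 5 (in
                                 #    nonancestral material - only [0,2) is
                                 #    carried, so the right side is empty)
            "common_ancestor",   # H: A + left side of G
            "recombination",     # I: splits H's lineage at 3
            "common_ancestor",   # J: right side of G + right side of F
            "common_ancestor",   # K: left sides of I and F; [0,3) fully
                                 #    coalesces here
            "recombination",     # L: splits I's right lineage at 4
            "recombination",     # M: splits J's lineage at 6
            "recombination",     # N: splits L's right lineage at 6
            "common_ancestor",   # O: right side of N + left side of M
            "common_ancestor",   # P: remaining lineages; [3,7) fully
                                 #    coalesces here
            "common_ancestor")   # Q: grand MRCA of the trapped lineages
  bp <- rep(NA_real_, 17)
  bp[id[c("D", "F", "G", "I", "L", "M", "N")]] <- c(2, 3, 5, 3, 4, 6, 6)
  nodes <- tibble::tibble(id = unname(id), kind = kind, breakpoint = bp,
                          time = c(0, 0, 0, 1:14), metadata = labels)
  e <- function(child, parent, side = "-") {
    tibble::tibble(child = id[[child]], parent = id[[parent]], side = side)
  }
  edges <- dplyr::bind_rows(
    e("A", "H"), e("B", "E"), e("C", "D"),
    e("D", "G", "L"), e("D", "E", "R"),
    e("E", "F"),
    e("F", "K", "L"), e("F", "J", "R"),
    e("G", "H", "L"), e("G", "J", "R"),
    e("H", "I"),
    e("I", "K", "L"), e("I", "L", "R"),
    e("J", "M"),
    e("K", "Q"),
    e("L", "P", "L"), e("L", "N", "R"),
    e("M", "O", "L"), e("M", "P", "R"),
    e("N", "P", "L"), e("N", "O", "R"),
    e("O", "P"),
    e("P", "Q")
  )
  earg(nodes = nodes, edges = edges, sequence_length = 7)
}

#' @rdname examples
#' @export
example_garg_wf <- function() {
  sim_wf_garg(population_size = 5, generations = 6, sequence_length = 10,
              crossover_rate = 1, seed = 42)
}
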