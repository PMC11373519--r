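# cheap tibble construction for hot paths (no recycling/checking needed)
fast_tbl <- function(...) {
  l <- list(...)
  tibble::new_tibble(l, nrow = if (length(l)) length(l[[1]]) else 0)
}

#' Interval sets over a genome
#'
#' A gARG edge is annotated with the set of half-open genomic intervals
#' `[left, right)` over which the child genome inherits from the parent.
#' Throughout the package such sets are represented as data frames with
#' numeric columns `left` and `right`; in *canonical* form the intervals are
#' non-empty (`left < right`), pairwise disjoint, sorted by `left`, and
#' adjacent intervals such as `[a,b)` and `[b,c)` are merged into `[a,c)`.
#'
#' `interval_set()` builds a canonical set from vectors of endpoints,
#' `interval_canonical()` canonicalises an arbitrary (possibly overlapping,
#' unsorted) table, and `interval_union()`, `interval_intersect()` and
#' `interval_subtract()` implement set algebra over genome positions.
#'
#' @param left,right Numeric vectors of interval endpoints (`left < right`).
#' @param x,a,b Data frames with columns `left` and `right`.
#' @return A tibble with columns `left` and `right` in canonical form.
#' @examples
#' interval_union(interval_set(0, 2), interval_set(2, 10))   # [0,10)
#' interval_intersect(interval_set(0, 2), interval_set(2, 10)) # empty
#' interval_subtract(interval_set(0, 10), interval_set(2, 7))
#' @export
interval_set <- function(left = numeric(), right = numeric()) {
  stopifnot(length(left) == length(right))
  if (any(!is.finite(left)) || any(!is.finite(right))) {
    stop("interval endpoints must be finite numbers", call. = FALSE)
  }
  if (any(left >= right)) {
    bad <- which(left >= right)[1]
    stop(sprintf("empty or inverted interval [%g,%g) is not representable",
                 left[bad], right[bad]), call. = FALSE)
  }
  interval_canonical(tibble::tibble(left = as.numeric(left),
                                    right = as.numeric(right)))
}

#' @rdname interval_set
#' @export
interval_canonical <- function(x) {
  left <- as.numeric(x$left)
  right <- as.numeric(x$right)
  if (length(left) == 0) {
    return(fast_tbl(left = numeric(), right = numeric()))
  }
  o <- order(left, right)
  left <- left[o]
  right <- right[o]
  out_l <- left[1]
  out_r <- right[1]
  k <- 1
  if (length(left) > 1) {
    for (i in 2:length(left)) {
      if (left[i] <= out_r[k]) {          # overlap or exact adjacency: merge
        out_r[k] <- max(out_r[k], right[i])
      } else {
        k <- k + 1
        out_l[k] <- left[i]
        out_r[k] <- right[i]
      }
    }
  }
  fast_tbl(left = out_l[1:k], right = out_r[1:k])
}

#' @rdname interval_set
#' @export
interval_union <- function(a, b) {
  interval_canonical(rbind(as.data.frame(a)[c("left", "right")],
                           as.data.frame(b)[c("left", "right")]))
}

#' @rdname interval_set
#' @export
interval_intersect <- function(a, b) {
  a <- interval_canonical(a)
  b <- interval_canonical(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(fast_tbl(left = numeric(), right = numeric()))
  }
  # all pairwise overlaps; canonical inputs keep this small
  grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  l <- pmax(a$left[grid$i], b$left[grid$j])
  r <- pmin(a$right[grid$i], b$right[grid$j])
  keep <- l < r
  if (!any(keep)) {
    return(fast_tbl(left = numeric(), right = numeric()))
  }
  interval_canonical(fast_tbl(left = l[keep], right = r[keep]))
}

#' @rdname interval_set
#' @export
interval_subtract <- function(a, b) {
  a <- interval_canonical(a)
  b <- interval_canonical(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(a)
  }
  out_l <- numeric()
  out_r <- numeric()
  for (i in seq_len(nrow(a))) {
    cur_l <- a$left[i]
    cur_r <- a$right[i]
    cuts <- b[b$right > cur_l & b$left < cur_r, , drop = FALSE]
    pos <- cur_l
    if (nrow(cuts) > 0) {
      for (j in seq_len(nrow(cuts))) {
        if (cuts$left[j] > pos) {
          out_l <- c(out_l, pos)
          out_r <- c(out_r, cuts$left[j])
        }
        pos <- max(pos, cuts$right[j])
      }
    }
    if (pos < cur_r) {
      out_l <- c(out_l, pos)
      out_r <- c(out_r, cur_r)
    }
  }
  fast_tbl(left = out_l, right = out_r)
}

#' Total length and membership of an interval set
#'
#' `interval_length()` returns the summed length of a canonical interval set;
#' `interval_contains()` tests which positions fall inside the set (left
#' endpoints included, right excluded).
#'
#' @param x A data frame with columns `left` and `right`.
#' @param pos Numeric vector of genome positions.
#' @return `interval_length()`: a number; `interval_contains()`: a logical
#'   vector along `pos`.
#' @export
interval_length <- function(x) {
  x <- interval_canonical(x)
  sum(x$right - x$left)
}

#' @rdname interval_length
#' @export
interval_contains <- function(x, pos) {
  x <- interval_canonical(x)
  vapply(pos, function(p) any(x$left <= p & p < x$right), logical(1))
}

# "l1,r1;l2,r2" serialization used by the edge table file format
format_interval_set <- function(x) {
  x <- interval_canonical(x)
  paste(sprintf("%s,%s", format_coord(x$left), format_coord(x$right)),
        collapse = ";")
}

format_coord <- function(x) {
  # integer-valued coordinates print without decimal point so canonical
  # tables round-trip bit-exact
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}

parse_interval_set <- function(s, where = "intervals") {
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  if (length(pairs) == 0 || all(!nzchar(pairs))) {
    stop(sprintf("%s: empty interval set", where), call. = FALSE)
  }
  lr <- lapply(pairs, function(p) {
    v <- suppressWarnings(as.numeric(strsplit(p, ",", fixed = TRUE)[[1]]))
    if (length(v) != 2 || any(is.na(v))) {
      stop(sprintf("%s: malformed interval '%s'", where, p), call. = FALSE)
    }
    if (v[1] >= v[2]) {
      stop(sprintf("%s: inverted or empty interval '%s'", where, p),
           call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, lr)
  interval_canonical(tibble::tibble(left = m[, 1], right = m[, 2]))
}
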