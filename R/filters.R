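# Split-system filters: top-x truncation, greedy tree extraction
# (strict), two greedy trees (2-tree), and greedy weakly compatible
# subset selection. All filters scan the system in its total order
# (weight descending, side pattern ascending), so results are
# deterministic.

#' Pairwise compatibility of two splits
#'
#' Two splits A|B and C|D on the same taxon set are compatible iff at
#' least one of the four intersections A&#x2229;C, A&#x2229;D, B&#x2229;C, B&#x2229;D is
#' empty; a pairwise-compatible split system is exactly the edge set of
#' an (unrooted) tree. Any trivial split is compatible with every
#' split.
#'
#' @param a,b Logical vectors (taxon membership of one side) of equal
#'   length.
#' @return `TRUE` or `FALSE`; symmetric in its arguments.
#' @export
split_compatible <- function(a, b) {
  !any(a & b) || !any(a & !b) || !any(!a & b) || !any(!a & !b)
}

#' Weak compatibility of a triple of splits
#'
#' Three splits are weakly compatible iff for every orientation
#' (A1, A2, A3) of their sides at least one of A1&#x2229;A2&#x2229;A3, A1&#x2229;B2&#x2229;B3,
#' B1&#x2229;A2&#x2229;B3, B1&#x2229;B2&#x2229;A3 is empty (Bi being the complement of Ai).
#' All 8 orientations are checked explicitly. Weakly compatible systems
#' can be drawn as split networks with boxes, and contain at most
#' n(n-1)/2 splits.
#'
#' @param a,b,c Logical side vectors of equal length.
#' @return `TRUE` or `FALSE`; invariant under permuting the three
#'   splits and under replacing any side by its complement.
#' @export
split_weakly_compatible <- function(a, b, c) {
  for (a1 in list(a, !a)) {
    for (a2 in list(b, !b)) {
      for (a3 in list(c, !c)) {
        if (any(a1 & a2 & a3) && any(a1 & !a2 & !a3) &&
            any(!a1 & a2 & !a3) && any(!a1 & !a2 & a3)) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Keep only the x highest-weighting splits
#'
#' @param system A `split_system` (already in total order).
#' @param x Number of splits to keep (all, if `x` exceeds the size).
#' @return The truncated `split_system`.
#' @export
filter_topx <- function(system, x) {
  stopifnot(inherits(system, "split_system"), x >= 0L)
  system_subset(system, seq_len(min(x, n_splits(system))))
}

#' Greedily extract a tree-like (pairwise compatible) subset
#'
#' Scans the splits in decreasing weight order and keeps each split iff
#' it is compatible with every split kept so far. The result is
#' pairwise compatible, hence corresponds to a tree, and contains at
#' most 2n-3 splits (trivial splits included).
#'
#' @param system A `split_system`.
#' @return The filtered `split_system`.
#' @export
filter_strict <- function(system) {
  m <- side_matrix(system)
  kept <- integer(0)
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    for (j in kept) {
      if (!split_compatible(m[i, ], m[j, ])) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  system_subset(system, kept)
}

#' Greedily extract two tree-like subsets
#'
#' Like [filter_strict()], but a split rejected by the first
#' (pairwise compatible) bin is offered to a second bin under the same
#' rule; splits rejected by both are dropped. The union of the two
#' bins is returned in the system's total order; the bin assignment is
#' attached as attribute `bin` (1 or 2, parallel to the rows).
#'
#' @param system A `split_system`.
#' @return The filtered `split_system`, a superset of the
#'   [filter_strict()] result.
#' @export
filter_2tree <- function(system) {
  m <- side_matrix(system)
  t1 <- integer(0); t2 <- integer(0)
  for (i in seq_len(nrow(m))) {
    ok1 <- all(vapply(t1, function(j) split_compatible(m[i, ], m[j, ]),
                      logical(1)))
    if (ok1) { t1 <- c(t1, i); next }
    ok2 <- all(vapply(t2, function(j) split_compatible(m[i, ], m[j, ]),
                      logical(1)))
    if (ok2) t2 <- c(t2, i)
  }
  kept <- sort(c(t1, t2))
  out <- system_subset(system, kept)
  attr(out, "bin") <- ifelse(kept %in% t1, 1L, 2L)
  out
}

#' Greedily extract a weakly compatible subset
#'
#' Scans the splits in decreasing weight order; a candidate is kept iff
#' every triple it forms with two already-kept splits is weakly
#' compatible (with fewer than two kept splits, any candidate is kept:
#' single splits and pairs are always weakly compatible). By induction
#' the kept set is weakly compatible as a whole.
#'
#' @param system A `split_system`.
#' @return The filtered `split_system`.
#' @export
filter_weakly <- function(system) {
  m <- side_matrix(system)
  kept <- integer(0)
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    nk <- length(kept)
    if (nk >= 2L) {
      for (p in 1:(nk - 1L)) {
        for (q in (p + 1L):nk) {
          if (!split_weakly_compatible(m[i, ], m[kept[p], ], m[kept[q], ])) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  system_subset(system, kept)
}

#' Apply a named filter to a split system
#'
#' Dispatch helper used by the command-line interface: `mode` is one of
#' `"none"`, `"topx"`, `"strict"`, `"2tree"`, `"weakly"`.
#'
#' @param system A `split_system`.
#' @param mode Filter name.
#' @param x Number of splits for `mode = "topx"`.
#' @return The filtered `split_system`.
#' @export
filter_splits <- function(system, mode = c("none", "topx", "strict",
                                           "2tree", "weakly"), x = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         none = system,
         topx = {
           if (is.null(x)) stop("filter 'topx' requires x")
           filter_topx(system, x)
         },
         strict = filter_strict(system),
         `2tree` = filter_2tree(system),
         weakly = filter_weakly(system))
}

#' Check pairwise compatibility of a whole system
#'
#' @param system A `split_system`.
#' @return `TRUE` iff every pair of splits is compatible.
#' @export
is_compatible_system <- function(system) {
  m <- side_matrix(system)
  ns <- nrow(m)
  if (ns < 2L) return(TRUE)
  for (i in 1:(ns - 1L)) {
    for (j in (i + 1L):ns) {
      if (!split_compatible(m[i, ], m[j, ])) return(FALSE)
    }
  }
  TRUE
}
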