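# Second pipeline stage: collapse presence/absence patterns into
# canonical splits with two complementary k-mer counts, weight them,
# and keep the system in a total deterministic order.

pattern_complement <- function(p) chartr("01", "10", p)

pattern_popcount <- function(p) {
  nchar(p) - nchar(gsub("1", "", p, fixed = TRUE))
}

#' Canonical side of a bipartition pattern
#'
#' A split is stored by the bit pattern of the smaller of its two
#' sides; for an even split (both sides of size n/2) the side
#' containing the first taxon (bit position 1) is kept, which makes the
#' representation unique and runs deterministic.
#'
#' @param p Character vector of `"0"/"1"` patterns.
#' @return Canonicalized patterns.
#' @keywords internal
canonical_side <- function(p) {
  ones <- pattern_popcount(p)
  n <- nchar(p)
  flip <- ones * 2L > n | (ones * 2L == n & substr(p, 1L, 1L) == "0")
  ifelse(flip, pattern_complement(p), p)
}

pattern_from_indices <- function(idx, n) {
  v <- rep("0", n)
  v[idx] <- "1"
  paste(v, collapse = "")
}

pattern_to_indices <- function(p) {
  which(strsplit(p, "", fixed = TRUE)[[1L]] == "1")
}

#' Aggregate k-mer presence/absence patterns into split counts
#'
#' The color table is scanned once and k-mers sharing the same pattern
#' are counted; each pair of complementary patterns is merged into one
#' split, keyed by its canonical (smaller) side, carrying two counts:
#' the number of distinct k-mers whose pattern equals the side and the
#' number whose pattern equals the complement. k-mers present in every
#' input file separate nothing and are dropped (their number is
#' returned in the `n_core` attribute).
#'
#' @param table A `color_table` from [build_color_table()].
#' @return A `data.table` with columns `side`, `count_side`,
#'   `count_comp`, plus attribute `n_core` (dropped all-ones k-mers).
#' @export
aggregate_splits <- function(table) {
  stopifnot(inherits(table, "color_table"))
  n <- table$n
  if (length(table$patterns) == 0L) {
    out <- data.table::data.table(side = character(0),
                                  count_side = integer(0),
                                  count_comp = integer(0))
    data.table::setattr(out, "n_core", 0L)
    return(out)
  }
  pattern <- NULL; N <- NULL; side <- NULL; is_side <- NULL # NSE bindings
  dt <- data.table::data.table(pattern = table$patterns)[, .N, by = pattern]
  all_ones <- strrep("1", n)
  n_core <- sum(dt[pattern == all_ones, N])
  dt <- dt[pattern != all_ones]
  dt[, side := canonical_side(pattern)]
  dt[, is_side := pattern == side]
  out <- dt[, list(count_side = sum(N[is_side]),
                   count_comp = sum(N[!is_side])), by = side]
  data.table::setattr(out, "n_core", as.integer(n_core))
  out[]
}

#' Split weight: geometric mean of the two pattern counts
#'
#' The two complementary k-mer counts of a split are combined into a
#' single weight as their geometric mean; by default a pseudocount of
#' one is added to each count first, so that one-sided splits (one
#' count zero) still receive a positive weight.
#'
#' @param count_side,count_comp Nonnegative integer vectors.
#' @param pseudocount Add 1 to each count before the geometric mean
#'   (default `TRUE`).
#' @return Numeric vector of weights,
#'   `sqrt((count_side + p) * (count_comp + p))` with `p` 1 or 0.
#' @export
split_weight <- function(count_side, count_comp, pseudocount = TRUE) {
  p <- if (isTRUE(pseudocount)) 1 else 0
  sqrt((as.numeric(count_side) + p) * (as.numeric(count_comp) + p))
}

#' Build the weighted split system from a k-mer table
#'
#' Aggregates the color table into splits, attaches geometric-mean
#' weights and sorts the system by weight (descending), breaking ties
#' by the side bit vector in ascending order, so that output files are
#' byte-reproducible. Trivial splits (single-taxon sides, i.e. leaf
#' edges) are retained like any other split.
#'
#' @param table A `color_table`.
#' @param taxa The matching `taxon_table`.
#' @param pseudocount Passed to [split_weight()].
#' @return A `split_system`: list with `taxa`, `splits` (a `data.table`
#'   with `side`, `count_side`, `count_comp`, `weight`), and `n_core`.
#' @export
build_split_system <- function(table, taxa, pseudocount = TRUE) {
  stopifnot(inherits(table, "color_table"), inherits(taxa, "taxon_table"),
            table$n == taxa$n)
  agg <- aggregate_splits(table)
  agg$weight <- split_weight(agg$count_side, agg$count_comp, pseudocount)
  new_split_system(taxa, agg, n_core = attr(agg, "n_core"))
}

#' Construct a split system from explicit sides and weights
#'
#' Low-level constructor used by the file readers, the tree converter
#' and the test fixtures. Sides are canonicalized, duplicates are
#' rejected, and the system is put into the package's total order
#' (weight descending, side pattern ascending).
#'
#' @param taxa A `taxon_table`.
#' @param splits A data.frame/data.table with columns `side` (bit
#'   pattern strings of length `taxa$n`), `weight`, and optionally
#'   `count_side`/`count_comp`.
#' @param n_core Number of all-ones k-mers dropped upstream (metadata).
#' @return A `split_system`.
#' @export
new_split_system <- function(taxa, splits, n_core = NA_integer_) {
  stopifnot(inherits(taxa, "taxon_table"))
  splits <- data.table::as.data.table(splits)
  if (nrow(splits) == 0L) {
    splits <- data.table::data.table(side = character(0),
                                     count_side = integer(0),
                                     count_comp = integer(0),
                                     weight = numeric(0))
  } else {
    stopifnot(all(c("side", "weight") %in% names(splits)),
              all(nchar(splits$side) == taxa$n))
    if (!"count_side" %in% names(splits)) splits$count_side <- NA_integer_
    if (!"count_comp" %in% names(splits)) splits$count_comp <- NA_integer_
    canon <- canonical_side(splits$side)
    flipped <- canon != splits$side
    if (any(flipped)) { # keep the counts attached to the stored side
      cs <- splits$count_side
      splits$count_side[flipped] <- splits$count_comp[flipped]
      splits$count_comp[flipped] <- cs[flipped]
      splits$side <- canon
    }
    ones <- pattern_popcount(splits$side)
    if (any(ones == 0L)) stop("empty split side")
    if (anyDuplicated(splits$side)) stop("duplicate split")
    data.table::setorderv(splits, c("weight", "side"), order = c(-1L, 1L))
    splits <- splits[, c("side", "count_side", "count_comp", "weight"),
                     with = FALSE]
  }
  structure(list(taxa = taxa, splits = splits,
                 n_core = as.integer(n_core)),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("split_system: ", nrow(x$splits), " splits over ", x$taxa$n,
      " taxa", if (!is.na(x$n_core)) paste0(" (", x$n_core,
      " core k-mers dropped)"), "\n", sep = "")
  if (nrow(x$splits) > 0L) {
    top <- utils::head(x$splits, 5L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %-10.6g %s\n", top$weight[i],
                  paste(x$taxa$names[pattern_to_indices(top$side[i])],
                        collapse = ",")))
    }
    if (nrow(x$splits) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' Number of splits in a system
#' @param system A `split_system`.
#' @export
n_splits <- function(system) nrow(system$splits)

# subset preserving class, taxa and metadata; order is preserved
system_subset <- function(system, idx) {
  out <- system
  out$splits <- system$splits[idx, ]
  out
}

# logical incidence matrix: one row per split, one column per taxon
side_matrix <- function(system) {
  s <- system$splits$side
  if (length(s) == 0L) {
    return(matrix(logical(0), nrow = 0L, ncol = system$taxa$n))
  }
  matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE) == "1",
         nrow = length(s), ncol = system$taxa$n, byrow = TRUE)
}

is_trivial_split <- function(side) pattern_popcount(side) == 1L
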