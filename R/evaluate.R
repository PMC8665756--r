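# Precision/recall of a called split set against a reference tree.

#' Compare called splits against a reference tree
#'
#' The reference tree is decomposed into its splits and both sets are
#' reduced to their nontrivial splits (splits separating a single leaf
#' correspond to leaf edges and are not informative about topology, so
#' they are excluded from both sides). Membership is exact equality of
#' the canonical side; weights play no role.
#'
#' Precision = (called splits also in the reference) / (all called
#' splits); recall = (reference splits also in the call set) / (all
#' reference splits). A zero denominator yields 0 with a warning.
#'
#' @param called A `split_system`.
#' @param reference A `phylo` reference tree, or a `split_system` over
#'   the same taxa.
#' @return A `split_comparison`: list with `n_called_nontrivial`,
#'   `n_ref_nontrivial`, `n_intersection`, `precision`, `recall`.
#' @export
compare_splits <- function(called, reference) {
  stopifnot(inherits(called, "split_system"))
  ref <- if (inherits(reference, "phylo")) {
    tree_to_splits(reference, taxa = called$taxa)
  } else if (inherits(reference, "split_system")) {
    if (!identical(reference$taxa$names, called$taxa$names)) {
      stop("called and reference systems have different taxon tables")
    }
    reference
  } else {
    stop("reference must be a 'phylo' tree or a 'split_system'")
  }
  nontrivial <- function(s) {
    unique(s$splits$side[pattern_popcount(s$splits$side) >= 2L])
  }
  cs <- nontrivial(called)
  rs <- nontrivial(ref)
  ni <- length(intersect(cs, rs))
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning("no nontrivial ", what, " splits; reporting 0")
      return(0)
    }
    num / den
  }
  structure(list(n_called_nontrivial = length(cs),
                 n_ref_nontrivial = length(rs),
                 n_intersection = ni,
                 precision = ratio(ni, length(cs), "called"),
                 recall = ratio(ni, length(rs), "reference")),
            class = "split_comparison")
}

#' @export
print.split_comparison <- function(x, ...) {
  cat(sprintf(
    "split_comparison: called=%d ref=%d shared=%d precision=%.4f recall=%.4f\n",
    x$n_called_nontrivial, x$n_ref_nontrivial, x$n_intersection,
    x$precision, x$recall))
  invisible(x)
}
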