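# Conversion between pairwise-compatible split systems and rooted
# trees (ape "phylo"), plus a deterministic Newick serializer.
#
# A pairwise-compatible split system is exactly the edge set of an
# unrooted tree. Newick needs a root, so each nontrivial split is
# oriented to the side NOT containing the first taxon; by
# compatibility these clusters form a laminar family, which is the
# cluster representation of a tree rooted "at" taxon 1's side.
# Trivial splits become leaf branch lengths (0 if absent).

newick_sanitize <- function(x) gsub("[ ;(),:]", "_", x)

fmt_len <- function(w) sprintf("%.6g", w)

#' Serialize a pairwise-compatible split system to Newick
#'
#' Builds the rooted tree corresponding to the split system (see
#' [splits_to_tree()]) and returns its Newick string: children ordered
#' by their smallest contained taxon index, branch lengths printed with
#' 6 significant digits, labels with the characters
#' `space ; ( ) , :` replaced by `_`, terminated by `;`.
#'
#' @param system A pairwise-compatible `split_system`.
#' @return A single Newick string (no trailing newline).
#' @export
splits_to_newick <- function(system) {
  stopifnot(inherits(system, "split_system"))
  m <- side_matrix(system)
  ns <- nrow(m)
  if (ns >= 2L) {
    for (i in 1:(ns - 1L)) {
      for (j in (i + 1L):ns) {
        if (!split_compatible(m[i, ], m[j, ])) {
          stop("split system is not pairwise compatible: {",
               paste(system$taxa$names[m[i, ]], collapse = ","), "} vs {",
               paste(system$taxa$names[m[j, ]], collapse = ","), "}")
        }
      }
    }
  }
  n <- system$taxa$n
  sides <- system$splits$side
  w <- system$splits$weight
  ones <- pattern_popcount(sides)
  leaf_len <- rep(0, n)
  trivial <- ones == 1L
  for (i in which(trivial)) {
    leaf_len[pattern_to_indices(sides[i])] <- w[i]
  }
  # orient nontrivial clusters away from taxon 1
  clusters <- list(); cw <- numeric(0)
  for (i in which(!trivial)) {
    inc <- m[i, ]
    if (inc[1L]) inc <- !inc
    clusters[[length(clusters) + 1L]] <- which(inc)
    cw <- c(cw, w[i])
  }
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]; cw <- cw[ord]
  root <- list(members = seq_len(n), length = NA_real_,
               children = lapply(seq_len(n), function(i) {
                 list(members = i, length = leaf_len[i], children = list())
               }))
  for (i in seq_along(clusters)) {
    root <- insert_cluster(root, clusters[[i]], cw[i])
  }
  paste0(newick_node(root, system$taxa$names, is_root = TRUE), ";")
}

insert_cluster <- function(node, cl, w) {
  for (j in seq_along(node$children)) {
    ch <- node$children[[j]]
    if (length(ch$members) > length(cl) && all(cl %in% ch$members)) {
      node$children[[j]] <- insert_cluster(ch, cl, w)
      return(node)
    }
  }
  inside <- vapply(node$children,
                   function(ch) all(ch$members %in% cl), logical(1))
  newnode <- list(members = cl, length = w,
                  children = node$children[inside])
  node$children <- c(node$children[!inside], list(newnode))
  node
}

newick_node <- function(node, labels, is_root = FALSE) {
  if (length(node$children) == 0L) {
    return(paste0(newick_sanitize(labels[node$members]), ":",
                  fmt_len(node$length)))
  }
  mins <- vapply(node$children, function(ch) min(ch$members), integer(1))
  parts <- vapply(node$children[order(mins)], newick_node,
                  character(1), labels = labels)
  inner <- paste0("(", paste(parts, collapse = ","), ")")
  if (is_root) inner else paste0(inner, ":", fmt_len(node$length))
}

#' Build a rooted tree from a pairwise-compatible split system
#'
#' Orients every nontrivial split to the side not containing the first
#' taxon (a laminar cluster family), nests the clusters by decreasing
#' size starting from a star tree, and assigns each new internal node
#' the weight of its split as branch length; leaf edges carry the
#' trivial-split weights (0 where the trivial split is absent). The
#' root is synthetic: the tree is rooted for Newick purposes but
#' represents the unrooted split system faithfully.
#'
#' @param system A pairwise-compatible `split_system` (checked; an
#'   error names the first incompatible pair otherwise).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
splits_to_tree <- function(system) {
  ape::read.tree(text = paste0(splits_to_newick(system), "\n"))
}

#' Decompose a tree into its split system
#'
#' Every edge of the tree defines a split (leaf set below the edge
#' versus the rest) with the branch length as weight. Sides are
#' canonicalized as in the rest of the package. In a rooted binary
#' tree the two root edges describe the same unrooted split; duplicate
#' splits arising this way are merged, summing their weights.
#'
#' @param tree A `phylo` object (e.g. from [ape::read.tree()]).
#' @param taxa Optional `taxon_table` fixing the taxon order (defaults
#'   to the tree's tip labels in tip-number order). All tip labels
#'   must resolve to table entries and vice versa.
#' @return A `split_system` with `count_side`/`count_comp` set to `NA`.
#' @export
tree_to_splits <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (is.null(taxa)) taxa <- new_taxon_table(tree$tip.label)
  if (nt != taxa$n || anyNA(match(tree$tip.label, taxa$names))) {
    stop("tree tip labels do not match the taxon table")
  }
  idx <- match(tree$tip.label, taxa$names)
  lens <- tree$edge.length
  if (is.null(lens)) lens <- rep(1, nrow(tree$edge))
  po <- ape::reorder.phylo(tree, "postorder")
  polens <- lens[match(paste(po$edge[, 1], po$edge[, 2]),
                       paste(tree$edge[, 1], tree$edge[, 2]))]
  below <- vector("list", nt + tree$Nnode)
  below[seq_len(nt)] <- as.list(idx)
  sides <- character(nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[ch]])
    sides[e] <- pattern_from_indices(below[[ch]], taxa$n)
  }
  keep <- pattern_popcount(sides) < taxa$n # drop a root edge to all tips
  dt <- data.table::data.table(side = canonical_side(sides[keep]),
                               weight = polens[keep])
  side <- NULL; weight <- NULL
  dt <- dt[, list(weight = sum(weight)), by = side]
  new_split_system(taxa, dt)
}
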