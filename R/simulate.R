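# Synthetic data with known ground truth: random binary trees,
# sequences evolved along them under a Jukes-Cantor-like per-edge
# substitution model, and optional IUPAC (N) corruption. Stands in for
# real bacterial assemblies in all tests; every function is
# bit-reproducible given a seed.

#' Simulate a random binary tree
#'
#' Builds a rooted binary topology by sequential random joins: starting
#' from `n_taxa` singleton lineages, two uniformly chosen lineages are
#' joined until one remains. Every edge gets branch length 1 (the
#' substitution process below is parameterized per edge, not per unit
#' length).
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Optional RNG seed for reproducibility.
#' @param labels Leaf labels (default `t01`, `t02`, ...).
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed = NULL,
                          labels = sprintf("t%02d", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 2L, length(labels) == n_taxa)
  if (!is.null(seed)) set.seed(seed)
  items <- as.list(labels)
  while (length(items) > 1L) {
    i <- sample.int(length(items), 2L)
    merged <- sprintf("(%s:1,%s:1)", items[[i[1L]]], items[[i[2L]]])
    items <- c(items[-i], list(merged))
  }
  ape::read.tree(text = paste0(items[[1L]], ";"))
}

#' Evolve sequences along a tree and write one FASTA per leaf
#'
#' A uniform-random root sequence of `seq_length` bases evolves down
#' the tree; on every edge each site is substituted independently with
#' probability `sub_prob`, drawing uniformly among the three
#' alternative bases. Writes `<label>.fasta` per leaf into `out_dir`,
#' plus the input list file (`genomes.txt`, absolute paths) and the
#' true tree (`true_tree.nwk`).
#'
#' @param tree A `phylo` tree (leaf labels become file names).
#' @param out_dir Output directory (created if needed).
#' @param seq_length Genome length in bases (default 10000).
#' @param sub_prob Per-site substitution probability per edge
#'   (default 0.01).
#' @param seed Optional RNG seed.
#' @return List with `fasta` (paths per leaf), `list_file`,
#'   `tree_file` and `tree`.
#' @export
evolve_sequences <- function(tree, out_dir, seq_length = 10000L,
                             sub_prob = 0.01, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), seq_length >= 1L,
            sub_prob >= 0, sub_prob < 1)
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  nt <- length(tree$tip.label)
  root <- nt + 1L
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    x <- seqs[[par]]
    mut <- which(stats::runif(seq_length) < sub_prob)
    if (length(mut)) {
      x[mut] <- (x[mut] - 1L + sample.int(3L, length(mut),
                                          replace = TRUE)) %% 4L + 1L
    }
    seqs[[ch]] <- x
  }
  fasta <- file.path(out_dir, paste0(tree$tip.label, ".fasta"))
  for (i in seq_len(nt)) {
    s <- Biostrings::DNAStringSet(paste(bases[seqs[[i]]], collapse = ""))
    names(s) <- tree$tip.label[i]
    Biostrings::writeXStringSet(s, fasta[i])
  }
  list_file <- file.path(out_dir, "genomes.txt")
  writeLines(normalizePath(fasta), list_file)
  tree_file <- file.path(out_dir, "true_tree.nwk")
  ape::write.tree(tree, tree_file)
  list(fasta = fasta, list_file = list_file, tree_file = tree_file,
       tree = tree)
}

#' Replace random bases by the ambiguity code N
#'
#' Reads a FASTA file and independently replaces each base by `N` with
#' probability `n_prob`, emulating ambiguous positions in real
#' assemblies; writes the corrupted records to `fasta_out`.
#'
#' @param fasta_in Input FASTA path.
#' @param fasta_out Output FASTA path.
#' @param n_prob Per-site corruption probability in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return Invisibly, `fasta_out`.
#' @export
corrupt_with_iupac <- function(fasta_in, fasta_out, n_prob, seed = NULL) {
  stopifnot(n_prob >= 0, n_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  recs <- Biostrings::readBStringSet(fasta_in)
  out <- vapply(as.character(recs), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[stats::runif(length(ch)) < n_prob] <- "N"
    paste(ch, collapse = "")
  }, character(1))
  res <- Biostrings::BStringSet(out)
  names(res) <- names(recs)
  Biostrings::writeXStringSet(res, fasta_out)
  invisible(fasta_out)
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper: random tree, evolved genomes, and (optionally)
#' N-corrupted copies of every genome in `<out_dir>/corrupted` with
#' their own list file.
#'
#' @param out_dir Output directory.
#' @param n_taxa,seq_length,sub_prob,seed See [simulate_tree()] and
#'   [evolve_sequences()].
#' @param n_prob Per-site N probability for the corrupted copy (0
#'   disables the copy).
#' @return The [evolve_sequences()] result, plus `corrupted_list_file`
#'   when `n_prob > 0`.
#' @export
simulate_dataset <- function(out_dir, n_taxa = 20L, seq_length = 10000L,
                             sub_prob = 0.01, n_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(n_taxa)
  res <- evolve_sequences(tree, out_dir, seq_length = seq_length,
                          sub_prob = sub_prob)
  if (n_prob > 0) {
    cdir <- file.path(out_dir, "corrupted")
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    cfasta <- file.path(cdir, basename(res$fasta))
    for (i in seq_along(res$fasta)) {
      corrupt_with_iupac(res$fasta[i], cfasta[i], n_prob = n_prob)
    }
    clist <- file.path(cdir, "genomes.txt")
    writeLines(normalizePath(cfasta), clist)
    res$corrupted_fasta <- cfasta
    res$corrupted_list_file <- clist
  }
  res
}
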