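# Independent oracles and fixture builders. Everything here is
# deliberately written with plain loops, string slicing and base set
# operations, sharing no code path with the package implementation.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  out <- character(length(x))
  for (i in seq_along(x)) out[i] <- if (x[i] <= rc[i]) x[i] else rc[i]
  out
}

# set of canonical k-mers of one A/C/G/T record, by string slicing
oracle_kmer_set <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  km <- character(L - k + 1)
  for (i in seq_len(L - k + 1)) km[i] <- substr(s, i, i + k - 1)
  unique(oracle_canonical(km))
}

# genomes: list (one element per taxon) of character vectors of records
# returns list(kmer = chr, pattern = chr) sorted by kmer
oracle_color_table <- function(genomes, k) {
  sets <- lapply(genomes, function(recs) {
    unique(unlist(lapply(recs, oracle_kmer_set, k = k)))
  })
  all_k <- sort(unique(unlist(sets)))
  pat <- vapply(all_k, function(km) {
    paste(ifelse(vapply(sets, function(s) km %in% s, logical(1)), "1", "0"),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  list(kmer = all_k, pattern = pat)
}

# group patterns into split -> (count_side, count_comp); complements
# merged; canonical = fewer ones, tie -> first char "1"
oracle_split_counts <- function(patterns, n) {
  tab <- table(patterns)
  out <- list()
  for (p in names(tab)) {
    ones <- sum(strsplit(p, "")[[1]] == "1")
    if (ones == n) next
    comp <- chartr("01", "10", p)
    canon <- if (ones * 2 < n || (ones * 2 == n && substr(p, 1, 1) == "1"))
      p else comp
    if (is.null(out[[canon]])) out[[canon]] <- c(0L, 0L)
    slot <- if (p == canon) 1L else 2L
    out[[canon]][slot] <- out[[canon]][slot] + as.integer(tab[[p]])
  }
  out
}

# compatibility by explicit index-set intersections
oracle_compatible <- function(A, B, n) {
  U <- seq_len(n)
  Ac <- setdiff(U, A); Bc <- setdiff(U, B)
  length(intersect(A, B)) == 0 || length(intersect(A, Bc)) == 0 ||
    length(intersect(Ac, B)) == 0 || length(intersect(Ac, Bc)) == 0
}

# brute-force weak compatibility over all 8 orientations
oracle_weakly_compatible <- function(A, B, C, n) {
  U <- seq_len(n)
  for (A1 in list(A, setdiff(U, A))) {
    for (A2 in list(B, setdiff(U, B))) {
      for (A3 in list(C, setdiff(U, C))) {
        B1 <- setdiff(U, A1); B2 <- setdiff(U, A2); B3 <- setdiff(U, A3)
        if (length(intersect(intersect(A1, A2), A3)) > 0 &&
            length(intersect(intersect(A1, B2), B3)) > 0 &&
            length(intersect(intersect(B1, A2), B3)) > 0 &&
            length(intersect(intersect(B1, B2), A3)) > 0) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# --- fixture builders -------------------------------------------------

write_genomes <- function(genomes, dir = tempfile("genomes")) {
  # genomes: named list of character vectors of records; returns the
  # list-file path
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(genomes))
  for (i in seq_along(genomes)) {
    fa <- file.path(dir, paste0(names(genomes)[i], ".fa"))
    writeLines(as.vector(rbind(paste0(">r", seq_along(genomes[[i]])),
                               genomes[[i]])), fa)
    paths[i] <- fa
  }
  lf <- file.path(dir, "list.txt")
  writeLines(paths, lf)
  lf
}

make_taxa <- function(n, labels = sprintf("g%d", seq_len(n))) {
  new_taxon_table(labels)
}

sides_system <- function(taxa, sides, weights) {
  # sides: list of taxon-index vectors
  pat <- vapply(sides, function(ix) {
    v <- rep("0", taxa$n); v[ix] <- "1"; paste(v, collapse = "")
  }, character(1))
  new_split_system(taxa, data.frame(side = pat, weight = weights))
}

# every bipartition of n taxa (canonical, unique), as index vectors
all_bipartitions <- function(n) {
  seen <- character(0)
  out <- list()
  for (m in 1:(2^n - 2)) {
    bits <- as.integer(intToBits(m)[1:n])
    p <- paste(bits, collapse = "")
    ones <- sum(bits)
    comp <- chartr("01", "10", p)
    canon <- if (ones * 2 < n || (ones * 2 == n && bits[1] == 1)) p else comp
    if (canon %in% seen) next
    seen <- c(seen, canon)
    out[[length(out) + 1]] <- which(strsplit(canon, "")[[1]] == "1")
  }
  out
}

split_side_indices <- function(system) {
  lapply(system$splits$side, function(p) which(strsplit(p, "")[[1]] == "1"))
}
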