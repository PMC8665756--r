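# k-mer extraction: sliding window, IUPAC expansion, canonicalization,
# and the first hash table (k-mer -> presence/absence pattern).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Expand a window containing IUPAC ambiguity codes
#'
#' Every ambiguity code is replaced by each of the bases it denotes and
#' the Cartesian product over all positions is returned (`N` expands to
#' 4 bases, `R` to `{A,G}`, three-base codes `B/D/H/V` to 3, ...). A
#' window containing any character outside the IUPAC nucleotide
#' alphabet, or whose expansion would exceed `cap` words, yields an
#' empty vector (the caller counts such skipped windows).
#'
#' @param window Character string of length k (uppercase).
#' @param cap Maximum number of expanded words (default 64).
#' @return Character vector of words over `{A,C,G,T}` (possibly empty).
#' @examples
#' expand_iupac("ANT")   # 4 words
#' expand_iupac("A-G")   # character(0): invalid character
#' @export
expand_iupac <- function(window, cap = 64L) {
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% names(IUPAC_SETS))) return(character(0))
  sets <- IUPAC_SETS[ch]
  if (prod(lengths(sets)) > cap) return(character(0))
  if (all(lengths(sets) == 1L)) return(window)
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

#' Reverse complement and canonical form of k-mers
#'
#' `revcomp_kmer` reverse-complements words over `{A,C,G,T}`;
#' `canonical_kmer` returns, per word, the smaller of the word and its
#' reverse complement under the 2-bit base order A < C < G < T (which
#' coincides with lexicographic order), making k-mer counting
#' strand-independent.
#'
#' @param x Character vector of DNA words (A/C/G/T only).
#' @return Character vector of the same length.
#' @export
revcomp_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp_kmer
#' @export
canonical_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp_kmer(x)
  ifelse(x <= rc, x, rc)
}

#' 2-bit integer encoding of k-mers
#'
#' Packs a DNA word into an integer with 2 bits per base (A=00, C=01,
#' G=10, T=11; first base in the most significant pair). Exact for
#' k <= 26 (the code is held in a double, exact up to 2^53); the
#' pipeline itself orders k-mers lexicographically, which induces the
#' identical order for any k.
#'
#' @param x Character vector of DNA words, all of one length k <= 26.
#' @param code Numeric vector of codes.
#' @param k Word length.
#' @return `encode_kmer`: numeric codes; `decode_kmer`: DNA words.
#' @export
encode_kmer <- function(x) {
  k <- unique(nchar(x))
  stopifnot(length(k) == 1L, k <= 26L)
  m <- vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    v <- match(ch, c("A", "C", "G", "T")) - 1
    if (anyNA(v)) stop("encode_kmer: non-ACGT character")
    sum(v * 4^((k - 1):0))
  }, numeric(1))
  m
}

#' @rdname encode_kmer
#' @export
decode_kmer <- function(code, k) {
  vapply(code, function(cd) {
    out <- character(k)
    for (i in k:1) {
      out[i] <- c("A", "C", "G", "T")[cd %% 4 + 1]
      cd <- cd %/% 4
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Extract canonical k-mers from one sequence record
#'
#' Slides a window of length `k` over the record; windows never span
#' record boundaries. Windows of plain A/C/G/T are taken directly;
#' windows containing IUPAC ambiguity codes are expanded via
#' [expand_iupac()] (subject to `iupac_cap`); windows containing any
#' other character, or exceeding the expansion cap, are skipped and
#' counted.
#'
#' @param seq One uppercase sequence string.
#' @param k Window length (>= 1).
#' @param iupac_cap Maximum expansions per window; `0` disables
#'   ambiguity handling entirely (all ambiguous windows are skipped),
#'   mirroring a plain k-mer counter.
#' @return List with `kmers` (canonical k-mers, with multiplicity) and
#'   `skipped` (number of windows dropped).
#' @export
extract_kmers <- function(seq, k, iupac_cap = 64L) {
  stopifnot(k >= 1L)
  seq <- chartr("Uu", "Tt", toupper(seq))
  L <- nchar(seq)
  if (L < k) return(list(kmers = character(0), skipped = 0L))
  nw <- L - k + 1L
  bad <- gregexpr("[^ACGT]", seq)[[1L]]
  if (bad[1L] == -1L) {
    return(list(kmers = canonical_kmer(substring(seq, 1:nw, k:L)),
                skipped = 0L))
  }
  touched <- logical(nw)
  for (b in as.integer(bad)) {
    lo <- max(1L, b - k + 1L)
    hi <- min(b, nw)
    if (lo <= hi) touched[lo:hi] <- TRUE
  }
  idx <- which(!touched)
  kmers <- if (length(idx)) substring(seq, idx, idx + k - 1L) else character(0)
  skipped <- 0L
  for (i in which(touched)) {
    ex <- expand_iupac(substr(seq, i, i + k - 1L), cap = iupac_cap)
    if (length(ex) == 0L) skipped <- skipped + 1L else kmers <- c(kmers, ex)
  }
  list(kmers = canonical_kmer(kmers), skipped = skipped)
}

#' Build the k-mer presence/absence table over all input genomes
#'
#' First pipeline stage: every input file is scanned with a sliding
#' window of length `k`; each (expanded, canonicalized) k-mer is stored
#' once as a key, and its value records in which input files it was
#' observed, as a bit pattern of length `n` whose i-th position is 1
#' iff the k-mer occurs in the i-th file of the taxon table. Presence
#' is binary: multiplicity within a file is ignored.
#'
#' @param taxa A `taxon_table` from [load_taxon_table()].
#' @param k k-mer length (default 31).
#' @param iupac_cap Per-window expansion cap; 0 skips all ambiguous
#'   windows (see [extract_kmers()]).
#' @param verbose Log per-file progress via `message()`.
#' @return A `color_table`: list with `kmers` (character vector of
#'   canonical k-mers), `patterns` (parallel vector of `"0"/"1"`
#'   strings of length `n`), `k`, `n` and `skipped_windows`.
#' @export
build_color_table <- function(taxa, k = 31L, iupac_cap = 64L,
                              verbose = FALSE) {
  stopifnot(inherits(taxa, "taxon_table"), k >= 1L)
  n <- taxa$n
  skipped <- 0L
  per_file <- vector("list", n)
  for (i in seq_len(n)) {
    recs <- read_sequences(taxa$paths[i])
    got <- lapply(recs, extract_kmers, k = k, iupac_cap = iupac_cap)
    skipped <- skipped + sum(vapply(got, `[[`, integer(1), "skipped"))
    km <- unique(unlist(lapply(got, `[[`, "kmers"), use.names = FALSE))
    per_file[[i]] <- km
    if (verbose) {
      message("[kmersplits] ", taxa$names[i], ": ", length(recs),
              " record(s), ", length(km), " distinct canonical ", k, "-mers")
    }
  }
  nk <- vapply(per_file, length, integer(1))
  if (sum(nk) == 0L) {
    warning("no k-mers extracted (k = ", k,
            " may exceed every sequence length)")
    return(new_color_table(character(0), character(0), k, n, skipped))
  }
  all_k <- unlist(per_file, use.names = FALSE)
  uk <- sort(unique(all_k))
  mat <- matrix(0L, nrow = length(uk), ncol = n)
  mat[cbind(match(all_k, uk), rep.int(seq_len(n), nk))] <- 1L
  patterns <- do.call(paste0, lapply(seq_len(n), function(j) mat[, j]))
  new_color_table(uk, patterns, k, n, skipped)
}

new_color_table <- function(kmers, patterns, k, n, skipped_windows = 0L) {
  structure(list(kmers = kmers, patterns = patterns, k = as.integer(k),
                 n = as.integer(n),
                 skipped_windows = as.integer(skipped_windows)),
            class = "color_table")
}

#' @export
print.color_table <- function(x, ...) {
  cat("color_table: ", length(x$kmers), " canonical ", x$k, "-mers over ",
      x$n, " genomes (", x$skipped_windows, " windows skipped)\n", sep = "")
  invisible(x)
}
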