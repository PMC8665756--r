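#' Load the ordered taxon table from an input list file
#'
#' The input list is a plain-text file with one genome file per line
#' (FASTA or FASTQ, optionally gzip-compressed). A line may carry an
#' explicit taxon label after a tab (`path<TAB>label`); otherwise the
#' label defaults to the file's basename with all extensions stripped
#' (`"g1.fa.gz"` becomes `"g1"`). Empty lines and lines starting with
#' `#` are ignored. Line order defines the taxon order, and thereby the
#' bit position of each genome in every presence/absence pattern, so it
#' must be stable across runs.
#'
#' Relative paths are resolved against the directory containing the
#' list file if they do not resolve from the working directory.
#'
#' @param list_path Path to the list file.
#' @return A `taxon_table`: list with `names` (unique labels), `paths`
#'   and `n`, preserving the file's line order.
#' @examples
#' f <- tempfile()
#' writeLines(c("# two genomes", "a.fa", "b.fa\tSampleB"), f)
#' load_taxon_table(f)
#' @export
load_taxon_table <- function(list_path) {
  if (!file.exists(list_path)) {
    stop("input list file not found: ", list_path)
  }
  lines <- trimws(readLines(list_path, warn = FALSE))
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    stop("input list file is empty: ", list_path)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  paths <- vapply(parts, function(p) trimws(p[[1L]]), character(1))
  labels <- vapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(trimws(p[[2L]]))) trimws(p[[2L]]) else ""
  }, character(1))
  auto <- !nzchar(labels)
  labels[auto] <- default_taxon_label(paths[auto])
  dup <- duplicated(labels)
  if (any(dup)) {
    first <- match(labels[dup][1L], labels)
    stop("duplicate taxon label '", labels[dup][1L], "' (lines ",
         lineno[first], " and ", lineno[which(dup)[1L]], " of ", list_path, ")")
  }
  # resolve paths relative to the list file when needed
  base <- dirname(normalizePath(list_path))
  rel <- !file.exists(paths) & file.exists(file.path(base, paths))
  paths[rel] <- file.path(base, paths[rel])
  new_taxon_table(labels, paths)
}

default_taxon_label <- function(path) {
  sub("\\..*$", "", basename(path))
}

#' @rdname load_taxon_table
#' @param names Character vector of unique taxon labels.
#' @param paths Character vector of file paths (may be `NA` for
#'   in-memory systems, e.g. in tests).
#' @export
new_taxon_table <- function(names, paths = rep(NA_character_, length(names))) {
  names <- as.character(names)
  stopifnot(length(names) >= 1L, length(paths) == length(names))
  if (anyDuplicated(names) || any(!nzchar(names))) {
    stop("taxon labels must be unique and non-empty")
  }
  structure(list(names = names, paths = as.character(paths),
                 n = length(names)),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("taxon_table with", x$n, "taxa:", paste(utils::head(x$names, 8L),
      collapse = ", "), if (x$n > 8L) "..." else "", "\n")
  invisible(x)
}

detect_seq_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    line <- trimws(line)
    if (nzchar(line)) break
  }
  first <- substr(line, 1L, 1L)
  if (first == ">") "fasta" else if (first == "@") "fastq" else NA_character_
}

#' Read all sequences from one genome file
#'
#' Reads a FASTA or FASTQ file (plain or gzip; format auto-detected from
#' the first record character) and returns the record sequences as
#' uppercase character strings with `U` mapped to `T`. FASTQ quality
#' lines are discarded. All records in one file belong to the same
#' taxon: the pipeline treats a file as one genome regardless of how
#' many contigs or reads it contains.
#'
#' @param path Path to a FASTA/FASTQ file, optionally `.gz`.
#' @return Character vector of record sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("sequence file not found: ", path)
  fmt <- detect_seq_format(path)
  if (is.na(fmt)) {
    con <- gzfile(path, "rt")
    nlines <- length(readLines(con, warn = FALSE))
    close(con)
    if (nlines == 0L) {
      warning("empty sequence file: ", path)
      return(character(0))
    }
    stop("cannot detect FASTA/FASTQ format of ", path,
         " (first record must start with '>' or '@')")
  }
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) {
      stop("failed to parse ", fmt, " file ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (length(recs) == 0L) {
    warning("no records in sequence file: ", path)
    return(character(0))
  }
  chartr("Uu", "Tt", toupper(unname(as.character(recs))))
}
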