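# Serialization of split systems: the tab-separated split table
# (weight + taxon names of the smaller side), a minimal NEXUS
# TAXA+SPLITS file for split-network viewers, and the matching readers
# used for round trips and for re-filtering saved runs.

#' Write a split system as a tab-separated split table
#'
#' One line per split, in system order (weight descending): the weight
#' (6 significant digits), a tab, then the taxon names of the
#' canonical (smaller) side, tab-separated. The complementary side is
#' implied by the taxon table. Output is byte-reproducible.
#'
#' @param system A `split_system`.
#' @param out Output file path.
#' @return Invisibly, `out`.
#' @export
write_splits_tsv <- function(system, out) {
  stopifnot(inherits(system, "split_system"))
  lines <- character(n_splits(system))
  for (i in seq_len(n_splits(system))) {
    nm <- system$taxa$names[pattern_to_indices(system$splits$side[i])]
    lines[i] <- paste(c(fmt_len(system$splits$weight[i]), nm),
                      collapse = "\t")
  }
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(out)
}

#' Read a split table written by [write_splits_tsv()]
#'
#' @param path Path to the TSV file.
#' @param taxa The `taxon_table` the sides refer to.
#' @return A `split_system` (counts are `NA`; weights as parsed).
#' @export
read_splits_tsv <- function(path, taxa) {
  stopifnot(inherits(taxa, "taxon_table"))
  if (!file.exists(path)) stop("split table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_split_system(taxa, NULL))
  }
  sides <- character(length(lines))
  weights <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    w <- suppressWarnings(as.numeric(parts[1L]))
    if (is.na(w) || length(parts) < 2L) {
      stop("malformed split table line ", i, " in ", path)
    }
    hit <- match(parts[-1L], taxa$names)
    if (anyNA(hit)) {
      stop("unknown taxon name '", parts[-1L][which(is.na(hit))[1L]],
           "' on line ", i, " of ", path)
    }
    sides[i] <- pattern_from_indices(hit, taxa$n)
    weights[i] <- w
  }
  new_split_system(taxa, data.frame(side = sides, weight = weights))
}

#' Write a split system as a NEXUS splits file
#'
#' Emits a minimal NEXUS file with a TAXA block (quoted labels,
#' 1-based indices) and a SPLITS block (per split: weight and the
#' 1-based taxon indices of the canonical side), as consumed by
#' split-network visualization software.
#'
#' @param system A `split_system`.
#' @param out Output file path.
#' @return Invisibly, `out`.
#' @export
write_nexus_splits <- function(system, out) {
  stopifnot(inherits(system, "split_system"))
  n <- system$taxa$n
  ns <- n_splits(system)
  lab <- gsub("'", "_", system$taxa$names)
  lines <- c(
    "#NEXUS",
    "",
    "BEGIN TAXA;",
    sprintf("DIMENSIONS NTAX=%d;", n),
    "TAXLABELS",
    sprintf("[%d] '%s'", seq_len(n), lab),
    ";",
    "END;",
    "",
    "BEGIN SPLITS;",
    sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", n, ns),
    "FORMAT LABELS=NO WEIGHTS=YES;",
    "MATRIX")
  for (i in seq_len(ns)) {
    lines <- c(lines, sprintf("[%d]\t%s\t%s,", i,
                              fmt_len(system$splits$weight[i]),
                              paste(pattern_to_indices(system$splits$side[i]),
                                    collapse = " ")))
  }
  lines <- c(lines, ";", "END;")
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(out)
}

#' Read a NEXUS splits file written by [write_nexus_splits()]
#'
#' Minimal reader for the dialect this package writes; used for round
#' trips in tests and to re-import saved runs.
#'
#' @param path Path to the NEXUS file.
#' @return A `split_system` (counts are `NA`).
#' @export
read_nexus_splits <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (length(lines) == 0L || lines[1L] != "#NEXUS") {
    stop("not a NEXUS file: ", path)
  }
  tl <- grep("^\\[\\d+\\] '", lines)
  if (length(tl) == 0L) stop("no TAXLABELS entries in ", path)
  labels <- sub("^\\[\\d+\\] '(.*)'$", "\\1", lines[tl])
  taxa <- new_taxon_table(labels)
  mstart <- which(lines == "MATRIX")
  if (length(mstart) != 1L) stop("no MATRIX in SPLITS block of ", path)
  sides <- character(0); weights <- numeric(0)
  for (i in (mstart + 1L):length(lines)) {
    if (lines[i] == ";") break
    body <- sub("^\\[\\d+\\]\\s*", "", sub(",$", "", lines[i]))
    parts <- strsplit(body, "[\t ]+")[[1L]]
    weights <- c(weights, as.numeric(parts[1L]))
    sides <- c(sides,
               pattern_from_indices(as.integer(parts[-1L]), taxa$n))
  }
  if (length(sides) == 0L) return(new_split_system(taxa, NULL))
  new_split_system(taxa, data.frame(side = sides, weight = weights))
}
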