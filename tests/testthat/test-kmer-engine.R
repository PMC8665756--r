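test_that("reverse complement and canonical form match the oracle", {
  expect_equal(revcomp_kmer("ACG"), "CGT")
  expect_equal(revcomp_kmer("AT"), "AT")
  expect_equal(canonical_kmer("CGT"), "ACG")
  expect_equal(canonical_kmer(c("AAA", "TTT")), c("AAA", "AAA"))
  set.seed(11)
  for (k in c(3, 5, 8)) {
    x <- vapply(1:50, function(i) random_dna(k), character(1))
    expect_identical(revcomp_kmer(revcomp_kmer(x)), x) # involution
    expect_identical(revcomp_kmer(x), oracle_revcomp(x))
    expect_identical(canonical_kmer(x), oracle_canonical(x))
    expect_identical(canonical_kmer(canonical_kmer(x)), canonical_kmer(x))
  }
})

test_that("2-bit encoding round-trips and orders like strings", {
  set.seed(3)
  for (k in c(1, 7, 26)) {
    x <- unique(vapply(1:30, function(i) random_dna(k), character(1)))
    expect_identical(decode_kmer(encode_kmer(x), k), x)
    expect_identical(order(encode_kmer(x)), order(x))
  }
  expect_equal(encode_kmer("ACGT"), 0 * 64 + 1 * 16 + 2 * 4 + 3)
})

test_that("expand_iupac expands ambiguity codes and rejects junk", {
  expect_equal(expand_iupac("ACG"), "ACG")
  expect_setequal(expand_iupac("ANT"), c("AAT", "ACT", "AGT", "ATT"))
  expect_setequal(expand_iupac("RY"), c("AC", "AT", "GC", "GT"))
  expect_equal(sort(expand_iupac("BDT")), # 3 x 3 words
               sort(as.vector(outer(c("C", "G", "T"), c("A", "G", "T"),
                                    function(a, b) paste0(a, b, "T")))))
  expect_length(expand_iupac("A-G"), 0) # non-IUPAC character
  expect_length(expand_iupac("NNNN", cap = 64L), 0) # 256 > cap
  expect_length(expand_iupac("NNN", cap = 64L), 4^3)
})

test_that("extract_kmers slides, skips and expands correctly", {
  got <- extract_kmers("ACGT", 3)
  expect_setequal(got$kmers, c("ACG", "ACG")) # CGT canonicalizes to ACG
  expect_equal(got$skipped, 0L)
  # invalid character invalidates exactly the windows covering it
  got <- extract_kmers("ACG-TACG", 3)
  expect_equal(got$skipped, 3L)
  expect_setequal(got$kmers, canonical_kmer(c("TAC", "ACG")))
  # ambiguity expansion at the window level
  got <- extract_kmers("ACGTN", 3, iupac_cap = 64L)
  expect_setequal(got$kmers,
                  canonical_kmer(c("ACG", "CGT", "GTA", "GTC", "GTG", "GTT")))
  # cap = 0 disables expansion: ambiguous windows are skipped
  got0 <- extract_kmers("ACGTN", 3, iupac_cap = 0L)
  expect_setequal(got0$kmers, canonical_kmer(c("ACG", "CGT")))
  expect_equal(got0$skipped, 1L)
  # short sequences yield nothing
  expect_length(extract_kmers("AC", 3)$kmers, 0)
})

test_that("build_color_table matches the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    k <- sample(3:7, 1)
    genomes <- lapply(seq_len(n), function(i) {
      vapply(seq_len(sample(1:3, 1)),
             function(j) random_dna(sample(k:60, 1)), character(1))
    })
    names(genomes) <- sprintf("g%d", seq_len(n))
    lf <- write_genomes(genomes)
    taxa <- load_taxon_table(lf)
    ct <- build_color_table(taxa, k = k)
    orc <- oracle_color_table(genomes, k)
    expect_identical(ct$kmers, orc$kmer)
    expect_identical(ct$patterns, orc$pattern)
    unlink(dirname(lf), recursive = TRUE)
  }
})

test_that("color table is invariant to record order, file order, strand", {
  set.seed(55)
  genomes <- list(g1 = c(random_dna(60), random_dna(40)),
                  g2 = c(random_dna(50)),
                  g3 = c(random_dna(70), random_dna(30)))
  base_lf <- write_genomes(genomes)
  base <- build_color_table(load_taxon_table(base_lf), k = 5)

  # permute records within a file
  perm <- genomes
  perm$g1 <- rev(perm$g1)
  ct2 <- build_color_table(load_taxon_table(write_genomes(perm)), k = 5)
  expect_identical(base[c("kmers", "patterns")], ct2[c("kmers", "patterns")])

  # reverse-complement an entire genome
  rc <- genomes
  rc$g2 <- oracle_revcomp(rc$g2)
  ct3 <- build_color_table(load_taxon_table(write_genomes(rc)), k = 5)
  expect_identical(base[c("kmers", "patterns")], ct3[c("kmers", "patterns")])

  # processing order of files is fixed by the list file: permuting the
  # list permutes pattern columns consistently
  d <- dirname(base_lf)
  lf_perm <- file.path(d, "perm.txt")
  writeLines(rev(readLines(base_lf)), lf_perm)
  ct4 <- build_color_table(load_taxon_table(lf_perm), k = 5)
  expect_identical(ct4$kmers, base$kmers)
  flip <- function(p) vapply(strsplit(p, ""), function(b)
    paste(rev(b), collapse = ""), character(1))
  expect_identical(ct4$patterns, flip(base$patterns))
})

test_that("k exceeding every sequence yields an empty table with warning", {
  lf <- write_genomes(list(g1 = "ACGT", g2 = "GGTT"))
  expect_warning(ct <- build_color_table(load_taxon_table(lf), k = 10),
                 "no k-mers")
  expect_length(ct$kmers, 0)
})
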