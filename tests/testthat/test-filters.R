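as_logical_side <- function(ix, n) seq_len(n) %in% ix

test_that("split_compatible matches the set-intersection oracle", {
  n <- 5
  expect_true(split_compatible(as_logical_side(1, n),
                               as_logical_side(2, n)))
  expect_false(split_compatible(as_logical_side(c(1, 2), 4),
                                as_logical_side(c(1, 3), 4)))
  expect_true(split_compatible(as_logical_side(c(1, 2), n),
                               as_logical_side(c(1, 2, 3), n)))
  set.seed(21)
  for (rep in 1:200) {
    nn <- sample(3:7, 1)
    A <- sample(seq_len(nn), sample(1:(nn - 1), 1))
    B <- sample(seq_len(nn), sample(1:(nn - 1), 1))
    expect_equal(split_compatible(as_logical_side(A, nn),
                                  as_logical_side(B, nn)),
                 oracle_compatible(A, B, nn))
  }
})

test_that("split_weakly_compatible matches brute-force orientation check", {
  # the three conflicting quartet splits are NOT weakly compatible
  q <- lapply(list(c(1, 2), c(1, 3), c(1, 4)), as_logical_side, n = 4)
  expect_false(split_weakly_compatible(q[[1]], q[[2]], q[[3]]))
  # any pairwise-compatible triple is weakly compatible
  t5 <- lapply(list(c(1, 2), c(4, 5), 3), as_logical_side, n = 5)
  expect_true(split_weakly_compatible(t5[[1]], t5[[2]], t5[[3]]))
  set.seed(31)
  for (rep in 1:150) {
    nn <- sample(4:7, 1)
    tri <- lapply(1:3, function(i) sample(seq_len(nn),
                                          sample(1:(nn - 1), 1)))
    got <- split_weakly_compatible(as_logical_side(tri[[1]], nn),
                                   as_logical_side(tri[[2]], nn),
                                   as_logical_side(tri[[3]], nn))
    expect_equal(got, oracle_weakly_compatible(tri[[1]], tri[[2]],
                                               tri[[3]], nn))
    # symmetry under permutation
    expect_equal(got, split_weakly_compatible(as_logical_side(tri[[3]], nn),
                                              as_logical_side(tri[[1]], nn),
                                              as_logical_side(tri[[2]], nn)))
  }
})

test_that("filter_topx truncates the sorted system", {
  taxa <- make_taxa(4)
  sys <- sides_system(taxa, all_bipartitions(4), weights = 7:1)
  expect_equal(n_splits(filter_topx(sys, 0)), 0L)
  expect_equal(n_splits(filter_topx(sys, 3)), 3L)
  expect_identical(filter_topx(sys, 99)$splits, sys$splits)
  expect_equal(filter_topx(sys, 3)$splits$weight, c(7, 6, 5))
})

test_that("filter_strict greedily builds a tree-like subset", {
  taxa <- make_taxa(4)
  # all 7 splits of 4 taxa; make {1,2}|{3,4} the best nontrivial
  sides <- all_bipartitions(4)
  sizes <- lengths(sides)
  w <- ifelse(sizes == 1, 10, 1)
  w[vapply(sides, function(s) setequal(s, c(1, 2)), logical(1))] <- 5
  sys <- sides_system(taxa, sides, w)
  out <- filter_strict(sys)
  ix <- split_side_indices(out)
  expect_true(any(vapply(ix, function(s) setequal(s, c(1, 2)), logical(1))))
  expect_false(any(vapply(ix, function(s) setequal(s, c(1, 3)) ||
                            setequal(s, c(1, 4)), logical(1))))
  expect_true(is_compatible_system(out))
  expect_lte(n_splits(out), 2 * 4 - 3)
  # pairwise-compatible input passes through unchanged
  tr <- simulate_tree(8, seed = 5)
  sys8 <- tree_to_splits(tr)
  expect_identical(filter_strict(sys8)$splits, sys8$splits)
})

test_that("filter_2tree keeps two compatible bins covering strict", {
  taxa <- make_taxa(4)
  sys <- sides_system(taxa, all_bipartitions(4), weights = 7:1)
  out <- filter_2tree(sys)
  strict <- filter_strict(sys)
  expect_true(all(strict$splits$side %in% out$splits$side))
  # both quartet-resolving splits of highest weight survive
  expect_gt(n_splits(out), n_splits(strict))
  bin <- attr(out, "bin")
  expect_equal(length(bin), n_splits(out))
  for (b in 1:2) {
    expect_true(is_compatible_system(
      kmersplits:::system_subset(out, which(bin == b))))
  }
  # compatible input: second bin stays empty
  tr <- tree_to_splits(simulate_tree(6, seed = 2))
  out2 <- filter_2tree(tr)
  expect_identical(out2$splits, filter_strict(tr)$splits)
  expect_true(all(attr(out2, "bin") == 1L))
})

test_that("filter_weakly output passes the all-triples audit", {
  audit_weak <- function(system) {
    ix <- split_side_indices(system)
    m <- length(ix)
    if (m < 3) return(TRUE)
    for (a in 1:(m - 2)) for (b in (a + 1):(m - 1)) for (cc in (b + 1):m) {
      if (!oracle_weakly_compatible(ix[[a]], ix[[b]], ix[[cc]],
                                    system$taxa$n)) return(FALSE)
    }
    TRUE
  }
  set.seed(13)
  for (n in 4:6) {
    taxa <- make_taxa(n)
    sides <- all_bipartitions(n)
    sys <- sides_system(taxa, sides, stats::runif(length(sides), 1, 10))
    out <- filter_weakly(sys)
    expect_true(audit_weak(out))
    expect_lte(n_splits(out), n * (n - 1) / 2) # Bandelt-Dress bound
    # weakly filter keeps everything a strict filter keeps
    expect_true(all(filter_strict(sys)$splits$side %in% out$splits$side))
  }
  # the 4-taxon all-splits system retains an incompatible pair (a box)
  taxa <- make_taxa(4)
  out <- filter_weakly(sides_system(taxa, all_bipartitions(4), 7:1))
  expect_false(is_compatible_system(out))
  expect_equal(n_splits(out), 6L) # 4 trivial + 2 of the 3 quartet splits
})

test_that("filters are deterministic and compose via filter_splits", {
  set.seed(4)
  taxa <- make_taxa(5)
  sides <- all_bipartitions(5)
  w <- sample(1:5, length(sides), replace = TRUE) # many ties
  sys <- sides_system(taxa, sides, w)
  for (mode in c("none", "strict", "2tree", "weakly")) {
    a <- filter_splits(sys, mode)
    b <- filter_splits(sys, mode)
    expect_identical(a$splits, b$splits)
  }
  expect_equal(n_splits(filter_splits(sys, "topx", x = 2)), 2L)
  expect_error(filter_splits(sys, "topx"), "requires x")
})
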