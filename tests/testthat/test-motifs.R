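test_that("the 3-node taxonomy has exactly 13 connected classes", {
  codes <- 0:63
  to_adj <- function(code) {
    bits <- as.integer(intToBits(code))[1:6]
    a <- matrix(0L, 3, 3)
    a[cbind(c(1, 2, 1, 3, 2, 3), c(2, 1, 3, 1, 3, 2))] <- bits
    a
  }
  ids <- vapply(codes, function(cd) {
    id <- triad_class(to_adj(cd))
    if (is.na(id)) 0L else id
  }, integer(1))
  expect_setequal(unique(ids[ids > 0]), 1:13)
  # classification is invariant under all 6 node permutations
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (cd in codes) {
    a <- to_adj(cd)
    base <- triad_class(a)
    for (r in 1:6) {
      p <- perms[r, ]
      expect_identical(triad_class(a[p, p]), base)
    }
  }
  # the package IDs agree with the independently hand-coded exemplar key
  for (id in 1:13) expect_identical(triad_class(triad_exemplars[[id]]), id)
})

test_that("specific triads land in the expected classes", {
  none <- matrix(0L, 3, 3)
  expect_true(is.na(triad_class(none)))
  # a single edge is not weakly connected as a triple
  one <- none; one[1, 2] <- 1L
  expect_true(is.na(triad_class(one)))
  # fully bidirectional triangle is the unique 6-edge class, highest ID
  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  expect_identical(triad_class(tri), 13L)
  # directed 3-cycle
  cyc <- matrix(0L, 3, 3); cyc[cbind(1:3, c(2, 3, 1))] <- 1L
  expect_identical(triad_class(cyc), 7L)
  expect_error(triad_class(matrix(0L, 4, 4)), "3 nodes")
})

test_that("the census matches brute force and igraph on random graphs", {
  set.seed(41)
  for (rep in 1:6) {
    a <- random_adjacency(12, runif(1, 0.08, 0.3))
    cen <- motif_census(a)
    expect_equal(unname(cen), oracle_motif_census(a))
    # independent counting route: igraph's 16-slot triad census
    tc <- igraph::triad_census(igraph::graph_from_adjacency_matrix(a, mode = "directed"))
    expect_equal(unname(cen), tc[4:16])
    # census total = number of weakly connected triples
    expect_equal(sum(cen), sum(tc[4:16]))
  }
  # empty graph and a single 3-cycle
  expect_true(all(motif_census(matrix(0L, 5, 5)) == 0))
  cyc5 <- matrix(0L, 5, 5); cyc5[cbind(1:3, c(2, 3, 1))] <- 1L
  cen <- motif_census(cyc5)
  expect_equal(sum(cen), 1)
  expect_equal(unname(cen[7]), 1)
})

test_that("functional counting includes contained sub-triads", {
  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  f <- motif_census(tri, counting = "functional")
  s <- motif_census(tri, counting = "structural")
  expect_equal(unname(s[13]), 1)
  expect_equal(unname(f[13]), 1)
  expect_gt(sum(f), sum(s))          # sub-patterns add counts
  # the 3-cycle contributes itself only, under both counting rules
  cyc <- matrix(0L, 3, 3); cyc[cbind(1:3, c(2, 3, 1))] <- 1L
  expect_equal(unname(motif_census(cyc, "functional")[7]), 1)
})

test_that("edge swaps preserve both degree sequences exactly", {
  set.seed(59)
  a <- random_adjacency(29, 0.1)
  for (s in 1:5) {
    r <- degree_preserving_randomize(a, swap_factor = 100, seed = s)
    expect_equal(rowSums(r), rowSums(a))
    expect_equal(colSums(r), colSums(a))
    expect_true(all(diag(r) == 0))
    expect_true(all(r %in% c(0L, 1L)))
  }
  # determinism under the seed, variation across seeds
  expect_identical(degree_preserving_randomize(a, seed = 3),
                   degree_preserving_randomize(a, seed = 3))
  expect_false(identical(degree_preserving_randomize(a, seed = 3),
                         degree_preserving_randomize(a, seed = 4)))
  # single-edge graphs cannot be rewired
  single <- matrix(0L, 3, 3); single[1, 2] <- 1L
  expect_warning(out <- degree_preserving_randomize(single), "fewer than 2")
  expect_equal(unname(out), unname(single))
})

test_that("two chain lengths agree on the randomized ensemble", {
  set.seed(61)
  a <- random_adjacency(29, 0.1)
  cell <- function(swap_factor, seeds) {
    mean(vapply(seeds, function(s)
      degree_preserving_randomize(a, swap_factor, seed = s)[2, 5], numeric(1)))
  }
  f_short <- cell(20, 1:300)
  f_long <- cell(200, 301:600)
  p <- (f_short + f_long) / 2
  se <- sqrt(2 * p * (1 - p) / 300)
  expect_lt(abs(f_short - f_long), 3 * se + 1e-9)
})

test_that("planted motifs are detected against the degree-preserving null", {
  # 6 disjoint directed 3-cycles: the cycle class is maximally enriched
  n <- 18
  a <- matrix(0L, n, n, dimnames = list(1:n, 1:n))
  for (b in 0:5) a[cbind(b * 3 + 1:3, b * 3 + c(2, 3, 1))] <- 1L
  res <- motif_significance(a, n_null = 1000, swap_factor = 100, seed = 5)
  tab <- res$table
  expect_equal(tab$count[7], 6)
  expect_lte(tab$p_empirical[7], 0.001)
  expect_true(tab$significant[7])
  # p-values live on the add-one grid
  expect_true(all(abs(tab$p_empirical * (res$n_null + 1) -
                      round(tab$p_empirical * (res$n_null + 1))) < 1e-9))
  # a class matching a constant null is not significant, z undefined
  degenerate <- tab[tab$null_sd == 0 & tab$count == round(tab$null_mean), ]
  if (nrow(degenerate)) {
    expect_true(all(!degenerate$significant))
    expect_true(all(is.na(degenerate$z)))
  }
})

test_that("graphs drawn from the null ensemble show no systematic enrichment", {
  set.seed(71)
  base <- random_adjacency(20, 0.12)
  zs <- c(); sig <- c()
  for (s in 1:10) {
    g <- degree_preserving_randomize(base, 100, seed = 1000 + s)
    res <- motif_significance(g, n_null = 200, swap_factor = 50, seed = s)
    ok <- !is.na(res$table$z)
    zs <- c(zs, res$table$z[ok])
    sig <- c(sig, res$table$significant)
  }
  expect_lt(mean(abs(zs)), 1.5)
  expect_lt(mean(sig), 0.15)
})
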