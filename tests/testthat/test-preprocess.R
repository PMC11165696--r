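test_that("rarefaction slope matches closed forms and brute-force enumeration", {
  # one genus: no new genus can ever appear
  expect_equal(rarefaction_slope(c(50), 10), 0)
  # all singletons: every read is a new genus, slope 1 until exhaustion
  expect_equal(rarefaction_slope(rep(1, 8), 3), 1)
  expect_equal(rarefaction_slope(rep(1, 8), 7), 1)
  # exhaustive enumeration oracle at small depth
  for (cc in list(c(4, 1), c(3, 2, 1), c(6, 3, 2, 1))) {
    N <- sum(cc)
    for (n in seq_len(N - 1)) {
      expect_equal(rarefaction_slope(cc, n),
                   enum_expected_richness(cc, n + 1) -
                     enum_expected_richness(cc, n),
                   tolerance = 1e-12,
                   label = sprintf("slope counts (%s) n=%d",
                                   paste(cc, collapse = ","), n))
    }
  }
  expect_error(rarefaction_slope(c(4, 1), 5), "depth")
})

test_that("expected richness at full depth is observed richness; slope non-increasing", {
  set.seed(42)
  for (rep_i in 1:5) {
    cc <- rmultinom(1, 500, prob = c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02))[, 1]
    cc <- cc[cc > 0]
    expect_equal(expected_richness(cc, sum(cc)), length(cc))
    grid <- unique(round(seq(1, sum(cc) - 1, length.out = 30)))
    slopes <- vapply(grid, function(n) rarefaction_slope(cc, n), numeric(1))
    expect_true(all(diff(slopes) <= 1e-12))
  }
})

test_that("coverage rarefaction subsamples to the coverage depth", {
  tab <- toy_counts(n_samples = 5, n_taxa = 8, depth = 3000, seed = 3)
  # slope <= 1 always, so slope_max = 1 rarefies everything to one read
  r1 <- coverage_rarefy(tab, slope_max = 1.0, seed = 1)
  expect_true(all(rowSums(r1$table) == 1))
  # at the conventional threshold: row sums hit the target depth exactly,
  # counts never exceed the originals, and the slope criterion holds
  r <- coverage_rarefy(tab, seed = 1)
  expect_identical(rownames(r$table), rownames(tab))
  for (i in seq_len(nrow(r$table))) {
    id <- rownames(r$table)[i]
    expect_equal(sum(r$table[i, ]), unname(r$depths[id]))
    expect_true(all(r$table[i, ] <= tab[id, colnames(r$table)]))
    expect_lte(rarefaction_slope(tab[id, ], r$depths[id]), 0.002259329)
    if (r$depths[id] > 1)
      expect_gt(rarefaction_slope(tab[id, ], r$depths[id] - 1L), 0.002259329)
  }
})

test_that("rarefaction target depth is deterministic, subsample is seed-dependent", {
  tab <- toy_counts(n_samples = 4, n_taxa = 10, depth = 2000, seed = 5)
  a <- coverage_rarefy(tab, seed = 1)
  b <- coverage_rarefy(tab, seed = 2)
  expect_identical(a$depths, b$depths)
  expect_false(identical(a$table, b$table))
  expect_identical(a$table, coverage_rarefy(tab, seed = 1)$table)
})

test_that("CLR transform matches hand computation and sums to zero", {
  # log(0.5, 0.25, 0.25) centred: frozen hand-derived values
  expect_equal(clr(c(0.5, 0.25, 0.25)),
               c(0.46209812, -0.23104906, -0.23104906), tolerance = 1e-8)
  expect_equal(sum(clr(c(0.2, 0.3, 0.5))), 0, tolerance = 1e-12)
  expect_error(clr(c(0.5, 0, 0.5)), "positive")
})

test_that("Dirichlet Monte-Carlo CLR: symmetry, zero-sum rows, determinism", {
  tab <- matrix(50L, 4, 6,
                dimnames = list(paste0("s", 1:4), paste0("g", 1:6)))
  arr <- dirichlet_clr(tab, n_instances = 400, seed = 9)
  # equal counts + symmetric prior: expected CLR is 0 per taxon
  expect_true(max(abs(apply(arr, 3, mean))) < 0.02)
  # CLR identity: every instance-sample row sums to 0
  sums <- apply(arr, c(1, 2), sum)
  expect_true(max(abs(sums)) < 1e-9)
  expect_identical(dirichlet_clr(tab, n_instances = 8, seed = 3),
                   dirichlet_clr(tab, n_instances = 8, seed = 3))
  expect_error(dirichlet_clr(rbind(tab, s5 = rep(0L, 6))), "all-zero")
})

test_that("median over instances matches a sort-based oracle", {
  tab <- toy_counts(n_samples = 3, n_taxa = 4, depth = 200, seed = 2)
  arr <- dirichlet_clr(tab, n_instances = 7, seed = 4)
  med <- median_clr(arr)
  for (s in seq_len(3)) for (t in seq_len(4)) {
    v <- sort(arr[, s, t])
    expect_equal(med[s, t], v[4])  # middle of 7 sorted values
  }
  # single instance: identity
  arr1 <- dirichlet_clr(tab, n_instances = 1, seed = 4)
  expect_equal(median_clr(arr1), arr1[1, , ])
})
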