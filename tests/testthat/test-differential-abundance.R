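test_that("effect sizes vanish when groups share a distribution", {
  arr <- normal_clr_array(n_inst = 128, n_case = 50, n_control = 50,
                          n_taxa = 5, seed = 2)
  eff <- aldex_effect(arr, attr(arr, "groups"), seed = 1)
  expect_true(all(abs(eff$effect) < 0.1))
})

test_that("swapping group labels negates every effect exactly", {
  arr <- normal_clr_array(n_inst = 32, n_case = 20, n_control = 30,
                          n_taxa = 4, shift = c(0.5, 0, -0.3, 0.1), seed = 3)
  g <- attr(arr, "groups")
  eff <- aldex_effect(arr, g, seed = 7)
  swapped <- factor(ifelse(g == "case", "control", "case"),
                    levels = c("control", "case"))
  eff_sw <- aldex_effect(arr, swapped, seed = 7)
  expect_equal(eff_sw$effect, -eff$effect)
  expect_equal(eff_sw$diff_btw, -eff$diff_btw)
  expect_equal(eff_sw$diff_win, eff$diff_win)
})

test_that("effect is invariant to a common location shift of all CLR values", {
  arr <- normal_clr_array(n_inst = 32, n_case = 15, n_control = 25,
                          n_taxa = 3, shift = c(0.4, 0, 0), seed = 5)
  eff <- aldex_effect(arr, attr(arr, "groups"), seed = 2)
  arr2 <- arr + 17.3
  attributes(arr2) <- attributes(arr)
  eff2 <- aldex_effect(arr2, attr(arr, "groups"), seed = 2)
  expect_equal(eff2$effect, eff$effect, tolerance = 1e-12)
})

test_that("effect magnitude grows with the planted shift", {
  shifts <- c(0, 0.2, 0.4, 0.8)
  med <- vapply(shifts, function(s) {
    vals <- vapply(1:2, function(seed) {
      arr <- normal_clr_array(n_inst = 48, n_case = 100, n_control = 100,
                              n_taxa = 3, shift = c(s, 0, 0), seed = seed)
      aldex_effect(arr, attr(arr, "groups"), seed = seed)$effect[1]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("a planted cohort-level shift yields the largest, positive effect", {
  cfg <- cohort_config(n_case_m = 2L, n_control_m = 2L,
                       n_case_f = 60L, n_control_f = 60L, n_taxa = 30L,
                       depth_range = c(2283L, 8000L),
                       planted_up = c(genus_003 = 0.8), seed = 5)
  sim <- generate_cohort(cfg)
  f <- sim$metadata$sex == "female"
  arr <- dirichlet_clr(sim$counts[f, ], n_instances = 64, seed = 2)
  g <- factor(sim$metadata$group[f], levels = c("control", "depression"))
  eff <- aldex_effect(arr, g, seed = 3)
  top <- eff$taxon[which.max(abs(eff$effect))]
  expect_equal(top, "genus_003")
  expect_gt(eff$effect[eff$taxon == "genus_003"], 0)
})

test_that("expected Wilcoxon p/q behave like p-values with BH dominance", {
  arr <- normal_clr_array(n_inst = 24, n_case = 20, n_control = 20,
                          n_taxa = 6, shift = c(1.5, rep(0, 5)), seed = 9)
  pq <- wilcoxon_bh(arr, attr(arr, "groups"))
  expect_true(all(pq$q_expected >= pq$p_expected - 1e-12))
  expect_true(all(pq$p_expected >= 0 & pq$p_expected <= 1))
  # the strongly shifted taxon is the most significant
  expect_equal(which.min(pq$p_expected), 1L)
  # median summary also available
  pq_med <- wilcoxon_bh(arr, attr(arr, "groups"), summary = "median")
  expect_true(all(pq_med$q_expected >= pq_med$p_expected - 1e-12))
})

test_that("taxon classification applies strict thresholds and ordering", {
  eff <- c(A = 0.25, B = -0.31, C = 0.10, D = 0.2, E = 0.6)
  cl <- classify_taxa(eff, threshold = 0.2)
  expect_equal(cl$more, c("E", "A"))     # ordered by |effect| desc
  expect_equal(cl$less, "B")
  expect_equal(cl$class$class[cl$class$taxon == "D"], "neutral")  # strict >
  expect_length(intersect(cl$more, cl$less), 0)
  expect_error(classify_taxa(eff, threshold = 0), "positive")
})
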