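test_that("subsample enumeration is exhaustive, lexicographic and guarded", {
  combos <- enumerate_subsamples(5, 3)
  expect_equal(nrow(combos), choose(5, 3))
  expect_equal(combos[1, ], c(1, 2, 3))
  expect_equal(combos[nrow(combos), ], c(3, 4, 5))
  expect_equal(nrow(unique(combos)), nrow(combos))
  # lexicographic: every row sorted ascending, rows in dictionary order
  expect_true(all(apply(combos, 1, function(x) !is.unsorted(x, strictly = TRUE))))
  key <- combos %*% 10^((ncol(combos) - 1):0)
  expect_true(!is.unsorted(key, strictly = TRUE))

  expect_equal(nrow(enumerate_subsamples(12, 12)), 1)
  expect_error(enumerate_subsamples(12, 2), ">= 3")
  expect_error(enumerate_subsamples(5, 6), "exceeds")

  # total networks across all analyzed sizes of a 12-animal cohort
  expect_equal(sum(choose(12, 3:11)), 4016)
})

test_that("the full-cohort subsample never flips and has zero variance", {
  fix <- demo_cohort(n_regions = 8, n_animals = 6)
  rep <- subsample_scan(fix$table, sizes = 6, spec = threshold_spec(0.05))
  expect_equal(unname(rep$n_combinations), 1L)
  expect_true(all(rep$flip_rate == 0))
  expect_true(all(rep$p_variance == 0))
})

test_that("an affinely duplicated region pair is perfectly stable", {
  set.seed(3)
  base <- abs(rnorm(10)) + 1
  m <- rbind(a = base, b = 2 * base + 0.5,
             c = abs(rnorm(10)), d = abs(rnorm(10)))
  colnames(m) <- paste0("m", 1:10)
  rep <- subsample_scan(region_table(m), sizes = 3:10,
                        spec = threshold_spec(0.05))
  i <- which(rep$edges$region_a == "a" & rep$edges$region_b == "b")
  expect_equal(unname(rep$flip_rate[i, ]), rep_len(0, 8))
  # p is numerically ~0 (r = 1 up to floating error), so its variance is ~0
  expect_true(all(rep$p_variance[i, ] < 1e-10))
  expect_equal(rep$edges$class[i], "false_negative_type")

  curve <- flip_rate_curves(rep, c("a", "b"))
  expect_equal(curve$flip_rate, rep_len(0, 8))
  expect_equal(unique(curve$class), "false_negative_type")
  expect_error(flip_rate_curves(rep, c("a", "nope")), "unknown region pair")
})

test_that("scan bookkeeping matches the combinatorics and stays in bounds", {
  fix <- demo_cohort(n_regions = 8, n_animals = 8,
                     structure_seed = 5, sample_seed = 6)
  rep <- subsample_scan(fix$table, sizes = 3:8, spec = threshold_spec(0.05))
  expect_equal(unname(rep$n_combinations), choose(8, 3:8))
  expect_true(all(rep$flip_rate >= 0 & rep$flip_rate <= 1))
  expect_true(all(rep$p_variance >= 0))
  expect_equal(nrow(rep$edges), choose(8, 2))
  expect_true(rep$exhaustive)
  expect_equal(length(rep$variance_by_size), 6)
})

test_that("permuting animals changes nothing but combination labels", {
  fix <- demo_cohort(n_regions = 6, n_animals = 6)
  tab <- unclass(fix$table)
  rep1 <- subsample_scan(region_table(tab), sizes = 3:6,
                         spec = threshold_spec(0.05))
  perm <- c(4, 1, 6, 2, 5, 3)
  rep2 <- subsample_scan(region_table(tab[, perm]), sizes = 3:6,
                         spec = threshold_spec(0.05))
  # per-edge flip rates and variances are permutation-invariant because the
  # same combinations are visited, just in a different order
  expect_equal(rep1$flip_rate, rep2$flip_rate)
  expect_equal(rep1$p_variance, rep2$p_variance)
  expect_equal(rep1$variance_by_size, rep2$variance_by_size)
})

test_that("a region constant within some subsample follows the r = 0, p = 1 rule", {
  m <- rbind(a = c(5, 5, 5, 7, 2, 9),
             b = c(1.2, 3.5, 2.8, 0.4, 6.1, 2.2),
             c = c(2.0, 1.1, 4.2, 3.3, 0.7, 5.0))
  colnames(m) <- paste0("m", 1:6)
  expect_warning(
    rep <- subsample_scan(region_table(m), sizes = 3:6,
                          spec = threshold_spec(0.05)),
    "zero-variance")
  expect_gt(rep$n_zero_variance, 0)
  expect_true(all(is.finite(rep$p_variance)))
})

test_that("median-variance selection picks the documented rank and rebuilds the network", {
  fix <- demo_cohort(n_regions = 8, n_animals = 7,
                     structure_seed = 21, sample_seed = 22)
  spec <- threshold_spec(0.05)

  # independent recomputation of every combination's p-variance score
  vals <- unclass(fix$table)
  combos <- t(combn(7, 5))
  scores <- apply(combos, 1, function(idx) {
    sub <- vals[, idx]
    ps <- c()
    for (i in 1:7) for (j in 1:8) if (i < j) {
      ps <- c(ps, cor.test(sub[i, ], sub[j, ])$p.value)
    }
    var(ps)
  })
  m <- length(scores)  # 21 combinations: odd count, true median
  expected <- which(rank(scores, ties.method = "first") == (m + 1) %/% 2)

  sel <- select_median_variance_network(fix$table, k = 5, spec = spec)
  expect_equal(sort(sel$combination), sort(combos[expected, ]))
  expect_equal(sel$score, scores[expected], tolerance = 1e-12)
  expect_s3_class(sel$network, "fc_network")
  expect_equal(length(sel$animals), 5)

  # even combination count: lower median (rank m/2); C(6, 3) = 20 combinations
  fix6 <- demo_cohort(n_regions = 8, n_animals = 6,
                      structure_seed = 23, sample_seed = 24)
  vals6 <- unclass(fix6$table)
  combos6 <- t(combn(6, 3))
  scores6 <- apply(combos6, 1, function(idx) {
    sub <- vals6[, idx]
    ps <- c()
    for (i in 1:7) for (j in 1:8) if (i < j) {
      ps <- c(ps, cor.test(sub[i, ], sub[j, ])$p.value)
    }
    var(ps)
  })
  expected6 <- which(rank(scores6, ties.method = "first") == length(scores6) %/% 2)
  sel6 <- select_median_variance_network(fix6$table, k = 3, spec = spec)
  expect_equal(sort(sel6$combination), sort(combos6[expected6, ]))
})

test_that("the selected small-group network differs from the full-cohort network", {
  fix <- paper_scale_cohort()
  spec <- threshold_spec(0.05)
  full <- binarize(correlate_table(fix$table), spec)
  sel <- select_median_variance_network(fix$table, k = 5, spec = spec)
  expect_false(identical(node_degree(full), node_degree(sel$network)))
})

test_that("Monte-Carlo mode caps the combination count for large cohorts", {
  fix <- demo_cohort(n_regions = 6, n_animals = 16,
                     structure_seed = 31, sample_seed = 32)
  rep <- subsample_scan(fix$table, sizes = c(5, 8), spec = threshold_spec(0.05),
                        mc_threshold = 10, mc_cap = 100, mc_seed = 9)
  expect_false(rep$exhaustive)
  expect_true(all(rep$n_combinations <= 100))
  rep2 <- subsample_scan(fix$table, sizes = c(5, 8), spec = threshold_spec(0.05),
                         mc_threshold = 10, mc_cap = 100, mc_seed = 9)
  expect_equal(rep$flip_rate, rep2$flip_rate)
})
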