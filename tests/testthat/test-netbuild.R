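test_that("pearson_r reproduces hand-computed coefficients and is affine-invariant", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  x <- c(0.3, 1.9, 0.2, 4.1, 2.2)
  y <- c(1.1, 0.4, 2.2, 3.0, 1.7)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  expect_equal(pearson_r(3.2 * x + 7, y), pearson_r(x, y))
  expect_equal(pearson_r(x, -2 * y + 1), -pearson_r(x, y))

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_r(1:4, 1:3), "equal length")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("the t-transform p-value behaves correctly at the boundaries", {
  expect_equal(p_two_tailed(0, 12), 1)
  expect_equal(p_two_tailed(1, 12), 0)
  expect_equal(p_two_tailed(-1, 12), 0)
  expect_error(p_two_tailed(0.5, 2), "n")
  expect_error(p_two_tailed(1.2, 12), "r")
  # two-tailed symmetry and monotonicity in |r|
  r <- seq(0.05, 0.95, by = 0.1)
  expect_equal(p_two_tailed(r, 10), p_two_tailed(-r, 10))
  expect_true(all(diff(p_two_tailed(r, 10)) < 0))
  # matches R's own correlation test on arbitrary data
  set.seed(31)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(p_two_tailed(cor(x, y), 9), cor.test(x, y)$p.value)
})

test_that("correlate_table produces a symmetric result over all region pairs", {
  fix <- demo_cohort(n_regions = 60, n_animals = 12,
                     structure_seed = 1, sample_seed = 2)
  corr <- correlate_table(fix$table)
  expect_equal(corr$n, 12)
  expect_equal(sum(upper.tri(corr$r)), choose(60, 2))
  expect_equal(sum(upper.tri(corr$r)), 1770)
  expect_identical(corr$r, t(corr$r))
  expect_identical(corr$p, t(corr$p))
  expect_true(all(abs(corr$r[upper.tri(corr$r)]) <= 1))
  expect_true(all(corr$p[upper.tri(corr$p)] >= 0 & corr$p[upper.tri(corr$p)] <= 1))
  expect_equal(unname(diag(corr$r)), rep(1, 60))
  expect_true(all(is.na(diag(corr$p))))
  # every off-diagonal pair agrees with the scalar routines
  i <- c(1, 5, 17); j <- c(2, 40, 60)
  for (k in seq_along(i)) {
    r_ij <- pearson_r(unclass(fix$table)[i[k], ], unclass(fix$table)[j[k], ])
    expect_equal(corr$r[i[k], j[k]], r_ij)
    expect_equal(corr$p[i[k], j[k]], p_two_tailed(r_ij, 12))
  }
})

test_that("affinely identical regions correlate perfectly", {
  base <- c(1.2, 3.4, 0.7, 5.1, 2.2)
  m <- rbind(a = base, b = 2 * base + 1, c = 0.5 * base + 3)
  colnames(m) <- paste0("m", 1:5)
  corr <- correlate_table(region_table(m))
  expect_true(all(abs(corr$r[upper.tri(corr$r)] - 1) < 1e-12))
})

test_that("zero-variance regions warn and take r = 0, p = 1", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  colnames(m) <- paste0("m", 1:4)
  expect_warning(corr <- correlate_table(region_table(m)), "zero variance")
  expect_equal(corr$r["a", "b"], 0)
  expect_equal(corr$p["a", "b"], 1)
  expect_equal(corr$r["a", "c"], -1)
  # and the constant region can never gain an edge
  net <- binarize(corr, threshold_spec(alpha = 0.05, sign_policy = "absolute"))
  expect_equal(unname(node_degree(net)["b"]), 0L)
})

test_that("BH step-up retains exactly the right p-values", {
  expect_identical(bh_fdr(c(0.9, 0.95), 0.05), c(FALSE, FALSE))
  expect_identical(bh_fdr(c(0.01, 0.02, 0.04, 0.8), 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(c(0.001, 0.002, 0.003), 0.05), c(TRUE, TRUE, TRUE))
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")

  # agrees with the literal step-up definition, and retention grows with q
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p, 0.05), bf_bh(p, 0.05))
    expect_true(all(bh_fdr(p, 0.05) <= bh_fdr(p, 0.2)))
  }
})

# Hand-built 4-region toy: one strong positive pair, one strong negative
# pair, everything else null.
toy_corr <- function() {
  regions <- c("A", "B", "C", "D")
  r <- diag(4); p <- matrix(0.9, 4, 4)
  dimnames(r) <- dimnames(p) <- list(regions, regions)
  r["A", "B"] <- r["B", "A"] <- 0.92
  r["C", "D"] <- r["D", "C"] <- -0.92
  p["A", "B"] <- p["B", "A"] <- 0.001
  p["C", "D"] <- p["D", "C"] <- 0.001
  diag(p) <- NA
  structure(list(r = r, p = p, n = 12, regions = regions),
            class = "correlation_result")
}

test_that("binarize applies alpha, FDR, r floor and the sign policy", {
  corr <- toy_corr()

  pos <- binarize(corr, threshold_spec(alpha = 0.05, sign_policy = "positive_only"))
  expect_equal(pos$adjacency["A", "B"], 1L)
  expect_equal(pos$adjacency["C", "D"], 0L)  # anticorrelation dropped

  abs_net <- binarize(corr, threshold_spec(alpha = 0.05, sign_policy = "absolute"))
  expect_equal(abs_net$adjacency["C", "D"], 1L)
  expect_equal(sum(abs_net$adjacency) / 2, 2)

  signed <- binarize(corr, threshold_spec(alpha = 0.05, sign_policy = "signed"))
  expect_equal(signed$signs["A", "B"], 1L)
  expect_equal(signed$signs["C", "D"], -1L)

  # r floor removes edges below the critical value
  floored <- binarize(corr, threshold_spec(alpha = 0.05, r_min = 0.95,
                                           sign_policy = "absolute"))
  expect_equal(sum(floored$adjacency), 0L)

  # FDR keeps the family-level filter: both small p survive at q = 0.05
  fdr_net <- binarize(corr, threshold_spec(alpha = 0.05, fdr_q = 0.05,
                                           sign_policy = "absolute"))
  expect_equal(sum(fdr_net$adjacency) / 2, 2)

  # adjacency invariants
  for (net in list(pos, abs_net, signed, fdr_net)) {
    expect_identical(net$adjacency, t(net$adjacency))
    expect_true(all(diag(net$adjacency) == 0))
    expect_true(all(net$adjacency %in% 0:1))
  }
})

test_that("nothing passes when all p are large; everything passes when r = 1", {
  corr <- toy_corr()
  corr$p[] <- 0.5; diag(corr$p) <- NA
  empty <- binarize(corr, threshold_spec(alpha = 0.05))
  expect_equal(sum(empty$adjacency), 0L)

  corr$r[] <- 1
  corr$p[] <- 1e-12; diag(corr$p) <- NA
  full <- binarize(corr, threshold_spec(alpha = 0.05, fdr_q = 0.05))
  expect_equal(sum(full$adjacency) / 2, choose(4, 2))
})

test_that("stricter thresholds give nested edge sets", {
  for (seed in 1:5) {
    fix <- demo_cohort(structure_seed = seed, sample_seed = seed + 50)
    corr <- correlate_table(fix$table)
    nets <- lapply(c(0.05, 0.005, 0.0005), function(a)
      binarize(corr, threshold_spec(alpha = a))$adjacency)
    expect_true(all(nets[[2]] <= nets[[1]]))
    expect_true(all(nets[[3]] <= nets[[2]]))
    # larger r floor also nests
    loose <- binarize(corr, threshold_spec(alpha = 0.05, r_min = 0.3))$adjacency
    tight <- binarize(corr, threshold_spec(alpha = 0.05, r_min = 0.6))$adjacency
    expect_true(all(tight <= loose))
  }
})

test_that("results are invariant to animal order and equivariant to region order", {
  set.seed(19)
  fix <- demo_cohort(n_regions = 10, n_animals = 8)
  tab <- unclass(fix$table)
  spec <- threshold_spec(alpha = 0.05, fdr_q = 0.2, sign_policy = "absolute")

  corr <- correlate_table(region_table(tab, check_nonnegative = FALSE))
  net <- binarize(corr, spec)

  perm_a <- sample(ncol(tab))
  corr2 <- correlate_table(region_table(tab[, perm_a], check_nonnegative = FALSE))
  expect_equal(corr$r, corr2$r)
  expect_equal(corr$p, corr2$p)
  expect_identical(binarize(corr2, spec)$adjacency, net$adjacency)

  perm_r <- sample(nrow(tab))
  corr3 <- correlate_table(region_table(tab[perm_r, ], check_nonnegative = FALSE))
  expect_equal(corr3$r, corr$r[perm_r, perm_r])
  expect_identical(binarize(corr3, spec)$adjacency,
                   net$adjacency[perm_r, perm_r])
})

test_that("edge lists carry the correlation annotation", {
  corr <- toy_corr()
  net <- binarize(corr, threshold_spec(alpha = 0.05, sign_policy = "absolute"))
  el <- edge_list(net, corr)
  expect_equal(nrow(el), 2)
  expect_setequal(el$sign, c(1L, -1L))
  expect_true(all(el$p <= 0.05))
})

test_that("threshold_spec validates its fields", {
  expect_error(threshold_spec(alpha = 0), "alpha")
  expect_error(threshold_spec(alpha = 1.5), "alpha")
  expect_error(threshold_spec(fdr_q = 0), "fdr_q")
  expect_error(threshold_spec(r_min = 1), "r_min")
  expect_error(threshold_spec(sign_policy = "sometimes"))
})
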