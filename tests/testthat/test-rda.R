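test_that("single-trait pseudo-F equals the classical ANOVA F", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    y <- rnorm(n) + rep(c(0, 0.8), length.out = n)
    g <- rep(c(0, 1), length.out = n)
    f_rda <- rda_pseudo_F(matrix(y), g)$pseudo_F
    f_aov <- summary(stats::aov(y ~ factor(g)))[[1]]$`F value`[1]
    expect_equal(f_rda, f_aov, tolerance = 1e-10)
  }
})

test_that("pseudo-F matches vegan's constrained ordination", {
  skip_if_not_installed("vegan")
  set.seed(202)
  Y <- matrix(rnorm(40 * 5), 40, 5)
  Y[1:20, 1] <- Y[1:20, 1] + 1
  g <- rep(c(1, 0), each = 20)
  ours <- rda_pseudo_F(Y, g)
  v <- vegan::rda(scale(Y) ~ g)
  f_vegan <- (v$CCA$tot.chi / 1) / (v$CA$tot.chi / (nrow(Y) - 2))
  expect_equal(ours$pseudo_F, f_vegan, tolerance = 1e-8)
  expect_equal(ours$variance_explained,
               v$CCA$tot.chi / v$tot.chi, tolerance = 1e-8)
})

test_that("pseudo-F geometry behaves as a projection statistic", {
  set.seed(303)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  g <- rep(c(0, 1), each = 15)
  # group means equal by construction -> F ~ 0
  Y0 <- Y
  for (j in 1:4) {
    Y0[g == 1, j] <- Y0[g == 1, j] - mean(Y0[g == 1, j])
    Y0[g == 0, j] <- Y0[g == 0, j] - mean(Y0[g == 0, j])
  }
  expect_lt(rda_pseudo_F(Y0, g)$pseudo_F, 1e-20)
  # duplicating columns leaves the statistic unchanged
  expect_equal(rda_pseudo_F(cbind(Y, Y), g)$pseudo_F,
               rda_pseudo_F(Y, g)$pseudo_F, tolerance = 1e-12)
  # relabeling the groups leaves it unchanged
  expect_equal(rda_pseudo_F(Y, 1 - g)$pseudo_F,
               rda_pseudo_F(Y, g)$pseudo_F, tolerance = 1e-12)
  # explained and residual proportions sum to one
  r <- rda_pseudo_F(Y, g)
  expect_equal(r$variance_explained + (r$ss_total - r$ss_explained) /
                 r$ss_total, 1)
})

test_that("degenerate trait matrices are handled", {
  set.seed(304)
  Y <- cbind(rnorm(20), rep(1, 20))
  g <- rep(c(0, 1), each = 10)
  expect_warning(r <- rda_pseudo_F(Y, g), "constant")
  expect_equal(r$p, 1L)
  expect_error(rda_pseudo_F(matrix(rnorm(20)), rep(1, 20)), "both groups")
})

test_that("permutation test is reproducible and respects the p floor", {
  set.seed(404)
  Y <- matrix(rnorm(24 * 3), 24, 3)
  Y[1:12, ] <- Y[1:12, ] + 3   # strong separation
  g <- rep(c(1, 0), each = 12)
  r1 <- permutation_test(Y, g, n_perm = 999, rng_seed = 7)
  r2 <- permutation_test(Y, g, n_perm = 999, rng_seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$p_value, 1 / 1000)   # floor attained on separated data
  expect_gte(r1$p_value, 1 / (r1$n_permutations + 1))
})

test_that("null permutation p-values are super-uniform", {
  set.seed(505)
  n_rep <- 500
  pvals <- vapply(seq_len(n_rep), function(i) {
    Y <- matrix(rnorm(20 * 2), 20, 2)
    g <- rep(c(0, 1), each = 10)
    permutation_test(Y, g, n_perm = 199, rng_seed = 600 + i)$p_value
  }, numeric(1))
  # permutation p-values are discrete, so KS ties are expected
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("univariate trait summaries assign conventional stars", {
  # identical groups: everything ns
  tt <- data.frame(mode_label = rep(c("apomict", "non_apomict"), each = 10),
                   a = rep(1:10, 2), b = rep(c(0, 1), 10))
  s <- table1_summary(tt, rng_seed = 1)
  expect_true(all(s$stars == "ns"))

  # clonality contrast at screen-like group sizes (13 apomicts vs 207
  # sexuals, prevalence 0.85 vs 0.33) is detected at P < 0.001 in most
  # replicates
  hits <- vapply(1:10, function(i) {
    t1 <- simulate_trait_table(trait_sim_config(rng_seed = 900 + i))
    s1 <- table1_summary(t1, rng_seed = i)
    s1$p_value[s1$trait == "clonal"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.7)

  # tiny groups are flagged not testable
  t2 <- data.frame(mode_label = c("apomict", rep("non_apomict", 5)),
                   a = rnorm(6))
  s2 <- table1_summary(t2, rng_seed = 1)
  expect_equal(s2$stars, "not_testable")
})
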