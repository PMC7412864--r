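test_that("identical noiseless arms give ratio 1 and p = 0.5", {
  r <- uptake_ratio(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$ratio, 1)
  expect_equal(r$p_one_tailed, 0.5)
})

test_that("an 8-fold conjugate enhancement is reported as such", {
  r <- uptake_ratio(c(8.2, 7.9, 7.9), c(1.02, 0.97, 1.01))
  expect_equal(r$ratio, 8, tolerance = 0.01)
  expect_equal(r$direction, "greater")
  expect_lt(r$p_one_tailed, 0.05)
  expect_true(r$ci_lower < r$ratio && r$ratio < r$ci_upper)
})

test_that("uptake comparison is scale invariant", {
  set.seed(61)
  a <- rlnorm(3, 0, 0.2); b <- rlnorm(3, 0.5, 0.2)
  r1 <- uptake_ratio(a, b)
  r2 <- uptake_ratio(a * 37.5, b * 37.5)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$p_one_tailed, r2$p_one_tailed)
  expect_equal(r1$ci_lower, r2$ci_lower)
  expect_equal(r1$ci_upper, r2$ci_upper)
})

test_that("observed-direction test doubles the one-sided null rate", {
  # under the null, rejecting when the doubled p-value < alpha is calibrated
  # for the pooled test; the Welch default is conservative at n = 3
  ps <- vapply(1:10000, function(s) {
    u <- simulate_uptake_experiment(1, n_reps = 3, cv = 0.1, seed = s,
                                    times = 1)
    conj <- u$uptake_ug_per_mg[u$arm == "conjugate"]
    ref <- u$uptake_ug_per_mg[u$arm == "reference"]
    c(pooled = uptake_ratio(conj, ref, var_equal = TRUE)$p_one_tailed,
      welch = uptake_ratio(conj, ref)$p_one_tailed)
  }, c(pooled = 0, welch = 0))
  rate_pooled <- mean(pmin(2 * ps["pooled", ], 1) < 0.05)
  rate_welch <- mean(pmin(2 * ps["welch", ], 1) < 0.05)
  expect_gte(rate_pooled, 0.04)
  expect_lte(rate_pooled, 0.06)
  # conservative, never anticonservative
  expect_lte(rate_welch, rate_pooled + 0.005)
  expect_lte(rate_welch, 0.06)
})

test_that("GAG variation reproduces constructed endpoints and scale invariance", {
  tc <- data.frame(group = "g", sample_id = "s1",
                   day = c(0, 2, 4, 6, 8),
                   gag_ug = 40 * c(1, 1.1, 1.3, 1.5, 1.7))
  cv <- gag_cumulative_variation(tc)
  expect_equal(cv$per_sample$variation_pct[cv$per_sample$day == 8], 70)
  tc$gag_ug <- 40 * c(1, 0.9, 0.75, 0.6, 0.5)
  expect_equal(
    gag_cumulative_variation(tc)$per_sample$variation_pct[tc$day == 8], -50)
  # rescaling the whole trajectory changes nothing
  tc2 <- tc; tc2$gag_ug <- tc$gag_ug * 3.3
  expect_equal(gag_cumulative_variation(tc2)$per_sample$variation_pct,
               gag_cumulative_variation(tc)$per_sample$variation_pct)
  expect_error(gag_cumulative_variation(
    data.frame(group = "g", sample_id = "s1", day = c(2, 4), gag_ug = c(1, 2))),
    "day-0")
})

test_that("ANOVA matches the explicit sum-of-squares decomposition", {
  set.seed(62)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    g <- rep(letters[1:k], each = sample(3:6, 1))
    v <- rnorm(length(g), mean = as.integer(factor(g)) * runif(1, 0, 2))
    a <- one_way_anova(v, g)
    expect_equal(a$F, naive_anova_F(v, g), tolerance = 1e-10)
    expect_equal(a$p, pf(a$F, a$df_between, a$df_within, lower.tail = FALSE))
  }
  # identical groups: F = 0, p = 1
  a0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1, tolerance = 1e-12)
  # fully separated means
  a1 <- one_way_anova(c(0, 0, 0, 10, 10, 10) + rnorm(6, sd = 1e-9),
                      rep(c("a", "b"), each = 3))
  expect_lt(a1$p, 1e-10)
})

test_that("Tukey HSD agrees with TukeyHSD and the two-group t-test", {
  set.seed(63)
  # two groups: Tukey p equals the pooled two-sided t-test p
  a <- rnorm(5); b <- rnorm(6, 0.5)
  tk <- tukey_hsd(c(a, b), rep(c("a", "b"), c(5, 6)))
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
  # identical groups: adjusted p = 1
  tk0 <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(abs(tk0$p_adj - 1) < 1e-9))
  # cross-check against stats::TukeyHSD on random 3-5 group data
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    g <- factor(rep(letters[1:k], times = sample(4:7, k, replace = TRUE)))
    v <- rnorm(length(g), as.integer(g) * 0.3)
    ours <- tukey_hsd(v, g)
    ref <- TukeyHSD(aov(v ~ g))$g
    expect_equal(ours$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
    expect_equal(ours$diff, unname(ref[, "diff"]), tolerance = 1e-10)
    expect_equal(ours$ci_lower, unname(ref[, "lwr"]), tolerance = 1e-8)
    # adjusted p never below the unadjusted pairwise p
    for (row in seq_len(nrow(ours))) {
      va <- v[g == ours$group_a[row]]; vb <- v[g == ours$group_b[row]]
      expect_gte(ours$p_adj[row] + 1e-12,
                 t.test(va, vb, var.equal = TRUE)$p.value * 0.999)
    }
  }
})

test_that("significance flags respect the alpha boundary and power", {
  res <- data.frame(polymer_id = c("A1", "A2"), endcap = "e1", time_min = 10,
                    ratio = c(2, 2), direction = "greater",
                    p_one_tailed = c(0.049, 0.051))
  fl <- flag_significant_uptake(res)
  expect_equal(fl$significant, c(TRUE, FALSE))
  empty <- flag_significant_uptake(res[0, ])
  expect_equal(nrow(empty), 0L)

  # planted ratio 3 at cv 10%, n = 3: detected as "greater" most of the time
  hits <- sapply(1:200, function(s) {
    u <- simulate_uptake_experiment(3, n_reps = 3, cv = 0.1, seed = s + 3000,
                                    times = 10)
    r <- uptake_ratio(u$uptake_ug_per_mg[u$arm == "conjugate"],
                      u$uptake_ug_per_mg[u$arm == "reference"])
    r$p_one_tailed < 0.05 && r$direction == "greater"
  })
  expect_gte(mean(hits), 0.9)
})
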