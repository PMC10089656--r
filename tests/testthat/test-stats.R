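# Fixture for the repeated-measures ANOVA: 8 subjects x 2 x 3 within
# design, generated once from a seeded normal model. Reference values
# (F, GG epsilon, GG-corrected p, generalized eta squared) were computed
# independently with an external reference implementation and frozen.
rm_fixture <- function() {
  y <- c(12.0947, 9.8541, 11.2091, 10.09, 13.1721, 10.7521, 13.1577, 10.2255,
         15.3897, 12.858, 15.0926, 15.3975, 11.5859, 12.4068, 11.868, 13.6867,
         9.7843, 6.6706, 6.602, 12.4645, 12.7503, 8.4017, 10.7908, 13.8442,
         16.1432, 13.1225, 12.9683, 8.2979, 16.2838, 12.6844, 14.0455, 14.8245,
         14.423, 12.7656, 14.4928, 8.3902, 13.7947, 12.2625, 8.3062, 13.4871,
         16.2648, 16.7614, 18.4992, 13.8708, 16.127, 18.33, 15.0119, 19.803)
  d <- expand.grid(subject = 1:8, A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$y <- y
  d
}

test_that("two-way within ANOVA reproduces the frozen reference", {
  d <- rm_fixture()
  res <- rm_anova(d, "y", c("A", "B"), "subject")
  expect_equal(res$F, c(70.540546, 6.093258, 1.218860), tolerance = 1e-6)
  expect_equal(res$eps_gg, c(1.0, 0.926577, 0.798900), tolerance = 1e-6)
  expect_equal(res$p_gg, c(0.000067, 0.014925, 0.320921), tolerance = 1e-4)
  expect_equal(res$eta_g_sq, c(0.408698, 0.241610, 0.053387), tolerance = 1e-6)
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, c(7, 14, 14))
})

test_that("one-way within ANOVA reproduces the frozen reference", {
  d <- aggregate(y ~ subject + B, rm_fixture(), mean)
  res <- rm_anova(d, "y", "B", "subject")
  expect_equal(res$F, 6.093258, tolerance = 1e-6)
  expect_equal(res$p_gg, 0.014925, tolerance = 1e-4)
  expect_equal(res$eta_g_sq, 0.344005, tolerance = 1e-6)
})

test_that("two-level factor F equals the squared paired t", {
  d <- rm_fixture()
  d2 <- aggregate(y ~ subject + A, d, mean)
  res <- rm_anova(d2, "y", "A", "subject")
  wide <- merge(d2[d2$A == "a1", ], d2[d2$A == "a2", ], by = "subject")
  tt <- t.test(wide$y.x, wide$y.y, paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("ANOVA is exchangeable over subject relabeling and flags gaps", {
  d <- rm_fixture()
  res1 <- rm_anova(d, "y", c("A", "B"), "subject")
  perm <- setNames(sample(1:8), 1:8)
  d2 <- d; d2$subject <- perm[as.character(d$subject)]
  res2 <- rm_anova(d2, "y", c("A", "B"), "subject")
  expect_equal(res1$F, res2$F, tolerance = 1e-10)
  expect_error(rm_anova(d[-1, ], "y", c("A", "B"), "subject"),
               "one observation per subject/cell")
})

test_that("post hoc paired t-tests are Bonferroni-adjusted", {
  # 5-pair hand-computed fixture: diffs 1, 2, 1.5, 0.5, 1
  d <- data.frame(subject = rep(1:5, 2),
                  cond = rep(c("x", "y"), each = 5),
                  v = c(5, 6, 7, 8, 9, 4, 4, 5.5, 7.5, 8))
  out <- posthoc_ttests(d, "v", "cond", "subject")
  diffs <- c(1, 2, 1.5, 0.5, 1)
  expect_equal(out$mean_diff, mean(diffs))
  expect_equal(out$t, mean(diffs) / (sd(diffs) / sqrt(5)), tolerance = 1e-12)
  expect_equal(out$cohens_d, mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_equal(out$p_adj, out$p) # single comparison: adjusted = raw
  # identical conditions: t = 0, d = 0
  d2 <- data.frame(subject = rep(1:4, 2), cond = rep(c("x", "y"), each = 4),
                   v = rep(c(1, 2, 3, 4), 2))
  out2 <- posthoc_ttests(d2, "v", "cond", "subject")
  expect_equal(out2$t, 0)
  expect_equal(out2$cohens_d, 0)
  # three levels: m = 3 comparisons, p_adj = min(1, 3p), monotone
  d3 <- rbind(d, data.frame(subject = 1:5, cond = "z", v = c(9, 9, 10, 11, 12)))
  out3 <- posthoc_ttests(d3, "v", "cond", "subject")
  expect_equal(nrow(out3), 3)
  expect_equal(out3$p_adj, pmin(1, out3$p * 3))
  expect_true(all(out3$p_adj >= out3$p))
})

test_that("bootstrap CI is a seeded percentile interval", {
  ci <- bootstrap_ci(rep(3.2, 10), seed = 1)
  expect_equal(ci, c(3.2, 3.2), ignore_attr = TRUE) # constant: zero width
  x <- c(1, 4, 2, 8, 5, 7, 3, 6)
  ci2 <- bootstrap_ci(x, level = 0.68, B = 500, seed = 2)
  expect_true(ci2[1] <= mean(x) && mean(x) <= ci2[2])
  expect_identical(ci2, bootstrap_ci(x, level = 0.68, B = 500, seed = 2))
  # level 1 returns the bootstrap range
  ci3 <- bootstrap_ci(x, level = 1, B = 200, seed = 3)
  expect_true(ci3[1] >= min(x) && ci3[2] <= max(x))
})

test_that("bootstrap coverage of the mean is near nominal", {
  set.seed(77)
  covered <- vapply(1:300, function(r) {
    x <- rnorm(12, mean = 1, sd = 2)
    ci <- bootstrap_ci(x, level = 0.68, B = 300, seed = r)
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.58)
  expect_lt(mean(covered), 0.78)
})

test_that("meridian correlation ranks concordant and discordant data", {
  sa <- data.frame(observer = rep(1:2, each = 3),
                   meridian = rep(c("HM", "LVM", "UVM"), 2),
                   area_mm2 = c(10, 8, 6, 12, 9, 7))
  conc <- data.frame(observer = sa$observer, meridian = sa$meridian,
                     value = sa$area_mm2 * 2 + 1)
  expect_equal(meridian_correlation(sa, conc)$rho, 1)
  disc <- conc; disc$value <- -conc$value
  expect_equal(meridian_correlation(sa, disc, tail = "two")$rho, -1)
  # 6-pair hand-ranked fixture: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  sa6 <- data.frame(observer = 1:6, meridian = "HM",
                    area_mm2 = c(10, 20, 30, 40, 50, 60))
  at6 <- data.frame(observer = 1:6, meridian = "HM",
                    value = c(1.2, 1.1, 1.5, 1.4, 1.9, 1.7))
  # attribute ranks: 2 1 4 3 6 5 vs area ranks 1..6 -> d^2 sums to 6
  expect_equal(meridian_correlation(sa6, at6)$rho,
               1 - 6 * 6 / (6 * 35), tolerance = 1e-12)
  expect_error(meridian_correlation(sa6[1:2, ], at6[1:2, ]), "3 matched")
})
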