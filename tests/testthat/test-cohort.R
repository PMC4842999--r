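# Cohort statistics: per-mouse median aggregation, ANOVA/Tukey, gradients
# and the subtype-weighted diameter consistency check.

test_that("region summaries are means of per-mouse medians", {
  d <- data.frame(mouse = rep(c("m1", "m2", "m3"), each = 5),
                  value = c(rep(300, 5), rep(330, 5), rep(360, 5)))
  s <- summarise_region(d, "value")
  expect_equal(unname(s$per_mouse_medians), c(300, 330, 360))
  expect_equal(s$group_mean, 330)
  expect_equal(s$group_sd, 30)
  expect_equal(s$n_mice, 3)
})

test_that("single-mouse summaries report SD 0 with a flag", {
  d <- data.frame(mouse = "m1", value = c(10, 20, 30))
  s <- summarise_region(d, "value")
  expect_equal(s$group_mean, 20)
  expect_equal(s$group_sd, 0)
  expect_true(s$single_mouse)
})

test_that("empty mouse groups are rejected by name", {
  d <- data.frame(mouse = c("m1", "m2"), value = c(1, NA))
  expect_error(summarise_region(d, "value"), "m2")
})

test_that("summaries are permutation-invariant and unit-equivariant", {
  set.seed(101)
  d <- data.frame(mouse = sample(rep(c("a", "b", "c"), each = 20)),
                  value = runif(60, 100, 400))
  s1 <- summarise_region(d, "value")
  s2 <- summarise_region(d[sample(nrow(d)), ], "value")
  expect_equal(s1$group_mean, s2$group_mean)
  d10 <- d; d10$value <- d$value * 10
  expect_equal(summarise_region(d10, "value")$group_mean,
               10 * s1$group_mean)
})

test_that("subtype fractions per mouse sum to 100", {
  set.seed(103)
  d <- data.frame(mouse = rep(c("m1", "m2", "m3"), each = 100),
                  subtype = classify_subtype(sample(1:4, 300, TRUE,
                                                    prob = c(.6, .25, .1, .05))))
  fr <- subtype_fractions(d)
  expect_equal(unname(rowSums(fr$per_mouse)), rep(100, 3), tolerance = 0.1)
  expect_equal(sum(fr$mean), 100, tolerance = 0.1)
})

test_that("ANOVA behaves at the extremes and matches closed form", {
  # identical group patterns -> F = 0, p = 1
  d0 <- data.frame(region = rep(c("a", "b"), each = 3),
                   value = rep(c(1, 2, 3), 2))
  r0 <- compare_regions(d0)
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  # separated groups -> significant
  d1 <- data.frame(region = rep(c("a", "b"), each = 3),
                   value = c(1, 1.01, 0.99, 2, 2.01, 1.99))
  expect_lt(compare_regions(d1)$p, 0.01)
  # closed-form oracle on a 3-group set
  set.seed(107)
  d2 <- data.frame(region = rep(c("a", "b", "c"), each = 4),
                   value = rnorm(12, rep(c(5, 6, 8), each = 4)))
  r2 <- compare_regions(d2)
  gm <- mean(d2$value)
  means <- tapply(d2$value, d2$region, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((d2$value - means[d2$region])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(r2$F, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(r2$tukey), 3)
  # undersized groups are rejected
  expect_error(compare_regions(data.frame(region = c("a", "a", "b"),
                                          value = 1:3)), "fewer than 2")
})

test_that("gradients handle constant, linear and underpopulated input", {
  d_const <- data.frame(distance_um = rep(seq(20, 140, 20), 3), value = 5)
  g0 <- gradient_analysis(d_const)
  expect_equal(g0$pearson_r, 0)
  d_lin <- data.frame(distance_um = rep(seq(20, 140, 20), 3))
  d_lin$value <- 2 * d_lin$distance_um + 1
  expect_equal(gradient_analysis(d_lin)$pearson_r, 1, tolerance = 1e-12)
  expect_error(gradient_analysis(data.frame(distance_um = c(20, 40),
                                            value = 1:2)), "3 distance bins")
})

test_that("a simulated density decline gives a stably negative correlation", {
  # image-level PSD densities falling 19.2 -> 16.5 per 20 um^2 over
  # 20-140 um, with between-image noise comparable to the reported SDs
  set.seed(109)
  signs <- replicate(50, {
    d <- expand.grid(distance_um = seq(20, 140, 20), img = 1:3)
    mu <- 19.2 + (16.5 - 19.2) * (d$distance_um - 20) / 120
    d$value <- rnorm(nrow(d), mu, 1)
    sign(gradient_analysis(d)$pearson_r)
  })
  expect_true(all(signs == -1))
})

test_that("the subtype-weighted mean diameter behaves correctly", {
  expect_equal(subtype_consistency_report(c(269, 412, 525), c(1, 0, 0)), 269)
  expect_equal(subtype_consistency_report(c(300, 300, 300), c(2, 5, 3)), 300)
  expect_error(subtype_consistency_report(c(1, 2), c(0, 0)), "zero")
})
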