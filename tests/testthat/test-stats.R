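two_pass_anova_f <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y)
  gm <- mean(y)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    yi <- y[g == lev]
    ssb <- ssb + length(yi) * (mean(yi) - gm)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

test_that("one-way ANOVA matches a naive sums-of-squares oracle", {
  for (seed in 1:8) {
    d <- withr::with_seed(seed, data.frame(
      y = rnorm(60), group = sample(c("NC", "SCD", "aMCI"), 60, replace = TRUE)
    ))
    if (min(table(d$group)) < 2) next
    cmp <- anova_oneway(d, "y")
    expect_equal(cmp$statistic, two_pass_anova_f(d$y, d$group), tolerance = 1e-10)
    expect_equal(cmp$p.value,
                 pf(cmp$statistic, cmp$df[1], cmp$df[2], lower.tail = FALSE))
  }
})

test_that("identical group means give F = 0 and degenerate input errors", {
  d <- data.frame(y = c(1, 2, 3, 1, 2, 3), group = rep(c("a", "b"), each = 3))
  expect_equal(anova_oneway(d, "y")$statistic, 0)
  d2 <- data.frame(y = rep(1, 6), group = rep(c("a", "b"), each = 3))
  expect_error(anova_oneway(d2, "y"), class = "wmnet_degenerate_error")
  expect_error(anova_oneway(data.frame(y = 1:3, group = c("a", "a", "b")), "y"),
               class = "wmnet_validation_error")
})

test_that("summary-based ANOVA agrees with raw-data ANOVA on exact summaries", {
  for (seed in 1:6) {
    d <- withr::with_seed(seed, data.frame(
      y = rnorm(45, 10, 3), group = rep(c("NC", "SCD", "aMCI"), each = 15)
    ))
    means <- tapply(d$y, d$group, mean)
    sds <- tapply(d$y, d$group, sd)
    ns <- tapply(d$y, d$group, length)
    f1 <- anova_from_summary(means, sds, ns)$statistic
    f2 <- anova_oneway(d, "y")$statistic
    expect_equal(f1, f2, tolerance = 1e-9)
  }
  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 3), c(10, 10, 10))$statistic, 0)
  expect_error(anova_from_summary(c(1, 2), c(0, 0), c(5, 5)),
               class = "wmnet_degenerate_error")
})

test_that("Pearson chi-square matches the closed form and the expected-count oracle", {
  expect_equal(chi_square_test(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  x <- matrix(c(20, 10, 10, 20), 2)
  expect_equal(chi_square_test(x)$statistic,
               60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30), tolerance = 1e-12)
  tbl <- withr::with_seed(3, matrix(rpois(12, 15) + 1, 3, 4))
  E <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  expect_equal(chi_square_test(tbl)$statistic, sum((tbl - E)^2 / E),
               tolerance = 1e-12)
  expect_equal(chi_square_test(tbl)$df, 6)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)),
               class = "wmnet_validation_error")
})

test_that("ANCOVA reduces to ANOVA with no covariates and vanishes when a covariate explains the metric", {
  d <- withr::with_seed(11, data.frame(
    y = rnorm(60), group = rep(c("NC", "SCD", "aMCI"), each = 20),
    age = rnorm(60, 60, 8), sex = sample(c("M", "F"), 60, TRUE),
    education = rnorm(60, 11, 3)
  ))
  f_red <- ancova_group_effect(d, "y", covariates = character())$statistic
  f_an <- anova_oneway(d, "y")$statistic
  expect_equal(f_red, f_an, tolerance = 1e-10)
})

test_that("a metric driven purely by a confounded covariate loses its group effect under ANCOVA", {
  d <- withr::with_seed(12, {
    group <- rep(c("NC", "SCD", "aMCI"), each = 25)
    age <- 60 + 8 * (group == "aMCI") + rnorm(75, 0, 4)
    data.frame(y = 2 * age + rnorm(75, 0, 1), group = group, age = age)
  })
  expect_lt(anova_oneway(d, "y")$p.value, 0.001) # spurious, via age
  expect_gt(ancova_group_effect(d, "y", covariates = "age")$p.value, 0.05)
})

test_that("ANCOVA reports the collinear column on rank deficiency", {
  d <- withr::with_seed(13, data.frame(
    y = rnorm(30), group = rep(c("a", "b", "c"), 10), age = rnorm(30)
  ))
  d$age2 <- d$age
  expect_error(ancova_group_effect(d, "y", covariates = c("age", "age2")),
               regexp = "age2", class = "wmnet_rank_error")
})

test_that("covariate adjustment shifts the group effect under planted confounding", {
  # age drives the metric AND differs by group; adjusting for age must
  # shrink the group F toward its age-free value
  d <- withr::with_seed(21, {
    group <- rep(c("NC", "SCD", "aMCI"), each = 30)
    age <- 60 + 6 * (group == "aMCI") + rnorm(90, 0, 5)
    data.frame(y = 0.5 * age + rnorm(90, 0, 1), group = group, age = age)
  })
  f_unadj <- anova_oneway(d, "y")$statistic
  f_adj <- ancova_group_effect(d, "y", covariates = "age")$statistic
  expect_lt(f_adj, f_unadj)
})

test_that("partial correlation equals plain Pearson without covariates", {
  d <- withr::with_seed(5, data.frame(x = rnorm(40), y = rnorm(40)))
  res <- partial_correlation(d$x, d$y)
  ct <- cor.test(d$x, d$y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-12)
  z <- withr::with_seed(6, rnorm(40))
  expect_equal(partial_correlation(d$x, d$x, data.frame(z = z))$r, 1,
               tolerance = 1e-12)
})

test_that("partial correlation recovers a planted association", {
  # y = 0.5-ish partial link to x after removing a shared covariate
  for (seed in 1:5) {
    d <- withr::with_seed(seed * 17, {
      z <- rnorm(200)
      x <- 0.8 * z + rnorm(200)
      y <- 0.577 * (x - 0.8 * z) + 2 * z + rnorm(200) # true partial r = 0.5
      data.frame(x = x, y = y, z = z)
    })
    r <- partial_correlation(d$x, d$y, d["z"])$r
    expect_lt(abs(r - 0.5), 0.12)
  }
  expect_error(partial_correlation(rep(1, 20), rnorm(20)),
               class = "wmnet_degenerate_error")
})

test_that("hub selection returns ceil(fraction * N) regions sorted by mean betweenness", {
  nodal <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:4), index = 1:10) |>
    dplyr::mutate(label = sprintf("R%02d", index),
                  betweenness = withr::with_seed(3, runif(40, 0, 20)))
  h <- identify_hubs(nodal, fraction = 0.10)
  expect_equal(nrow(h), 1)
  means <- nodal |> dplyr::group_by(index) |>
    dplyr::summarise(b = mean(betweenness))
  expect_equal(h$index, means$index[which.max(means$b)])
  h3 <- identify_hubs(nodal, fraction = 0.25)
  expect_equal(nrow(h3), 3)
  expect_true(all(diff(h3$betweenness) <= 0))
  expect_error(identify_hubs(nodal[0, ]), class = "wmnet_validation_error")
})

test_that("ties at the hub cutoff keep the lower region index with a warning", {
  nodal <- tibble::tibble(index = 1:10, label = sprintf("R%02d", 1:10),
                          betweenness = c(9, 5, 5, rep(1, 7)))
  expect_warning(h <- identify_hubs(nodal, fraction = 0.2), "tie")
  expect_equal(h$index, c(1, 2))
})

test_that("Bonferroni-adjusted post hoc p values are >= raw and <= 1", {
  d <- withr::with_seed(31, data.frame(
    y = c(rnorm(20), rnorm(20, 1.2), rnorm(20, 2.5)),
    group = rep(c("NC", "SCD", "aMCI"), each = 20)
  ))
  cmp <- anova_oneway(d, "y")
  expect_false(is.null(cmp$posthoc))
  expect_true(all(cmp$posthoc$p.adj >= cmp$posthoc$p.value))
  expect_true(all(cmp$posthoc$p.adj <= 1))
  td <- tidy(cmp)
  expect_true("posthoc" %in% td$term)
  gl <- glance(cmp)
  expect_equal(gl$n, 60)
})
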