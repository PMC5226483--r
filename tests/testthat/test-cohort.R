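test_that("cohort generation is a pure function of the spec", {
  spec <- cohort_spec(n_per_group = c(NC = 2, SCD = 2, aMCI = 2),
                      n_regions = 30, master_seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$subjects[[1]]$fn, b$subjects[[1]]$fn)
  expect_identical(a$subjects[[4]]$fa, b$subjects[[4]]$fa)
  expect_identical(a$table, b$table)
  s1 <- generate_subject(spec, "aMCI", seed = 99)
  s2 <- generate_subject(spec, "aMCI", seed = 99)
  expect_identical(s1$fn, s2$fn)
  expect_identical(s1$scores, s2$scores)
})

test_that("invalid specs are rejected with the offending fields named", {
  expect_error(cohort_spec(lattice_k = 7), regexp = "lattice_k",
               class = "wmnet_validation_error")
  expect_error(cohort_spec(effect_long_range = c(NC = 0, SCD = 0.5, aMCI = 0.2)),
               regexp = "effect_long_range", class = "wmnet_validation_error")
  expect_error(cohort_spec(fa_range = c(0.9, 0.2)), regexp = "fa_range",
               class = "wmnet_validation_error")
})

test_that("generated subjects satisfy all connectivity invariants", {
  spec <- cohort_spec(n_per_group = c(NC = 2, SCD = 2, aMCI = 2), n_regions = 40)
  coh <- generate_cohort(spec, scores = FALSE)
  for (s in coh$subjects) {
    expect_identical(s$fn, t(s$fn))
    expect_true(all(diag(s$fn) == 0))
    expect_true(all(s$fn >= 0) && all(s$fn == round(s$fn)))
    expect_true(all(s$fa >= 0 & s$fa <= 1))
    expect_true(all(s$fa[s$fn == 0] == 0))
    expect_true(all(s$volumes > 0))
    expect_true(s$age >= 50 && s$age <= 80)
    expect_true(s$education >= 0)
    # construction runs without warnings
    expect_no_warning(build_weight_matrix(s))
  }
})

test_that("zero attenuation makes group edge distributions indistinguishable", {
  zero <- c(NC = 0, SCD = 0, aMCI = 0)
  spec <- cohort_spec(n_per_group = c(NC = 8, SCD = 8, aMCI = 8),
                      effect_long_range = zero, effect_hub = zero,
                      subject_sd = 0, master_seed = 42)
  coh <- generate_cohort(spec, scores = FALSE)
  g <- coh$table$group
  pooled_fn <- function(grp) {
    unlist(lapply(coh$subjects[g == grp], function(s) s$fn[upper.tri(s$fn)]))
  }
  ks <- suppressWarnings(ks.test(pooled_fn("NC"), pooled_fn("aMCI")))
  expect_gt(ks$p.value, 0.01)
})

test_that("near-total attenuation erases the long-range edges and collapses efficiency", {
  spec <- cohort_spec(
    n_per_group = c(NC = 6, SCD = 1, aMCI = 6),
    effect_long_range = c(NC = 0, SCD = 0, aMCI = 0.99),
    effect_hub = c(NC = 0, SCD = 0, aMCI = 0.99),
    master_seed = 7
  )
  coh <- generate_cohort(spec, scores = FALSE)
  g <- coh$table$group
  lr <- which(coh$truth$long_range & upper.tri(coh$truth$long_range))
  for (s in coh$subjects[g == "aMCI"]) {
    net <- build_weight_matrix(s)
    expect_true(all(net$weights[lr] == 0)) # shortcuts fall below threshold
  }
  eg <- vapply(coh$subjects, function(s) global_efficiency(build_weight_matrix(s)),
               numeric(1))
  # efficiency collapses toward the lattice-only level; the short-range
  # lattice keeps Eg well above zero, so the drop is large but bounded
  expect_lt(mean(eg[g == "aMCI"]), 0.8 * mean(eg[g == "NC"]))
})

test_that("default cohort shows the planted efficiency gradient NC > SCD > aMCI", {
  coh <- generate_cohort(cohort_spec(master_seed = 1), scores = FALSE)
  eg <- vapply(coh$subjects, function(s) global_efficiency(build_weight_matrix(s)),
               numeric(1))
  g <- coh$table$group
  expect_gt(mean(eg[g == "NC"]), mean(eg[g == "SCD"]))
  expect_gt(mean(eg[g == "SCD"]), mean(eg[g == "aMCI"]))
})

test_that("the targeted hub loses betweenness in aMCI relative to NC", {
  coh <- generate_cohort(cohort_spec(master_seed = 2), scores = FALSE)
  hub <- coh$truth$hub_index
  b <- vapply(coh$subjects, function(s) {
    betweenness_centrality(build_weight_matrix(s))$betweenness[hub]
  }, numeric(1))
  g <- coh$table$group
  expect_lt(mean(b[g == "aMCI"]), mean(b[g == "NC"]))
})

test_that("planted betweenness-score link is recovered by partial correlation", {
  hits <- vapply(1:6, function(s) {
    coh <- generate_cohort(cohort_spec(master_seed = 3000 + s))
    hub <- coh$truth$hub_index
    b <- vapply(coh$subjects, function(su) {
      betweenness_centrality(build_weight_matrix(su))$betweenness[hub]
    }, numeric(1))
    d <- coh$table
    partial_correlation(b, d$AVLT_D, d[c("age", "sex", "education")])$r > 0
  }, logical(1))
  expect_true(all(hits))
})

test_that("ground truth records the planted structure", {
  spec <- cohort_spec(n_per_group = c(NC = 2, SCD = 1, aMCI = 1), n_regions = 30)
  coh <- generate_cohort(spec, scores = FALSE)
  tr <- coh$truth
  expect_true(all(tr$long_range[tr$long_range] %in% tr$scaffold[tr$long_range]))
  expect_true(sum(tr$long_range) > 0)
  expect_equal(tr$effect_long_range[["aMCI"]], 0.30)
  expect_equal(tr$master_seed, spec$master_seed)
  # long-range edges are a subset of the scaffold edges
  expect_true(all(which(tr$long_range) %in% which(tr$scaffold)))
})
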