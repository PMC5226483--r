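#' Identify betweenness hubs for one group
#'
#' Averages nodal betweenness across a group's subjects and returns the top
#' `ceiling(fraction * N)` regions — the conventional top-decile hub
#' definition. A tie exactly at the cut-off is broken toward the lower
#' region index, with a warning.
#'
#' @param nodal Tibble of per-subject nodal metrics for ONE group, with
#'   columns `index`, `label`, `betweenness` (and typically `subject_id`).
#' @param fraction Hub fraction in (0, 1); default 0.10.
#' @return A tibble of class `hub_report` (columns `rank`, `index`, `label`,
#'   `betweenness`), sorted descending, with attributes `cutoff_rank` and
#'   `fraction`.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = c(NC = 3, SCD = 2, aMCI = 2))
#' coh <- generate_cohort(spec)
#' nets <- lapply(coh$subjects, build_weight_matrix)
#' nodal <- dplyr::bind_rows(lapply(nets, nodal_metrics))
#' identify_hubs(nodal)
identify_hubs <- function(nodal, fraction = 0.10) {
  if (!is.data.frame(nodal) || nrow(nodal) == 0) {
    abort("nodal metrics table is empty", class = "wmnet_validation_error")
  }
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie in (0, 1)", class = "wmnet_validation_error")
  }
  means <- nodal |>
    dplyr::group_by(.data$index, .data$label) |>
    dplyr::summarise(betweenness = mean(.data$betweenness), .groups = "drop")
  n_regions <- nrow(means)
  n_hubs <- ceiling(fraction * n_regions)
  ranked <- dplyr::arrange(means, dplyr::desc(.data$betweenness), .data$index)
  cut_val <- ranked$betweenness[n_hubs]
  if (n_hubs < n_regions && ranked$betweenness[n_hubs + 1] == cut_val) {
    warn(sprintf("tie at the hub cutoff (betweenness = %.6g); keeping the lower region index",
                 cut_val))
  }
  out <- ranked |>
    dplyr::slice_head(n = n_hubs) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  attr(out, "cutoff_rank") <- n_hubs
  attr(out, "fraction") <- fraction
  class(out) <- c("hub_report", class(out))
  out
}

new_group_comparison <- function(metric, method, statistic, df1, df2, p,
                                 group_stats, posthoc = NULL, model = NULL) {
  structure(
    list(metric = metric, method = method, statistic = statistic,
         df = c(df1, df2), p.value = p, group_stats = group_stats,
         posthoc = posthoc, model = model),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): F(%g, %g) = %.3f, p = %.4g\n",
              x$metric, x$method, x$df[1], x$df[2], x$statistic, x$p.value))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Bonferroni):\n")
    for (r in seq_len(nrow(x$posthoc))) {
      cat(sprintf("    %-10s p_adj = %.4g\n", x$posthoc$contrast[r],
                  x$posthoc$p.adj[r]))
    }
  }
  invisible(x)
}

# Canonical NC < SCD < aMCI ordering when the labels are the clinical
# groups; otherwise the natural factor order.
group_factor <- function(g) {
  g <- as.character(g)
  canon <- c("NC", "SCD", "aMCI")
  if (all(unique(g) %in% canon)) factor(g, intersect(canon, unique(g)))
  else factor(g)
}

group_summaries <- function(value, group) {
  tibble::tibble(group = group, value = value) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
}

# Pooled-variance pairwise t tests (classical post hoc after a one-way
# ANOVA), Bonferroni-adjusted over the number of pairs.
pairwise_posthoc <- function(value, group, msw, df_w) {
  gs <- group_summaries(value, group)
  pairs <- utils::combn(gs$group, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- gs[gs$group == p[1], ]; b <- gs[gs$group == p[2], ]
    se <- sqrt(msw * (1 / a$n + 1 / b$n))
    t <- (a$mean - b$mean) / se
    praw <- 2 * pt(-abs(t), df_w)
    tibble::tibble(contrast = paste(p, collapse = "-"),
                   estimate = a$mean - b$mean, t = t, df = df_w,
                   p.value = praw,
                   p.adj = pmin(1, length(pairs) * praw))
  })
}

#' One-way ANOVA across groups
#'
#' Classical between/within decomposition: `F = MSB / MSW` on
#' `(k - 1, n - k)` degrees of freedom. When the omnibus test is significant
#' at `alpha`, pooled-variance pairwise t tests with Bonferroni adjustment
#' are attached.
#'
#' @param data A data frame.
#' @param value Name of the numeric outcome column (string).
#' @param group Name of the group column (string).
#' @param alpha Omnibus significance level gating the post hoc tests.
#' @return A `group_comparison` object (see [tidy.group_comparison()]).
#' @export
anova_oneway <- function(data, value, group = "group", alpha = 0.05) {
  y <- data[[value]]; g <- group_factor(data[[group]])
  keep <- stats::complete.cases(y, g)
  y <- y[keep]; g <- droplevels(g[keep])
  k <- nlevels(g); n <- length(y)
  if (k < 2 || any(table(g) < 2)) {
    abort("need >= 2 groups with >= 2 observations each",
          class = "wmnet_validation_error")
  }
  gm <- mean(y)
  means <- tapply(y, g, mean); ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  if (ssw == 0) {
    abort("zero within-group variance; F undefined", class = "wmnet_degenerate_error")
  }
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  f <- msb / msw
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  posthoc <- if (p < alpha) pairwise_posthoc(y, g, msw, n - k) else NULL
  new_group_comparison(value, "anova", f, k - 1, n - k, p,
                       group_summaries(y, g), posthoc)
}

#' One-way ANOVA from published group summaries
#'
#' Reconstructs the F statistic from group means, SDs and sizes alone:
#' `SSB` from the means about the size-weighted grand mean and
#' `SSW = sum (n_g - 1) sd_g^2`. Exact summaries reproduce [anova_oneway()]
#' on the raw data; rounded published summaries reproduce published F values
#' to within their rounding error.
#'
#' @param means,sds,ns Numeric vectors, one entry per group.
#' @param metric Label for the comparison.
#' @return A `group_comparison` object.
#' @export
#' @examples
#' # Montreal Cognitive Assessment, three diagnostic groups:
#' anova_from_summary(c(26.7, 26.0, 19.8), c(2.7, 2.0, 3.8), c(36, 21, 33))
anova_from_summary <- function(means, sds, ns, metric = "summary") {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) {
    abort("means, sds, ns must have equal length >= 2", class = "wmnet_validation_error")
  }
  if (any(ns < 2)) abort("every group needs n >= 2", class = "wmnet_validation_error")
  if (any(sds < 0)) abort("sds must be non-negative", class = "wmnet_validation_error")
  n <- sum(ns)
  gm <- sum(ns * means) / n
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) {
    abort("all group SDs are zero; F undefined", class = "wmnet_degenerate_error")
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  gs <- tibble::tibble(group = as.character(seq_len(k)), n = ns,
                       mean = means, sd = sds)
  new_group_comparison(metric, "anova_from_summary", f, k - 1, n - k, p, gs)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum (O - E)^2 / E` with `(r - 1)(c - 1)` degrees of freedom, no
#' continuity correction (matching the usual categorical group comparison
#' of, e.g., sex ratios).
#'
#' @param tbl A matrix of counts.
#' @return A tibble `statistic`, `df`, `p.value`.
#' @export
chi_square_test <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    abort("contingency table has a zero marginal", class = "wmnet_validation_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value)
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' Fits `value ~ covariates + group` and tests the group factor by the
#' partial F comparing the full model against the covariates-only model
#' (Type-III style). When the omnibus test is significant, Bonferroni-
#' adjusted pairwise contrasts of the adjusted group means are attached.
#'
#' @param data A data frame containing the outcome, group and covariates.
#' @param value Outcome column name (string).
#' @param group Group column name.
#' @param covariates Character vector of covariate column names (may be
#'   empty, reducing to one-way ANOVA by regression).
#' @param alpha Significance level gating post hoc contrasts.
#' @return A `group_comparison` object with `method = "ancova"`.
#' @export
ancova_group_effect <- function(data, value, group = "group",
                                covariates = c("age", "sex", "education"),
                                alpha = 0.05) {
  data <- as.data.frame(data)
  data[[group]] <- group_factor(data[[group]])
  if ("sex" %in% covariates && !is.numeric(data$sex)) {
    data$sex <- as.numeric(factor(data$sex)) - 1 # 0/1 coding
  }
  keep <- stats::complete.cases(data[c(value, group, covariates)])
  data <- data[keep, , drop = FALSE]
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- lm(stats::reformulate(c(covariates, group), response = value), data = data)
  if (anyNA(coef(full))) {
    bad <- names(coef(full))[is.na(coef(full))]
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(bad, collapse = ", ")), class = "wmnet_rank_error")
  }
  reduced <- lm(stats::reformulate(strsplit(rhs_cov, " \\+ ")[[1]], response = value),
                data = data)
  if (full$df.residual < 1) {
    abort(sprintf("no residual degrees of freedom (n = %d, %d parameters)",
                  nrow(data), length(coef(full))),
          class = "wmnet_validation_error")
  }
  cmp <- anova(reduced, full)
  f <- cmp$F[2]; df1 <- cmp$Df[2]; df2 <- cmp$Res.Df[2]
  p <- cmp$`Pr(>F)`[2]
  posthoc <- if (p < alpha) ancova_posthoc(full, group) else NULL
  new_group_comparison(value, "ancova", f, df1, df2, p,
                       group_summaries(data[[value]], data[[group]]),
                       posthoc, model = full)
}

# Pairwise contrasts of adjusted group means from the fitted ANCOVA,
# Bonferroni-adjusted.
ancova_posthoc <- function(fit, group) {
  levs <- levels(fit$model[[group]])
  cf <- coef(fit); V <- vcov(fit)
  term_of <- function(lev) if (lev == levs[1]) NULL else paste0(group, lev)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  df <- fit$df.residual
  purrr::map_dfr(pairs, function(p) {
    L <- setNames(numeric(length(cf)), names(cf))
    t1 <- term_of(p[1]); t2 <- term_of(p[2])
    if (!is.null(t1)) L[t1] <- 1
    if (!is.null(t2)) L[t2] <- L[t2] - 1
    est <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    t <- est / se
    praw <- 2 * pt(-abs(t), df)
    tibble::tibble(contrast = paste(p, collapse = "-"), estimate = est,
                   t = t, df = df, p.value = praw,
                   p.adj = pmin(1, length(pairs) * praw))
  })
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariates; the p value uses the t transform on
#' `n - 2 - k` degrees of freedom (k = number of covariates). With no
#' covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates; a `sex`
#'   column of characters or factors is recoded 0/1.
#' @return A tibble `r`, `n`, `df`, `statistic`, `p.value`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    Z <- NULL; k <- 0
    keep <- stats::complete.cases(x, y)
  } else {
    Z <- as.data.frame(covariates)
    if ("sex" %in% names(Z) && !is.numeric(Z$sex)) {
      Z$sex <- as.numeric(factor(Z$sex)) - 1
    }
    keep <- stats::complete.cases(x, y, Z)
    Z <- as.matrix(Z[keep, , drop = FALSE])
    k <- ncol(Z)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n <= k + 2) {
    abort("need n > number of covariates + 2", class = "wmnet_validation_error")
  }
  if (!is.null(Z)) {
    x <- resid(lm(x ~ Z))
    y <- resid(lm(y ~ Z))
  }
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    abort("residuals are (near-)constant; correlation undefined",
          class = "wmnet_degenerate_error")
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, n = n, df = df, statistic = t,
                 p.value = 2 * pt(-abs(t), df))
}
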