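#' Run the full connectome analysis pipeline
#'
#' Orchestrates, for a cohort of subjects: weighted network construction at
#' the streamline threshold; global metrics (optionally normalized against
#' degree-preserving null networks); nodal betweenness; per-group hub
#' identification; group statistics on every global metric and on nodal
#' betweenness across all regions; and, within each patient group,
#' covariate-adjusted correlations between cognitive scores and the
#' betweenness of regions showing significant group differences.
#'
#' @param subjects Either a list of [subject_connectivity()] objects, a
#'   [generate_cohort()] result, or the path to a subject table (see
#'   [read_subject_table()]).
#' @param fn_threshold Streamline threshold (default 3).
#' @param n_nulls Null networks per subject for gamma/lambda/sigma
#'   (default 100; 0 skips normalization).
#' @param swaps_per_edge Rewiring effort per null.
#' @param hub_fraction Hub fraction (default 0.10).
#' @param stats_mode `"ancova"` (covariate-adjusted, the default) or
#'   `"anova"`.
#' @param covariates Covariate columns for ANCOVA / partial correlations
#'   (default age, sex, education).
#' @param nodal_correction Multiple-comparison mode across regions for the
#'   nodal tests: `"none"` (default), `"fdr"`, or `"bonferroni"`. Reports
#'   always carry the chosen mode.
#' @param alpha Significance level (default 0.05).
#' @param correlate_all Correlate scores with all regions, not only those
#'   with significant group differences.
#' @param seed Master seed for all randomness (null ensembles).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param skip_bad Skip subjects whose files fail to load instead of
#'   aborting.
#' @return A list of class `wmnet_results` with tibbles `global_metrics`,
#'   `nodal_metrics`, `hubs`, `global_comparisons`, `nodal_comparisons`,
#'   `correlations`, and a `manifest` list.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = c(NC = 4, SCD = 3, aMCI = 4),
#'                     n_regions = 30)
#' res <- run_pipeline(generate_cohort(spec), n_nulls = 5, seed = 1)
#' res$global_comparisons
run_pipeline <- function(subjects,
                         fn_threshold = 3,
                         n_nulls = 100,
                         swaps_per_edge = 10,
                         hub_fraction = 0.10,
                         stats_mode = c("ancova", "anova"),
                         covariates = c("age", "sex", "education"),
                         nodal_correction = c("none", "fdr", "bonferroni"),
                         alpha = 0.05,
                         correlate_all = FALSE,
                         seed = 1L,
                         out_dir = NULL,
                         skip_bad = FALSE) {
  stats_mode <- match.arg(stats_mode)
  nodal_correction <- match.arg(nodal_correction)
  excluded <- tibble::tibble(subject_id = character(), reason = character())

  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  if (is.character(subjects)) {
    tbl <- read_subject_table(subjects)
    loaded <- purrr::map(seq_len(nrow(tbl)), function(i) {
      tryCatch(load_subject(tbl[i, ]), error = function(e) {
        structure(list(id = tbl$subject_id[i], msg = conditionMessage(e)),
                  class = "wmnet_load_failure")
      })
    })
    bad <- purrr::keep(loaded, inherits, "wmnet_load_failure")
    if (length(bad)) {
      excluded <- purrr::map_dfr(bad, function(b) {
        tibble::tibble(subject_id = b$id, reason = b$msg)
      })
      if (!skip_bad) {
        abort(paste0("failed to load subject(s): ",
                     paste(excluded$subject_id, collapse = ", "),
                     "; first error: ", excluded$reason[1]),
              class = "wmnet_load_error")
      }
    }
    subjects <- purrr::discard(loaded, inherits, "wmnet_load_failure")
  }
  if (length(subjects) == 0) {
    abort("no usable subjects", class = "wmnet_validation_error")
  }
  groups_present <- unique(vapply(subjects, `[[`, character(1), "group"))
  if (length(groups_present) < 2) {
    abort("need at least 2 groups for group statistics",
          class = "wmnet_validation_error")
  }

  covars <- purrr::map_dfr(subjects, function(s) {
    tibble::tibble(subject_id = s$subject_id, group = s$group, age = s$age,
                   sex = s$sex, education = s$education)
  })
  score_tbl <- purrr::map_dfr(subjects, function(s) {
    base <- tibble::tibble(subject_id = s$subject_id)
    if (length(s$scores)) {
      base <- dplyr::bind_cols(base, tibble::as_tibble(as.list(s$scores)))
    }
    base
  })

  networks <- purrr::map(subjects, build_weight_matrix, fn_threshold = fn_threshold)

  global <- purrr::imap_dfr(networks, function(net, i) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = subjects[[i]]$subject_id,
                     group = subjects[[i]]$group),
      global_metrics(net, n_nulls = n_nulls, swaps_per_edge = swaps_per_edge,
                     seed = derive_seed(seed, i))
    )
  })

  nodal <- purrr::imap_dfr(networks, function(net, i) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = subjects[[i]]$subject_id,
                     group = subjects[[i]]$group),
      nodal_metrics(net)
    )
  })

  hubs <- nodal |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(d, key) {
      h <- identify_hubs(d, fraction = hub_fraction)
      dplyr::mutate(tibble::as_tibble(h), group = key$group, .before = 1)
    }) |>
    dplyr::bind_rows()

  metric_cols <- intersect(c("Cp", "Lp", "Eg", "Eloc", "gamma", "lambda", "sigma"),
                           names(global))
  gdata <- dplyr::left_join(global, covars, by = c("subject_id", "group"))
  run_test <- function(data, value) {
    if (stats_mode == "ancova") {
      ancova_group_effect(data, value, covariates = covariates, alpha = alpha)
    } else {
      anova_oneway(data, value, alpha = alpha)
    }
  }
  global_cmp <- purrr::map_dfr(metric_cols, function(mc) {
    ok <- is.finite(gdata[[mc]])
    cmp <- tryCatch(run_test(gdata[ok, ], mc), error = function(e) {
      warn(sprintf("group test on %s failed: %s", mc, conditionMessage(e)))
      NULL
    })
    if (is.null(cmp)) return(NULL)
    tidy_comparison(cmp)
  })

  ndata <- dplyr::left_join(nodal, covars, by = c("subject_id", "group"))
  nodal_cmp <- ndata |>
    dplyr::group_by(.data$index, .data$label) |>
    dplyr::group_map(function(d, key) {
      cmp <- tryCatch(run_test(dplyr::rename(d, value = "betweenness"), "value"),
                      error = function(e) NULL)
      if (is.null(cmp)) return(NULL)
      dplyr::mutate(tidy_comparison(cmp), index = key$index, label = key$label,
                    .before = 1)
    }) |>
    dplyr::bind_rows()
  if (nrow(nodal_cmp) == 0) {
    nodal_cmp <- tibble::tibble(index = integer(), label = character(),
                                metric = character(), method = character(),
                                statistic = numeric(), df1 = numeric(),
                                df2 = numeric(), p.value = numeric())
  }
  nodal_cmp$p.adjusted <- switch(nodal_correction,
    none = nodal_cmp$p.value,
    fdr = stats::p.adjust(nodal_cmp$p.value, "fdr"),
    bonferroni = stats::p.adjust(nodal_cmp$p.value, "bonferroni")
  )
  nodal_cmp$correction <- nodal_correction

  sig_regions <- nodal_cmp$label[nodal_cmp$p.adjusted < alpha]
  corr_regions <- if (correlate_all) unique(nodal$label) else sig_regions
  score_cols <- setdiff(names(score_tbl), "subject_id")
  cdata <- nodal |>
    dplyr::filter(.data$label %in% corr_regions) |>
    dplyr::left_join(covars, by = c("subject_id", "group")) |>
    dplyr::left_join(score_tbl, by = "subject_id")
  correlations <- purrr::map_dfr(
    intersect(c("SCD", "aMCI"), groups_present), function(g) {
      dg <- dplyr::filter(cdata, .data$group == g)
      purrr::map_dfr(unique(dg$label), function(reg) {
        dr <- dplyr::filter(dg, .data$label == reg)
        purrr::map_dfr(score_cols, function(sc) {
          res <- tryCatch(
            partial_correlation(dr$betweenness, dr[[sc]],
                                dr[intersect(covariates, names(dr))]),
            error = function(e) NULL
          )
          if (is.null(res)) return(NULL)
          dplyr::mutate(res, group = g, region = reg, score = sc, .before = 1)
        })
      })
    }
  )

  manifest <- list(
    package = "wmnet", version = as.character(utils::packageVersion("wmnet")),
    fn_threshold = fn_threshold, n_nulls = n_nulls,
    swaps_per_edge = swaps_per_edge, hub_fraction = hub_fraction,
    stats_mode = stats_mode, covariates = covariates,
    nodal_correction = nodal_correction, alpha = alpha,
    correlate_all = correlate_all, seed = seed,
    n_subjects = as.list(table(covars$group)),
    excluded = excluded
  )

  res <- structure(
    list(global_metrics = global, nodal_metrics = nodal, hubs = hubs,
         global_comparisons = global_cmp, nodal_comparisons = nodal_cmp,
         correlations = correlations, manifest = manifest,
         networks = networks),
    class = "wmnet_results"
  )
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.wmnet_results <- function(x, ...) {
  cat(sprintf("<wmnet_results> %d subjects, %d global comparisons, %d hub rows\n",
              nrow(x$global_metrics), nrow(x$global_comparisons), nrow(x$hubs)))
  print(x$global_comparisons)
  invisible(x)
}

# Flatten a group_comparison into one tidy row with post hoc columns.
tidy_comparison <- function(cmp) {
  row <- tibble::tibble(
    metric = cmp$metric, method = cmp$method, statistic = cmp$statistic,
    df1 = cmp$df[1], df2 = cmp$df[2], p.value = cmp$p.value
  )
  if (!is.null(cmp$posthoc)) {
    ph <- setNames(cmp$posthoc$p.adj,
                   paste0("p_", gsub("-", "_", cmp$posthoc$contrast)))
    row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(ph)))
  }
  row
}

#' Write pipeline results to a directory
#'
#' Emits tidy delimited-text tables (`global_metrics.csv`,
#' `nodal_metrics.csv`, `group_comparison.csv`, `nodal_comparison.csv`,
#' `hubs_<group>.csv`, `correlations.csv`), per-group BrainNet `.node` /
#' `.edge` files on the group-mean network, and a `manifest.json` recording
#' configuration, seed and software version — enough to reproduce the run.
#'
#' @param res A `wmnet_results` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$global_metrics, file.path(dir, "global_metrics.csv"))
  readr::write_csv(res$nodal_metrics, file.path(dir, "nodal_metrics.csv"))
  readr::write_csv(res$global_comparisons, file.path(dir, "group_comparison.csv"))
  readr::write_csv(res$nodal_comparisons, file.path(dir, "nodal_comparison.csv"))
  if (nrow(res$correlations)) {
    readr::write_csv(res$correlations, file.path(dir, "correlations.csv"))
  } else {
    readr::write_csv(tibble::tibble(group = character(), region = character(),
                                    score = character(), r = numeric(),
                                    p.value = numeric(), n = integer()),
                     file.path(dir, "correlations.csv"))
  }
  atlas <- res$networks[[1]]$atlas
  groups <- unique(res$hubs$group)
  for (g in groups) {
    hg <- dplyr::filter(res$hubs, .data$group == g)
    readr::write_csv(hg, file.path(dir, sprintf("hubs_%s.csv", g)))
    nodal_g <- res$nodal_metrics |>
      dplyr::filter(.data$group == g) |>
      dplyr::group_by(.data$index, .data$label) |>
      dplyr::summarise(betweenness = mean(.data$betweenness), .groups = "drop")
    if (all(is.finite(atlas$x))) {
      write_node_file(nodal_g, atlas, file.path(dir, sprintf("%s.node", g)),
                      hubs = hg$label)
      grp_ids <- res$global_metrics$group == g
      mean_w <- Reduce(`+`, purrr::map(res$networks[grp_ids], "weights")) / sum(grp_ids)
      write_edge_file(weighted_network(mean_w, atlas),
                      file.path(dir, sprintf("%s.edge", g)))
    }
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
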