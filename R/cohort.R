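#' Specification of a synthetic three-group connectome cohort
#'
#' Parameterizes a generator that emulates tractography-derived inputs
#' (fiber-number matrices, per-connection FA, region volumes) for a
#' normal-control (NC), subjective-cognitive-decline (SCD) and amnestic-MCI
#' (aMCI) cohort with planted, graded network disruption. All subjects in a
#' cohort share one anatomical scaffold — a ring lattice with `lattice_k`
#' neighbors rewired with probability `rewire_p` (a Watts–Strogatz
#' small-world construction) — and differ in per-subject edge noise. Disease
#' effects attenuate FN and FA jointly (each by `1 - effect`) on the
#' rewired, long-range edges and on edges incident to `hub_region`, so edge
#' weights inherit the effect monotonically; SCD attenuation is intermediate
#' between NC (zero) and aMCI by default, mirroring the graded-disruption
#' hypothesis the generator exists to exercise.
#'
#' @param n_per_group Named counts for NC/SCD/aMCI (default 36/21/33).
#' @param n_regions Number of regions (default 90, the AAL-90 atlas).
#' @param lattice_k Ring-lattice neighbor count (even; default 8).
#' @param rewire_p Rewiring probability creating long-range edges
#'   (default 0.1).
#' @param fn_mean,fn_dispersion Negative-binomial streamline-count model
#'   (mean 20, dispersion 5).
#' @param fa_shape Beta shape parameters for FA (default c(4, 4)).
#' @param fa_range FA support after scaling (default \[0.2, 0.7\]).
#' @param vol_meanlog,vol_sdlog Log-normal region-volume model
#'   (median 8000 mm^3, sdlog 0.3).
#' @param effect_long_range Named fractional attenuation of FN and FA on
#'   long-range edges per group (default NC 0, SCD 0.15, aMCI 0.30).
#' @param effect_hub Attenuation on edges incident to `hub_region`
#'   (default NC 0, SCD 0, aMCI 0.4: the hub disruption is an aMCI-stage
#'   phenomenon; the SCD hub set stays control-like).
#' @param hub_region Label of the targeted hub (default `"PCUN.R"`; ignored
#'   with fewer than 90 regions, where the last region is used).
#' @param subject_sd SD of the per-subject log-normal global FN scale —
#'   between-subject biological heterogeneity (default 0.18).
#' @param score_model Cognitive-score model: per-group means/SDs, the
#'   betweenness-linked coefficients, and the standardization constants for
#'   the hub-betweenness covariate. See [default_score_model()].
#' @param master_seed Integer master seed; the cohort is a pure function of
#'   the spec (which includes this seed).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(NC = 36, SCD = 21, aMCI = 33),
                        n_regions = 90,
                        lattice_k = 8, rewire_p = 0.1,
                        fn_mean = 20, fn_dispersion = 5,
                        fa_shape = c(4, 4), fa_range = c(0.2, 0.7),
                        vol_meanlog = log(8000), vol_sdlog = 0.3,
                        effect_long_range = c(NC = 0, SCD = 0.15, aMCI = 0.30),
                        effect_hub = c(NC = 0, SCD = 0, aMCI = 0.4),
                        hub_region = "PCUN.R",
                        subject_sd = 0.18,
                        score_model = default_score_model(),
                        master_seed = 1L) {
  spec <- list(
    n_per_group = n_per_group, n_regions = n_regions,
    lattice_k = lattice_k, rewire_p = rewire_p,
    fn_mean = fn_mean, fn_dispersion = fn_dispersion,
    fa_shape = fa_shape, fa_range = fa_range,
    vol_meanlog = vol_meanlog, vol_sdlog = vol_sdlog,
    effect_long_range = effect_long_range, effect_hub = effect_hub,
    hub_region = hub_region, subject_sd = subject_sd,
    score_model = score_model, master_seed = as.integer(master_seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  bad <- character()
  groups <- c("NC", "SCD", "aMCI")
  if (!all(groups %in% names(spec$n_per_group)) || any(spec$n_per_group < 1)) {
    bad <- c(bad, "n_per_group")
  }
  if (spec$n_regions < 10) bad <- c(bad, "n_regions")
  if (spec$lattice_k < 2 || spec$lattice_k %% 2 != 0 ||
      spec$lattice_k >= spec$n_regions) bad <- c(bad, "lattice_k")
  if (spec$rewire_p < 0 || spec$rewire_p > 1) bad <- c(bad, "rewire_p")
  if (spec$fn_mean <= 0 || spec$fn_dispersion <= 0) bad <- c(bad, "fn_mean/fn_dispersion")
  if (any(spec$fa_range < 0) || any(spec$fa_range > 1) ||
      diff(spec$fa_range) <= 0) bad <- c(bad, "fa_range")
  for (eff in c("effect_long_range", "effect_hub")) {
    e <- spec[[eff]]
    if (!all(groups %in% names(e)) || any(e < 0) || any(e >= 1)) bad <- c(bad, eff)
    else if (e["SCD"] > e["aMCI"]) bad <- c(bad, paste0(eff, " (SCD > aMCI)"))
  }
  if (spec$subject_sd < 0) bad <- c(bad, "subject_sd")
  if (length(bad)) {
    abort(paste0("invalid cohort spec field(s): ", paste(bad, collapse = ", ")),
          class = "wmnet_validation_error")
  }
  invisible(spec)
}

#' Default cognitive-score model
#'
#' Group means and SDs typical of NC/SCD/aMCI neuropsychology (MMSE, MoCA,
#' and the immediate/delayed/recognition subscores of an auditory verbal
#' learning test), plus a planted positive link from hub betweenness to MoCA
#' and delayed recall. The link coefficient is 0.4 of the score SD per SD of
#' betweenness, giving a true partial correlation near 0.4; `b_center` and
#' `b_scale` standardize hub betweenness to roughly zero mean / unit SD
#' under the default generator.
#'
#' @return A list with elements `means`, `sds` (5 x 3 matrices), `betas`,
#'   `b_center`, `b_scale`.
#' @export
default_score_model <- function() {
  scores <- c("MMSE", "MoCA", "AVLT_I", "AVLT_D", "AVLT_R")
  groups <- c("NC", "SCD", "aMCI")
  means <- matrix(c(
    28.1, 27.9, 25.0,
    26.7, 26.0, 19.8,
    8.9, 7.8, 5.7,
    10.3, 7.9, 3.9,
    12.5, 10.4, 7.9
  ), nrow = 5, byrow = TRUE, dimnames = list(scores, groups))
  sds <- matrix(c(
    1.9, 1.5, 3.0,
    2.7, 2.0, 3.8,
    1.5, 1.9, 1.5,
    2.4, 2.4, 2.4,
    2.1, 2.2, 4.1
  ), nrow = 5, byrow = TRUE, dimnames = list(scores, groups))
  betas <- setNames(c(0, 0.4 * 2.7, 0, 0.4 * 2.4, 0), scores)
  betas["MoCA"] <- 0.4 * 2.7
  betas["AVLT_D"] <- 0.4 * 2.4
  list(means = means, sds = sds, betas = betas, b_center = 77, b_scale = 112)
}

# Watts-Strogatz scaffold: ring lattice plus rewired shortcuts. Returns the
# logical adjacency, with rewired ("long-range") edges flagged. Pure
# function of (spec); seeded from the spec's master seed so every subject
# shares the anatomy.
cohort_scaffold <- function(spec) {
  n <- spec$n_regions
  k2 <- spec$lattice_k / 2
  local_seed(derive_seed(spec$master_seed, 0), {
    adj <- matrix(FALSE, n, n)
    long <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (d in seq_len(k2)) {
        j <- ((i - 1 + d) %% n) + 1
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    # rewire a fixed count round(p * m) of lattice edges so the planted
    # long-range substrate (and hence the disease effect) has the same size
    # in every cohort; placement is still random
    n_rewire <- round(spec$rewire_p * nrow(edges))
    for (e in sample.int(nrow(edges), n_rewire)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      if (!adj[i, j]) next # already rewired away
      cand <- which(!adj[i, ] & seq_len(n) != i)
      if (length(cand) == 0) next
      jnew <- cand[sample.int(length(cand), 1)]
      adj[i, j] <- adj[j, i] <- FALSE
      long[i, j] <- long[j, i] <- FALSE
      adj[i, jnew] <- adj[jnew, i] <- TRUE
      long[i, jnew] <- long[jnew, i] <- TRUE
    }
    list(adj = adj, long = long)
  })
}

hub_index <- function(spec, atlas) {
  if (spec$n_regions == 90 && spec$hub_region %in% atlas$label) {
    match(spec$hub_region, atlas$label)
  } else {
    spec$n_regions # fallback for reduced toy atlases
  }
}

truncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Generate one synthetic subject
#'
#' Draws one participant's FN/FA/volume data on the cohort scaffold, with
#' the group's attenuation applied to long-range and hub-incident edges, and
#' demographics near the reference cohort (age ~ N(62, 9) truncated to
#' 50–80 years; education ~ N(10.5, 4) truncated at 0; group-specific sex
#' ratios). With `scores = TRUE` the cognitive scores are generated from the
#' score model, linked to the subject's realized hub betweenness.
#'
#' @param spec A [cohort_spec()].
#' @param group `"NC"`, `"SCD"` or `"aMCI"`.
#' @param seed Integer seed; the subject is a pure function of
#'   `(spec, group, seed)`.
#' @param scaffold Optional precomputed scaffold (shared across a cohort).
#' @param scores Generate cognitive scores (default TRUE; requires building
#'   the subject's network once).
#' @param subject_id Identifier (default derived from group and seed).
#' @return A [subject_connectivity()] object.
#' @export
generate_subject <- function(spec, group, seed, scaffold = NULL,
                             scores = TRUE, subject_id = NULL) {
  validate_cohort_spec(spec)
  group <- match.arg(group, c("NC", "SCD", "aMCI"))
  if (is.null(scaffold)) scaffold <- cohort_scaffold(spec)
  n <- spec$n_regions
  atlas <- if (n == 90) aal90_atlas() else region_atlas(sprintf("R%02d", seq_len(n)))
  hub <- hub_index(spec, atlas)
  e_lr <- spec$effect_long_range[[group]]
  e_hub <- spec$effect_hub[[group]]
  sex_p_male <- c(NC = 12 / 36, SCD = 6 / 21, aMCI = 16 / 33)[[group]]

  sub <- local_seed(seed, {
    idx <- which(upper.tri(scaffold$adj) & scaffold$adj, arr.ind = TRUE)
    m <- nrow(idx)
    is_long <- scaffold$long[idx]
    is_hub <- idx[, 1] == hub | idx[, 2] == hub
    atten <- (1 - e_lr * is_long) * (1 - e_hub * is_hub)

    s_subj <- exp(stats::rnorm(1, 0, spec$subject_sd)) # global biological scale
    mu <- spec$fn_mean * s_subj * atten
    fn_e <- stats::rnbinom(m, mu = mu, size = spec$fn_dispersion)
    fa_e <- spec$fa_range[1] +
      diff(spec$fa_range) * stats::rbeta(m, spec$fa_shape[1], spec$fa_shape[2])
    fa_e <- fa_e * atten
    fa_e[fn_e == 0] <- 0

    fn <- matrix(0, n, n); fa <- matrix(0, n, n)
    fn[idx] <- fn_e; fa[idx] <- fa_e
    fn <- fn + t(fn); fa <- fa + t(fa)
    volumes <- stats::rlnorm(n, spec$vol_meanlog, spec$vol_sdlog)

    age <- truncnorm1(62, 9, 50, 80)
    education <- truncnorm1(10.5, 4, 0)
    sex <- if (stats::runif(1) < sex_p_male) "M" else "F"

    s <- subject_connectivity(
      subject_id = subject_id %||% sprintf("%s_%06d", group, seed %% 1000000L),
      group = group, fn = fn, fa = fa, volumes = volumes,
      age = age, sex = sex, education = education, atlas = atlas
    )
    if (scores) {
      net <- build_weight_matrix(s)
      b_hub <- betweenness_centrality(net)$betweenness[hub]
      sm <- spec$score_model
      z <- (b_hub - sm$b_center) / sm$b_scale
      sc <- vapply(rownames(sm$means), function(nm) {
        beta <- sm$betas[[nm]]
        sd_total <- sm$sds[nm, group]
        sd_resid <- sqrt(max(sd_total^2 - beta^2, 0.01))
        sm$means[nm, group] + beta * z + stats::rnorm(1, 0, sd_resid)
      }, numeric(1))
      s$scores <- sc
    }
    s
  })
  sub
}

#' Generate a full synthetic cohort
#'
#' Draws `n_per_group` subjects per group on a shared anatomical scaffold,
#' with per-subject seeds derived from the spec's master seed by a counter
#' scheme. The returned ground-truth record stores everything needed to
#' check planted-effect recovery: the scaffold, which edges are long-range,
#' the targeted hub, the attenuation per group, and the score model.
#'
#' @param spec A [cohort_spec()].
#' @param scores Generate cognitive scores per subject (default TRUE; set
#'   FALSE to skip the per-subject network build when scores are not
#'   needed).
#' @return A list of class `cohort` with elements `subjects` (list of
#'   [subject_connectivity()]), `table` (tibble of ids, groups, covariates,
#'   scores), and `truth`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = c(NC = 3, SCD = 2, aMCI = 2),
#'                                    n_regions = 30))
#' length(coh$subjects)
generate_cohort <- function(spec, scores = TRUE) {
  validate_cohort_spec(spec)
  scaffold <- cohort_scaffold(spec)
  groups <- rep(c("NC", "SCD", "aMCI"), times = spec$n_per_group[c("NC", "SCD", "aMCI")])
  subjects <- purrr::imap(groups, function(g, i) {
    generate_subject(spec, g, seed = derive_seed(spec$master_seed, i),
                     scaffold = scaffold, scores = scores,
                     subject_id = sprintf("%s%03d", g, i))
  })
  tbl <- purrr::map_dfr(subjects, function(s) {
    base <- tibble::tibble(subject_id = s$subject_id, group = s$group,
                           age = s$age, sex = s$sex, education = s$education)
    if (length(s$scores)) {
      base <- dplyr::bind_cols(base, tibble::as_tibble(as.list(s$scores)))
    }
    base
  })
  truth <- list(
    scaffold = scaffold$adj, long_range = scaffold$long,
    hub_region = spec$hub_region,
    hub_index = hub_index(spec, subjects[[1]]$atlas),
    effect_long_range = spec$effect_long_range,
    effect_hub = spec$effect_hub,
    score_model = spec$score_model,
    master_seed = spec$master_seed
  )
  structure(list(subjects = subjects, table = tbl, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s=%d", names(table(x$table$group)),
                            table(x$table$group)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk in the exchange formats
#'
#' Writes per-subject `fn_*.csv`, `fa_*.csv`, `vol_*.csv` files, a
#' `subjects.csv` table pointing at them, and `ground_truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The path to `subjects.csv`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(cohort$subjects, function(s) {
    id <- s$subject_id
    fn_path <- file.path(dir, paste0("fn_", id, ".csv"))
    fa_path <- file.path(dir, paste0("fa_", id, ".csv"))
    vol_path <- file.path(dir, paste0("vol_", id, ".csv"))
    utils::write.table(s$fn, fn_path, sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(s$fa, fa_path, sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(s$atlas$label, s$volumes), vol_path, sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    sget <- function(nm) if (nm %in% names(s$scores)) s$scores[[nm]] else NA_real_
    tibble::tibble(
      subject_id = id, group = s$group, age = s$age, sex = s$sex,
      education = s$education,
      MMSE = sget("MMSE"), MoCA = sget("MoCA"), AVLT_I = sget("AVLT_I"),
      AVLT_D = sget("AVLT_D"), AVLT_R = sget("AVLT_R"),
      fn_path = basename(fn_path), fa_path = basename(fa_path),
      vol_path = basename(vol_path)
    )
  })
  readr::write_csv(rows, file.path(dir, "subjects.csv"))
  truth <- cohort$truth
  truth$scaffold <- which(upper.tri(truth$scaffold) & truth$scaffold)
  truth$long_range <- which(upper.tri(truth$long_range) & truth$long_range)
  truth$score_model$means <- as.data.frame(truth$score_model$means)
  truth$score_model$sds <- as.data.frame(truth$score_model$sds)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "subjects.csv"))
}
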