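# Orchestration: the full in-silico replication of the volumetry validation
# study (cohort -> observers -> stereology -> agreement statistics), plus the
# observer-noise calibration and a real-data measurement mode.

#' Default observer set (mask-level raters, volume-level automated method)
#'
#' Two human raters emulated as mask-level boundary perturbations and an
#' automated method emulated at volume level. The noise magnitudes were
#' calibrated (see [calibrate_observers()]) so that expected 10-subject
#' pairwise ICCs sit in the high-agreement regime reported for manual
#' stereology vs automated thalamic volumetry (all above 0.9); the automated
#' method carries a small negative bias, mirroring the slightly smaller mean
#' volumes automated segmentation tends to report.
#'
#' @return Named list of three [observer_model()]s: `rater1`, `rater2`,
#'   `automated`.
#' @export
default_observers <- function() {
  list(
    rater1 = observer_model("rater1", mode = "mask", boundary_noise_sd = 0.15),
    rater2 = observer_model("rater2", mode = "mask", boundary_noise_sd = 0.33),
    automated = observer_model("automated", mode = "volume",
                               volume_noise_sd = 230, bias = -0.005)
  )
}

#' Volume-level observer set for replicate simulations
#'
#' Volume-level equivalents of [default_observers()]: the raters' boundary
#' noise plus point-counting sampling noise is folded into a single additive
#' volume SD, so large replicate ensembles (power/agreement studies) run
#' without rasterizing masks. The equivalent SDs were measured once by
#' Monte Carlo on the mask-level pipeline.
#'
#' @return Named list of three volume-mode [observer_model()]s.
#' @export
volume_level_observers <- function() {
  list(
    rater1 = observer_model("rater1", mode = "volume", volume_noise_sd = 120),
    rater2 = observer_model("rater2", mode = "volume", volume_noise_sd = 190),
    automated = observer_model("automated", mode = "volume",
                               volume_noise_sd = 230, bias = -0.005)
  )
}

#' Configure an in-silico validation study
#'
#' @param cohort A [cohort_spec()] (its own seed is overridden by a stream
#'   derived from `seed`).
#' @param observers Named list of three [observer_model()]s: `rater1`,
#'   `rater2`, `automated`.
#' @param u,d,slice_axis Sampling design parameters (see [make_design()]).
#' @param resample_per_section Re-randomize the in-plane grid position on
#'   every section of a rater's count (default `TRUE`). This emulates
#'   on-screen point counting, where the software places a fresh random grid
#'   on each image; it is also the regime in which the Gundersen-Jensen noise
#'   term is valid. With `FALSE` a single grid offset is reused down the
#'   stack, which serially correlates the in-plane counting errors, roughly
#'   triples the effective CE and caps achievable inter-rater agreement.
#' @param m,shape_coef Coefficient-of-error options (see
#'   [gundersen_jensen_ce()]).
#' @param n_icc_subjects Number of randomly selected controls for the
#'   rater/method ICC matrix.
#' @param alpha Significance level for group tests.
#' @param p_adjust Multiplicity adjustment for the group-difference ANOVAs.
#' @param seed Master seed; every stochastic stage derives its stream from it
#'   via [child_seed()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         observers = default_observers(),
                         u = 3.12, d = 1, slice_axis = 3L,
                         resample_per_section = TRUE,
                         m = 1, shape_coef = 4,
                         n_icc_subjects = 10L, alpha = 0.05,
                         p_adjust = c("bonferroni", "holm"),
                         seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!all(c("rater1", "rater2", "automated") %in% names(observers))) {
    stop("`observers` must name rater1, rater2 and automated models",
         call. = FALSE)
  }
  for (o in observers) stopifnot(inherits(o, "observer_model"))
  if (is.null(seed)) stop("a master `seed` is required", call. = FALSE)
  structure(
    list(cohort = cohort, observers = observers, u = u, d = d,
         slice_axis = as.integer(slice_axis),
         resample_per_section = isTRUE(resample_per_section),
         m = m, shape_coef = shape_coef,
         n_icc_subjects = as.integer(n_icc_subjects), alpha = alpha,
         p_adjust = match.arg(p_adjust), seed = as.integer(seed)),
    class = "study_config"
  )
}

# measure one subject/hemisphere with one observer; returns volume + CE
measure_one <- function(subject, hemisphere, obs, config, seed) {
  if (obs$mode == "volume") {
    v <- observe_subject(subject, obs, hemisphere, seed = seed)
    return(c(volume = v, ce = NA_real_))
  }
  mask <- observe_subject(subject, obs, hemisphere, seed = seed)
  des <- make_design(u = config$u, d = config$d,
                     slice_axis = config$slice_axis,
                     seed = child_seed(seed, 101L),
                     resample_per_section = config$resample_per_section)
  est <- estimate_volume(mask, des, m = config$m,
                         shape_coef = config$shape_coef)
  c(volume = est$volume, ce = est$ce)
}

pairwise_icc <- function(tab, pairs) {
  out <- lapply(pairs, function(pr) {
    res <- tryCatch(
      icc_absolute_agreement(tab[, pr, drop = FALSE]),
      stereovol_degenerate_table = function(e) NULL
    )
    data.frame(
      method_a = pr[1], method_b = pr[2],
      icc = if (is.null(res)) NA_real_ else res$icc,
      lower = if (is.null(res)) NA_real_ else res$lower,
      upper = if (is.null(res)) NA_real_ else res$upper,
      n = nrow(tab), degenerate = is.null(res),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Run the full in-silico validation study
#'
#' Generates a cohort, observes every subject and hemisphere with the two
#' raters and the automated method (mask-mode observers go through the full
#' stereological chain: perturbed mask, point counting, Cavalieri estimate and
#' predicted CE), then computes the study's statistics: the pairwise ICC
#' matrix on a random subset of controls, whole-sample rater-1 vs automated
#' ICCs, the left-right volume comparison, the between-method asymmetry
#' comparison, and the per-hemisphere patient-control ANOVAs with multiplicity
#' adjustment. Deterministic given the config's master seed.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report`: `volumes` (long data frame:
#'   subject, group, hemisphere, method, volume, ce), `icc_subset` (pairwise
#'   ICCs per hemisphere on the control subset, plus the selected ids),
#'   `icc_whole` (rater1 vs automated per hemisphere, all subjects pooled),
#'   `lr_tests`, `asymmetry` (per-subject indices and the between-method
#'   test), `group_tests` (with adjusted p-values), `summary` (mean (SD) per
#'   group/method/hemisphere) and the `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  master <- config$seed
  cspec <- config$cohort
  cspec$seed <- child_seed(master, 1L)
  cohort <- sample_cohort(cspec)

  methods <- c("rater1", "rater2", "automated")
  hemis <- c("left", "right")
  rows <- vector("list", length(cohort) * 2L * 3L)
  r <- 0L
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    for (h in seq_along(hemis)) {
      for (o in seq_along(methods)) {
        obs <- config$observers[[methods[o]]]
        mres <- measure_one(subj, hemis[h], obs, config,
                            seed = child_seed(master, 2L, i, h, o))
        r <- r + 1L
        rows[[r]] <- data.frame(
          subject = subj$subject_id, group = subj$group,
          hemisphere = hemis[h], method = methods[o],
          volume = unname(mres["volume"]), ce = unname(mres["ce"]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  volumes <- do.call(rbind, rows)

  getv <- function(method, hemisphere, group = NULL) {
    sel <- volumes$method == method & volumes$hemisphere == hemisphere
    if (!is.null(group)) sel <- sel & volumes$group == group
    out <- volumes[sel, c("subject", "volume")]
    stats::setNames(out$volume, out$subject)
  }

  # rater/method agreement on a random subset of controls
  control_ids <- unique(volumes$subject[volumes$group == "control"])
  n_icc <- min(config$n_icc_subjects, length(control_ids))
  sel_ids <- with_seed(child_seed(master, 3L),
                       sort(sample(control_ids, n_icc)))
  pairs <- list(c("rater1", "rater2"), c("rater1", "automated"),
                c("rater2", "automated"))
  icc_subset <- do.call(rbind, lapply(hemis, function(h) {
    tab <- sapply(methods, function(m) getv(m, h)[sel_ids])
    cbind(hemisphere = h, pairwise_icc(tab, pairs))
  }))

  # whole-sample consistency: rater 1 stereology vs automated, pooled groups
  icc_whole <- do.call(rbind, lapply(hemis, function(h) {
    tab <- sapply(c("rater1", "automated"), function(m) getv(m, h))
    cbind(hemisphere = h,
          pairwise_icc(tab, list(c("rater1", "automated"))))
  }))

  # left vs right volumes per method
  lr_tests <- lapply(c("rater1", "automated"), function(m) {
    anova_between(getv(m, "left"), getv(m, "right"))
  })
  names(lr_tests) <- c("rater1", "automated")

  # per-subject asymmetry, compared between methods
  ids <- unique(volumes$subject)
  asym <- data.frame(
    subject = ids,
    group = volumes$group[match(ids, volumes$subject)],
    rater1 = asymmetry_index(getv("rater1", "left")[ids],
                             getv("rater1", "right")[ids]),
    automated = asymmetry_index(getv("automated", "left")[ids],
                                getv("automated", "right")[ids]),
    stringsAsFactors = FALSE
  )
  asym_test <- anova_between(asym$rater1, asym$automated)

  # patient-control atrophy per method and hemisphere
  gt <- list()
  for (m in c("rater1", "automated")) {
    for (h in hemis) {
      res <- anova_between(getv(m, h, "control"), getv(m, h, "patient"))
      gt[[paste(m, h, sep = "_")]] <- data.frame(
        method = m, hemisphere = h, f = res$statistic,
        df1 = res$df[1], df2 = res$df[2], p = res$p_value,
        control_mean = res$group_means[1], control_sd = res$group_sds[1],
        patient_mean = res$group_means[2], patient_sd = res$group_sds[2],
        stringsAsFactors = FALSE
      )
    }
  }
  group_tests <- do.call(rbind, c(gt, list(make.row.names = FALSE)))
  group_tests$p_adjusted <- adjust_pvalues(group_tests$p,
                                           method = config$p_adjust)
  group_tests$significant <- group_tests$p_adjusted < config$alpha

  summary_tab <- stats::aggregate(
    volume ~ group + method + hemisphere, data = volumes,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  )
  summary_tab <- cbind(summary_tab[, 1:3], as.data.frame(summary_tab$volume))

  structure(
    list(volumes = volumes,
         icc_subset = list(table = icc_subset, subjects = sel_ids),
         icc_whole = icc_whole, lr_tests = lr_tests,
         asymmetry = list(table = asym, test = asym_test),
         group_tests = group_tests, summary = summary_tab, config = config),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d measurements (%d subjects x 2 hemispheres x 3 methods)\n",
              nrow(x$volumes), nrow(x$volumes) / 6))
  cat("Control-subset ICCs:\n")
  print(x$icc_subset$table, row.names = FALSE)
  cat("Patient-control ANOVAs:\n")
  print(x$group_tests[, c("method", "hemisphere", "f", "df1", "df2", "p",
                          "p_adjusted")], row.names = FALSE)
  invisible(x)
}

#' Calibrate observer noise to target agreement levels
#'
#' Searches a grid of per-method volume-noise SDs for the triple whose
#' expected pairwise ICCs (over replicate simulated rating tables) are closest
#' in squared distance to the targets. Published agreement coefficients can be
#' reproduced in expectation but are not deterministic outputs: one replicate
#' cohort scatters around the expectation.
#'
#' @param target_iccs Named numeric: `r1_r2`, `r1_auto`, `r2_auto`, each in
#'   (0, 1].
#' @param search_grid Data frame with columns `sd_r1`, `sd_r2`, `sd_auto`
#'   (mm^3). Default: a coarse lattice from 0 to 320 mm^3.
#' @param seed Integer seed.
#' @param n_reps Replicate rating tables per grid point (>= 50).
#' @param n_subjects Subjects per replicate table (the agreement sub-sample
#'   size).
#' @param true_mean,true_sd True-volume distribution of the simulated
#'   subjects (mm^3).
#' @param tol Warn if any achieved ICC misses its target by more than this.
#' @return A list: `observers` (volume-mode [observer_model()]s with the
#'   selected SDs), `achieved` (expected ICCs at the selected grid point),
#'   `target`, `selected` (the grid row), and `grid` (all grid points with
#'   achieved ICCs and distances).
#' @export
calibrate_observers <- function(target_iccs = c(r1_r2 = 0.977,
                                                r1_auto = 0.969,
                                                r2_auto = 0.925),
                                search_grid = NULL, seed = 1L, n_reps = 50L,
                                n_subjects = 10L, true_mean = 7507.8,
                                true_sd = 805.6, tol = 0.05) {
  stopifnot(all(c("r1_r2", "r1_auto", "r2_auto") %in% names(target_iccs)))
  if (any(target_iccs <= 0) || any(target_iccs > 1)) {
    stop("target ICCs must lie in (0, 1]", call. = FALSE)
  }
  if (n_reps < 50L) stop("`n_reps` must be >= 50", call. = FALSE)
  if (is.null(search_grid)) {
    search_grid <- expand.grid(sd_r1 = c(0, 80, 160, 240),
                               sd_r2 = c(0, 80, 160, 240),
                               sd_auto = c(0, 110, 220, 320))
  }
  if (nrow(search_grid) == 0L) stop("empty search grid", call. = FALSE)

  targets <- target_iccs[c("r1_r2", "r1_auto", "r2_auto")]
  achieved <- matrix(NA_real_, nrow(search_grid), 3,
                     dimnames = list(NULL, names(targets)))
  for (g in seq_len(nrow(search_grid))) {
    sds <- as.numeric(search_grid[g, c("sd_r1", "sd_r2", "sd_auto")])
    achieved[g, ] <- expected_pairwise_iccs(sds, n_reps = n_reps,
                                            n_subjects = n_subjects,
                                            true_mean = true_mean,
                                            true_sd = true_sd,
                                            seed = child_seed(seed, g))
  }
  dist2 <- rowSums(sweep(achieved, 2, targets)^2)
  best <- which.min(dist2)
  miss <- max(abs(achieved[best, ] - targets))
  if (miss > tol) {
    warning(sprintf(
      "no grid point reproduces all targets within %.3f (worst miss %.3f); returning best effort",
      tol, miss
    ))
  }
  sds <- as.numeric(search_grid[best, c("sd_r1", "sd_r2", "sd_auto")])
  list(
    observers = list(
      rater1 = observer_model("rater1", mode = "volume", volume_noise_sd = sds[1]),
      rater2 = observer_model("rater2", mode = "volume", volume_noise_sd = sds[2]),
      automated = observer_model("automated", mode = "volume",
                                 volume_noise_sd = sds[3])
    ),
    achieved = achieved[best, ], target = targets,
    selected = search_grid[best, ],
    grid = cbind(search_grid, achieved, dist2 = dist2)
  )
}

#' Expected pairwise ICCs for a triple of observer noise SDs
#'
#' Monte-Carlo expectation of the three pairwise ICC(A,1) coefficients
#' (rater1-rater2, rater1-automated, rater2-automated) when three observers
#' with additive volume noise rate the same simulated subjects.
#'
#' @param sds Numeric length-3 noise SDs (mm^3) for rater1, rater2, automated.
#' @param n_reps Number of replicate rating tables.
#' @param n_subjects Subjects per table.
#' @param true_mean,true_sd True-volume distribution (mm^3).
#' @param seed Integer seed.
#' @return Named numeric length-3 of expected ICCs.
#' @export
expected_pairwise_iccs <- function(sds, n_reps = 50L, n_subjects = 10L,
                                   true_mean = 7507.8, true_sd = 805.6,
                                   seed = 1L) {
  stopifnot(length(sds) == 3L, all(sds >= 0))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  with_seed(seed, {
    acc <- matrix(NA_real_, n_reps, 3)
    for (r in seq_len(n_reps)) {
      true <- stats::rnorm(n_subjects, true_mean, true_sd)
      tab <- sapply(sds, function(s) true + stats::rnorm(n_subjects, 0, s))
      acc[r, ] <- vapply(pairs, function(pr) {
        res <- tryCatch(icc_absolute_agreement(tab[, pr]),
                        stereovol_degenerate_table = function(e) NULL)
        if (is.null(res)) NA_real_ else res$icc
      }, numeric(1))
    }
    stats::setNames(colMeans(acc, na.rm = TRUE),
                    c("r1_r2", "r1_auto", "r2_auto"))
  })
}

#' Replicate the atrophy-detection comparison across many simulated cohorts
#'
#' Repeats the study (by default with volume-level observers, so hundreds of
#' replicates are cheap) and records, per replicate and hemisphere, whether
#' the manual (rater 1) and automated methods each detect the patient-control
#' volume difference at level `alpha` (unadjusted), and whether the two
#' methods agree on the decision in both hemispheres.
#'
#' @param n_reps Number of replicate cohorts.
#' @param cohort A [cohort_spec()] (per-replicate seeds are derived from
#'   `seed`).
#' @param observers Observer set; default [volume_level_observers()].
#' @param alpha Detection level.
#' @param seed Integer seed.
#' @return A data frame with one row per replicate: p-values per method and
#'   hemisphere, per-hemisphere agreement flags and overall `agree`;
#'   attributes `agreement` (fraction of replicates where methods agree in
#'   both hemispheres) and `rejection_rates`.
#' @export
replicate_sensitivity <- function(n_reps = 200L, cohort = cohort_spec(),
                                  observers = volume_level_observers(),
                                  alpha = 0.05, seed = 1L) {
  stopifnot(n_reps >= 1L)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- study_config(cohort = cohort, observers = observers,
                        seed = child_seed(seed, r))
    rep_out <- run_study(cfg)
    gt <- rep_out$group_tests
    p <- stats::setNames(gt$p, paste(gt$method, gt$hemisphere, sep = "_"))
    dec <- p < alpha
    rows[[r]] <- data.frame(
      replicate = r,
      p_manual_left = p[["rater1_left"]], p_manual_right = p[["rater1_right"]],
      p_auto_left = p[["automated_left"]], p_auto_right = p[["automated_right"]],
      agree_left = dec[["rater1_left"]] == dec[["automated_left"]],
      agree_right = dec[["rater1_right"]] == dec[["automated_right"]]
    )
  }
  out <- do.call(rbind, rows)
  out$agree <- out$agree_left & out$agree_right
  attr(out, "agreement") <- mean(out$agree)
  attr(out, "rejection_rates") <- c(
    manual_left = mean(out$p_manual_left < alpha),
    manual_right = mean(out$p_manual_right < alpha),
    auto_left = mean(out$p_auto_left < alpha),
    auto_right = mean(out$p_auto_right < alpha)
  )
  out
}

#' Measure user-supplied segmentation masks (real-data mode)
#'
#' Runs the identical stereological chain on NIfTI masks on disk, with the
#' synthetic observers bypassed: each mask is point-counted under its own
#' seeded random design and reported with its Cavalieri volume and predicted
#' CE.
#'
#' @param paths Character vector of NIfTI mask paths, or a directory
#'   containing `.nii` / `.nii.gz` files.
#' @param u,d,slice_axis Sampling design parameters.
#' @param m,shape_coef CE options.
#' @param seed Integer seed (one design per mask, derived per file).
#' @return Data frame: `file`, `volume`, `ce`, `n_points`, `n_sections`.
#' @export
measure_masks <- function(paths, u = 3.12, d = 1, slice_axis = 3L,
                          m = 1, shape_coef = 4, seed = 1L) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no mask files to measure", call. = FALSE)
  out <- lapply(seq_along(paths), function(i) {
    mask <- read_mask(paths[i])
    des <- make_design(u = u, d = d, slice_axis = slice_axis,
                       seed = child_seed(seed, i))
    est <- estimate_volume(mask, des, m = m, shape_coef = shape_coef)
    data.frame(file = basename(paths[i]), volume = est$volume, ce = est$ce,
               n_points = est$n_points, n_sections = est$n_sections,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
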