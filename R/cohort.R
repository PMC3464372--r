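# Synthetic two-group cohorts: per-hemisphere true volumes drawn from
# group-specific truncated normal distributions, one phantom per hemisphere.

#' Specify a synthetic two-group cohort
#'
#' Default group means and SDs are the stereological (rater 1) thalamic volume
#' distributions of the validation study this package replicates in silico:
#' 62 healthy controls (left 7507.8 (805.6) mm^3, right 7482.6 (767.2) mm^3)
#' and 10 patients with juvenile myoclonic epilepsy, a model of bilateral
#' thalamic atrophy (left 6843.2 (746.6) mm^3, right 6763.3 (824.0) mm^3).
#' Left and right true volumes are drawn from a bivariate normal with
#' correlation `lr_cor` (default 0.7, a modeling choice giving realistic
#' asymmetry scatter), truncated so both volumes are positive.
#'
#' @param n_controls,n_patients Group sizes (> 0).
#' @param control_mean,control_sd,patient_mean,patient_sd Length-2 numeric
#'   `(left, right)` true-volume means and SDs in mm^3; SDs may be 0.
#' @param lr_cor Left-right correlation of true volumes, in `[-1, 1]`.
#' @param shape_ratios Relative semi-axes of the per-hemisphere phantoms.
#' @param exponent Superellipsoid exponent of the phantoms.
#' @param bump_amp Phantom bump amplitude in mm (see [phantom_spec()]).
#' @param voxel_size Voxel size (mm) used when phantoms are rasterized.
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 62L, n_patients = 10L,
                        control_mean = c(left = 7507.8, right = 7482.6),
                        control_sd = c(left = 805.6, right = 767.2),
                        patient_mean = c(left = 6843.2, right = 6763.3),
                        patient_sd = c(left = 746.6, right = 824.0),
                        lr_cor = 0.7,
                        shape_ratios = c(1.5, 1.0, 0.8),
                        exponent = 2.5, bump_amp = 0,
                        voxel_size = c(1, 1, 1), seed = 1L) {
  if (n_controls <= 0 || n_patients <= 0) {
    stop("group sizes must be positive", call. = FALSE)
  }
  for (v in list(control_sd, patient_sd)) {
    if (any(v < 0)) stop("volume SDs must be >= 0", call. = FALSE)
  }
  for (v in list(control_mean, patient_mean)) {
    if (any(v <= 0)) stop("volume means must be > 0", call. = FALSE)
  }
  if (abs(lr_cor) > 1) stop("`lr_cor` must be in [-1, 1]", call. = FALSE)
  structure(
    list(
      n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
      control_mean = unname(control_mean), control_sd = unname(control_sd),
      patient_mean = unname(patient_mean), patient_sd = unname(patient_sd),
      lr_cor = lr_cor, shape_ratios = shape_ratios, exponent = exponent,
      bump_amp = bump_amp, voxel_size = voxel_size, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# one subject's true volumes: correlated bivariate normal, redrawn until both
# are positive (truncation is negligible at thalamic means/SDs but guaranteed)
draw_lr_volumes <- function(mean_lr, sd_lr, rho) {
  repeat {
    z1 <- stats::rnorm(1)
    z2 <- stats::rnorm(1)
    l <- mean_lr[1] + sd_lr[1] * z1
    r <- mean_lr[2] + sd_lr[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
    if (l > 0 && r > 0) return(c(left = l, right = r))
  }
}

#' Sample a synthetic cohort of true subjects
#'
#' Draws per-hemisphere true volumes for every subject and attaches a
#' volume-matched superellipsoid phantom (random orientation) per hemisphere.
#' Bit-identical given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `true_subject` objects (class `cohort`), each with
#'   `subject_id`, `group`, `true_volume_left`, `true_volume_right` and
#'   `phantom_left` / `phantom_right` ([phantom_spec()]s whose analytic volume
#'   equals the true volume exactly).
#' @seealso [cohort_table()]
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- c(rep("control", spec$n_controls), rep("patient", spec$n_patients))
    ids <- c(sprintf("C%02d", seq_len(spec$n_controls)),
             sprintf("P%02d", seq_len(spec$n_patients)))
    subjects <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      if (groups[i] == "control") {
        vol <- draw_lr_volumes(spec$control_mean, spec$control_sd, spec$lr_cor)
      } else {
        vol <- draw_lr_volumes(spec$patient_mean, spec$patient_sd, spec$lr_cor)
      }
      phantoms <- lapply(vol, function(v) {
        phantom_spec(
          semi_axes = spec$shape_ratios, exponent = spec$exponent,
          target_volume = v, voxel_size = spec$voxel_size,
          orientation = stats::runif(3, 0, 360), bump_amp = spec$bump_amp
        )
      })
      subjects[[i]] <- structure(
        list(
          subject_id = ids[i], group = groups[i],
          true_volume_left = unname(vol[1]), true_volume_right = unname(vol[2]),
          phantom_left = phantoms[[1]], phantom_right = phantoms[[2]]
        ),
        class = "true_subject"
      )
    }
    structure(subjects, class = "cohort", spec = spec)
  })
}

#' Cohort truth table
#'
#' @param cohort A cohort from [sample_cohort()].
#' @return A data frame with one row per subject and hemisphere:
#'   `subject_id`, `group`, `hemisphere`, `true_volume` (mm^3).
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(
      subject_id = s$subject_id, group = s$group,
      hemisphere = c("left", "right"),
      true_volume = c(s$true_volume_left, s$true_volume_right),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.cohort <- function(x, ...) {
  tab <- cohort_table(x)
  cat(sprintf("<cohort> %d subjects (%d controls, %d patients)\n",
              length(x), sum(tab$group == "control") / 2,
              sum(tab$group == "patient") / 2))
  invisible(x)
}
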