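# Observation models: the two human raters and the automated method are
# emulated as noisy measurement processes applied to the true phantom.

#' Specify an observation process
#'
#' Two modes are supported. `mode = "mask"` emulates a human rater outlining
#' the structure: the phantom surface is displaced by a spatially smooth
#' radial Gaussian field (SD `boundary_noise_sd` mm, correlation length
#' `corr_length` mm), then scaled by the fractional volume `bias`; the result
#' is rasterized to a new mask, which downstream is point-counted like any
#' real segmentation. `mode = "volume"` emulates a method that reports a
#' number directly: `true_volume * (1 + bias) + N(0, volume_noise_sd^2)`.
#'
#' @param label Method name (e.g. `"rater1"`, `"automated"`).
#' @param mode `"mask"` or `"volume"`.
#' @param boundary_noise_sd Radial surface perturbation SD in mm (mask mode).
#' @param volume_noise_sd Additive volume noise SD in mm^3 (volume mode).
#' @param bias Fractional volume bias (dimensionless; 0.05 inflates volumes
#'   by 5%).
#' @param corr_length Surface correlation length of the boundary noise, mm.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(label, mode = c("mask", "volume"),
                           boundary_noise_sd = 0, volume_noise_sd = 0,
                           bias = 0, corr_length = 5) {
  mode <- match.arg(mode)
  if (boundary_noise_sd < 0 || volume_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (bias <= -1) stop("`bias` must be > -1", call. = FALSE)
  if (corr_length <= 0) stop("`corr_length` must be > 0", call. = FALSE)
  structure(
    list(label = label, mode = mode,
         boundary_noise_sd = boundary_noise_sd,
         volume_noise_sd = volume_noise_sd,
         bias = bias, corr_length = corr_length),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  if (x$mode == "mask") {
    cat(sprintf("<observer_model> %s: mask-level, boundary SD %.2f mm, bias %+.1f%%\n",
                x$label, x$boundary_noise_sd, 100 * x$bias))
  } else {
    cat(sprintf("<observer_model> %s: volume-level, SD %.0f mm^3, bias %+.1f%%\n",
                x$label, x$volume_noise_sd, 100 * x$bias))
  }
  invisible(x)
}

#' Observe one hemisphere of a subject through a measurement process
#'
#' Mask-mode observers return a perturbed segmentation mask (re-seeded up to
#' `max_retries` times if the perturbation disconnects the shape); volume-mode
#' observers return a single observed volume in mm^3. With zero noise and zero
#' bias the observation is the identity on volume (up to rasterization for
#' mask mode).
#'
#' @param subject A `true_subject` from [sample_cohort()].
#' @param model An [observer_model()].
#' @param hemisphere `"left"` or `"right"`.
#' @param seed Integer seed; observation is deterministic given it.
#' @param max_retries Connectivity retries for mask mode.
#' @return A [seg_mask()] (mask mode) or a numeric volume in mm^3.
#' @export
observe_subject <- function(subject, model, hemisphere = c("left", "right"),
                            seed = 1L, max_retries = 5L) {
  stopifnot(inherits(subject, "true_subject"), inherits(model, "observer_model"))
  hemisphere <- match.arg(hemisphere)
  spec <- if (hemisphere == "left") subject$phantom_left else subject$phantom_right
  true_vol <- if (hemisphere == "left") subject$true_volume_left else subject$true_volume_right

  if (model$mode == "volume") {
    obs <- with_seed(seed, {
      true_vol * (1 + model$bias) + stats::rnorm(1, 0, model$volume_noise_sd)
    })
    return(max(obs, 0))
  }

  scale <- (1 + model$bias)^(1 / 3)
  if (model$boundary_noise_sd == 0) {
    return(rasterize_shape(spec$semi_axes, spec$exponent, spec$orientation,
                           spec$voxel_size, margin = 2, scale = scale))
  }
  r_char <- prod(spec$semi_axes)^(1 / 3)
  for (try in seq_len(max_retries)) {
    field <- radial_field(model$boundary_noise_sd, model$corr_length,
                          r_char = r_char, seed = child_seed(seed, try))
    mask <- rasterize_shape(spec$semi_axes, spec$exponent, spec$orientation,
                            spec$voxel_size, margin = 2, field = field,
                            scale = scale,
                            field_margin = field_bound(model$boundary_noise_sd))
    if (is_connected(mask)) return(mask)
  }
  stop("boundary perturbation disconnected the mask after ", max_retries,
       " attempts; reduce `boundary_noise_sd`", call. = FALSE)
}
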