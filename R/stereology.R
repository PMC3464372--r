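# Cavalieri volume estimation: systematic uniform random sections and square
# point grids over binary masks, in physical coordinates.

#' Create a systematic uniform random sampling design
#'
#' Draws a uniform random grid offset in `[0, u)^2` and section offset in
#' `[0, d)`; the same grid offset is applied to every section of one subject
#' (standard Cavalieri practice), unless `resample_per_section = TRUE`, which
#' redraws the in-plane grid position per section. The defaults (4 mm grid is
#' not used here: `u` = 3.12 mm point separation, `d` = 1 mm section interval)
#' are the sampling density of the validated thalamus protocol.
#'
#' @param u Grid spacing in mm (> 0); the area per point is `a_p = u^2`.
#' @param d Section interval in mm (> 0).
#' @param slice_axis Array axis (1, 2 or 3) perpendicular to the sections.
#' @param seed Integer seed; offsets are deterministic given it.
#' @param resample_per_section Redraw the grid offset on every section.
#' @return An object of class `sampling_design`.
#' @export
#' @examples
#' des <- make_design(u = 3.12, d = 1, seed = 7)
#' des$a_p # 9.7344 mm^2
make_design <- function(u = 3.12, d = 1, slice_axis = 3L, seed = 1L,
                        resample_per_section = FALSE) {
  if (!is.finite(u) || u <= 0) stop("`u` must be > 0", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("`d` must be > 0", call. = FALSE)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  off <- with_seed(seed, c(stats::runif(2, 0, u), stats::runif(1, 0, d)))
  structure(
    list(u = u, a_p = u^2, d = d, slice_axis = as.integer(slice_axis),
         grid_offset = off[1:2], section_offset = off[3],
         resample_per_section = isTRUE(resample_per_section),
         seed = as.integer(seed)),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(
    "<sampling_design> u = %.3f mm (a_p = %.4f mm^2), d = %.3f mm, axis %d, offsets (%.3f, %.3f | %.3f)\n",
    x$u, x$a_p, x$d, x$slice_axis,
    x$grid_offset[1], x$grid_offset[2], x$section_offset
  ))
  invisible(x)
}

#' Count grid points hitting the structure on systematic sections
#'
#' Sections sit at physical positions `section_offset + k * d` along the slice
#' axis; on each, test points lie at `grid_offset + (i, j) * u` (mm). A point
#' is "in" iff the voxel containing it (half-open voxel boxes) is foreground;
#' points outside the array count zero. The record covers the full systematic
#' series intersecting the foreground bounding range, so interior zero-count
#' sections are retained (the precision estimator needs the serial structure).
#'
#' @param mask A [seg_mask()]; anisotropic spacing is honored.
#' @param design A [make_design()] with spacings in the mask's physical units.
#' @return An object of class `point_count_record`: integer `counts` (ordered
#'   by position), `positions` (mm), `n_sections` (sections with a positive
#'   count), `total`, and the `design`.
#' @export
count_points <- function(mask, design) {
  stopifnot(inherits(mask, "seg_mask"), inherits(design, "sampling_design"))
  ax <- design$slice_axis
  inplane <- setdiff(1:3, ax)
  # permute so sections are the 3rd array index
  a <- aperm(mask$data, c(inplane, ax))
  sp <- mask$spacing[c(inplane, ax)]
  dm <- dim(a)
  extent <- dm * sp

  fg_slab <- which(apply(a, 3L, any))
  if (length(fg_slab) == 0L) {
    lo <- 0; hi <- extent[3]
  } else {
    lo <- (min(fg_slab) - 1) * sp[3]
    hi <- max(fg_slab) * sp[3]
  }
  k <- seq(ceiling((lo - design$section_offset) / design$d),
           floor((hi - design$section_offset) / design$d))
  positions <- design$section_offset + k * design$d
  positions <- positions[positions >= lo & positions < hi & positions >= 0 &
                           positions < extent[3]]
  n_sec <- length(positions)
  if (n_sec == 0L) {
    return(structure(
      list(counts = integer(0), positions = numeric(0), n_sections = 0L,
           total = 0L, design = design),
      class = "point_count_record"
    ))
  }

  grid_offsets <- matrix(design$grid_offset, nrow = n_sec, ncol = 2, byrow = TRUE)
  if (design$resample_per_section) {
    grid_offsets <- with_seed(child_seed(design$seed, 997L), {
      matrix(stats::runif(2L * n_sec, 0, design$u), ncol = 2, byrow = TRUE)
    })
  }

  counts <- integer(n_sec)
  for (s in seq_len(n_sec)) {
    iz <- floor(positions[s] / sp[3]) + 1L
    gx <- grid_offsets[s, 1]; gy <- grid_offsets[s, 2]
    xs <- seq(gx, extent[1], by = design$u)
    xs <- xs[xs < extent[1]]
    ys <- seq(gy, extent[2], by = design$u)
    ys <- ys[ys < extent[2]]
    if (!length(xs) || !length(ys)) next
    ix <- floor(xs / sp[1]) + 1L
    iy <- floor(ys / sp[2]) + 1L
    counts[s] <- sum(a[ix, iy, iz])
  }
  structure(
    list(counts = counts, positions = positions,
         n_sections = sum(counts > 0L), total = sum(counts), design = design),
    class = "point_count_record"
  )
}

#' @export
print.point_count_record <- function(x, ...) {
  cat(sprintf(
    "<point_count_record> %d sections (%d hitting), total %d points, u = %.3f mm, d = %.3f mm\n",
    length(x$counts), x$n_sections, x$total, x$design$u, x$design$d
  ))
  invisible(x)
}

#' Cavalieri volume estimate from a point-count record
#'
#' The estimator: each section's transect area is (points counted) x (area per
#' point `a_p = u^2`); the volume is the sum of section areas times the
#' section interval, `V = sum(P_i) * a_p * d`. With uniform random offsets
#' this is unbiased for the mask's voxel-count volume.
#'
#' @param record A [count_points()] record.
#' @param ce Optional predicted coefficient of error to attach (see
#'   [gundersen_jensen_ce()]).
#' @param method,rater,subject,hemisphere Optional labels carried in the
#'   estimate.
#' @return An object of class `volume_estimate` with `volume` (mm^3), `ce`,
#'   `n_points`, `n_sections` and the labels.
#' @export
#' @examples
#' des <- make_design(u = 3.12, d = 1, seed = 1)
#' rec <- structure(list(counts = c(10L, 20L, 30L), positions = 0:2,
#'                       n_sections = 3L, total = 60L, design = des),
#'                  class = "point_count_record")
#' cavalieri_volume(rec)$volume # 60 * 9.7344 * 1
cavalieri_volume <- function(record, ce = NA_real_, method = NA_character_,
                             rater = NA_character_, subject = NA_character_,
                             hemisphere = NA_character_) {
  stopifnot(inherits(record, "point_count_record"))
  v <- sum(record$counts) * record$design$a_p * record$design$d
  structure(
    list(volume = v, ce = ce, n_points = sum(record$counts),
         n_sections = record$n_sections, method = method, rater = rater,
         subject = subject, hemisphere = hemisphere),
    class = "volume_estimate"
  )
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> %.1f mm^3 (%d points on %d sections%s)\n",
              x$volume, x$n_points, x$n_sections,
              if (is.na(x$ce)) "" else sprintf(", predicted CE %.3f", x$ce)))
  invisible(x)
}

#' Point-count a mask and estimate its volume with predicted precision
#'
#' Convenience wrapper: [count_points()], [cavalieri_volume()] and
#' [gundersen_jensen_ce()] in one call.
#'
#' @inheritParams count_points
#' @param m,shape_coef,include_noise Passed to [gundersen_jensen_ce()].
#' @inheritParams cavalieri_volume
#' @return A `volume_estimate` with the predicted CE filled in.
#' @export
estimate_volume <- function(mask, design, m = 1, shape_coef = 4,
                            include_noise = TRUE, method = NA_character_,
                            rater = NA_character_, subject = NA_character_,
                            hemisphere = NA_character_) {
  rec <- count_points(mask, design)
  ce <- if (sum(rec$counts) > 0) {
    gundersen_jensen_ce(rec, m = m, shape_coef = shape_coef,
                        include_noise = include_noise)
  } else {
    NA_real_
  }
  cavalieri_volume(rec, ce = as.numeric(ce), method = method, rater = rater,
                   subject = subject, hemisphere = hemisphere)
}
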