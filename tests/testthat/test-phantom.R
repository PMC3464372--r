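test_that("analytic superellipsoid volume matches closed forms", {
  expect_equal(superellipsoid_volume(c(10, 10, 10), 2), 4 / 3 * pi * 1000)
  expect_equal(superellipsoid_volume(c(15, 10, 8), 2), 4 / 3 * pi * 15 * 10 * 8)
  # p -> large approaches the box volume
  expect_equal(superellipsoid_volume(c(2, 3, 4), 200), 8 * 24, tolerance = 0.01)
})

test_that("target_volume rescales the spec exactly", {
  spec <- phantom_spec(semi_axes = c(15, 10, 8), exponent = 2.5,
                       target_volume = 7400)
  expect_equal(spec$analytic_volume, 7400)
  # axis ratios preserved
  expect_equal(spec$semi_axes[1] / spec$semi_axes[2], 1.5)
})

test_that("voxelized volume matches the analytic volume within 2% at 1 mm", {
  sphere <- phantom_spec(semi_axes = c(10, 10, 10), exponent = 2)
  m <- make_phantom(sphere)
  expect_lt(abs(mask_volume(m) - 4188.79) / 4188.79, 0.02)

  ell <- phantom_spec(semi_axes = c(15, 10, 8), exponent = 2,
                      orientation = c(30, 20, 10))
  m2 <- make_phantom(ell)
  expect_lt(abs(mask_volume(m2) - 5026.5) / 5026.5, 0.02)
})

test_that("rasterization error decreases monotonically as voxels shrink", {
  # a small shape keeps discretization error above the grid-phase noise
  # floor; the error is averaged over generic orientations because special
  # (axis-aligned) poses can cancel coarse-grid error by symmetry
  orientations <- list(c(15, 40, 70), c(30, 60, 10), c(80, 25, 140))
  errs <- vapply(c(1, 0.5, 0.25), function(vs) {
    mean(vapply(orientations, function(o) {
      spec <- phantom_spec(semi_axes = c(4, 3, 2.5), exponent = 2.5,
                           voxel_size = vs, orientation = o)
      m <- make_phantom(spec, check_connected = FALSE)
      abs(mask_volume(m) - spec$analytic_volume) / spec$analytic_volume
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)

  # and the thalamus-scale phantom is already accurate at 1 mm voxels
  m <- thalamus_phantom()
  expect_lt(abs(mask_volume(m) - 7400) / 7400, 0.02)
})

test_that("phantoms are single connected components and validation works", {
  m <- thalamus_phantom()
  expect_true(is_connected(m))
  expect_error(phantom_spec(semi_axes = c(0, 1, 1)), "semi_axes")
  expect_error(phantom_spec(exponent = 0.5), "exponent")
  expect_error(make_phantom(thalamus_spec <- phantom_spec(target_volume = 7400),
                            dim = c(10, 10, 10)), "bounds")
})

test_that("bump-deformed phantoms stay connected and near the target volume", {
  spec <- phantom_spec(target_volume = 7400, bump_amp = 0.5)
  m <- make_phantom(spec, seed = 11)
  expect_true(is_connected(m))
  expect_lt(abs(mask_volume(m) - 7400) / 7400, 0.05)
})

test_that("cohorts are reproducible and match configured distributions", {
  spec <- cohort_spec(n_controls = 6, n_patients = 3, seed = 99)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(cohort_table(c1), cohort_table(c2))

  # SD = 0 gives volumes exactly at the mean
  d0 <- cohort_spec(n_controls = 4, n_patients = 2,
                    control_sd = c(0, 0), patient_sd = c(0, 0), seed = 1)
  tab <- cohort_table(sample_cohort(d0))
  ctl_l <- tab$true_volume[tab$group == "control" & tab$hemisphere == "left"]
  expect_true(all(ctl_l == 7507.8))

  expect_error(cohort_spec(n_controls = 0), "positive")
  expect_error(cohort_spec(control_sd = c(-1, 0)), "SD")
})

test_that("large-sample cohort means converge to configured parameters", {
  spec <- cohort_spec(n_controls = 10000, n_patients = 10000, seed = 21)
  tab <- cohort_table(sample_cohort(spec))
  for (grp in c("control", "patient")) {
    for (h in c("left", "right")) {
      v <- tab$true_volume[tab$group == grp & tab$hemisphere == h]
      mu <- if (grp == "control") {
        if (h == "left") 7507.8 else 7482.6
      } else {
        if (h == "left") 6843.2 else 6763.3
      }
      sdv <- if (grp == "control") {
        if (h == "left") 805.6 else 767.2
      } else {
        if (h == "left") 746.6 else 824.0
      }
      expect_lt(abs(mean(v) - mu), 3 * sdv / sqrt(10000))
    }
  }
  # expected control - patient difference on the left is 664.6 mm^3
  diff_l <- mean(tab$true_volume[tab$group == "control" & tab$hemisphere == "left"]) -
    mean(tab$true_volume[tab$group == "patient" & tab$hemisphere == "left"])
  expect_lt(abs(diff_l - 664.6), 3 * sqrt(805.6^2 + 746.6^2) / sqrt(10000))
})

test_that("subject phantoms carry the true volume exactly", {
  co <- sample_cohort(cohort_spec(n_controls = 3, n_patients = 2, seed = 4))
  s <- co[[1]]
  expect_equal(s$phantom_left$analytic_volume, s$true_volume_left)
  expect_equal(s$phantom_right$analytic_volume, s$true_volume_right)
})
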