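test_that("the Gundersen-Jensen formula matches hand arithmetic", {
  p <- c(5, 5, 5, 5)
  # by hand: A = 100, B = 75, C = 50, n = 4, total = 20
  expect_equal(serial_sum(p, 0), 100)
  expect_equal(serial_sum(p, 1), 75)
  expect_equal(serial_sum(p, 2), 50)
  noise <- 0.0724 * 3.545 * sqrt(4 * 20)
  var_surs <- (1 / 240) * (3 * (100 - noise) - 4 * 75 + 50)
  expected <- sqrt(noise + max(var_surs, 0)) / 20
  expect_equal(as.numeric(gundersen_jensen_ce(p, m = 1, shape_coef = 3.545)),
               expected, tolerance = 1e-12)

  # m = 0 uses alpha = 1/12
  var0 <- (1 / 12) * (3 * (100 - noise) - 4 * 75 + 50)
  expect_equal(as.numeric(gundersen_jensen_ce(p, m = 0, shape_coef = 3.545)),
               sqrt(noise + max(var0, 0)) / 20, tolerance = 1e-12)
})

test_that("noise-free variance matches brute-force serial sums", {
  set.seed(31)
  for (rep in 1:25) {
    p <- rpois(sample(4:15, 1), lambda = 20)
    if (sum(p) == 0) next
    A <- serial_sum(p, 0); B <- serial_sum(p, 1); C <- serial_sum(p, 2)
    expected <- sqrt(max((1 / 240) * (3 * A - 4 * B + C), 0)) / sum(p)
    got <- suppressWarnings(
      gundersen_jensen_ce(p, m = 1, include_noise = FALSE)
    )
    expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  }
})

test_that("CE shrinks when counts grow", {
  p <- c(5, 5, 5, 5)
  expect_lt(as.numeric(gundersen_jensen_ce(10 * p)),
            as.numeric(gundersen_jensen_ce(p)))
})

test_that("CE is invariant to leading and trailing zero sections", {
  p <- c(4, 9, 12, 10, 5)
  base <- as.numeric(gundersen_jensen_ce(p))
  padded <- as.numeric(gundersen_jensen_ce(c(0, 0, p, 0)))
  expect_equal(padded, base, tolerance = 1e-12)
})

test_that("degenerate count series are handled per contract", {
  expect_error(gundersen_jensen_ce(c(0, 0, 0)), "all-zero")
  expect_warning(ce <- gundersen_jensen_ce(c(0, 7, 3, 0)), "noise-only")
  expect_true(isTRUE(attr(ce, "noise_only")))
  expect_equal(as.numeric(ce), sqrt(0.0724 * 4 * sqrt(2 * 10)) / 10,
               tolerance = 1e-12)
  expect_error(gundersen_jensen_ce(c(1, 2), m = 2), "smoothness")
})

test_that("empirical CE behaves like a relative standard error", {
  sphere <- make_phantom(phantom_spec(semi_axes = c(12, 12, 12), exponent = 2))
  ce <- empirical_ce(sphere, u = 3.12, d = 1, n_reps = 300, seed = 3)
  expect_gt(as.numeric(ce), 0)
  expect_lt(as.numeric(ce), 0.05)

  # near-empty sampling is imprecise: one expected point
  ce_sparse <- empirical_ce(sphere, u = 40, d = 8, n_reps = 150, seed = 4)
  expect_gt(as.numeric(ce_sparse), 0.5)

  expect_error(empirical_ce(sphere, n_reps = 50), "n_reps")
  expect_error(empirical_ce(seg_mask(array(0L, c(5, 5, 5))), n_reps = 100),
               "empty")
})

test_that("empirical CE is stable in n_reps within its Monte-Carlo error", {
  m <- thalamus_phantom()
  ce1 <- empirical_ce(m, n_reps = 200, seed = 9)
  ce2 <- empirical_ce(m, n_reps = 400, seed = 9)
  # bootstrap SE of the CE from the first replicate set
  v <- attr(ce1, "volumes")
  boot <- vapply(1:200, function(i) {
    set.seed(i)
    vb <- sample(v, replace = TRUE)
    stats::sd(vb) / mean(vb)
  }, numeric(1))
  expect_lt(abs(as.numeric(ce2) - as.numeric(ce1)), 4 * stats::sd(boot))
})

test_that("refining the design never increases empirical CE (with MC slack)", {
  m <- thalamus_phantom()
  ladder <- list(list(u = 12, d = 4), list(u = 6, d = 2), list(u = 3.12, d = 1))
  ces <- vapply(ladder, function(cand) {
    as.numeric(empirical_ce(m, u = cand$u, d = cand$d, n_reps = 200, seed = 13))
  }, numeric(1))
  expect_true(all(diff(ces) < 0.1 * ces[-length(ces)]))
})

test_that("optimize_density returns the coarsest design meeting the target", {
  m <- thalamus_phantom()
  ladder <- list(list(u = 20, d = 8), list(u = 10, d = 4),
                 list(u = 6, d = 2), list(u = 3.12, d = 1))
  des <- optimize_density(m, target_ce = 0.05, candidates = ladder, seed = 2)
  expect_s3_class(des, "sampling_design")
  expect_lte(attr(des, "mean_ce"), 0.05)

  # an impossible target errors and reports the best achieved CE
  expect_error(optimize_density(m, target_ce = 1e-5, candidates = ladder,
                                seed = 2), "best achieved")

  # a trivial target returns the coarsest candidate
  des_loose <- optimize_density(m, target_ce = 1.0, candidates = ladder,
                                seed = 2)
  expect_equal(des_loose$u, 20)
})
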