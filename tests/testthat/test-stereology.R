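test_that("sampling designs are deterministic and internally consistent", {
  d1 <- make_design(u = 3.12, d = 1, seed = 7)
  d2 <- make_design(u = 3.12, d = 1, seed = 7)
  expect_identical(d1$grid_offset, d2$grid_offset)
  expect_identical(d1$section_offset, d2$section_offset)
  expect_equal(d1$a_p, 9.7344)
  expect_true(all(d1$grid_offset >= 0 & d1$grid_offset < 3.12))
  expect_true(d1$section_offset >= 0 && d1$section_offset < 1)
  expect_error(make_design(u = 0), "u")
  expect_error(make_design(d = -1), "d")
})

test_that("design offsets are uniform on their ranges", {
  u <- 3.12
  offs <- t(vapply(1:10000, function(i) {
    des <- make_design(u = u, d = 1, seed = i)
    c(des$grid_offset, des$section_offset)
  }, numeric(3)))
  # chi-square goodness of fit against uniform, alpha = 0.01
  for (j in 1:2) {
    counts <- table(cut(offs[, j], breaks = seq(0, u, length.out = 11)))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
  counts <- table(cut(offs[, 3], breaks = seq(0, 1, length.out = 11)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("empty masks give all-zero counts, not errors", {
  m <- seg_mask(array(0L, c(10, 10, 10)))
  rec <- count_points(m, make_design(u = 2, d = 1, seed = 1))
  expect_equal(sum(rec$counts), 0)
  expect_equal(rec$n_sections, 0L)
  expect_equal(cavalieri_volume(rec)$volume, 0)
})

test_that("a single voxel is estimated without bias at fine sampling", {
  a <- array(0L, c(5, 5, 5)); a[3, 3, 3] <- 1L
  m <- seg_mask(a)
  vhats <- vapply(1:100, function(i) {
    des <- make_design(u = 0.1, d = 0.1, seed = i)
    sum(count_points(m, des)$counts) * des$a_p * des$d
  }, numeric(1))
  expect_lt(abs(mean(vhats) - 1), 0.15)
})

test_that("expected total count matches V / (a_p * d) on a thalamus phantom", {
  m <- thalamus_phantom()
  v_vox <- mask_volume(m)
  totals <- vapply(1:500, function(i) {
    sum(count_points(m, make_design(u = 3.12, d = 1, seed = i))$counts)
  }, numeric(1))
  expected <- v_vox / (9.7344 * 1)
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 4 * se)
  # roughly 760 points at this density
  expect_gt(mean(totals), 700)
  expect_lt(mean(totals), 820)
})

test_that("the Cavalieri formula is applied exactly", {
  des <- make_design(u = 3.12, d = 1, seed = 1)
  rec <- structure(
    list(counts = c(10L, 20L, 30L), positions = c(0.5, 1.5, 2.5),
         n_sections = 3L, total = 60L, design = des),
    class = "point_count_record"
  )
  expect_equal(cavalieri_volume(rec)$volume, 60 * 9.7344 * 1)
  expect_equal(cavalieri_volume(rec)$volume, 584.064)
})

test_that("mean Cavalieri estimate is unbiased for the voxel volume", {
  m <- thalamus_phantom()
  v_vox <- mask_volume(m)
  vhats <- vapply(1:300, function(i) {
    des <- make_design(u = 3.12, d = 1, seed = child_seed(5, i))
    sum(count_points(m, des)$counts) * des$a_p * des$d
  }, numeric(1))
  z <- (mean(vhats) - v_vox) / (stats::sd(vhats) / sqrt(length(vhats)))
  expect_lt(abs(z), stats::qnorm(0.995))
})

test_that("doubling u quadruples a_p and leaves the expectation unchanged", {
  m <- thalamus_phantom()
  expect_equal(make_design(u = 6.24, seed = 1)$a_p,
               4 * make_design(u = 3.12, seed = 1)$a_p)
  est <- function(u, n) {
    mean(vapply(1:n, function(i) {
      des <- make_design(u = u, d = 1, seed = child_seed(u * 100, i))
      sum(count_points(m, des)$counts) * des$a_p * des$d
    }, numeric(1)))
  }
  v1 <- est(3.12, 300); v2 <- est(6.24, 300)
  expect_lt(abs(v2 - v1) / v1, 0.03)
})

test_that("counts are invariant to shifting the mask by a whole grid period", {
  a <- array(0L, c(40, 40, 20))
  a[10:20, 12:22, 5:12] <- 1L
  m <- seg_mask(a)
  u <- 2 # grid period = 2 voxels at 1 mm spacing
  shifted <- array(0L, c(40, 40, 20))
  shifted[(10:20) + u, (12:22) + u, 5:12] <- 1L
  m2 <- seg_mask(shifted)
  for (i in 1:20) {
    des <- make_design(u = u, d = 1, seed = i)
    expect_identical(sum(count_points(m, des)$counts),
                     sum(count_points(m2, des)$counts))
  }
})

test_that("anisotropic voxel spacing is honored in physical units", {
  a <- array(0L, c(30, 20, 16))
  a[8:23, 6:15, 4:11] <- 1L # 16 x 10 x 8 voxels
  m <- seg_mask(a, spacing = c(0.5, 1, 2))
  true_v <- 16 * 10 * 8 * 0.5 * 1 * 2
  expect_equal(mask_volume(m), true_v)
  vhats <- vapply(1:200, function(i) {
    des <- make_design(u = 1.3, d = 0.9, seed = i)
    sum(count_points(m, des)$counts) * des$a_p * des$d
  }, numeric(1))
  expect_lt(abs(mean(vhats) - true_v) / true_v, 0.02)
})

test_that("slice axis choice does not bias the estimate", {
  m <- thalamus_phantom()
  for (ax in 1:3) {
    vhats <- vapply(1:150, function(i) {
      des <- make_design(u = 3.12, d = 1, slice_axis = ax, seed = i)
      sum(count_points(m, des)$counts) * des$a_p * des$d
    }, numeric(1))
    expect_lt(abs(mean(vhats) - mask_volume(m)) / mask_volume(m), 0.02)
  }
})
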