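# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: mean squares come from stats::aov, serial sums
# from explicit loops.

# two-way mean squares via aov on the long-format table
aov_mean_squares <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  long <- data.frame(
    y = as.vector(tab),
    subj = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  list(msr = ms[1], msc = ms[2], mse = ms[3])
}

# ICC(A,1) from aov-derived mean squares (the published formula applied to
# independently computed mean squares)
aov_icc_a1 <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  ms <- aov_mean_squares(tab)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# serial products of a count series by explicit loop
serial_sum <- function(p, lag) {
  s <- 0
  for (i in seq_len(length(p) - lag)) s <- s + p[i] * p[i + lag]
  s
}

# a quick 7400 mm^3 thalamus-scale phantom used by several files
thalamus_phantom <- function(target_volume = 7400, ...) {
  make_phantom(phantom_spec(target_volume = target_volume, ...))
}
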