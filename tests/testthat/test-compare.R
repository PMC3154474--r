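# Ensemble comparison statistics: Z-scores, exact KS statistics and
# ratios, heat-map matrices, class histograms, equilibration trimming.

test_that("zscore matches the direct formula and its symmetries", {
  set.seed(401)
  a <- stats::rnorm(14, 0, 1); b <- stats::rnorm(14, 1, 1.3)
  direct <- (mean(a) - mean(b)) /
    sqrt(stats::var(a) / 14 + stats::var(b) / 14)
  expect_equal(zscore(a, b), direct, tolerance = 1e-12)
  expect_equal(zscore(a, a), 0)
  expect_equal(zscore(b, a), -zscore(a, b), tolerance = 1e-12)
  # affine invariance (sign flips with the scale sign)
  expect_equal(zscore(2 * a + 5, 2 * b + 5), zscore(a, b),
               tolerance = 1e-9)
  expect_equal(zscore(-a, -b), -zscore(a, b), tolerance = 1e-9)
  expect_error(zscore(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(zscore(c(1, 1), c(1, 1)), 0)
})

ks_oracle <- function(a, b) {
  # O(n^2): evaluate both ECDFs at every sample point
  pts <- c(a, b)
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, 0))
}

test_that("ks_statistic equals the quadratic ECDF-scan oracle", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(5, 6, 7)), 1)
  set.seed(402)
  for (i in 1:25) {
    na <- sample(5:120, 1); nb <- sample(5:120, 1)
    a <- round(stats::rnorm(na), sample(0:2, 1))  # induce ties
    b <- round(stats::rnorm(nb, 0.3), sample(0:2, 1))
    expect_identical(ks_statistic(a, b), ks_oracle(a, b))
  }
})

test_that("ks_ratio is 1 at the critical value and linear in D", {
  set.seed(403)
  a <- stats::rnorm(30); b <- stats::rnorm(40, 2)
  D <- ks_statistic(a, b)
  calpha <- D / sqrt((30 + 40) / (30 * 40))
  alpha_star <- 2 * exp(-2 * calpha^2)
  expect_gt(alpha_star, 0); expect_lt(alpha_star, 1)
  expect_equal(ks_ratio(a, b, alpha_star), 1, tolerance = 1e-9)
  expect_equal(ks_ratio(a, a), 0)
  # at fixed sizes and alpha the ratio is proportional to D
  b2 <- stats::rnorm(40, 0.5)
  expect_equal(ks_ratio(a, b2, 0.05) / ks_statistic(a, b2),
               ks_ratio(a, b, 0.05) / D, tolerance = 1e-12)
  expect_error(ks_ratio(a, b, 1.5), "alpha")
})

test_that("self-comparison gives a zero matrix with designation labels", {
  spec <- generator_spec(n_frames = 50, seed = 31)
  tab <- sample_param_tables(spec)
  mat <- comparison_matrix(list(a = tab, b = tab), statistic = "ks")
  expect_true(all(mat == 0))
  expect_setequal(rownames(mat), setdiff(colnames(tab), "frame_index"))
  expect_equal(colnames(mat), "a vs b")
})

test_that("a planted two-SD central-step roll shift is the matrix maximum", {
  spec_a <- generator_spec(n_frames = 500, seed = 51)
  spec_b <- generator_spec(n_frames = 500, seed = 52)
  spec_b$step_mean[6, "roll"] <- spec_b$step_mean[6, "roll"] +
    2 * spec_b$step_sd[5]
  ta <- sample_param_tables(spec_a)
  tb <- sample_param_tables(spec_b)
  for (stat in c("z", "ks")) {
    mat <- comparison_matrix(list(ref = ta, shifted = tb), statistic = stat)
    expect_equal(rownames(mat)[which.max(abs(mat))], "step_6_7_roll")
  }
})

test_that("mismatched designations are schema errors", {
  spec <- generator_spec(n_frames = 20, seed = 1)
  ta <- sample_param_tables(spec)
  tb <- ta[, -3]
  class(tb) <- class(ta)
  expect_error(comparison_matrix(list(a = ta, b = tb)), "schema")
})

test_that("class histogram masses conserve totals and class marginals", {
  be <- plant_hbond_classes(c(0.4, 0.3, 0.2, 0.1), n_frames = 400,
                            seed = 23)
  cls <- classify_frames(be$ensemble)
  v <- be$truth$step_6_7_roll
  ch <- class_histograms(v, cls)
  expect_equal(sum(ch$mass), 1, tolerance = 1e-12)
  fq <- frequency_table(cls, digits = 6)
  for (cl in fq$class) {
    expect_equal(ch$class_totals[[cl]], fq$percent[fq$class == cl] / 100,
                 tolerance = 1e-9)
  }
  expect_error(class_histograms(v[-1], cls), "alignment")
})

test_that("per-class modes sit at planted class-conditional means", {
  # two classes with well-separated planted parameter distributions
  set.seed(404)
  values <- c(stats::rnorm(600, -3, 0.5), stats::rnorm(400, 3, 0.5))
  cls <- data.frame(frame_index = 1:1000,
                    class = rep(c("A", "B"), c(600, 400)))
  ch <- class_histograms(values, cls)
  centers <- (ch$breaks[-1] + ch$breaks[-length(ch$breaks)]) / 2
  bw <- diff(ch$breaks[1:2])
  expect_lt(abs(centers[which.max(ch$mass["A", ])] - (-3)), bw)
  expect_lt(abs(centers[which.max(ch$mass["B", ])] - 3), bw)
  # single class reduces to an ordinary normalized histogram
  ch1 <- class_histograms(values[1:600], cls[1:600, ])
  expect_equal(sum(ch1$mass), 1, tolerance = 1e-12)
})

test_that("equilibration trimming keeps the final fraction, per run", {
  spec <- generator_spec(n_frames = 100, seed = 3)
  tab <- sample_param_tables(spec)
  expect_equal(trim_equilibration(tab, 0), tab)
  tr <- trim_equilibration(tab, 0.4)
  expect_equal(nrow(tr), 60)
  expect_equal(tr$frame_index, 41:100)
  # five concatenated runs trimmed within each run
  big <- do.call(rbind, lapply(1:5, function(r) {
    tab5 <- sample_param_tables(generator_spec(n_frames = 2000,
                                               seed = 100 + r))
    tab5$run <- r
    tab5
  }))
  class(big) <- c("param_table", "data.frame")
  tr5 <- trim_equilibration(big, 0.4)
  expect_equal(nrow(tr5), 6000)
  expect_equal(unname(table(tr5$run)), rep(1200L, 5), ignore_attr = TRUE)
  expect_error(trim_equilibration(tab, 100), "empty-table")
})
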