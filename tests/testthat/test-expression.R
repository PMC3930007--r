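test_that("percentile normalization pins the per-sample 75th percentile", {
  # oracle: type-7 quantile of log2 values [1,2,3,4] is 3.25 by linear
  # interpolation, so normalized values are [-2.25,-1.25,-0.25,0.75]
  raw <- matrix(2^c(1, 2, 3, 4), ncol = 1,
                dimnames = list(letters[1:4], "S1"))
  nm <- normalize_percentile(raw)
  expect_equal(as.numeric(nm), c(-2.25, -1.25, -0.25, 0.75))

  # all-equal sample maps to all zeros
  eq <- normalize_percentile(matrix(c(8, 8, 8), ncol = 1))
  expect_equal(as.numeric(eq), c(0, 0, 0))

  # multiplying a sample by a constant leaves normalized values unchanged
  nm2 <- normalize_percentile(raw * 37.5)
  expect_equal(nm, nm2, ignore_attr = TRUE, tolerance = 1e-12)

  # idempotence: re-normalizing the back-transformed matrix is a no-op
  nm3 <- normalize_percentile(2^nm)
  expect_equal(as.numeric(nm3), as.numeric(nm), tolerance = 1e-9)

  # the pinned percentile equals the offset
  big <- matrix(rlnorm(200 * 6, 5, 1), 200, 6,
                dimnames = list(NULL, paste0("S", 1:6)))
  nb <- normalize_percentile(big)
  expect_equal(unname(apply(nb, 2, quantile, 0.75, type = 7)), rep(0, 6),
               tolerance = 1e-9)

  expect_error(normalize_percentile(matrix(c(-1, 0, -5), ncol = 1)),
               "positive")
})

make_sheet <- function(n_ind = 8, n_tp = 3) {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n_ind * n_tp)),
    individual_id = rep(sprintf("i%d", seq_len(n_ind)), each = n_tp),
    time_point = rep(sprintf("t%d", seq_len(n_tp)), times = n_ind),
    group = "g", stringsAsFactors = FALSE)
}

test_that("core membership requires detection in every individual", {
  sheet <- make_sheet()
  mat <- matrix(0, nrow = 3, ncol = 24,
                dimnames = list(c("all_t1", "seven_of_eight", "scattered"),
                                sheet$sample_id))
  t1 <- sheet$time_point == "t1"
  mat["all_t1", t1] <- 5                        # every steer at time 1 only
  mat["seven_of_eight", sheet$individual_id != "i8"] <- 5
  for (k in 1:8) {                              # each steer somewhere
    mat["scattered", sheet$individual_id == sprintf("i%d", k) &
          sheet$time_point == sprintf("t%d", (k %% 3) + 1)] <- 5
  }
  res <- detect_core(mat, sheet, floor = 0)
  expect_setequal(res$core, c("all_t1", "scattered"))

  # the common-timepoint reading drops the scattered pattern
  res2 <- detect_core(mat, sheet, floor = 0, rule = "common-timepoint")
  expect_setequal(res2$core, "all_t1")

  # monotone: raising the floor never adds core members
  floors <- c(-1, 0, 1, 4, 6)
  sizes <- vapply(floors, function(f) {
    length(detect_core(mat, sheet, floor = f)$core)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # explicit flag matrix overrides values
  flags <- mat > 0
  expect_setequal(detect_core(mat * 0, sheet, flags = flags)$core,
                  c("all_t1", "scattered"))
})

test_that("summary statistics match closed forms", {
  mat <- matrix(c(1, 3, 2, 2, 5, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("ab", "const", "wide"), c("S1", "S2")))
  st <- summarize_expression(mat, scale = "log")
  expect_equal(st$mean[1], 2)
  expect_equal(st$sd[1], sqrt(2), tolerance = 1e-12)
  expect_equal(st$cv[1], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(st$cv[2], 0)
  expect_equal(st$n_samples, c(2L, 2L, 2L))
})

test_that("power fit is exact on noise-free data and scale-equivariant", {
  x <- c(0.1, 0.5, 1, 2)
  fit <- fit_power(data.frame(mean = 2 * x^-1, cv = x))
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, -1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  flat <- fit_power(data.frame(mean = rep(3, 4), cv = x))
  expect_equal(flat$b, 0, tolerance = 1e-10)
  expect_equal(flat$r2, 0)

  # multiplying all means by c multiplies a by c, leaves b and r2 alone
  pts <- simulate_power_points(60, a = 1, b = -0.8, sigma = 0.3, seed = 5)
  f1 <- fit_power(pts)
  f2 <- fit_power(transform(pts, mean = mean * 10))
  expect_equal(f2$a, 10 * f1$a, tolerance = 1e-9)
  expect_equal(f2$b, f1$b, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)

  expect_error(fit_power(data.frame(mean = c(1, 2), cv = c(1, 2))),
               ">= 3")
})

test_that("category comparisons reproduce the ANOVA decomposition and Tukey HSD", {
  # fixed fixture: 3 groups of 6, one shifted
  vals <- c(5.1, 4.8, 5.3, 5.0, 4.9, 5.2,
            5.2, 5.0, 4.7, 5.1, 5.3, 4.9,
            6.0, 6.3, 5.9, 6.1, 6.4, 5.8)
  labs <- rep(c("g1", "g2", "g3"), each = 6)
  cmp <- compare_categories(vals, labs)

  # oracle: from-scratch sums of squares
  gm <- mean(vals)
  mg <- tapply(vals, labs, mean)
  ssb <- sum(6 * (mg - gm)^2)
  ssw <- sum((vals - mg[labs])^2)
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(cmp$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(cmp$p, pf(f_oracle, 2, 15, lower.tail = FALSE),
               tolerance = 1e-9)

  # oracle: studentized-range comparison for each pair
  msw <- ssw / 15
  for (pair in list(c("g2", "g1"), c("g3", "g1"), c("g3", "g2"))) {
    q <- abs(mg[pair[1]] - mg[pair[2]]) / sqrt(msw / 6)
    p_or <- unname(ptukey(q, nmeans = 3, df = 15, lower.tail = FALSE))
    row <- cmp$tukey[cmp$tukey$comparison == paste(pair, collapse = "-"), ]
    expect_equal(row$p_adj, p_or, tolerance = 1e-8)
  }
  expect_equal(cmp$tukey$significant, c(FALSE, TRUE, TRUE))

  # identical groups: F = 0, p = 1
  same <- compare_categories(rep(c(1, 2, 3), times = 3),
                             rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # clear separation gives p < 0.001
  sep <- compare_categories(c(0, 0.01, 0, 0.02, 0, 1, 1.01, 1, 1.02, 1),
                            rep(c("lo", "hi"), each = 5))
  expect_lt(sep$p, 0.001)

  # two-group ANOVA equals the pooled t-test: F = t^2
  v2 <- vals[1:12]; l2 <- labs[1:12]
  tt <- compare_categories(v2, l2)
  av <- compare_categories(c(v2, 7, 7.2), c(l2, "g9", "g9"))
  f2 <- stats::aov(v2 ~ factor(l2))
  expect_equal(summary(f2)[[1]][["F value"]][1], tt$statistic^2,
               tolerance = 1e-9)

  expect_error(compare_categories(c(1, 2, 3), c("a", "a", "b")), "n < 2")
})
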