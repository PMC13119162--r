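test_that("calibration fits recover known lines and report uncertainty honestly", {
  conc <- c(2, 5, 10, 20, 30, 40)
  exact <- fit_calibration(conc, 0.05 * conc)
  expect_equal(exact$slope, 0.05, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$range_lo, 2)
  expect_equal(exact$range_hi, 40)
  # replication invariance
  dup <- fit_calibration(rep(conc, 2), rep(0.05 * conc, 2))
  expect_equal(dup$slope, exact$slope)
  # noisy recovery within 3 standard errors (closed-form OLS variance)
  sigma <- 0.01
  se_slope <- sigma / sqrt(sum((conc - mean(conc))^2))
  fits <- withr::with_seed(42, replicate(20, {
    fit_calibration(conc, 0.02 * conc + rnorm(6, 0, sigma))$slope
  }))
  expect_true(all(abs(fits - 0.02) < 3 * se_slope * 1.5))
  expect_gt(mean(abs(fits - 0.02) < 3 * se_slope), 0.9)
  expect_error(fit_calibration(c(5, 5, 5), c(1, 1, 1)), "distinct")
})

test_that("cumulative release correction matches a compartment bookkeeping oracle", {
  # single sample: plain mass balance
  expect_equal(corrected_cumulative_q(0.05, 900, 5, 100), 45)
  expect_equal(corrected_cumulative_q(c(0.05, 0.05), 900, 5, 100),
               c(45, 45.25))
  expect_equal(corrected_cumulative_q(rep(0, 5)), rep(0, 5))
  # brute-force vessel simulator: dissolve random mass increments, withdraw
  # and replace medium, record concentrations, then check the correction
  # recovers the true cumulative dissolved mass
  withr::with_seed(7, {
    for (rep in 1:5) {
      v <- 900; vs <- 5; dose <- 100
      increments <- runif(8, 0, 8)          # mg dissolved per interval
      mass_in_vessel <- 0; removed <- 0
      conc <- numeric(8); true_cum <- numeric(8)
      for (i in 1:8) {
        mass_in_vessel <- mass_in_vessel + increments[i]
        true_cum[i] <- sum(increments[1:i])
        conc[i] <- mass_in_vessel / v
        mass_in_vessel <- mass_in_vessel - conc[i] * vs  # withdraw + replace
      }
      expect_equal(corrected_cumulative_q(conc, v, vs, dose),
                   100 * true_cum / dose, tolerance = 1e-10)
    }
  })
  # reduces to the naive formula when nothing is withdrawn
  conc <- c(0.01, 0.03, 0.04)
  expect_equal(corrected_cumulative_q(conc, 900, 0, 100),
               100 * conc * 900 / 100)
  expect_error(corrected_cumulative_q(c(-0.1, 0.2)), "non-negative")
})

test_that("time matrices are uniform and round-trip the time point", {
  tm <- build_time_matrix(120, size = 16)
  expect_equal(dim(tm), c(16, 16, 1))
  expect_equal(max(tm) - min(tm), 0)
  expect_equal(unique(as.vector(tm)), 0.5)
  expect_equal(unique(as.vector(build_time_matrix(0, size = 8))), 0)
  expect_equal(unique(as.vector(build_time_matrix(240, size = 8))), 1)
  for (t in c(0, 7, 133, 240)) {
    expect_equal(unique(as.vector(build_time_matrix(t, size = 4))) * 240, t)
  }
  expect_error(build_time_matrix(300), "t_max")
})

test_that("frame preprocessing rescales, resizes and preserves means", {
  z <- array(0, c(16, 16, 3))
  expect_equal(preprocess_frame(z, 16), z)
  u <- array(255, c(16, 16, 3))
  expect_equal(preprocess_frame(u, 16), array(1, c(16, 16, 3)))
  # 2x box-average oracle on a checkerboard
  cb <- array(0, c(32, 32, 3))
  cb[, , ] <- 255 * ((row(matrix(0, 32, 32)) + col(matrix(0, 32, 32))) %% 2)
  out <- preprocess_frame(cb, 16)
  expect_equal(dim(out), c(16, 16, 3))
  expect_equal(mean(out), mean(cb / 255), tolerance = 1 / 255)
  expect_error(preprocess_frame(matrix(0, 8, 8)), "RGB")
})

test_that("seeded splits are deterministic partitions with the ceil rule", {
  s <- make_split(153, 0.2, 1234)
  expect_length(s$train, 122)
  expect_length(s$test, 31)
  expect_identical(make_split(153, 0.2, 1234), s)
  expect_false(identical(make_split(153, 0.2, 4321)$test, s$test))
  for (n in c(10, 17, 107, 153)) {
    sp <- make_split(n, 0.2, 99)
    expect_length(sp$test, ceiling(0.2 * n))
    expect_setequal(c(sp$train, sp$test), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_length(make_split(10, 0.2, 5)$test, 2)
})

test_that("condition encoding is canonical, stable and injective", {
  v <- encode_condition("asa_lactose", 1.2)
  expect_equal(unname(v), c(1, 0, 0, 1, 0, 0))
  expect_identical(encode_condition("asa_lactose", 1.2), v)
  expect_equal(sum(v[1:3]), 1)
  expect_equal(sum(v[4:5]), 1)
  # all 16 formulation x pH combinations are distinct with the medium flag
  f <- default_formulations()
  combos <- expand.grid(id = f$formulation_id, ph = c(1.2, 6.8),
                        stringsAsFactors = FALSE)
  codes <- apply(combos, 1, function(r) {
    paste(encode_condition(r[["id"]], as.numeric(r[["ph"]])), collapse = "")
  })
  expect_equal(length(unique(codes)), 16)
  # placebo encodes with no API flag set
  expect_equal(sum(encode_condition("placebo_mc", 1.2)[1:3]), 0)
  expect_length(encode_condition("asa_mc", 1.2, include_ph = FALSE), 5)
  expect_error(encode_condition("nope", 1.2), "Unknown")
})

test_that("dataset assembly excludes placebos and aligns tensors with labels", {
  sdi <- tiny_sdi(ids = c("asa_lactose", "placebo_lactose"),
                  sample_times = c(0, 30, 60))
  ds <- build_dataset(sdi, size = 32)
  expect_equal(length(ds$q), sum(!is.na(sdi$manifest$q_percent)))
  expect_equal(dim(ds$x280), c(32, 32, 3, length(ds$q)))
  expect_true(all(ds$x280 >= 0 & ds$x280 <= 1))
  expect_true(all(ds$meta$api != "none"))
  expect_equal(ds$time_norm, ds$meta$time_min / 240)
})
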