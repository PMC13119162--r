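test_that("dissolved fraction follows the cylinder volume ratio", {
  init <- tablet_state()
  expect_equal(q_from_geometry(init), 0)
  gone <- tablet_state(radius = 0, height = 0, radius_init = 5,
                       height_init = 3.2)
  expect_equal(q_from_geometry(gone), 100)
  # voxelized-cylinder oracle at half radius: volume ratio = 1/4, Q = 75
  half <- tablet_state(radius = 2.5, height = 3.2, radius_init = 5,
                       height_init = 3.2)
  nx <- 400
  xs <- seq(-5 + 5 / nx, 5 - 5 / nx, length.out = nx)
  grid <- expand.grid(x = xs, y = xs)
  vox_ratio <- sum(grid$x^2 + grid$y^2 <= 2.5^2) /
    sum(grid$x^2 + grid$y^2 <= 5^2)
  expect_equal(q_from_geometry(half), 100 * (1 - vox_ratio), tolerance = 0.01)
  expect_equal(q_from_geometry(half), 75)
})

test_that("stepping is exact and partition-independent for linear kinetics", {
  lin <- formulation_spec("lin", "asa", "lactose", erosion_rate = 0.02,
                          release_exponent = 1)
  one_step <- step_tablet(tablet_state(), lin, 60)
  many <- tablet_state()
  for (i in 1:60) many <- step_tablet(many, lin, 1)
  # closed form r(t) = r0 - k t
  expect_equal(one_step$radius, 5 - 0.02 * 60, tolerance = 1e-12)
  expect_equal(many$radius, one_step$radius, tolerance = 1e-9)
  expect_equal(many$q_percent, one_step$q_percent, tolerance = 1e-9)
  # rate multiplier scales the front linearly
  fast <- step_tablet(tablet_state(), lin, 30, rate_mult = 2)
  expect_equal(fast$radius, 5 - 0.02 * 60, tolerance = 1e-12)
})

test_that("partition independence also holds for saturating gel kinetics", {
  mc <- get_formulation("asa_mc")
  one <- step_tablet(tablet_state(), mc, 120)
  many <- tablet_state()
  for (i in 1:24) many <- step_tablet(many, mc, 5)
  expect_equal(many$radius, one$radius, tolerance = 1e-9)
  expect_equal(many$gel_thickness, one$gel_thickness, tolerance = 1e-9)
})

test_that("a dissolved tablet is an absorbing state and dt = 0 is identity", {
  lin <- get_formulation("asa_lactose")
  st <- tablet_state()
  expect_identical(step_tablet(st, lin, 0), st)
  gone <- tablet_state(radius = 0, height = 0, q_percent = 100,
                       radius_init = 5, height_init = 3.2)
  after <- step_tablet(gone, lin, 30)
  expect_equal(after$radius, 0)
  expect_equal(after$q_percent, 100)
})

test_that("release is monotone and bounded for every default formulation", {
  f <- default_formulations()
  times <- seq(0, 240, by = 5)
  for (i in seq_len(nrow(f))) {
    st <- tablet_state()
    qs <- numeric(length(times))
    for (k in seq_along(times)) {
      st <- step_tablet(st, f[i, ], times[k] - st$time)
      qs[k] <- st$q_percent
    }
    expect_true(all(diff(qs) >= -1e-12), info = f$formulation_id[i])
    expect_true(all(qs >= 0 & qs <= 100), info = f$formulation_id[i])
  }
})

test_that("simulated pH 1.2 profiles track the reference release tables", {
  # reference single-experiment profiles at the standard sampling times
  refs <- list(
    nasal_lactose = list(t = c(5, 10, 15, 30, 45, 60),
                         q = c(2.8, 12.5, 20.8, 44.1, 61.8, 69.8)),
    nasal_mc = list(t = c(5, 10, 15, 30, 45, 60, 120, 180, 240),
                    q = c(0.5, 2.6, 4.1, 8.8, 11.7, 14.1, 23.2, 30.2, 35.8)),
    asa_mc = list(t = c(5, 10, 15, 30, 45, 60, 120, 180, 240),
                  q = c(0.2, 4.2, 11.6, 35.0, 67.0, 82.8, 90.9, 91.0, 91.9)),
    sam_mc = list(t = c(5, 10, 15, 30, 45, 60, 120, 180, 240),
                  q = c(0.0, 1.0, 4.8, 25.7, 56.1, 76.6, 88.1, 88.0, 88.6)),
    sam_lactose = list(t = c(5, 10, 15, 30, 45, 60, 120, 180, 240),
                       q = c(0.1, 1.1, 2.4, 6.2, 10.0, 13.4, 26.7, 39.5, 46.4)))
  for (id in names(refs)) {
    fr <- get_formulation(id)
    st <- tablet_state()
    qs <- numeric(length(refs[[id]]$t))
    for (k in seq_along(qs)) {
      st <- step_tablet(st, fr, refs[[id]]$t[k] - st$time)
      qs[k] <- st$q_percent
    }
    expect_lt(max(abs(qs - refs[[id]]$q)), 7, label = id)
  }
})
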