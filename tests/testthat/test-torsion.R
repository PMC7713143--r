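test_that("curve generator: linear case lies on tau = k * theta", {
  sp <- torsion_curve_spec(stiffness = 5, toe_extent = 0, yield_torque = 45,
                           post_yield_slope = 5, failure_angle = 10)
  g <- generate_torsion_curve(sp)
  pre <- g$curve[g$curve$angle_deg <= 10, ]
  expect_equal(pre$torque_Nm, 5 * pre$angle_deg, tolerance = 1e-12)
})

test_that("curve generator is reproducible under a fixed seed", {
  sp <- torsion_curve_spec(noise_sd = 0.2, seed = 9)
  a <- generate_torsion_curve(sp)
  b <- generate_torsion_curve(sp)
  expect_identical(a$curve$torque_Nm, b$curve$torque_Nm)
  sp$seed <- 10L
  expect_false(identical(generate_torsion_curve(sp)$curve$torque_Nm,
                         a$curve$torque_Nm))
})

test_that("generator rejects a failure angle inside the toe region", {
  expect_error(torsion_curve_spec(toe_extent = 5, failure_angle = 4),
               "toe")
  expect_error(torsion_curve_spec(stiffness = -1), "stiffness")
})

test_that("all five truth metrics are recovered on noiseless curves", {
  for (sp in list(torsion_curve_spec(),
                  torsion_curve_spec(stiffness = 4.4, toe_extent = 2,
                                     yield_torque = 30, failure_angle = 12),
                  torsion_curve_spec(stiffness = 8, toe_extent = 0,
                                     yield_torque = 50,
                                     post_yield_slope = 0.5,
                                     failure_angle = 9))) {
    g <- generate_torsion_curve(sp)
    est <- analyze_torsion_curve(g$curve)
    step <- sp$angular_rate_deg_min / 60 / sp$sampling_rate_hz
    expect_equal(est$stiffness, g$truth$stiffness, tolerance = 0.01)
    expect_equal(est$ultimate_torque, g$truth$ultimate_torque,
                 tolerance = 0.01)
    expect_lt(abs(est$rotation_to_failure - g$truth$rotation_to_failure),
              step + 1e-9)
    expect_equal(est$yield_torque, g$truth$yield_torque, tolerance = 0.01)
    expect_equal(est$energy_to_failure, g$truth$energy_to_failure,
                 tolerance = 0.01)
  }
})

test_that("failure detector fires at the constructed drop", {
  # monotone increasing curve: no failure
  lin <- torsion_curve(0:19, seq(0, 38, by = 2))
  f <- detect_failure(lin)
  expect_false(f$detected)
  expect_equal(f$index, 20L)
  # peak at 40 then decay: first sample at or below 37 Nm
  tq <- c(seq(2, 40, by = 2), 39, 38, 37, 36, 35)
  crv <- torsion_curve(seq_along(tq), tq)
  f2 <- detect_failure(crv)
  expect_true(f2$detected)
  expect_equal(crv$torque_Nm[f2$index], 37)
  expect_error(detect_failure(crv, drop = 0), "drop")
  # synthetic drop at 10 degrees detected within one sample step
  g <- generate_torsion_curve(torsion_curve_spec(failure_angle = 10))
  f3 <- detect_failure(g$curve)
  step <- 5 / 60 / 20
  expect_lt(abs(g$curve$angle_deg[f3$index] - 10), 2 * step)
})

test_that("apparent stiffness: exact on a line, robust to toe and noise", {
  lin <- torsion_curve(0:9, 5 * (0:9))
  expect_equal(as.numeric(apparent_stiffness(lin)), 5, tolerance = 1e-12)
  g <- generate_torsion_curve(torsion_curve_spec(stiffness = 4.4,
                                                 toe_extent = 2,
                                                 yield_torque = 30,
                                                 failure_angle = 12))
  expect_equal(as.numeric(apparent_stiffness(g$curve)), 4.4,
               tolerance = 0.01)
  gn <- generate_torsion_curve(torsion_curve_spec(noise_sd = 0.1, seed = 3))
  expect_lt(abs(as.numeric(apparent_stiffness(gn$curve)) / 5 - 1), 0.05)
  expect_error(apparent_stiffness(torsion_curve(1:10, c(1:4, 4, 3, 2, 1, 1, 1))),
               "pre-ultimate")
})

test_that("yield point: offset method on bilinear curves, flagged on lines", {
  lin <- torsion_curve(0:9, 5 * (0:9))
  y <- yield_point(lin)
  expect_equal(attr(y, "flag"), "no_yield")
  expect_equal(as.numeric(y), 45)
  # near-plateau after the break: yield recovered at the break torque
  g <- generate_torsion_curve(torsion_curve_spec(stiffness = 5,
                                                 toe_extent = 0,
                                                 yield_torque = 37,
                                                 post_yield_slope = 0.01,
                                                 failure_angle = 10))
  y2 <- yield_point(g$curve)
  expect_equal(as.numeric(y2), 37, tolerance = 0.005)
  # yield never exceeds ultimate across a parameter grid
  for (k2 in c(0.05, 0.5, 1.5)) {
    gi <- generate_torsion_curve(torsion_curve_spec(post_yield_slope = k2))
    est <- analyze_torsion_curve(gi$curve)
    expect_lte(est$yield_torque, est$ultimate_torque)
  }
})

test_that("energy to failure: triangle, zero and piecewise closed forms", {
  tri <- torsion_curve(seq(0, 10, by = 0.5), 5 * seq(0, 10, by = 0.5))
  expect_equal(energy_to_failure(tri, failure_index = 21L), 250)
  flat <- torsion_curve(0:10, rep(0, 11))
  expect_equal(energy_to_failure(flat), 0)
  g <- generate_torsion_curve(torsion_curve_spec())
  expect_equal(energy_to_failure(g$curve), g$truth$energy_to_failure,
               tolerance = 0.005)
  # additivity over contiguous segments
  crv <- g$curve
  i <- 1000L
  n <- detect_failure(crv)$index
  e_all <- energy_to_failure(crv, n)
  e_a <- callusmorph:::trapz(crv$angle_deg[1:i], crv$torque_Nm[1:i])
  e_b <- callusmorph:::trapz(crv$angle_deg[i:n], crv$torque_Nm[i:n])
  expect_equal(e_all, e_a + e_b, tolerance = 1e-9)
})

test_that("contralateral normalization reports percent of contralateral", {
  m <- analyze_torsion_curve(generate_torsion_curve(torsion_curve_spec())$curve)
  same <- normalize_to_contralateral(m, m)
  expect_equal(unname(same$normalized), rep(100, 5))
  half <- m; half$stiffness <- m$stiffness / 2
  expect_equal(normalize_to_contralateral(half, m)$normalized[["stiffness"]],
               50)
  # pair constructed to land at 89.9% stiffness
  contra <- m; contra$stiffness <- m$stiffness / 0.899
  expect_equal(normalize_to_contralateral(m, contra)$normalized[["stiffness"]],
               89.9, tolerance = 1e-9)
  bad <- m; bad$stiffness <- 0
  expect_error(normalize_to_contralateral(m, bad), "non-positive")
})

test_that("torsion curves round-trip through CSV", {
  g <- generate_torsion_curve(torsion_curve_spec(noise_sd = 0.05, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_torsion_csv(g$curve, path)
  back <- read_torsion_csv(path)
  expect_equal(back$angle_deg, g$curve$angle_deg)
  expect_equal(back$torque_Nm, g$curve$torque_Nm)
  # header-less two-column files are accepted too
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(data.frame(g$curve$angle_deg, g$curve$torque_Nm),
                     path2, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_torsion_csv(path2)$torque_Nm, g$curve$torque_Nm)
})

test_that("curve validation: channels, length, monotonicity", {
  expect_error(torsion_curve(1:5, 1:4), "length")
  expect_error(torsion_curve(1:5, 1:5), "10 samples")
  expect_error(torsion_curve(c(1:10, 9.5), c(1:10, 9.5) * 2), "increasing")
  dedup <- torsion_curve(c(0, 1:10, 10), c(0, 1:10, 10) * 2)
  expect_equal(nrow(dedup), 11L)
})
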