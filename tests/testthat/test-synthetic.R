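test_that("fixtures are bit-identical for identical config and seed", {
  cfg <- fixture_config(n_residues = 8, n_frames = 30, base_jitter_sigma = 0.3,
                        events = list(event_step("2-4", 10, c(1, 2, 2))),
                        seed = 7)
  a <- generate_fixture(cfg)
  b <- generate_fixture(cfg)
  expect_identical(a$ensemble$coords, b$ensemble$coords)
  c2 <- generate_fixture(fixture_config(n_residues = 8, n_frames = 30,
                                        base_jitter_sigma = 0.3, seed = 8))
  expect_false(identical(a$ensemble$coords, c2$ensemble$coords))
})

test_that("a noise-free, event-free fixture is static with an all-zero map", {
  fx <- generate_fixture(fixture_config(n_residues = 5, n_frames = 10,
                                        base_jitter_sigma = 0, seed = 1))
  m <- compute_shift_matrix(fx$topology, fx$ensemble)
  expect_equal(m$values, matrix(0, 5, 10))
  expect_equal(compute_shift_matrix(fx$topology, fx$ensemble,
                                    reference = "previous")$values,
               matrix(0, 5, 10))
})

test_that("a noise-free step paints an exact piecewise-constant band", {
  fx <- generate_fixture(fixture_config(
    n_residues = 6, n_frames = 12, base_jitter_sigma = 0,
    events = list(event_step("2-4", 7, c(4, 0, 0))), seed = 1))
  m <- compute_shift_matrix(fx$topology, fx$ensemble)
  expect_equal(m$values[2:4, 7:12], matrix(4, 3, 6), tolerance = 1e-9)
  expect_equal(m$values[2:4, 1:6], matrix(0, 3, 6))
  expect_equal(m$values[c(1, 5, 6), ], matrix(0, 3, 12))
  # previous-step map: nonzero only at the onset column
  mp <- compute_shift_matrix(fx$topology, fx$ensemble, reference = "previous")
  expect_equal(mp$values[2:4, 7], rep(4, 3), tolerance = 1e-9)
  mp$values[2:4, 7] <- 0
  expect_equal(mp$values, matrix(0, 6, 12))
})

test_that("ramped steps interpolate linearly to the full displacement", {
  fx <- generate_fixture(fixture_config(
    n_residues = 3, n_frames = 12, base_jitter_sigma = 0,
    events = list(event_step("2-2", 5, c(3, 0, 0), ramp_frames = 2))))
  m <- compute_shift_matrix(fx$topology, fx$ensemble)
  expect_equal(m$values[2, 4:8], c(0, 1, 2, 3, 3), tolerance = 1e-9)
})

test_that("a fluctuation change raises jitter only after its onset", {
  fx <- generate_fixture(fixture_config(
    n_residues = 6, n_frames = 400, base_jitter_sigma = 0.1,
    events = list(event_fluctuation("2-4", 201, 0.5)), seed = 13))
  mp <- compute_shift_matrix(fx$topology, fx$ensemble, reference = "previous")
  s <- region_shift_series(mp, "2-4")
  pre <- mean(s$values[3:200])
  post <- mean(s$values[203:400])
  expect_gt(post, 3 * pre)  # sigma ratio 5 -> prev-step shifts scale ~5x
  # untouched residues keep their noise floor
  s_out <- region_shift_series(mp, "6-6")
  expect_lt(abs(mean(s_out$values[203:400]) / mean(s_out$values[3:200]) - 1), 0.3)
})

test_that("COM noise floor matches the chi-distribution expectation", {
  # per-atom jitter sigma on 4 mass-weighted atoms gives per-coordinate COM
  # noise sigma*sqrt(sum w^2); the null previous-step shift is then a 3-dof
  # chi scaled by that sigma times sqrt(2) (two independently jittered frames)
  sigma <- 0.3
  fx <- generate_fixture(fixture_config(n_residues = 10, n_frames = 500,
                                        base_jitter_sigma = sigma, seed = 31))
  mp <- compute_shift_matrix(fx$topology, fx$ensemble, reference = "previous")
  observed <- mean(mp$values[, 3:500])
  w <- fx$topology$atoms$mass[1:4]
  w <- w / sum(w)
  sc <- sigma * sqrt(sum(w^2)) * sqrt(2)
  expected <- sc * sqrt(2 / pi) * 2  # E[chi_3] = 2*sqrt(2/pi), MC-verified below
  set.seed(2)
  mc <- mean(sqrt(stats::rnorm(2e4, 0, sc)^2 + stats::rnorm(2e4, 0, sc)^2 +
                    stats::rnorm(2e4, 0, sc)^2))
  expect_lt(abs(mc - expected) / expected, 0.02)
  expect_lt(abs(observed - expected) / expected, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(fixture_config(n_residues = 1), "config error")
  expect_error(fixture_config(base_jitter_sigma = -1), "config error")
  expect_error(fixture_config(events = list(event_step("2-3", 1, c(1, 0, 0)))),
               "onset")
  expect_error(fixture_config(events = list(event_step("2-3", 999, c(1, 0, 0))),
                              n_frames = 10), "onset")
  expect_error(fixture_config(n_residues = 5,
                              events = list(event_step("2-9", 3, c(1, 0, 0)))),
               "region")
  expect_error(event_fluctuation("1-2", 5, 0), "sigma")
  expect_error(
    fixture_config(events = list(event_step("2-6", 10, c(1, 0, 0)),
                                 event_step("5-8", 20, c(0, 1, 0)))),
    "overlapping")
  # same region, different kinds: allowed
  cfg <- fixture_config(events = list(event_step("2-6", 10, c(1, 0, 0)),
                                      event_fluctuation("2-6", 20, 0.5)))
  expect_s3_class(cfg, "fixture_config")
})

test_that("written fixtures round-trip within format precision and stay small", {
  fx <- generate_fixture(fixture_config(n_residues = 10, n_frames = 40,
                                        base_jitter_sigma = 0.3, seed = 3))
  dir <- withr::local_tempdir()
  p <- write_fixture(fx$topology, fx$ensemble, dir, config = fx$config)
  lt <- load_trajectory(p$trajectory, p$topology)
  m_file <- compute_shift_matrix(lt$topology, lt$ensemble)
  m_mem <- compute_shift_matrix(fx$topology, fx$ensemble)
  expect_lt(max(abs(m_file$values - m_mem$values)), 1e-3)
  total <- sum(file.size(unlist(p)))
  expect_lt(total, 50 * 1024^2)
  manifest <- jsonlite::read_json(p$manifest)
  expect_equal(manifest$n_frames, 40)
})
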