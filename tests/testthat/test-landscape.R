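test_that("potential has the documented well, asymptote and catalysis coupling", {
  m <- landscape_model(well_depth = 5, catalysis_strength = 2)
  # global minimum of the bare well sits at eq_distance with value -well_depth
  expect_equal(evaluate_potential(m, m$eq_distance, 0), -5)
  xs <- seq(2.2, 6, by = 0.01)
  expect_true(all(evaluate_potential(m, xs, 0) >= -5))
  # dissociated reference vanishes
  expect_equal(evaluate_potential(m, 60, 0), 0, tolerance = 1e-10)
  # occupied-water stabilisation is exactly -c * g(x) at any x
  g_centre <- 0.5  # logistic switch at its own centre
  expect_equal(
    evaluate_potential(m, m$catalysis_center, 1) -
      evaluate_potential(m, m$catalysis_center, 0),
    -m$catalysis_strength * g_centre)
  diff_far <- evaluate_potential(m, 8, 1) - evaluate_potential(m, 8, 0)
  expect_equal(diff_far, -m$catalysis_strength, tolerance = 1e-9)
})

test_that("potential rejects invalid coordinates and occupancies", {
  m <- landscape_model()
  expect_error(evaluate_potential(m, NaN, 0), "finite")
  expect_error(evaluate_potential(m, Inf, 0), "finite")
  expect_error(evaluate_potential(m, -1, 0), "positive")
  expect_error(evaluate_potential(m, 3, 0.5), "0 or 1")
  expect_error(landscape_model(shielding = 1.2), "0, 1")
})

test_that("equilibration is deterministic under a fixed seed", {
  m <- shielded_model()
  cfg <- equilibrium_config(duration = 0.02, n_replicas = 2,
                            frame_interval = 0.001, seed = 99)
  a <- run_equilibration(m, config = cfg)
  b <- run_equilibration(m, config = cfg)
  expect_identical(a$distance, b$distance)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("zero-temperature dynamics started at the minimum stay there", {
  m <- shielded_model()
  cfg <- equilibrium_config(duration = 0.01, n_replicas = 1,
                            frame_interval = 0.0005,
                            temperature = 1e-8, diffusion_coeff = 1e-8,
                            seed = 1)
  eq <- run_equilibration(m, config = cfg, x_init = m$eq_distance)
  # thermal width sqrt(kT/k) is ~7e-7 A at this temperature
  expect_true(all(abs(eq$distance - m$eq_distance) < 1e-4))
})

test_that("flat-bottom restraint drives an outside start back into the window", {
  m <- shielded_model()
  cfg <- equilibrium_config(duration = 0.05, n_replicas = 1,
                            frame_interval = 0.0005, seed = 3)
  eq <- run_equilibration(m, config = cfg, x_init = 4.5)
  # monotone early drift toward the 3.5 A wall, and eventual re-entry
  expect_lt(eq$distance[1], 4.5)
  expect_lt(min(eq$distance), 3.5)
})

test_that("restrained equilibration samples the Boltzmann distribution (quadrature oracle)", {
  m <- shielded_model()
  r <- restraint_spec()
  eq <- run_equilibration(m, r, equilibrium_config(
    duration = 10, n_replicas = 2, frame_interval = 0.001, seed = 42))
  breaks <- seq(2.0, 4.2, by = 0.04)
  x <- eq$distance
  counts <- table(cut(x[x >= 2 & x < 4.2], breaks = breaks, right = FALSE))
  u_tot <- function(xx) {
    wall <- ifelse(xx < r$lower, 0.5 * r$force_k * (xx - r$lower)^2,
                   ifelse(xx > r$upper, 0.5 * r$force_k * (xx - r$upper)^2, 0))
    evaluate_potential(m, xx, 0) + wall
  }
  kT <- rt298
  dens <- function(xx) exp(-u_tot(xx) / kT)
  p_exp <- vapply(seq_len(length(breaks) - 1), function(i) {
    stats::integrate(dens, breaks[i], breaks[i + 1])$value
  }, numeric(1))
  p_exp <- p_exp / sum(p_exp)
  p_obs <- as.numeric(counts) / sum(counts)
  tv <- 0.5 * sum(abs(p_obs - p_exp))
  expect_lt(tv, 0.05)
})

test_that("unstable time steps are flagged", {
  m <- shielded_model()
  cfg <- equilibrium_config(duration = 0.001, n_replicas = 1,
                            frame_interval = 5e-4, time_step = 5e-4,
                            diffusion_coeff = 3e4, seed = 1)
  expect_warning(run_equilibration(m, config = cfg), "unstable")
})

test_that("solvent frames honour the exclusion model", {
  # no exclusion: particles everywhere, count conserved
  fr0 <- sample_solvent_frames(10, 200, exclusion_prob = 0, seed = 1)
  solv0 <- dplyr::filter(fr0, role == "solvent")
  expect_equal(nrow(solv0), 2000)
  r0 <- sqrt(solv0$x^2 + solv0$y^2 + solv0$z^2)
  expect_true(all(r0 <= 12))
  expect_gt(sum(r0 < 4), 0)
  # full exclusion: no particle within the exclusion radius
  fr1 <- sample_solvent_frames(10, 200, exclusion_radius = 5,
                               exclusion_prob = 1, seed = 1)
  solv1 <- dplyr::filter(fr1, role == "solvent")
  r1 <- sqrt(solv1$x^2 + solv1$y^2 + solv1$z^2)
  expect_true(all(r1 > 5))
  expect_error(sample_solvent_frames(1, 10, box_radius = 3,
                                     exclusion_radius = 5), "box_radius")
})

test_that("shell counts outside the exclusion zone match the uniform expectation", {
  n_frames <- 200; n_solv <- 500; R <- 12
  fr <- sample_solvent_frames(n_frames, n_solv, box_radius = R,
                              exclusion_radius = 3, exclusion_prob = 0.5,
                              seed = 7)
  solv <- dplyr::filter(fr, role == "solvent")
  r <- sqrt(solv$x^2 + solv$y^2 + solv$z^2)
  # shell [6, 7) A lies outside the exclusion zone
  count <- sum(r >= 6 & r < 7)
  rho <- n_solv / (4 / 3 * pi * R^3)
  expected <- n_frames * rho * 4 / 3 * pi * (7^3 - 6^3)
  expect_lt(abs(count - expected), 3 * sqrt(expected))
})

test_that("distance statistics: degenerate, known-normal and shielding-width cases", {
  s <- equilibrium_distance_stats(rep(2.9, 100))
  expect_equal(s$sd, 0)
  expect_equal(s$mean, 2.9)

  x <- withr::with_seed(10, rnorm(20000, mean = 3.0, sd = 0.1))
  s2 <- equilibrium_distance_stats(x)
  expect_equal(s2$mean, 3.0, tolerance = 0.01)
  expect_equal(s2$sd, 0.1, tolerance = 0.01)
  expect_equal(sum(s2$histogram$count), length(x))

  # a shielded interface shows a narrower bond-length distribution
  cfg <- equilibrium_config(duration = 2, n_replicas = 2,
                            frame_interval = 0.001, seed = 21)
  sd_s <- equilibrium_distance_stats(
    run_equilibration(shielded_model(), config = cfg))$sd
  sd_u <- equilibrium_distance_stats(
    run_equilibration(exposed_model(), config = cfg))$sd
  expect_lt(sd_s, sd_u)
})
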