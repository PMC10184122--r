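test_that("Jarzynski average: degenerate and two-term closed forms", {
  expect_equal(jarzynski_free_energy(c(3, 3, 3)), 3)
  expect_equal(jarzynski_free_energy(7.2), 7.2)
  # one negligible exponential: -RT ln(1/2) = RT ln 2
  expect_equal(jarzynski_free_energy(c(0, 1e6)), rt298 * log(2),
               tolerance = 1e-12)
  expect_equal(jarzynski_free_energy(c(1, 2)), jarz2(1, 2))
  expect_error(jarzynski_free_energy(numeric(0)), "at least one")
  expect_error(jarzynski_free_energy(c(1, NA)), "finite")
})

test_that("Jensen bound and gauge invariance hold on random ensembles", {
  withr::with_seed(17, {
    for (i in 1:20) {
      w <- rnorm(25, mean = runif(1, 0, 10), sd = runif(1, 0.1, 3))
      est <- jarzynski_free_energy(w)
      expect_lte(est, mean(w) + 1e-12)
      expect_gte(est, min(w) - 1e-12)
      shift <- runif(1, -5, 5)
      expect_equal(jarzynski_free_energy(w + shift), est + shift,
                   tolerance = 1e-9)
    }
  })
})

test_that("PMF profiles apply the scalar estimator pointwise on the shared grid", {
  # identical profiles collapse onto that profile
  w <- c(0, 1.3, 2.8)
  ens <- toy_ensemble(list(w, w, w))
  prof <- build_pmf_profile(ens)
  expect_equal(prof$pmf, w)
  expect_equal(prof$distance, c(2.5, 3.75, 5.0))
  # two-profile set matches the per-point two-term closed form
  wa <- c(0, 2.0, 4.0); wb <- c(0, 1.0, 1.5)
  prof2 <- build_pmf_profile(toy_ensemble(list(wa, wb)))
  expect_equal(prof2$pmf,
               purrr::map2_dbl(wa, wb, jarz2))
  expect_equal(prof2$pmf[1], 0)
  # mismatched grids are rejected
  bad <- dplyr::bind_rows(
    tibble::tibble(traj_id = 1L, distance = c(2.5, 5.0), work = c(0, 1)),
    tibble::tibble(traj_id = 2L, distance = c(2.5, 4.9), work = c(0, 1)))
  expect_error(build_pmf_profile(bad), "grid")
})

test_that("bootstrap errors: degenerate, seeded and enumerated-resampling cases", {
  w <- c(0, 1.3, 2.8)
  same <- toy_ensemble(list(w, w, w))
  bs <- bootstrap_errors(same, n_boot = 10, seed = 1)
  expect_true(all(bs$sd == 0))
  expect_error(bootstrap_errors(same, n_boot = 1), "at least 2")

  two <- toy_ensemble(list(c(0, 2.0, 4.0), c(0, 1.0, 1.5)))
  a <- bootstrap_errors(two, n_boot = 50, seed = 7)
  b <- bootstrap_errors(two, n_boot = 50, seed = 7)
  expect_identical(a$sd, b$sd)

  # exhaustive oracle: resamples of a 2-profile set can only be the three
  # multisets {AA}, {AB}, {BB} with probabilities 1/4, 1/2, 1/4
  endpoint_vals <- c(4.0, jarz2(4.0, 1.5), 1.5)
  p_multi <- c(0.25, 0.5, 0.25)
  mu <- sum(p_multi * endpoint_vals)
  sd_exact <- sqrt(sum(p_multi * (endpoint_vals - mu)^2))
  big <- bootstrap_errors(two, n_boot = 4000, seed = 11)
  expect_equal(big$sd[3], sd_exact, tolerance = 0.05)
})

test_that("endpoint accessor returns the final grid value and rejects truncation", {
  prof <- bootstrap_errors(toy_ensemble(list(c(0, 1, 2), c(0, 1, 2))),
                           n_boot = 5, seed = 1)
  ep <- endpoint_value(prof)
  expect_equal(ep$distance, 5.0)
  expect_equal(ep$pmf, 2)
  expect_equal(ep$sd, 0)
  zero <- build_pmf_profile(toy_ensemble(list(c(0, 0, 0))))
  expect_equal(endpoint_value(zero)$pmf, 0)
  short <- toy_ensemble(list(c(0, 1, 2)), grid = c(2.5, 3.0, 3.5))
  expect_error(endpoint_value(build_pmf_profile(short)), "truncated")
})

test_that("convergence scan: full-size row, zero drift for identical profiles, size checks", {
  w <- withr::with_seed(3, replicate(20, c(0, rnorm(1, 2), rnorm(1, 4)),
                                     simplify = FALSE))
  ens <- toy_ensemble(w)
  tab <- convergence_scan(ens, sizes = c(5, 10, 20), seed = 5)
  full <- endpoint_value(build_pmf_profile(ens))
  expect_equal(tab$endpoint[tab$size == 20], full$pmf)
  expect_equal(tab$drift[tab$size == 20], 0)

  same <- toy_ensemble(rep(list(c(0, 1, 2)), 10))
  tab2 <- convergence_scan(same, sizes = c(2, 5, 10), seed = 5)
  expect_true(all(tab2$drift == 0))

  expect_error(convergence_scan(ens, sizes = c(10, 50)), "exceed")
})

test_that("the finite-N Jarzynski bias shrinks toward the analytic Gaussian value", {
  mu <- 3; sigma <- 1
  df_true <- mu - sigma^2 / (2 * rt298)
  est_at <- function(n, reps) {
    withr::with_seed(29, {
      mean(replicate(reps, jarzynski_free_energy(rnorm(n, mu, sigma))))
    })
  }
  small_n <- est_at(5, 400)
  large_n <- est_at(150, 400)
  # biased high at small N, decreasing toward the analytic value
  expect_gt(small_n, large_n)
  expect_gt(small_n, df_true)
  expect_equal(large_n, df_true, tolerance = 0.15)
})

test_that("second-cumulant estimator matches its closed form and the Jarzynski
           average for Gaussian work", {
  expect_equal(second_cumulant_estimate(c(4, 4, 4, 4)), 4)
  w <- withr::with_seed(13, rnorm(5000, mean = 5, sd = 1))
  expect_equal(second_cumulant_estimate(w), 5 - 1 / (2 * rt298),
               tolerance = 0.1)
  # near-Gaussian ensemble: the two estimators agree within bootstrap error
  works <- withr::with_seed(14, rnorm(100, mean = 2, sd = 0.5))
  ens <- toy_ensemble(purrr::map(works, function(x) c(0, x / 2, x)))
  bs <- bootstrap_errors(ens, n_boot = 30, seed = 15)
  ep <- endpoint_value(bs)
  expect_lt(abs(second_cumulant_estimate(works) - ep$pmf),
            3 * ep$sd + 0.05)
})
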