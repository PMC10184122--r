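# shared fixtures: small models and ensembles used across test files

kB <- 0.0019872
rt298 <- kB * 298

shielded_model <- function(...) landscape_model(shielding = 1, ...)
exposed_model <- function(...) landscape_model(shielding = 0, ...)

# fast pulls for property tests: 2.5 A/ns (1 ns per pull), coarse grid
fast_protocol <- function(n_traj = 5, seed = 1, ...) {
  pulling_protocol(n_traj = n_traj, rate = 2.5, report_step = 0.025,
                   seed = seed, ...)
}

# a tiny deterministic work ensemble on a 3-point grid
toy_ensemble <- function(works_by_traj, grid = c(2.5, 3.75, 5.0),
                         temperature = 298) {
  out <- purrr::list_rbind(purrr::imap(works_by_traj, function(w, i) {
    tibble::tibble(traj_id = as.integer(i), distance = grid, work = w)
  }))
  attr(out, "temperature") <- temperature
  class(out) <- c("work_ensemble", class(out))
  out
}

# closed-form two-value Jarzynski average
jarz2 <- function(w1, w2, temperature = 298) {
  rt <- kB * temperature
  -rt * log((exp(-w1 / rt) + exp(-w2 / rt)) / 2)
}

# analytic free-energy difference between guided endpoints of a pull:
# quadrature over the bond coordinate with the spring at fixed guide centre
guided_free_energy_difference <- function(model, protocol) {
  kT <- kB * protocol$temperature
  f_at <- function(lam) {
    dens <- function(x) {
      exp(-(evaluate_potential(model, x, 0) +
              0.5 * protocol$spring_k * (x - lam)^2) / kT)
    }
    -kT * log(stats::integrate(dens, lam - 1, lam + 1)$value)
  }
  f_at(protocol$end_distance) - f_at(protocol$start_distance)
}
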