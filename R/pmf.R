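#' Jarzynski free-energy estimate from nonequilibrium work values
#'
#' Computes the Boltzmann-averaged free-energy estimate
#' \deqn{\Delta F = -RT \ln \frac{1}{N} \sum_i e^{-W_i / RT}}
#' from a set of nonequilibrium work values, using a log-sum-exp shift by
#' the minimum work for numerical stability. By Jensen's inequality the
#' estimate never exceeds the arithmetic mean of the works.
#'
#' @param works numeric vector of work values, kcal/mol (at least one
#'   finite value).
#' @param temperature Kelvin.
#' @return The free-energy estimate, kcal/mol (scalar).
#' @examples
#' jarzynski_free_energy(c(3, 3, 3))          # 3
#' jarzynski_free_energy(c(0, 1e6)) / log(2)  # RT at 298 K
#' @export
jarzynski_free_energy <- function(works, temperature = 298) {
  if (length(works) == 0) abort("`works` must contain at least one value.")
  if (!is.numeric(works) || any(!is.finite(works))) {
    abort("`works` must be finite numeric.")
  }
  rt <- .rt(temperature)
  m <- min(works)
  m - rt * log(mean(exp(-(works - m) / rt)))
}

## columns of `w` (grid x N matrix) are trajectories; returns the
## Jarzynski profile over the grid, log-sum-exp shifted row-wise
.jarzynski_profile <- function(w, rt) {
  m <- do.call(pmin, as.data.frame(w))
  m - rt * log(rowMeans(exp(-(w - m) / rt)))
}

## validate and reshape a work ensemble into a grid x N matrix
.work_matrix <- function(set) {
  stopifnot(is.data.frame(set))
  need <- c("traj_id", "distance", "work")
  if (!all(need %in% names(set))) {
    abort("a work ensemble needs columns traj_id, distance, work.")
  }
  if (any(!is.finite(set$work))) abort("work values must be finite.")
  wide <- pivot_wider(set, id_cols = "distance", names_from = "traj_id",
                      values_from = "work")
  w <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(w)) abort("profiles in the ensemble do not share one grid.")
  grid <- wide$distance
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("the distance grid must be strictly increasing.")
  }
  list(grid = grid, w = w)
}

#' Pointwise Jarzynski PMF profile from a work ensemble
#'
#' Applies [jarzynski_free_energy()] at every distance of the shared
#' report grid. Since all profiles carry zero work at the pull start, the
#' PMF is exactly zero there.
#'
#' @param set a `work_ensemble` tibble (columns `traj_id`, `distance`,
#'   `work`), e.g. from [generate_work_ensemble()] or
#'   [read_work_profiles()].
#' @param temperature Kelvin; defaults to the ensemble's
#'   `temperature` attribute, else 298.
#' @return A tibble of class `pmf_profile` with columns `distance` and
#'   `pmf` (kcal/mol); attributes `temperature` and `n_traj`.
#' @export
build_pmf_profile <- function(set, temperature = NULL) {
  temperature <- temperature %||% attr(set, "temperature") %||% 298
  wm <- .work_matrix(set)
  out <- tibble(distance = wm$grid,
                pmf = .jarzynski_profile(wm$w, .rt(temperature)))
  attr(out, "temperature") <- temperature
  attr(out, "n_traj") <- ncol(wm$w)
  class(out) <- c("pmf_profile", class(out))
  out
}

#' Bootstrap errors for a Jarzynski PMF profile
#'
#' Resamples whole trajectories with replacement `n_boot` times and
#' reports, at every grid distance, the standard deviation of the
#' resampled Jarzynski estimates. Resampling whole profiles (rather than
#' independent per-point works) preserves the within-trajectory
#' correlation of the work along the pull.
#'
#' @inheritParams build_pmf_profile
#' @param n_boot number of bootstrap resamples (>= 2; default 10).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A `pmf_profile` tibble with columns `distance`, `pmf`
#'   (full-ensemble estimate) and `sd` (bootstrap standard deviation);
#'   attribute `n_boot`.
#' @export
bootstrap_errors <- function(set, n_boot = 10, seed = NULL,
                             temperature = NULL) {
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  temperature <- temperature %||% attr(set, "temperature") %||% 298
  rt <- .rt(temperature)
  wm <- .work_matrix(set)
  n <- ncol(wm$w)
  run <- function() {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .jarzynski_profile(wm$w[, idx, drop = FALSE], rt)
    }, numeric(length(wm$grid)))
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble(
    distance = wm$grid,
    pmf = .jarzynski_profile(wm$w, rt),
    sd = apply(reps, 1, stats::sd)
  )
  attr(out, "temperature") <- temperature
  attr(out, "n_traj") <- n
  attr(out, "n_boot") <- n_boot
  class(out) <- c("pmf_profile", class(out))
  out
}

#' Endpoint of a PMF profile
#'
#' The rupture free energy is read at the final grid distance of the
#' profile (conventionally 5.0 Angstrom).
#'
#' @param profile a `pmf_profile` tibble.
#' @param end_distance distance the profile must reach, Angstrom.
#' @param tol tolerance on reaching `end_distance`, Angstrom.
#' @return A one-row tibble with `distance`, `pmf` and `sd` (`NA` if the
#'   profile carries no bootstrap column).
#' @export
endpoint_value <- function(profile, end_distance = 5.0, tol = 1e-6) {
  stopifnot(is.data.frame(profile),
            all(c("distance", "pmf") %in% names(profile)))
  last_d <- max(profile$distance)
  if (last_d < end_distance - tol) {
    abort(sprintf(
      "profile is truncated: reaches %.4f A, expected %.4f A.",
      last_d, end_distance))
  }
  i <- which.max(profile$distance)
  tibble(distance = profile$distance[i], pmf = profile$pmf[i],
         sd = if ("sd" %in% names(profile)) profile$sd[i] else NA_real_)
}

#' Convergence of the Jarzynski endpoint with ensemble size
#'
#' For each subsample size, draws trajectories without replacement,
#' estimates the endpoint PMF and its bootstrap error, and reports the
#' drift relative to the full-ensemble estimate. The full ensemble is
#' always included as the last row. The finite-N Jarzynski estimator is
#' biased high, so well-behaved ensembles drift downward toward the
#' large-N value.
#'
#' @inheritParams bootstrap_errors
#' @param sizes subsample sizes (all `<=` the number of trajectories).
#' @return A tibble of class `convergence_table` with columns `size`,
#'   `endpoint`, `sd` and `drift` (endpoint minus full-ensemble endpoint).
#' @export
convergence_scan <- function(set, sizes = c(10, 25, 50, 75, 100),
                             n_boot = 10, seed = NULL, temperature = NULL) {
  temperature <- temperature %||% attr(set, "temperature") %||% 298
  rt <- .rt(temperature)
  wm <- .work_matrix(set)
  n <- ncol(wm$w)
  if (any(sizes > n)) {
    abort(sprintf("subsample sizes exceed the ensemble size N = %d.", n))
  }
  sizes <- sort(unique(c(sizes, n)))
  last_row <- nrow(wm$w)
  run <- function() {
    list_rbind(map(sizes, function(s) {
      idx <- if (s == n) seq_len(n) else sample.int(n, s, replace = FALSE)
      w_end <- wm$w[last_row, idx]
      est <- jarzynski_free_energy(w_end, temperature)
      boots <- vapply(seq_len(n_boot), function(b) {
        jarzynski_free_energy(w_end[sample.int(s, s, replace = TRUE)],
                              temperature)
      }, numeric(1))
      tibble(size = s, endpoint = est, sd = stats::sd(boots))
    }))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$drift <- out$endpoint - out$endpoint[out$size == n]
  attr(out, "temperature") <- temperature
  class(out) <- c("convergence_table", class(out))
  out
}

#' Second-cumulant (Gaussian-work) free-energy estimate
#'
#' For near-Gaussian work distributions the Jarzynski average reduces to
#' `mean(W) - var(W) / (2 RT)`; comparing the two estimators is a standard
#' convergence cross-check.
#'
#' @inheritParams jarzynski_free_energy
#' @return The second-cumulant estimate, kcal/mol.
#' @export
second_cumulant_estimate <- function(works, temperature = 298) {
  if (length(works) < 2) abort("need at least two work values.")
  mean(works) - stats::var(works) / (2 * .rt(temperature))
}
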