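#' Restrained equilibration of the bond coordinate
#'
#' Runs overdamped Langevin dynamics on the landscape plus a flat-bottom
#' restraint, sampling the donor--acceptor distance and the water occupancy.
#' Replica `i` is seeded with `config$seed + i - 1`, so a fixed seed gives a
#' bit-identical series.
#'
#' @param model a [landscape_model()].
#' @param restraint a [restraint_spec()].
#' @param config an [equilibrium_config()].
#' @param x_init initial distance, Angstrom (default: the well minimum).
#' @param n_init initial water occupancy (0 or 1).
#' @return A tibble of class `equilibrium_series` with columns `replica`,
#'   `time` (ns), `distance` (Angstrom), `occupancy`; the final state of
#'   each replica is in `attr(, "final_states")`.
#' @examples
#' m <- landscape_model(shielding = 1)
#' eq <- run_equilibration(m, config = equilibrium_config(
#'   duration = 0.1, n_replicas = 2, seed = 1))
#' @export
run_equilibration <- function(model,
                              restraint = restraint_spec(),
                              config = equilibrium_config(),
                              x_init = model$eq_distance,
                              n_init = 0) {
  stopifnot(inherits(model, "landscape_model"),
            inherits(restraint, "restraint_spec"),
            inherits(config, "equilibrium_config"))
  if (!n_init %in% c(0, 1)) abort("`n_init` must be 0 or 1.")
  pars <- .land_pars(model)
  kT <- .rt(config$temperature)
  sample_every <- max(1L, round(config$frame_interval / config$time_step))
  one <- function(i) {
    run <- function() {
      cpp_equilibrate(pars, x_init, as.integer(n_init),
                      restraint$lower, restraint$upper, restraint$force_k,
                      config$time_step, config$duration, sample_every,
                      config$diffusion_coeff, kT)
    }
    res <- if (is.null(config$seed)) run() else
      withr::with_seed(config$seed + i - 1L, run())
    if (res$max_dx > 0.5) {
      warn(sprintf(
        "replica %d unstable: max |dx| per step = %.3f A (> 0.5 A); reduce time_step",
        i, res$max_dx))
    }
    nf <- length(res$x)
    list(
      series = tibble(
        replica = i,
        time = seq_len(nf) * sample_every * config$time_step,
        distance = res$x,
        occupancy = res$n
      ),
      final = tibble(replica = i, distance = res$x_final,
                     occupancy = res$n_final)
    )
  }
  runs <- map(seq_len(config$n_replicas), one)
  out <- list_rbind(map(runs, "series"))
  attr(out, "final_states") <- list_rbind(map(runs, "final"))
  attr(out, "temperature") <- config$temperature
  class(out) <- c("equilibrium_series", class(out))
  out
}

#' Single steered rupture pull
#'
#' Drags the bond coordinate with a stiff harmonic guide moving at constant
#' rate from `start_distance` to `end_distance`, accumulating the external
#' work `dW = k (lambda - x) dlambda` and reporting it on the fixed
#' report grid. If the initial distance is more than 0.1 Angstrom from the
#' pull start, a 1 ns approach stage (guide moved linearly to the start
#' distance) is applied internally first.
#'
#' @param model a [landscape_model()].
#' @param protocol a [pulling_protocol()]. `protocol$seed`, when non-NULL,
#'   seeds this pull directly.
#' @param x_init initial distance, Angstrom.
#' @param n_init initial water occupancy (0 or 1).
#' @param traj_id integer identifier stored with the profile.
#' @param lag_tol stiff-spring tolerance on the time-averaged
#'   guide--particle lag, Angstrom; a larger observed mean lag flags the
#'   profile with a warning.
#' @return A tibble of class `work_profile` with columns `traj_id`,
#'   `distance` (guide position, Angstrom) and `work` (kcal/mol);
#'   `attr(, "mean_lag")` / `attr(, "max_lag")` hold the observed lags
#'   and `attr(, "stiff_spring_ok")` the flag.
#' @export
run_pull <- function(model, protocol = pulling_protocol(),
                     x_init = protocol$start_distance, n_init = 0,
                     traj_id = 1L, lag_tol = 0.2) {
  stopifnot(inherits(model, "landscape_model"),
            inherits(protocol, "pulling_protocol"))
  if (!n_init %in% c(0, 1)) abort("`n_init` must be 0 or 1.")
  pars <- .land_pars(model)
  kT <- .rt(protocol$temperature)
  run <- function() {
    x <- x_init
    n <- as.integer(n_init)
    if (abs(x - protocol$start_distance) > 0.1) {
      appr <- cpp_pull(pars, x, n, x, protocol$start_distance,
                       abs(x - protocol$start_distance) / 1.0,  # 1 ns approach
                       protocol$spring_k, protocol$time_step,
                       protocol$diffusion_coeff, kT, 1, FALSE)
      x <- appr$x_final
      n <- appr$n_final
    }
    cpp_pull(pars, x, n, protocol$start_distance, protocol$end_distance,
             protocol$rate, protocol$spring_k, protocol$time_step,
             protocol$diffusion_coeff, kT, protocol$report_step, TRUE)
  }
  res <- if (is.null(protocol$seed)) run() else
    withr::with_seed(protocol$seed, run())
  if (res$max_dx > 0.5) {
    warn(sprintf("pull unstable: max |dx| per step = %.3f A; reduce time_step",
                 res$max_dx))
  }
  ok <- res$mean_lag <= lag_tol
  if (!ok) {
    warn(sprintf(
      "stiff-spring check failed: mean guide-particle lag %.3f A (tolerance %.2f A)",
      res$mean_lag, lag_tol))
  }
  grid <- seq(protocol$start_distance, protocol$end_distance,
              by = protocol$report_step)
  out <- tibble(traj_id = as.integer(traj_id), distance = grid,
                work = res$work)
  attr(out, "temperature") <- protocol$temperature
  attr(out, "mean_lag") <- res$mean_lag
  attr(out, "max_lag") <- res$max_lag
  attr(out, "stiff_spring_ok") <- ok
  attr(out, "final_state") <- c(distance = res$x_final, occupancy = res$n_final)
  class(out) <- c("work_profile", class(out))
  out
}

#' Ensemble of steered rupture pulls (three-stage protocol)
#'
#' For each of `protocol$n_traj` trajectories: (1) restrained equilibration
#' of `stage1_duration` ns in the flat-bottom window, (2) a 1 ns approach
#' moving the guide to the pull start, (3) the rupture pull recording work
#' on the report grid. Trajectory `i` is seeded with
#' `protocol$seed + i - 1`, making the whole ensemble reproducible.
#'
#' @inheritParams run_pull
#' @param restraint a [restraint_spec()] used in stage 1.
#' @param stage1_duration stage-1 equilibration length per trajectory, ns.
#' @param x_init starting distance for stage 1.
#' @return A tibble of class `work_ensemble` with columns `traj_id`,
#'   `distance`, `work`; attributes `temperature`, `n_traj`,
#'   `stiff_spring_ok` (all-trajectory AND) and `max_lag`.
#' @examples
#' m <- landscape_model(shielding = 1)
#' p <- pulling_protocol(n_traj = 2, report_step = 0.05, seed = 7)
#' w <- generate_work_ensemble(m, p, stage1_duration = 0.02)
#' @export
generate_work_ensemble <- function(model, protocol = pulling_protocol(),
                                   restraint = restraint_spec(),
                                   stage1_duration = 1,
                                   x_init = model$eq_distance,
                                   n_init = 0, lag_tol = 0.2) {
  stopifnot(inherits(model, "landscape_model"),
            inherits(protocol, "pulling_protocol"),
            inherits(restraint, "restraint_spec"))
  pars <- .land_pars(model)
  kT <- .rt(protocol$temperature)
  eq_dt <- 5e-6  # no pulling spring in stage 1: a larger step is stable
  one <- function(i) {
    run <- function() {
      eq <- cpp_equilibrate(pars, x_init, as.integer(n_init),
                            restraint$lower, restraint$upper,
                            restraint$force_k, eq_dt, stage1_duration,
                            .Machine$integer.max, protocol$diffusion_coeff, kT)
      x <- eq$x_final
      n <- eq$n_final
      if (abs(x - protocol$start_distance) > 1e-12) {
        appr <- cpp_pull(pars, x, n, x, protocol$start_distance,
                         max(abs(x - protocol$start_distance), 0.05) / 1.0,
                         protocol$spring_k, protocol$time_step,
                         protocol$diffusion_coeff, kT, 1, FALSE)
        x <- appr$x_final
        n <- appr$n_final
      }
      cpp_pull(pars, x, n, protocol$start_distance, protocol$end_distance,
               protocol$rate, protocol$spring_k, protocol$time_step,
               protocol$diffusion_coeff, kT, protocol$report_step, TRUE)
    }
    if (is.null(protocol$seed)) run() else
      withr::with_seed(protocol$seed + i - 1L, run())
  }
  grid <- seq(protocol$start_distance, protocol$end_distance,
              by = protocol$report_step)
  pulls <- map(seq_len(protocol$n_traj), one)
  max_dx <- max(map_dbl(pulls, "max_dx"))
  if (max_dx > 0.5) {
    warn(sprintf("ensemble unstable: max |dx| per step = %.3f A; reduce time_step",
                 max_dx))
  }
  mean_lag <- max(map_dbl(pulls, "mean_lag"))
  max_lag <- max(map_dbl(pulls, "max_lag"))
  ok <- mean_lag <= lag_tol
  if (!ok) {
    warn(sprintf(
      "stiff-spring check failed: mean guide-particle lag %.3f A (tolerance %.2f A)",
      mean_lag, lag_tol))
  }
  out <- list_rbind(imap(pulls, function(p, i) {
    tibble(traj_id = as.integer(i), distance = grid, work = p$work)
  }))
  attr(out, "temperature") <- protocol$temperature
  attr(out, "n_traj") <- protocol$n_traj
  attr(out, "mean_lag") <- mean_lag
  attr(out, "max_lag") <- max_lag
  attr(out, "stiff_spring_ok") <- ok
  class(out) <- c("work_ensemble", class(out))
  out
}

#' Summary statistics of an equilibrium distance series
#'
#' @param series numeric vector of distances, or an `equilibrium_series`
#'   tibble (its `distance` column is used).
#' @param breaks histogram bin edges, Angstrom (fixed bins so histograms
#'   from different runs are comparable).
#' @return A list of class `distance_stats`: `mean`, `sd`, `n` and
#'   `histogram` (tibble with `lower`, `upper`, `mid`, `count`, `density`).
#' @export
equilibrium_distance_stats <- function(series,
                                       breaks = seq(2, 4.5, by = 0.05)) {
  x <- if (is.data.frame(series)) series$distance else series
  if (length(x) == 0) abort("empty distance series.")
  x_in <- x[x >= min(breaks) & x < max(breaks)]
  counts <- table(cut(x_in, breaks = breaks, right = FALSE))
  widths <- diff(breaks)
  hist <- tibble(
    lower = head(breaks, -1), upper = tail(breaks, -1),
    mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
    count = as.integer(counts),
    density = as.integer(counts) / (length(x) * widths)
  )
  structure(
    list(mean = mean(x), sd = stats::sd(x), n = length(x), histogram = hist),
    class = "distance_stats"
  )
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("<distance_stats> n = %d, mean = %.3f A, sd = %.3f A\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Synthetic solvent frames around a probe atom
#'
#' Emulates solvent-shell coordinate frames: in each frame, solvent
#' particles are placed uniformly in a sphere of radius `box_radius`
#' centred on the probe, then thinned inside `exclusion_radius` with
#' probability `exclusion_prob` (1 = complete exclusion, the shielded
#' interface; 0 = fully exposed).
#'
#' @param n_frames number of frames (>= 1).
#' @param n_solvent solvent particles per frame before thinning.
#' @param box_radius spherical box radius, Angstrom.
#' @param exclusion_radius radius of the exclusion zone, Angstrom
#'   (must not exceed `box_radius`).
#' @param exclusion_prob probability that a particle inside the exclusion
#'   zone is removed, in `[0, 1]`.
#' @param probe probe position, numeric length-3 (Angstrom).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble of class `solvent_frames` with columns `frame`, `role`
#'   ("probe"/"solvent"), `x`, `y`, `z`; box and exclusion parameters are
#'   stored as attributes.
#' @examples
#' fr <- sample_solvent_frames(5, 100, exclusion_prob = 1, seed = 1)
#' @export
sample_solvent_frames <- function(n_frames, n_solvent,
                                  box_radius = 12,
                                  exclusion_radius = 4,
                                  exclusion_prob = 0,
                                  probe = c(0, 0, 0),
                                  seed = NULL) {
  stopifnot(n_frames >= 1, n_solvent >= 0, length(probe) == 3)
  if (exclusion_radius > box_radius) {
    abort("`box_radius` must be at least `exclusion_radius`.")
  }
  if (exclusion_prob < 0 || exclusion_prob > 1) {
    abort("`exclusion_prob` must lie in [0, 1].")
  }
  gen <- function() {
    list_rbind(map(seq_len(n_frames), function(f) {
      # uniform in sphere: r ~ R * U^(1/3), isotropic direction
      r <- box_radius * runif(n_solvent)^(1 / 3)
      z <- runif(n_solvent, -1, 1)
      phi <- runif(n_solvent, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - z^2))
      px <- r * s * cos(phi)
      py <- r * s * sin(phi)
      pz <- r * z
      keep <- r > exclusion_radius | runif(n_solvent) >= exclusion_prob
      bind_rows(
        tibble(frame = f, role = "probe",
               x = probe[1], y = probe[2], z = probe[3]),
        tibble(frame = f, role = "solvent",
               x = probe[1] + px[keep], y = probe[2] + py[keep],
               z = probe[3] + pz[keep])
      )
    }))
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "box_radius") <- box_radius
  attr(out, "exclusion_radius") <- exclusion_radius
  attr(out, "exclusion_prob") <- exclusion_prob
  attr(out, "n_solvent") <- n_solvent
  class(out) <- c("solvent_frames", class(out))
  out
}
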