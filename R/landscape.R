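#' Model hydrogen-bond rupture landscape with water catalysis
#'
#' Defines a one-dimensional free-energy landscape for a donor--acceptor
#' hydrogen bond as a function of the heavy-atom distance `x` (in Angstrom),
#' coupled to a two-state water-occupancy coordinate `n`:
#'
#' \deqn{U(x, n) = U_0(x) - n \, c \, g(x)}
#'
#' `U_0` is an asymmetric Morse-form single well: it is minimised (value
#' `-well_depth`) at `eq_distance`, rises with steepness `steepness` on the
#' dissociation side and with the softer `compression_steepness` on the
#' compressed side, and vanishes at large separation. The water-catalysis
#' weight `g(x)` is a smooth logistic switch centred at `catalysis_center`
#' with width `catalysis_width`: it is ~0 in the bound well and tends to 1
#' once the bond is broken, so an interfacial water (`n = 1`) stabilises
#' stretched and dissociated configurations by up to `catalysis_strength`
#' kcal/mol. This encodes the catalytic role of incoming waters that
#' hydrogen-bond the freed carbonyl acceptor.
#'
#' Water occupancy evolves as a two-state Markov jump process with entry
#' rate `(1 - shielding) * water_entry_rate` and exit rate
#' `water_exit_rate`. `shielding = 1` (a bound molecular glue fully
#' blocking the interface) forbids water entry; `shielding = 0` is the
#' fully exposed binary complex.
#'
#' @param well_depth well depth in kcal/mol (> 0).
#' @param eq_distance equilibrium donor--acceptor distance in Angstrom.
#' @param steepness Morse steepness on the dissociation side, 1/Angstrom.
#' @param compression_steepness Morse steepness on the compressed side,
#'   1/Angstrom. Kept soft so that the conventional 2.5 Angstrom pull start
#'   lies within ~0.25 kcal/mol of the well floor.
#' @param catalysis_strength barrier reduction (kcal/mol) when a water
#'   occupies the interface.
#' @param catalysis_center centre of the catalysis switch, Angstrom.
#' @param catalysis_width width of the catalysis switch, Angstrom.
#' @param shielding dimensionless in `[0, 1]`; 1 = water entry fully blocked.
#' @param water_entry_rate water entry attempt rate at zero shielding, 1/ns.
#' @param water_exit_rate water exit rate, 1/ns.
#'
#' @return An object of class `landscape_model` (a validated named list).
#' @examples
#' m <- landscape_model()
#' evaluate_potential(m, m$eq_distance, n = 0) # equals -well_depth
#' @export
landscape_model <- function(well_depth = 5,
                            eq_distance = 2.9,
                            steepness = 2,
                            compression_steepness = 0.5,
                            catalysis_strength = 3,
                            catalysis_center = 3.2,
                            catalysis_width = 0.15,
                            shielding = 0,
                            water_entry_rate = 5,
                            water_exit_rate = 0.5) {
  stopifnot(
    is.numeric(well_depth), length(well_depth) == 1, well_depth > 0,
    eq_distance > 0, steepness > 0, compression_steepness > 0,
    catalysis_strength >= 0, catalysis_center > 0, catalysis_width > 0,
    water_entry_rate >= 0, water_exit_rate >= 0
  )
  if (!is.numeric(shielding) || shielding < 0 || shielding > 1) {
    abort("`shielding` must lie in [0, 1].")
  }
  structure(
    list(
      well_depth = well_depth, eq_distance = eq_distance,
      steepness = steepness, compression_steepness = compression_steepness,
      catalysis_strength = catalysis_strength,
      catalysis_center = catalysis_center, catalysis_width = catalysis_width,
      shielding = shielding,
      water_entry_rate = water_entry_rate, water_exit_rate = water_exit_rate
    ),
    class = "landscape_model"
  )
}

#' @export
print.landscape_model <- function(x, ...) {
  cat("<landscape_model>\n")
  cat(sprintf("  well: %.2f kcal/mol at %.2f A (steepness %.2f / %.2f 1/A)\n",
              x$well_depth, x$eq_distance, x$steepness, x$compression_steepness))
  cat(sprintf("  water catalysis: %.2f kcal/mol, switch at %.2f A (width %.2f A)\n",
              x$catalysis_strength, x$catalysis_center, x$catalysis_width))
  cat(sprintf("  shielding: %.2f (entry %.2f /ns, exit %.2f /ns)\n",
              x$shielding, x$water_entry_rate, x$water_exit_rate))
  invisible(x)
}

## bare well U0(x): asymmetric Morse form, C1 at the minimum
.u0 <- function(model, x) {
  a <- ifelse(x >= model$eq_distance, model$steepness, model$compression_steepness)
  e <- exp(-a * (x - model$eq_distance))
  model$well_depth * ((1 - e)^2 - 1)
}

## catalysis weight g(x): logistic switch, 0 in the well, -> 1 when broken
.gcat <- function(model, x) {
  1 / (1 + exp(-(x - model$catalysis_center) / model$catalysis_width))
}

#' Evaluate the landscape potential
#'
#' @param model a [landscape_model()].
#' @param x donor--acceptor distance(s), Angstrom (> 0, finite).
#' @param n water occupancy, 0 or 1 (scalar or vector recycled against `x`).
#' @return `U(x, n) = U0(x) - n * catalysis_strength * g(x)` in kcal/mol.
#' @examples
#' m <- landscape_model(catalysis_strength = 2)
#' evaluate_potential(m, 3.2, 1) - evaluate_potential(m, 3.2, 0) # -2 * g(3.2)
#' @export
evaluate_potential <- function(model, x, n = 0) {
  stopifnot(inherits(model, "landscape_model"))
  if (!is.numeric(x) || any(!is.finite(x))) abort("`x` must be finite numeric.")
  if (any(x <= 0)) abort("`x` must be positive.")
  if (!all(n %in% c(0, 1))) abort("occupancy `n` must be 0 or 1.")
  .u0(model, x) - n * model$catalysis_strength * .gcat(model, x)
}

#' Stiff-spring pulling protocol
#'
#' Parameters of the steered pull: the guide centre moves from
#' `start_distance` to `end_distance` at constant `rate`, coupled to the
#' bond coordinate through a harmonic spring of constant `spring_k`.
#' Defaults mirror the conventional H-bond rupture protocol: 2.5 -> 5.0
#' Angstrom at 0.5 Angstrom/ns with a 500 kcal/(mol A^2) spring, work
#' reported every 0.0005 Angstrom, 100 trajectories at 298 K.
#'
#' @param start_distance,end_distance pull window, Angstrom (`end > start`).
#' @param rate guide speed, Angstrom/ns (> 0).
#' @param spring_k guide spring constant, kcal/(mol A^2).
#' @param temperature Kelvin.
#' @param n_traj number of independent pulls.
#' @param report_step work-report grid spacing, Angstrom.
#' @param time_step integrator step, ns. The default keeps
#'   `k_max * D * dt / kT` well below 0.1 for the default landscape.
#' @param diffusion_coeff diffusion coefficient of the bond coordinate,
#'   Angstrom^2/ns.
#' @param seed integer seed for the ensemble (trajectory `i` uses
#'   `seed + i - 1`); `NULL` leaves the RNG state alone.
#' @return An object of class `pulling_protocol`.
#' @export
pulling_protocol <- function(start_distance = 2.5,
                             end_distance = 5.0,
                             rate = 0.5,
                             spring_k = 500,
                             temperature = 298,
                             n_traj = 100,
                             report_step = 0.0005,
                             time_step = 1e-6,
                             diffusion_coeff = 30,
                             seed = NULL) {
  stopifnot(
    end_distance > start_distance, rate > 0, spring_k > 0,
    temperature > 0, n_traj >= 1, report_step > 0, time_step > 0,
    diffusion_coeff > 0
  )
  n_grid <- (end_distance - start_distance) / report_step
  if (abs(n_grid - round(n_grid)) > 1e-8) {
    abort("(end_distance - start_distance) must be a multiple of report_step.")
  }
  structure(
    list(
      start_distance = start_distance, end_distance = end_distance,
      rate = rate, spring_k = spring_k, temperature = temperature,
      n_traj = as.integer(n_traj), report_step = report_step,
      time_step = time_step, diffusion_coeff = diffusion_coeff,
      seed = seed
    ),
    class = "pulling_protocol"
  )
}

#' Flat-bottom distance restraint
#'
#' Zero force inside `[lower, upper]`, harmonic with constant `force_k`
#' outside. The defaults hold a formed hydrogen bond in the 2.5--3.5
#' Angstrom window with 60 kcal/(mol A^2) walls.
#'
#' @param lower,upper window bounds, Angstrom.
#' @param force_k wall force constant, kcal/(mol A^2).
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(lower = 2.5, upper = 3.5, force_k = 60) {
  stopifnot(upper > lower, force_k >= 0)
  structure(list(lower = lower, upper = upper, force_k = force_k),
            class = "restraint_spec")
}

#' Restrained-equilibration configuration
#'
#' Defaults reproduce the study conditions for the restrained equilibration
#' stage: 100 replicas of 10 ns each, frames stored every 0.005 ns with the
#' bond distance and the water occupancy.
#'
#' @param duration length of each replica, ns.
#' @param n_replicas number of independent replicas.
#' @param frame_interval time between stored frames, ns.
#' @param time_step integrator step, ns.
#' @param temperature Kelvin.
#' @param diffusion_coeff diffusion coefficient of the bond coordinate,
#'   Angstrom^2/ns.
#' @param seed integer seed (replica `i` uses `seed + i - 1`); `NULL`
#'   leaves the RNG state alone.
#' @return An object of class `equilibrium_config`.
#' @export
equilibrium_config <- function(duration = 10,
                               n_replicas = 100,
                               frame_interval = 0.005,
                               time_step = 5e-6,
                               temperature = 298,
                               diffusion_coeff = 30,
                               seed = NULL) {
  stopifnot(duration > 0, n_replicas >= 1, frame_interval > 0,
            time_step > 0, temperature > 0, frame_interval >= time_step,
            diffusion_coeff > 0)
  structure(
    list(duration = duration, n_replicas = as.integer(n_replicas),
         frame_interval = frame_interval, time_step = time_step,
         temperature = temperature, diffusion_coeff = diffusion_coeff,
         seed = seed),
    class = "equilibrium_config"
  )
}

## pack model parameters for the C++ engine
.land_pars <- function(model) {
  list(
    D = model$well_depth, x0 = model$eq_distance, a = model$steepness,
    a_rep = model$compression_steepness, c = model$catalysis_strength,
    xc = model$catalysis_center, w = model$catalysis_width,
    k_entry = (1 - model$shielding) * model$water_entry_rate,
    k_exit = model$water_exit_rate
  )
}
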