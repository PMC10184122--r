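#' Run the end-to-end rupture-robustness pipeline
#'
#' Executes, per scenario (a complex with its shielding level and
#' landscape overrides): restrained equilibration, the steered-pull
#' ensemble, Jarzynski PMF with bootstrap errors, and the endpoint value;
#' then aggregates endpoints across scenarios and, when `affinities` are
#' supplied, correlates per-complex totals with binding free energies.
#' Alternatively, a pre-computed per-bond endpoint table
#' (`endpoints_file`, TSV with columns `complex`, `bond`, `pmf`, `sd`)
#' can replace the simulation stage, in which case only the energetics
#' layer runs.
#'
#' Every stochastic stage receives an explicit seed derived from
#' `config$seed` (scenario `i` uses `seed + 1000 * (i - 1)`), so a fixed
#' configuration yields an identical report.
#'
#' @param config a named list (or the result of [read_run_config()])
#'   with entries:
#'   * `seed`: integer master seed (required for simulation scenarios),
#'   * `scenarios`: named list; each element a list of
#'     [landscape_model()] arguments (typically `shielding`),
#'   * `protocol`: optional list of [pulling_protocol()] overrides,
#'   * `stage1_duration`: stage-1 equilibration per trajectory, ns,
#'   * `n_boot`: bootstrap resamples (default 10),
#'   * `reference`: scenario/complex label for relative values,
#'   * `endpoints_file`: optional TSV path replacing simulation,
#'   * `printed_totals_file`: optional TSV (`complex`, `total`, `error`)
#'     cross-checked against recomputed sums,
#'   * `affinities`: optional tibble (`complex`, `dg_bin`).
#' @return An object of class `pipeline_report`: list with `endpoints`
#'   (per-scenario or per-bond tibble), `table` (an `energetics_table`
#'   when per-bond records are available), `correlation` (slope,
#'   intercept, r_squared when affinities are given) and `provenance`
#'   (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  seed <- config$seed
  prov <- list(config_hash = rlang::hash(config), seed = seed,
               version = as.character(utils::packageVersion("glueforce")))
  table <- NULL
  correlation <- NULL

  if (!is.null(config$endpoints_file)) {
    records <- readr::read_tsv(config$endpoints_file, comment = "#",
                               show_col_types = FALSE, progress = FALSE)
    .check_records(records)
    endpoints <- records
  } else {
    if (is.null(config$scenarios) || length(config$scenarios) == 0) {
      abort("config needs `scenarios` or `endpoints_file`.")
    }
    if (is.null(seed)) abort("simulation scenarios need `config$seed`.")
    proto_args <- config$protocol %||% list()
    n_boot <- config$n_boot %||% 10
    run_one <- function(name, i) {
      largs <- config$scenarios[[name]]
      model <- do.call(landscape_model, largs)
      sc_seed <- seed + 1000L * (i - 1L)
      protocol <- do.call(pulling_protocol,
                          c(proto_args, list(seed = sc_seed)))
      works <- generate_work_ensemble(
        model, protocol,
        stage1_duration = config$stage1_duration %||% 1)
      prof <- bootstrap_errors(works, n_boot = n_boot,
                               seed = sc_seed + 500L)
      ep <- endpoint_value(prof, end_distance = protocol$end_distance)
      tibble(complex = name, pmf = ep$pmf, sd = ep$sd,
             n_traj = protocol$n_traj)
    }
    endpoints <- list_rbind(
      map2(names(config$scenarios), seq_along(config$scenarios), run_one))
  }

  if (!is.null(config$reference) && "bond" %in% names(endpoints)) {
    printed <- NULL
    if (!is.null(config$printed_totals_file)) {
      printed <- readr::read_tsv(config$printed_totals_file, comment = "#",
                                 show_col_types = FALSE, progress = FALSE)
    }
    table <- build_energetics_table(endpoints, config$reference,
                                    printed_totals = printed)
  }

  if (!is.null(config$affinities)) {
    totals <- if (!is.null(table)) {
      table$totals[, c("complex", "total")]
    } else if ("bond" %in% names(endpoints)) {
      sum_pmf(endpoints)[, c("complex", "total")]
    } else {
      tibble(complex = endpoints$complex, total = endpoints$pmf)
    }
    corr <- correlate_with_affinity(totals, as_tibble(config$affinities))
    correlation <- list(slope = corr$slope, intercept = corr$intercept,
                        r_squared = corr$r_squared, n = corr$n)
  }

  structure(
    list(endpoints = endpoints, table = table, correlation = correlation,
         provenance = prov),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> config %s, seed %s\n",
              substr(x$provenance$config_hash, 1, 8),
              format(x$provenance$seed)))
  print(as.data.frame(x$endpoints), row.names = FALSE)
  if (!is.null(x$table)) print(x$table)
  if (!is.null(x$correlation)) {
    cat(sprintf("correlation: R^2 = %.3f (n = %d)\n",
                x$correlation$r_squared, x$correlation$n))
  }
  invisible(x)
}
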