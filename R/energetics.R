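#' Sum per-bond rupture free energies into per-complex totals
#'
#' Adds the PMF endpoints of all hydrogen bonds of each complex and
#' propagates the uncertainty by linear addition of the per-bond errors
#' (the convention matching published per-complex totals; use
#' `quadrature = TRUE` for root-sum-square propagation instead).
#'
#' @param records a tibble with columns `complex`, `bond`, `pmf`, `sd`
#'   (kcal/mol; one row per complex/bond pair).
#' @param bonds bond set every complex must provide; defaults to the
#'   union of bonds present. Complexes missing any of them are rejected
#'   by name.
#' @param quadrature propagate errors in quadrature instead of linearly.
#' @return A tibble with one row per complex: `complex`, `total`, `error`.
#' @examples
#' recs <- tibble::tibble(
#'   complex = "wt_LEN", bond = c("W400-N39", "H357-T38", "N351-I37"),
#'   pmf = c(10.9, 6.2, 10.9), sd = c(0.3, 0.3, 0.1))
#' sum_pmf(recs) # 28.0 +- 0.7
#' @export
sum_pmf <- function(records, bonds = NULL, quadrature = FALSE) {
  .check_records(records)
  bonds <- bonds %||% unique(records$bond)
  bad <- records |>
    group_by(.data$complex) |>
    summarise(missing = paste(setdiff(bonds, .data$bond), collapse = ", "),
              .groups = "drop") |>
    filter(.data$missing != "")
  if (nrow(bad) > 0) {
    abort(sprintf("complex(es) with missing bonds: %s.",
                  paste(sprintf("%s (%s)", bad$complex, bad$missing),
                        collapse = "; ")))
  }
  records |>
    filter(.data$bond %in% bonds) |>
    group_by(.data$complex) |>
    summarise(
      total = sum(.data$pmf),
      error = if (quadrature) sqrt(sum(.data$sd^2)) else sum(.data$sd),
      .groups = "drop"
    )
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("complex", "bond", "pmf", "sd")
  if (!all(need %in% names(records))) {
    abort("records need columns complex, bond, pmf, sd.")
  }
  if (any(records$sd < 0)) abort("`sd` must be non-negative.")
  if (anyDuplicated(records[, c("complex", "bond")])) {
    abort("(complex, bond) pairs must be unique.")
  }
  invisible(records)
}

#' Rupture free energies relative to a reference complex
#'
#' Subtracts the reference complex's value bond-by-bond (or total-by-total
#' when no `bond` column is present) and adds the two standard deviations
#' linearly, matching the published convention for relative values.
#'
#' @param records a tibble with columns `complex`, `pmf`, `sd` and
#'   optionally `bond`; for totals use columns `complex`, `total`, `error`.
#' @param reference label of the reference complex (must be present).
#' @return The input rows (reference excluded unless `keep_reference`)
#'   with `delta` and `delta_sd` columns appended.
#' @param keep_reference keep the reference rows (their `delta` is 0).
#' @export
relative_pmf <- function(records, reference, keep_reference = FALSE) {
  stopifnot(is.data.frame(records))
  if ("total" %in% names(records) && !"pmf" %in% names(records)) {
    records <- dplyr::rename(records, pmf = "total", sd = "error")
    totals <- TRUE
  } else {
    totals <- FALSE
  }
  if (!all(c("complex", "pmf", "sd") %in% names(records))) {
    abort("records need columns complex, pmf, sd (or complex, total, error).")
  }
  if (!reference %in% records$complex) {
    abort(sprintf("reference complex '%s' not found.", reference))
  }
  by_bond <- "bond" %in% names(records)
  ref <- records[records$complex == reference, ]
  if (by_bond) {
    missing_b <- setdiff(unique(records$bond), ref$bond)
    if (length(missing_b) > 0) {
      abort(sprintf("reference lacks bond(s): %s.",
                    paste(missing_b, collapse = ", ")))
    }
    refv <- setNames(ref$pmf, ref$bond)
    refs <- setNames(ref$sd, ref$bond)
    out <- mutate(records,
                  delta = .data$pmf - unname(refv[.data$bond]),
                  delta_sd = .data$sd + unname(refs[.data$bond]))
  } else {
    out <- mutate(records,
                  delta = .data$pmf - ref$pmf[1],
                  delta_sd = .data$sd + ref$sd[1])
  }
  if (!keep_reference) out <- filter(out, .data$complex != reference)
  if (totals) out <- dplyr::rename(out, total = "pmf", error = "sd")
  out
}

#' Per-complex energetics table with totals, relative values and flags
#'
#' Builds the summary table of absolute and relative hydrogen-bond
#' rupture free energies: per-bond values with deltas against the
#' reference complex, recomputed per-complex totals with linearly
#' propagated errors, and relative totals. If externally printed totals
#' are supplied, any disagreement at one decimal is flagged (and warned
#' about) but never silently corrected: the recomputed sums are
#' authoritative in the outputs.
#'
#' @inheritParams sum_pmf
#' @param reference label of the reference complex.
#' @param printed_totals optional tibble `complex`, `total`, `error` of
#'   externally printed totals to cross-check against.
#' @return An object of class `energetics_table`: list with `records`
#'   (per-bond tibble with `delta`, `delta_sd`), `totals` (per-complex
#'   tibble with `total`, `error`, `delta`, `delta_sd` and, when
#'   `printed_totals` is given, `printed_total`, `printed_error`,
#'   `mismatch`), `reference`, `bonds`.
#' @export
build_energetics_table <- function(records, reference,
                                   printed_totals = NULL,
                                   quadrature = FALSE) {
  .check_records(records)
  if (!reference %in% records$complex) {
    abort(sprintf("reference complex '%s' not found.", reference))
  }
  bonds <- unique(records$bond)
  recs <- relative_pmf(records, reference, keep_reference = TRUE)
  totals <- sum_pmf(records, bonds = bonds, quadrature = quadrature)
  totals <- relative_pmf(totals, reference, keep_reference = TRUE)
  if (!is.null(printed_totals)) {
    stopifnot(all(c("complex", "total", "error") %in% names(printed_totals)))
    totals <- left_join(
      totals,
      setNames(printed_totals[, c("complex", "total", "error")],
               c("complex", "printed_total", "printed_error")),
      by = "complex")
    totals <- mutate(totals, mismatch = !is.na(.data$printed_total) &
                       (abs(.data$total - .data$printed_total) > 0.05 + 1e-9 |
                          abs(.data$error - .data$printed_error) > 0.05 + 1e-9))
    if (any(totals$mismatch)) {
      warn(sprintf(
        "printed totals differ from recomputed sums for: %s (recomputed values are authoritative).",
        paste(totals$complex[totals$mismatch], collapse = ", ")))
    }
  }
  structure(
    list(records = recs, totals = totals, reference = reference,
         bonds = bonds),
    class = "energetics_table"
  )
}

#' @export
print.energetics_table <- function(x, ...) {
  cat(sprintf("<energetics_table> reference: %s\n", x$reference))
  wide <- pivot_wider(
    mutate(x$records,
           cell = sprintf("%.1f +- %.1f", .data$pmf, .data$sd)),
    id_cols = "bond", names_from = "complex", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  cat("totals:\n")
  tot <- mutate(x$totals,
                cell = sprintf("%.1f +- %.1f", .data$total, .data$error))
  print(as.data.frame(tot[, c("complex", "cell")]), row.names = FALSE)
  if ("mismatch" %in% names(x$totals) && any(x$totals$mismatch)) {
    cat(sprintf("flagged printed-total mismatches: %s\n",
                paste(x$totals$complex[x$totals$mismatch], collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn build_energetics_table tidy long-format view: one row per
#'   complex/bond plus per-complex `(all)` total rows.
#' @param x an `energetics_table`.
#' @param ... unused.
#' @export
tidy.energetics_table <- function(x, ...) {
  bind_rows(
    mutate(x$records[, c("complex", "bond", "pmf", "sd", "delta", "delta_sd")],
           quantity = "bond"),
    mutate(
      dplyr::rename(x$totals[, c("complex", "total", "error", "delta",
                                 "delta_sd")],
                    pmf = "total", sd = "error"),
      bond = "(all)", quantity = "total")
  )
}

#' Correlate per-complex rupture totals with binding free energies
#'
#' Ordinary least-squares regression of the binding free energy on the
#' summed rupture free energy across complexes, with the squared Pearson
#' correlation as the headline statistic.
#'
#' @param totals tibble with columns `complex` and `total` (kcal/mol),
#'   e.g. from [sum_pmf()].
#' @param affinities tibble with columns `complex` and `dg_bin`
#'   (kcal/mol). Labels must pair up exactly with `totals`.
#' @return An object of class `affinity_correlation`: list with `data`,
#'   `slope`, `intercept`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
correlate_with_affinity <- function(totals, affinities) {
  stopifnot(is.data.frame(totals), is.data.frame(affinities),
            all(c("complex", "total") %in% names(totals)),
            all(c("complex", "dg_bin") %in% names(affinities)))
  un_a <- setdiff(totals$complex, affinities$complex)
  un_b <- setdiff(affinities$complex, totals$complex)
  if (length(un_a) > 0 || length(un_b) > 0) {
    abort(sprintf("unpaired complex labels: %s.",
                  paste(c(un_a, un_b), collapse = ", ")))
  }
  data <- inner_join(totals[, c("complex", "total")],
                     affinities[, c("complex", "dg_bin")], by = "complex")
  if (nrow(data) < 3) abort("need at least 3 paired points.")
  fit <- stats::lm(dg_bin ~ total, data = data)
  # collinear input is legitimate; silence lm's perfect-fit notice
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(data = data,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2,
         n = nrow(data),
         fit = fit),
    class = "affinity_correlation"
  )
}

#' @export
print.affinity_correlation <- function(x, ...) {
  cat(sprintf(
    "<affinity_correlation> n = %d, R^2 = %.3f, dG_bin = %.3f x SumPMF + %.3f\n",
    x$n, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' @describeIn correlate_with_affinity coefficient-level summary.
#' @param x an `affinity_correlation`.
#' @param ... unused.
#' @export
tidy.affinity_correlation <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @describeIn correlate_with_affinity one-row model summary
#'   (`r.squared`, `slope`, `intercept`, `n`).
#' @export
glance.affinity_correlation <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, n = x$n)
}
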