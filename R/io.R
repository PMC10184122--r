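## header comment written at the top of every output file: provenance
## (package version, config hash, seed) without timestamps so identical
## runs give byte-identical files
.provenance_header <- function(seed = NULL, pars = NULL) {
  c(sprintf("# glueforce %s",
            as.character(utils::packageVersion("glueforce"))),
    sprintf("# config_hash: %s", rlang::hash(pars)),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)))
}

#' Write a work-profile ensemble to TSV
#'
#' Columns `traj_id`, `distance_angstrom`, `work_kcal_mol`, preceded by
#' `#` provenance comment lines (package version, config hash, seed).
#' Values are stored at 6 decimals, the round-trip precision of the
#' reader. `grid_step` optionally coarsens the report grid to keep files
#' compact.
#'
#' @param set a `work_ensemble` tibble (columns `traj_id`, `distance`,
#'   `work`).
#' @param path output file path.
#' @param grid_step optional coarser grid spacing, Angstrom (must be a
#'   multiple of the stored spacing).
#' @param seed seed recorded in the header (provenance only).
#' @return `path`, invisibly.
#' @export
write_work_profiles <- function(set, path, grid_step = NULL, seed = NULL) {
  stopifnot(is.data.frame(set),
            all(c("traj_id", "distance", "work") %in% names(set)))
  if (!is.null(grid_step)) {
    d0 <- min(set$distance)
    keep <- abs((set$distance - d0) / grid_step -
                  round((set$distance - d0) / grid_step)) < 1e-9
    set <- set[keep, ]
  }
  out <- tibble(
    traj_id = set$traj_id,
    distance_angstrom = round(set$distance, 6),
    work_kcal_mol = round(set$work, 6)
  )
  writeLines(.provenance_header(seed, list(n = dplyr::n_distinct(set$traj_id),
                                           grid_step = grid_step)), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a work-profile ensemble from TSV
#'
#' Expects a header line `traj_id  distance_angstrom  work_kcal_mol`;
#' `#` comment lines and trailing blank lines are tolerated. Each
#' trajectory's distances must be strictly increasing and all
#' trajectories must share one grid.
#'
#' @param path input file path.
#' @param temperature Kelvin attached to the returned ensemble.
#' @return A `work_ensemble` tibble (columns `traj_id`, `distance`,
#'   `work`).
#' @export
read_work_profiles <- function(path, temperature = 298) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("traj_id", "distance_angstrom", "work_kcal_mol")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("missing column(s) in %s: %s.", path,
                  paste(miss, collapse = ", ")))
  }
  out <- tibble(traj_id = as.integer(raw$traj_id),
                distance = raw$distance_angstrom,
                work = raw$work_kcal_mol)
  out <- out[!is.na(out$traj_id), ]
  for (id in unique(out$traj_id)) {
    d <- out$distance[out$traj_id == id]
    if (is.unsorted(d, strictly = TRUE)) {
      abort(sprintf("non-monotone distance grid in trajectory %d.", id))
    }
  }
  grids <- split(out$distance, out$traj_id)
  ref <- grids[[1]]
  same <- vapply(grids, function(g) {
    length(g) == length(ref) && max(abs(g - ref)) < 1e-9
  }, logical(1))
  if (!all(same)) {
    abort(sprintf("mixed distance grids across trajectories (e.g. trajectory %s).",
                  names(grids)[which(!same)[1]]))
  }
  attr(out, "temperature") <- temperature
  attr(out, "n_traj") <- length(grids)
  class(out) <- c("work_ensemble", class(out))
  out
}

#' Write a PMF profile to TSV
#'
#' Columns `distance_angstrom`, `pmf_kcal_mol` and (when present)
#' `sd_kcal_mol`, with `#` provenance comment lines.
#'
#' @param profile a `pmf_profile` tibble.
#' @param path output file path.
#' @param seed seed recorded in the header (provenance only).
#' @return `path`, invisibly.
#' @export
write_pmf_profile <- function(profile, path, seed = NULL) {
  stopifnot(is.data.frame(profile),
            all(c("distance", "pmf") %in% names(profile)))
  out <- tibble(distance_angstrom = round(profile$distance, 6),
                pmf_kcal_mol = round(profile$pmf, 6))
  if ("sd" %in% names(profile)) out$sd_kcal_mol <- round(profile$sd, 6)
  writeLines(.provenance_header(seed, list(n = nrow(out))), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write solvent frames as plain multi-frame XYZ
#'
#' Standard XYZ layout per frame: an atom-count line, a comment line
#' (carrying the frame index and box/exclusion parameters), then one
#' `element x y z` line per atom, the probe first (element `P`), solvent
#' oxygens after (element `O`).
#'
#' @param frames a `solvent_frames` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(frames, path) {
  stopifnot(is.data.frame(frames),
            all(c("frame", "role", "x", "y", "z") %in% names(frames)))
  box <- attr(frames, "box_radius") %||% NA
  exr <- attr(frames, "exclusion_radius") %||% NA
  exp_ <- attr(frames, "exclusion_prob") %||% NA
  con <- file(path, "w")
  on.exit(close(con))
  for (f in unique(frames$frame)) {
    sub <- frames[frames$frame == f, ]
    sub <- sub[order(sub$role != "probe"), ]  # probe first
    writeLines(as.character(nrow(sub)), con)
    writeLines(sprintf(
      "frame=%d box_radius=%s exclusion_radius=%s exclusion_prob=%s",
      f, format(box), format(exr), format(exp_)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f",
                       ifelse(sub$role == "probe", "P", "O"),
                       sub$x, sub$y, sub$z), con)
  }
  invisible(path)
}

#' Read solvent frames from plain multi-frame XYZ
#'
#' Inverse of [write_xyz_frames()]: the first atom of each frame is the
#' probe, the rest are solvent. Box and exclusion parameters are
#' recovered from the comment line when present.
#'
#' @param path input file path.
#' @return A `solvent_frames` tibble.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > max(which(nzchar(lines)), 0))]
  i <- 1
  frames <- list()
  meta <- c(box_radius = NA_real_, exclusion_radius = NA_real_,
            exclusion_prob = NA_real_)
  fidx <- 0
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) abort(sprintf("malformed XYZ atom count at line %d.", i))
    comment <- lines[i + 1]
    fidx <- fidx + 1
    for (key in names(meta)) {
      m <- regmatches(comment,
                      regexpr(sprintf("%s=[^ ]+", key), comment))
      if (length(m) == 1) {
        meta[key] <- suppressWarnings(as.numeric(sub(".*=", "", m)))
      }
    }
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4)) {
      abort(sprintf("malformed XYZ atom line in frame %d.", fidx))
    }
    frames[[fidx]] <- tibble(
      frame = fidx,
      role = c("probe", rep("solvent", nat - 1)),
      x = as.numeric(vapply(parts, `[`, "", 2)),
      y = as.numeric(vapply(parts, `[`, "", 3)),
      z = as.numeric(vapply(parts, `[`, "", 4))
    )
    i <- i + 2 + nat
  }
  out <- list_rbind(frames)
  attr(out, "box_radius") <- meta[["box_radius"]]
  attr(out, "exclusion_radius") <- meta[["exclusion_radius"]]
  attr(out, "exclusion_prob") <- meta[["exclusion_prob"]]
  class(out) <- c("solvent_frames", class(out))
  out
}

#' Write a flat key = value configuration file
#'
#' Nested lists are flattened with dotted keys
#' (`scenario.wt_LEN.shielding = 1`); [read_run_config()] reverses the
#' flattening, so configurations round-trip losslessly.
#'
#' @param config a (possibly nested) named list of scalar values.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  flatten <- function(x, prefix = "") {
    out <- character(0)
    for (k in names(x)) {
      key <- if (prefix == "") k else paste0(prefix, ".", k)
      v <- x[[k]]
      if (is.list(v)) {
        out <- c(out, flatten(v, key))
      } else {
        out <- c(out, setNames(
          format(v, digits = 15, scientific = TRUE, trim = TRUE), key))
      }
    }
    out
  }
  kv <- flatten(config)
  writeLines(sprintf("%s = %s", names(kv), unname(kv)), path)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' @param path input file path.
#' @return A nested named list; values are converted to numeric where
#'   possible, with `TRUE`/`FALSE` recognised as logical.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) abort(sprintf("malformed config line: '%s'.", ln))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
    path_keys <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- .assign_nested(out, path_keys, parsed)
  }
  out
}

.assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  sub <- lst[[keys[1]]] %||% list()
  lst[[keys[1]]] <- .assign_nested(sub, keys[-1], value)
  lst
}
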