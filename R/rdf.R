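#' Water radial distribution function around a probe atom
#'
#' Histograms probe--solvent distances into half-open bins `[r, r + dr)`
#' and normalises each bin by the frame-average bulk density times the
#' exact spherical-shell volume `4/3 pi ((r+dr)^3 - r^3)`, averaging over
#' frames. Bulk density follows the frame's own box convention:
#' (mean solvent particles per frame) / (spherical box volume), so a
#' uniform ideal-gas generator yields `g = 1` by construction.
#'
#' @param frames a `solvent_frames` tibble (see [sample_solvent_frames()]
#'   or [read_xyz_frames()]): columns `frame`, `role`, `x`, `y`, `z` with
#'   one "probe" row per frame.
#' @param r_max histogram range, Angstrom; `r_max / bin_width` must be
#'   integral.
#' @param bin_width bin spacing, Angstrom.
#' @param box_radius spherical box radius used for the bulk density;
#'   defaults to the `box_radius` attribute of `frames`.
#' @return A tibble of class `rdf_profile` with columns `r` (bin centre,
#'   Angstrom) and `g`; attributes `bin_width`, `n_frames`.
#' @examples
#' fr <- sample_solvent_frames(20, 500, seed = 1)
#' rdf <- compute_rdf(fr)
#' @export
compute_rdf <- function(frames, r_max = 10, bin_width = 0.1,
                        box_radius = NULL) {
  stopifnot(is.data.frame(frames),
            all(c("frame", "role", "x", "y", "z") %in% names(frames)))
  nbin <- r_max / bin_width
  if (abs(nbin - round(nbin)) > 1e-9) {
    abort("`r_max / bin_width` must be integral.")
  }
  nbin <- as.integer(round(nbin))
  box_radius <- box_radius %||% attr(frames, "box_radius")
  if (is.null(box_radius)) {
    abort("`box_radius` is needed (argument or attribute) for the bulk density.")
  }
  probes <- frames[frames$role == "probe", ]
  solv <- frames[frames$role == "solvent", ]
  frame_ids <- unique(frames$frame)
  n_frames <- length(frame_ids)
  if (nrow(probes) != n_frames) {
    abort("every frame needs exactly one probe row.")
  }
  if (nrow(solv) == 0) {
    warn("no solvent particles: returning an all-zero RDF.")
    out <- tibble(r = (seq_len(nbin) - 0.5) * bin_width, g = 0)
  } else {
    solv <- left_join(solv,
                      setNames(probes[, c("frame", "x", "y", "z")],
                               c("frame", "px", "py", "pz")),
                      by = "frame")
    d <- sqrt((solv$x - solv$px)^2 + (solv$y - solv$py)^2 +
                (solv$z - solv$pz)^2)
    idx <- floor(d / bin_width) + 1  # half-open [r, r + dr)
    idx <- idx[idx >= 1 & idx <= nbin]
    counts <- tabulate(idx, nbins = nbin)
    rho <- (nrow(solv) / n_frames) / (4 / 3 * pi * box_radius^3)
    edges <- (0:nbin) * bin_width
    shell_vol <- 4 / 3 * pi * diff(edges^3)
    out <- tibble(
      r = (head(edges, -1) + tail(edges, -1)) / 2,
      g = counts / (n_frames * rho * shell_vol)
    )
  }
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- n_frames
  class(out) <- c("rdf_profile", class(out))
  out
}

#' Near-probe shielding contrast between two RDF profiles
#'
#' Difference of the mean `g` over bins whose centres lie below `r_cut`
#' (default 5 Angstrom, the region where shielded interfaces drop to
#' zero): `mean(g_a) - mean(g_b)`. Negative values mean profile `a` is
#' the more water-depleted (shielded) one.
#'
#' @param rdf_a,rdf_b `rdf_profile` tibbles on identical binning.
#' @param r_cut upper radius of the comparison window, Angstrom.
#' @return A scalar contrast (dimensionless).
#' @export
shielding_contrast <- function(rdf_a, rdf_b, r_cut = 5) {
  stopifnot(is.data.frame(rdf_a), is.data.frame(rdf_b))
  if (nrow(rdf_a) != nrow(rdf_b) ||
      max(abs(rdf_a$r - rdf_b$r)) > 1e-9) {
    abort("RDF profiles must share identical binning.")
  }
  sel <- rdf_a$r < r_cut
  if (!any(sel)) abort("no bins below `r_cut`.")
  mean(rdf_a$g[sel]) - mean(rdf_b$g[sel])
}

#' Pairwise co-dependence of bond-distance series
#'
#' Pearson correlation matrix of named distance series sharing one time
#' base; used to check that the rupture fluctuations of different
#' hydrogen bonds are uncoupled before summing their rupture free
#' energies. A constant series has no defined correlation; its entries
#' are reported as 0 and flagged.
#'
#' @param set a data frame whose numeric columns are the per-bond series
#'   (a `time` column, if present, is ignored), or a named list of
#'   equal-length numeric vectors.
#' @return A symmetric correlation matrix with unit diagonal; attribute
#'   `flagged` names any constant series.
#' @export
codependence_matrix <- function(set) {
  if (is.data.frame(set)) {
    set <- set[, setdiff(names(set), c("time", "frame")), drop = FALSE]
    cols <- as.list(set)
  } else {
    cols <- set
  }
  if (length(cols) < 2) abort("need at least two series.")
  if (is.null(names(cols)) || any(names(cols) == "") ||
      anyDuplicated(names(cols))) {
    abort("series must carry unique names.")
  }
  len <- unique(lengths(cols))
  if (length(len) != 1) abort("series must share one time base (equal lengths).")
  m <- do.call(cbind, cols)
  const <- apply(m, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  cm <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    warn(sprintf("constant series (%s): correlation undefined, reported as 0.",
                 paste(names(cols)[const], collapse = ", ")))
    cm[const, ] <- 0
    cm[, const] <- 0
  }
  diag(cm) <- 1
  attr(cm, "flagged") <- names(cols)[const]
  cm
}

#' Centre-of-mass distance series between two atom groups
#'
#' Per-frame Euclidean distance between the (optionally mass-weighted)
#' centroids of two atom groups, e.g. a ligand's centre of mass and a
#' residue's alpha carbon.
#'
#' @param frames a tibble with columns `frame`, `x`, `y`, `z`; atoms are
#'   indexed by their row order within each frame.
#' @param group_a,group_b integer atom indices (non-empty, within range).
#' @param weights_a,weights_b optional per-atom masses for weighted
#'   centroids (default: unweighted).
#' @return A tibble of class `com_distance` with columns `frame` and
#'   `distance` (Angstrom); `attr(, "mean_distance")` holds the average.
#' @export
com_distance_series <- function(frames, group_a, group_b,
                                weights_a = NULL, weights_b = NULL) {
  stopifnot(is.data.frame(frames),
            all(c("frame", "x", "y", "z") %in% names(frames)))
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("atom groups must be non-empty.")
  }
  centroid <- function(sub, idx, wts) {
    if (any(idx < 1) || any(idx > nrow(sub))) {
      abort("atom index out of range for a frame.")
    }
    w <- wts %||% rep(1, length(idx))
    c(sum(sub$x[idx] * w), sum(sub$y[idx] * w), sum(sub$z[idx] * w)) / sum(w)
  }
  out <- list_rbind(map(split(frames, frames$frame), function(sub) {
    ca <- centroid(sub, group_a, weights_a)
    cb <- centroid(sub, group_b, weights_b)
    tibble(frame = sub$frame[1], distance = sqrt(sum((ca - cb)^2)))
  }))
  out <- arrange(out, .data$frame)
  attr(out, "mean_distance") <- mean(out$distance)
  class(out) <- c("com_distance", class(out))
  out
}
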