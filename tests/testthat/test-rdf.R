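test_that("uniform ideal-gas frames give g near 1 away from the origin", {
  fr <- sample_solvent_frames(200, 2000, box_radius = 12, seed = 2)
  rdf <- compute_rdf(fr)
  band <- rdf$g[rdf$r > 2 & rdf$r < 8]
  expect_equal(mean(band), 1, tolerance = 0.02)
  # per-bin scatter stays within Poisson counting noise (4 sigma at the
  # sparsest bin of the band)
  rho <- 2000 / (4 / 3 * pi * 12^3)
  min_count <- 200 * rho * 4 / 3 * pi * (2.1^3 - 2.0^3)
  expect_lt(max(abs(band - 1)), 4 / sqrt(min_count))
})

test_that("full exclusion zeroes the RDF below the exclusion radius exactly", {
  fr <- sample_solvent_frames(50, 500, box_radius = 12,
                              exclusion_radius = 5, exclusion_prob = 1,
                              seed = 3)
  rdf <- compute_rdf(fr)
  expect_true(all(rdf$g[rdf$r < 5] == 0))
  expect_gt(mean(rdf$g[rdf$r > 6 & rdf$r < 9]), 0.9)
})

test_that("a single particle lands in its bin with the shell-volume weight", {
  R <- 10
  fr <- tibble::tibble(frame = 1L, role = c("probe", "solvent"),
                       x = c(0, 3.05), y = c(0, 0), z = c(0, 0))
  rdf <- compute_rdf(fr, box_radius = R)
  rho <- 1 / (4 / 3 * pi * R^3)
  v_shell <- 4 / 3 * pi * (3.1^3 - 3.0^3)
  hit <- rdf$g[abs(rdf$r - 3.05) < 1e-9]
  expect_equal(hit, 1 / (rho * v_shell))
  expect_equal(sum(rdf$g > 0), 1)
})

test_that("the RDF is invariant under rigid translation of every frame", {
  fr <- sample_solvent_frames(20, 300, seed = 5)
  shifted <- dplyr::mutate(fr, x = x + 100, y = y - 50, z = z + 7)
  attr(shifted, "box_radius") <- attr(fr, "box_radius")
  expect_equal(compute_rdf(fr)$g, compute_rdf(shifted)$g)
})

test_that("stronger exclusion never raises the near-probe RDF", {
  rdf_at <- function(p) {
    compute_rdf(sample_solvent_frames(100, 800, exclusion_radius = 4,
                                      exclusion_prob = p, seed = 6))
  }
  g0 <- rdf_at(0); g5 <- rdf_at(0.5); g1 <- rdf_at(1)
  inside <- g0$r < 4
  # 3-sigma allowance from the expected per-bin uniform counts
  rho <- 800 / (4 / 3 * pi * 12^3)
  edges <- seq(0, 10, by = 0.1)
  counts <- 100 * rho * 4 / 3 * pi * diff(edges^3)
  expect_true(all(g5$g[inside] <= g0$g[inside] +
                    3 / sqrt(pmax(counts[inside], 1))))
  expect_true(all(g1$g[inside] == 0))
})

test_that("shielding contrast compares mean near-probe densities", {
  uni <- compute_rdf(sample_solvent_frames(100, 800, seed = 8))
  excl <- compute_rdf(sample_solvent_frames(100, 800, exclusion_radius = 5,
                                            exclusion_prob = 1, seed = 8))
  expect_equal(shielding_contrast(uni, uni), 0)
  expect_equal(shielding_contrast(excl, uni, r_cut = 5), -1,
               tolerance = 0.08)
  expect_equal(shielding_contrast(uni, excl, r_cut = 5),
               -shielding_contrast(excl, uni, r_cut = 5))
  other <- compute_rdf(sample_solvent_frames(5, 50, seed = 1),
                       bin_width = 0.2)
  expect_error(shielding_contrast(uni, other), "binning")
})

test_that("co-dependence matrix: duplicates, independence, hand oracle, flags", {
  x <- withr::with_seed(9, rnorm(10000))
  dup <- tibble::tibble(a = x, b = x)
  cm <- codependence_matrix(dup)
  expect_equal(cm["a", "b"], 1)
  expect_equal(diag(cm), c(a = 1, b = 1))

  ind <- withr::with_seed(10, tibble::tibble(a = rnorm(10000),
                                             b = rnorm(10000),
                                             c = rnorm(10000)))
  cmi <- codependence_matrix(ind)
  expect_lt(max(abs(cmi[upper.tri(cmi)])), 0.05)

  # 5-point toy series against the explicit covariance formula
  a <- c(1, 2, 4, 3, 5); b <- c(2, 1, 3, 5, 4)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cm2 <- codependence_matrix(tibble::tibble(a = a, b = b))
  expect_equal(cm2["a", "b"], r_hand)

  const <- tibble::tibble(a = c(1, 2, 3), b = c(2, 2, 2))
  expect_warning(cmc <- codependence_matrix(const), "constant")
  expect_equal(cmc["a", "b"], 0)
  expect_equal(attr(cmc, "flagged"), "b")
  expect_error(codependence_matrix(tibble::tibble(a = 1:3)), "at least two")
})

test_that("centre-of-mass distances: identity, 3-4-5 triangle, centroid oracle", {
  fr <- tibble::tibble(
    frame = rep(1:2, each = 3),
    x = c(0, 3, 1, 0, 3, 2), y = c(0, 4, 1, 0, 4, 2), z = c(0, 0, 1, 0, 0, 2))
  same <- com_distance_series(fr, group_a = 1:2, group_b = 1:2)
  expect_true(all(same$distance == 0))

  tri <- com_distance_series(fr, group_a = 1, group_b = 2)
  expect_equal(tri$distance, c(5, 5))

  # two-point centroid against direct averaging
  pair <- com_distance_series(fr, group_a = c(1, 3), group_b = 2)
  cen1 <- c(mean(c(0, 1)), mean(c(0, 1)), mean(c(0, 1)))
  expect_equal(pair$distance[1],
               sqrt(sum((cen1 - c(3, 4, 0))^2)))
  expect_equal(attr(pair, "mean_distance"), mean(pair$distance))
  expect_error(com_distance_series(fr, group_a = 1, group_b = 9),
               "out of range")
})
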