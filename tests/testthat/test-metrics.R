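test_that("an empty image yields all-zero metrics with zero-valued averages", {
  m <- suppressMessages(compute_metrics(sbp_image(matrix(0L, 64, 64))))
  for (f in c("component_pixels", "component_ratio_pct", "n_components",
              "homogeneity", "skeleton_pixels", "single_nerve_fibres",
              "fibres_per_component", "total_fibre_length_um",
              "avg_single_fibre_length_um", "fibre_density_um_per_um2",
              "n_branches", "n_connectivity_points", "n_endpoints"))
    expect_equal(m[[f]], 0)
})

test_that("a single full-width fibre reproduces the hand-computed metric vector", {
  m <- matrix(0L, 384, 384); m[200, ] <- 1L
  met <- compute_metrics(sbp_image(m))
  expect_equal(met$single_nerve_fibres, 1)
  expect_equal(met$n_branches, 0)
  expect_equal(met$n_connectivity_points, 2)
  expect_equal(met$n_endpoints, 0)
  expect_equal(met$total_fibre_length_um, 383 * 400 / 384, tolerance = 1e-12)
  expect_equal(met$total_fibre_length_um, 398.96, tolerance = 1e-4)
  expect_equal(met$fibre_density_um_per_um2,
               met$total_fibre_length_um / 160000, tolerance = 1e-12)
  expect_equal(round(met$fibre_density_um_per_um2, 4), 0.0025)
})

test_that("density identity holds for every processed phantom", {
  for (ph in make_phantoms(41:44, size = 192)) {
    met <- compute_metrics(ph$image)
    area_um2 <- met$image_area_mm2 * 1e6
    expect_equal(met$fibre_density_um_per_um2 * area_um2,
                 met$total_fibre_length_um,
                 tolerance = 1e-6 * max(1, met$total_fibre_length_um))
    norm <- normalize_metrics(met)
    expect_equal(norm$fibre_density_um_per_um2, met$fibre_density_um_per_um2)
    # normalised total length / 1e6 um^2-per-mm^2 recovers the density
    expect_equal(norm$total_fibre_length_um / 1e6,
                 met$fibre_density_um_per_um2, tolerance = 1e-12)
  }
})

test_that("normalisation scales extensive fields by the area and guards re-entry", {
  m <- matrix(0L, 384, 384); m[100, ] <- 1L; m[250, ] <- 1L
  met <- compute_metrics(sbp_image(m))
  norm <- normalize_metrics(met)
  expect_equal(norm$total_fibre_length_um, met$total_fibre_length_um / 0.16)
  expect_equal(norm$component_pixels, met$component_pixels * 6.25)
  expect_equal(norm$n_branches, met$n_branches * 6.25)
  # intensive fields unchanged
  expect_equal(norm$component_ratio_pct, met$component_ratio_pct)
  expect_equal(norm$homogeneity, met$homogeneity)
  expect_equal(norm$avg_single_fibre_length_um, met$avg_single_fibre_length_um)
  expect_equal(norm$fibres_per_component, met$fibres_per_component)
  expect_error(normalize_metrics(norm), "already")
  # a 3193.8 um per-image total maps to 19961 um per mm^2 on a 0.16 mm^2 field
  expect_equal(3193.8 / 0.16, 19961.25)
})

test_that("deleting a fibre decreases the extensive measurements", {
  sp <- phantom_spec(n_fibres = 3, branch_prob = 0, seed = 51,
                     width_px = 192, height_px = 192)
  full <- generate_phantom(sp)
  lab <- label_components(full$image)
  expect_gte(lab$n_components, 2)
  reduced <- full$image$mask
  reduced[lab$labels == 1L] <- 0L
  m_full <- compute_metrics(full$image)
  m_red <- compute_metrics(sbp_image(reduced, full$image$pixel_pitch_um))
  expect_lt(m_red$component_pixels, m_full$component_pixels)
  expect_lt(m_red$skeleton_pixels, m_full$skeleton_pixels)
  expect_lt(m_red$total_fibre_length_um, m_full$total_fibre_length_um)
  expect_lte(m_red$single_nerve_fibres, m_full$single_nerve_fibres)
})

test_that("metrics CSV round-trips and rejects mixed normalisation", {
  m <- matrix(0L, 96, 96); m[50, 10:90] <- 1L
  met <- compute_metrics(sbp_image(m))
  rows <- list(list(subject_id = "s1", group = "control", metrics = met),
               list(subject_id = "s2", group = "diabetic", metrics = met))
  p <- file.path(tempdir(), "metrics.csv")
  write_metrics_csv(rows, p)
  back <- read_metrics_csv(p)
  expect_equal(nrow(back), 2)
  expect_equal(back$subject_id, c("s1", "s2"))
  expect_equal(back$total_fibre_length_um,
               rep(met$total_fibre_length_um, 2), tolerance = 1e-9)

  # header-only CSV for an empty list
  write_metrics_csv(list(), p)
  expect_equal(nrow(read_metrics_csv(p)), 0)

  rows_mixed <- list(rows[[1]],
                     list(subject_id = "s3", group = "diabetic",
                          metrics = normalize_metrics(met)))
  expect_error(write_metrics_csv(rows_mixed, p), "mixed")
  unlink(p)
})
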