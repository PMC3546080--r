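test_that("component labeling follows 8-connectivity with deterministic order", {
  # two horizontal lines separated by background
  m <- matrix(0L, 10, 20)
  m[3, 4:13] <- 1L
  m[6, 4:13] <- 1L
  lab <- label_components(sbp_image(m))
  expect_equal(lab$n_components, 2)
  expect_equal(unique(lab$labels[3, 4:13]), 1L)  # first in raster order
  expect_equal(unique(lab$labels[6, 4:13]), 2L)

  # diagonal touch is one component
  m2 <- matrix(0L, 5, 5); m2[2, 2] <- 1L; m2[3, 3] <- 1L
  expect_equal(label_components(sbp_image(m2))$n_components, 1)

  # empty mask
  expect_equal(label_components(sbp_image(matrix(0L, 5, 5)))$n_components, 0)
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.1, 0.6)), 32, 32)
    lab <- label_components(sbp_image(m))
    expect_equal(lab$n_components, oracle_n_components(m))
    # per-component pixel counts conserve the foreground total
    expect_equal(sum(tabulate(lab$labels[lab$labels > 0])), sum(m))
    # labels cover exactly the foreground
    expect_true(all((lab$labels > 0) == (m == 1)))
  }
})

test_that("component pixel count and ratio match direct summation", {
  expect_equal(component_pixels(sbp_image(matrix(0L, 10, 10))), 0)
  full <- sbp_image(matrix(1L, 384, 384))
  expect_equal(component_pixels(full), 147456)
  expect_equal(component_ratio(full), 100)
  set.seed(5)
  m <- matrix(rbinom(50 * 50, 1, 0.2), 50, 50)
  img <- sbp_image(m)
  expect_equal(component_pixels(img), sum(m))
  expect_equal(component_ratio(img), 100 * sum(m) / 2500)
  # 8465 foreground px on 384x384 -> 5.74 %
  m2 <- matrix(0L, 384, 384); m2[seq_len(8465)] <- 1L
  expect_equal(component_ratio(sbp_image(m2)), 100 * 8465 / 147456)
  expect_equal(round(component_ratio(sbp_image(m2)), 2), 5.74)
})

test_that("component ratio is invariant under rotation and mirroring", {
  set.seed(9)
  m <- matrix(rbinom(40 * 40, 1, 0.25), 40, 40)
  r0 <- component_ratio(sbp_image(m))
  expect_equal(component_ratio(sbp_image(rot90(m))), r0)
  expect_equal(component_ratio(sbp_image(m[, 40:1])), r0)
  expect_equal(component_ratio(sbp_image(m[40:1, ])), r0)
})

test_that("homogeneity is zero for uniform masks and has the closed form for one busy tile", {
  expect_equal(homogeneity(sbp_image(matrix(1L, 40, 40))), 0)
  expect_equal(homogeneity(sbp_image(matrix(0L, 40, 40))), 0)
  # all foreground in exactly one of k^2 tiles -> variance (k^2-1)/k^4
  for (k in c(2L, 4L, 8L)) {
    n <- 8 * k
    m <- matrix(0L, n, n)
    m[1:(n %/% k), 1:(n %/% k)] <- 1L
    expect_equal(homogeneity(sbp_image(m), k), (k^2 - 1) / k^4,
                 tolerance = 1e-12)
  }
})

test_that("homogeneity increases as a fixed pixel budget concentrates and matches the naive variance", {
  set.seed(33)
  m <- matrix(rbinom(64 * 64, 1, 0.15), 64, 64)
  expect_equal(homogeneity(sbp_image(m), 8), oracle_homogeneity(m, 8))
  expect_equal(homogeneity(sbp_image(m), 4), oracle_homogeneity(m, 4))
  # same budget, 1 vs 4 occupied tiles (of 16): more concentrated is larger
  n <- 32
  spread <- matrix(0L, n, n)
  spread[1:4, 1:8] <- 1L; spread[9:12, 1:8] <- 1L
  spread[17:20, 1:8] <- 1L; spread[25:28, 1:8] <- 1L
  conc <- matrix(0L, n, n)
  conc[1:8, 1:8] <- 1L; conc[1:8, 9:16] <- 1L
  expect_equal(sum(spread), 128); expect_equal(sum(conc), 128)
  expect_gt(homogeneity(sbp_image(conc), 4), homogeneity(sbp_image(spread), 4))
  expect_error(homogeneity(sbp_image(matrix(0L, 10, 10)), 1), "tiles_per_axis")
  expect_error(homogeneity(sbp_image(matrix(0L, 10, 10)), 11), "tiles_per_axis")
})
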