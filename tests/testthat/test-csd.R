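mont <- montage_biosemi64()
gh <- build_gh_matrices(mont)

erp_of <- function(values, channels = mont$labels, fs = 256) {
  erp(values, 1, channels, fs, c(0, ncol(as.matrix(values)) / fs * 1000))
}

test_that("G and H kernels are symmetric with constant diagonals", {
  expect_lt(max(abs(gh$G - t(gh$G))), 1e-10)
  expect_lt(max(abs(gh$H - t(gh$H))), 1e-10)
  expect_lt(diff(range(diag(gh$G))), 1e-12)
  expect_lt(diff(range(diag(gh$H))), 1e-12)
})

test_that("coincident electrodes are rejected by name", {
  pos <- mont$positions[1:4, ]
  pos[2, ] <- pos[1, ]
  bad <- montage(c("Fpz", "Fpz2", "X", "Y"), pos)
  expect_error(build_gh_matrices(bad), "Fpz.*Fpz2")
})

test_that("Legendre truncation has converged by 50 terms", {
  gh200 <- build_gh_matrices(mont, spline_params(n_terms = 200))
  expect_lt(max(abs(gh$G - gh200$G)), 1e-6)
  expect_lt(max(abs(gh$H - gh200$H)), 1e-6)
})

test_that("CSD of a channel-constant potential is zero and the transform is reference-free", {
  cst <- erp_of(matrix(2.5, 64, 16))
  expect_lt(max(abs(csd_transform(cst, gh)$values)), 1e-10)

  set.seed(21)
  e1 <- erp_of(matrix(rnorm(64 * 16), 64, 16))
  e2 <- e1
  e2$values <- e1$values + 7.3 # re-referencing offset
  c1 <- csd_transform(e1, gh)$values
  c2 <- csd_transform(e2, gh)$values
  expect_lt(max(abs(c1 - c2)) / max(abs(c1)), 1e-8)
})

test_that("CSD of a degree-1 harmonic matches a dense-grid Laplace-Beltrami oracle", {
  z <- mont$positions[, "z"] # P1(cos theta) sampled at the electrodes
  cs <- csd_transform(erp_of(matrix(z, 64, 1)), gh)$values[, 1]
  # independent oracle: finite-difference surface Laplacian of cos(theta)
  # on a dense polar grid, interpolated to the electrode inclinations
  grid <- seq(1e-3, pi - 1e-3, length.out = 20001)
  dth <- grid[2] - grid[1]
  f <- cos(grid)
  fp <- (f[c(2:20001, 20001)] - f[c(1, 1:20000)]) / (2 * dth)
  g <- sin(grid) * fp
  gp <- (g[c(2:20001, 20001)] - g[c(1, 1:20000)]) / (2 * dth)
  lap <- gp / sin(grid)
  ok <- seq(3, 19999)
  expect_lt(max(abs(lap[ok] + 2 * cos(grid[ok]))), 1e-6) # oracle sanity
  th <- acos(pmin(pmax(z, -1), 1))
  lap_at <- approx(grid[ok], lap[ok], xout = th, rule = 2)$y
  # sources positive: CSD is minus the surface Laplacian (up to 1/r^2)
  expect_gt(cor(cs, -lap_at), 0.99)
})

test_that("the transform is linear and scales with the data", {
  set.seed(22)
  a <- erp_of(matrix(rnorm(64 * 8), 64, 8))
  b <- erp_of(matrix(rnorm(64 * 8), 64, 8))
  ab <- a
  ab$values <- a$values - b$values
  expect_equal(csd_transform(ab, gh)$values,
               difference_csd(csd_transform(a, gh), csd_transform(b, gh))$values,
               tolerance = 1e-10)
  k <- -3.7
  ka <- a
  ka$values <- k * a$values
  expect_equal(csd_transform(ka, gh)$values, k * csd_transform(a, gh)$values,
               tolerance = 1e-12)
})

test_that("CSD magnitude scales as the inverse square of the head radius", {
  set.seed(23)
  e <- erp_of(matrix(rnorm(64 * 4), 64, 4))
  c10 <- csd_transform(e, build_gh_matrices(mont, spline_params(head_radius_cm = 10)))
  c20 <- csd_transform(e, build_gh_matrices(mont, spline_params(head_radius_cm = 20)))
  expect_equal(c10$values, 4 * c20$values, tolerance = 1e-12)
})

test_that("difference maps subtract pointwise and validate their inputs", {
  set.seed(24)
  v <- matrix(rnorm(64 * 8), 64, 8)
  m1 <- csd_map(v, mont$labels, 256, c(0, 500), "s01", "scrambled")
  m2 <- csd_map(v, mont$labels, 256, c(0, 500), "s01", "comprehension")
  d <- difference_csd(m1, m2)
  expect_equal(max(abs(d$values)), 0)
  expect_identical(d$condition, "difference")
  m3 <- csd_map(v - 1.5, mont$labels, 256, c(0, 500), "s01", "comprehension")
  expect_lt(max(abs(difference_csd(m1, m3)$values - 1.5)), 1e-12)
  m4 <- csd_map(v[, 1:4], mont$labels, 256, c(0, 250), "s01", "comprehension")
  expect_error(difference_csd(m1, m4), "shape")
})

test_that("channel mismatch against the montage kernels is an error", {
  e <- erp(matrix(0, 3, 4), 1, c("A", "B", "C"), 256, c(0, 15.625))
  expect_error(csd_transform(e, gh), "match the montage")
})
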