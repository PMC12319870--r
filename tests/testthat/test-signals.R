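test_that("surface noise is deterministic with standard-normal moments", {
  p <- make_folded_sheet(small_params(seed = 1))
  x1 <- surface_noise(p$mesh, T = 200, seed = 9)
  x2 <- surface_noise(p$mesh, T = 200, seed = 9)
  expect_identical(x1, x2)
  expect_lt(abs(mean(x1)), 4 / sqrt(length(x1)))
  expect_equal(var(as.vector(x1)), 1, tolerance = 0.05)
  # two different seeds: vertexwise correlations stay in the null band
  y <- surface_noise(p$mesh, T = 200, seed = 10)
  r <- foldbias:::.row_standardise(x1) * foldbias:::.row_standardise(y)
  r <- rowSums(r)
  expect_equal(mean(abs(r)), sqrt(2 / (pi * 200)), tolerance = 0.15)
  expect_lt(max(abs(r)), 6 / sqrt(200))
})

test_that("volume noise has null moments and uncorrelated neighbours", {
  p <- make_folded_sheet(small_params(seed = 2))
  g <- make_voxel_grid(p$mesh, voxel_size = 4, pad = 2)
  g1 <- volume_noise(g, T = 100, seed = 4)
  expect_identical(volume_noise(g, T = 100, seed = 4)$values, g1$values)
  expect_lt(abs(mean(g1$values)), 4 / sqrt(length(g1$values)))
  expect_equal(var(as.vector(g1$values)), 1, tolerance = 0.05)
  lc <- volumetric_local_correlation(g1)
  expect_lt(abs(mean(lc, na.rm = TRUE)), 4 / sqrt(100))
})

test_that("projection honours voxel-centre identities and linear weights", {
  # grid with voxel centres at integer mm: one vertex exactly on a centre,
  # one at the midpoint of two centres
  v <- rbind(c(2, 2, 2), c(2.5, 2, 2), c(2, 3, 2), c(5, 5, 5))
  mesh <- fb_mesh(rbind(v, c(3, 2.5, 2.5)),
                  rbind(c(1, 2, 3), c(2, 4, 3), c(1, 2, 5)))
  g <- make_voxel_grid(mesh, voxel_size = 1, pad = 2)
  g <- volume_noise(g, T = 5, seed = 1)
  tri <- project_volume_to_surface(g, mesh, "trilinear")
  nn <- project_volume_to_surface(g, mesh, "nearest")
  inv <- solve(g$affine)
  u <- (cbind(mesh$vertices, 1) %*% t(inv))[, 1:3]
  V <- matrix(g$values, ncol = dim(g$values)[4])
  lin <- function(ijk) 1 + ijk[1] + g$shape[1] * (ijk[2] + g$shape[2] * ijk[3])
  # vertex 1 sits on a voxel centre: both methods return that series
  expect_equal(tri[1, ], V[lin(round(u[1, ])), ])
  expect_equal(nn[1, ], V[lin(round(u[1, ])), ])
  # vertex 2 is at a midpoint along x: trilinear averages the two centres
  lo <- floor(u[2, ]); hi <- lo + c(1, 0, 0)
  expect_equal(tri[2, ], (V[lin(lo), ] + V[lin(hi), ]) / 2)
})

test_that("trilinear projection equals the 8-corner oracle", {
  p <- make_folded_sheet(small_params(seed = 3))
  g <- volume_noise(make_voxel_grid(p$mesh, 2, 2), T = 8, seed = 2)
  got <- project_volume_to_surface(g, p$mesh, "trilinear")
  inv <- solve(g$affine)
  u <- (cbind(p$mesh$vertices, 1) %*% t(inv))[, 1:3]
  sh <- g$shape
  for (v in sample(seq_len(nrow(u)), 25)) {
    c0 <- pmin(floor(u[v, ]), sh - 2)
    f <- u[v, ] - c0
    want <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      want <- want + w * g$values[c0[1] + dx + 1, c0[2] + dy + 1,
                                  c0[3] + dz + 1, ]
    }
    expect_equal(got[v, ], want, tolerance = 1e-12)
  }
  expect_error(project_volume_to_surface(
    volume_noise(make_voxel_grid(triangle_mesh(), 1, 0), T = 5, seed = 1),
    p$mesh), "outside")
})

test_that("kernel geometry follows the closed forms", {
  p <- make_folded_sheet(small_params(seed = 4))
  k <- build_kernel(p$mesh, fwhm = 2)
  expect_equal(k$sigma, 2 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(k$sigma, 0.8493218, tolerance = 1e-6)
  expect_equal(k$radius, k$sigma * sqrt(2 * log(100)), tolerance = 1e-12)
  expect_equal(k$radius / k$sigma, 3.034854, tolerance = 1e-6)
  expect_equal(Matrix::rowSums(k$W), rep(1, nrow(k$W)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # isolated vertex: neighbours beyond the truncation radius -> identity row
  m <- triangle_mesh(side = 50)
  ki <- build_kernel(m, fwhm = 2)
  expect_equal(as.matrix(ki$W), diag(3), ignore_attr = TRUE)
})

test_that("smoothing preserves constants and has the predicted variance", {
  p <- make_folded_sheet(small_params(seed = 5))
  k <- build_kernel(p$mesh, fwhm = 2)
  expect_equal(smooth_surface(rep(3, nrow(k$W)), k), rep(3, nrow(k$W)),
               tolerance = 1e-12)
  x <- surface_noise(p$mesh, T = 400, seed = 6)
  s <- smooth_surface(x, k)
  v_emp <- apply(s, 1, var)
  v_want <- Matrix::rowSums(k$W^2)
  expect_equal(mean(v_emp / v_want), 1, tolerance = 0.05)
  expect_error(smooth_surface(matrix(0, 5, 2), k), "differ")
})
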