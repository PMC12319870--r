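test_that("local correlation obeys its defining identities", {
  m <- two_triangle_mesh()
  base <- rnorm(50)
  # identical series everywhere: correlation 1 with every neighbour
  x <- matrix(rep(base, each = 4), nrow = 4)
  expect_equal(local_correlation(x, m), rep(1, 4))
  # all neighbour correlations exactly 0.5 -> local correlation 0.5
  q <- qr.Q(qr(cbind(1, matrix(rnorm(10 * 4), 10, 4))))[, 2:5]  # orthonormal
  s <- 0.5 * q[, 1] + sqrt(0.75) * q[, 2]  # corr(s, q1) = 0.5 exactly
  m3 <- triangle_mesh()
  x3 <- rbind(q[, 1], s3 <- 0.5 * q[, 1] + sqrt(0.75) * q[, 3], s)
  # vertex 1 correlates 0.5 with both neighbours
  expect_equal(local_correlation(x3, m3)[1], 0.5, tolerance = 1e-12)
})

test_that("local correlation equals the per-edge loop oracle", {
  p <- make_folded_sheet(fold_params(grid_n = 8, seed = 2))
  x <- surface_noise(p$mesh, T = 40, seed = 3)
  got <- local_correlation(x, p$mesh)
  adj <- neighbours(p$mesh)
  want <- vapply(seq_along(adj), function(v)
    tanh(mean(vapply(adj[[v]], function(u)
      atanh(cor(x[v, ], x[u, ])), 0))), 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("zero-variance series yield NaN with a warning", {
  m <- two_triangle_mesh()
  x <- matrix(rnorm(4 * 20), 4)
  x[2, ] <- 7
  expect_warning(lc <- local_correlation(x, m), "zero-variance")
  expect_true(is.nan(lc[2]))
  expect_false(anyNA(lc[c(1, 3)]))   # other vertices keep their valid edges
})

test_that("neighbourhood normalisation subtracts the local mean", {
  p <- make_folded_sheet(small_params(seed = 3))
  n <- nrow(p$mesh$vertices)
  expect_equal(normalise_local(rep(2.5, n), p$mesh), rep(0, n))
  # radius below the shortest edge: neighbourhood is the vertex itself
  mp <- runif(n)
  expect_equal(normalise_local(mp, p$mesh, radius = 0.2), rep(0, n))
  # explicit neighbourhood-mean oracle
  g <- geodesic_distances(p$mesh, max_radius = 6)
  want <- mp - vapply(seq_len(n), function(v)
    mean(mp[g$to[g$from == v]]), 0)
  expect_equal(normalise_local(mp, p$mesh, radius = 6), want,
               tolerance = 1e-12)
})

test_that("volumetric local correlation matches a hand-rolled oracle", {
  g <- structure(list(shape = c(3L, 3L, 3L), affine = diag(4), values = NULL),
                 class = "fb_voxel_grid")
  g <- volume_noise(g, T = 30, seed = 5)
  got <- volumetric_local_correlation(g)
  idx <- arrayInd(seq_len(27), c(3, 3, 3))
  for (v in seq_len(27)) {
    zs <- c()
    for (ax in 1:3) for (st in c(-1, 1)) {
      nb <- idx[v, ]; nb[ax] <- nb[ax] + st
      if (all(nb >= 1 & nb <= 3)) {
        r <- cor(g$values[idx[v, 1], idx[v, 2], idx[v, 3], ],
                 g$values[nb[1], nb[2], nb[3], ])
        zs <- c(zs, atanh(r))
      }
    }
    expect_equal(got[idx[v, 1], idx[v, 2], idx[v, 3]], tanh(mean(zs)),
                 tolerance = 1e-10)
  }
  # identical series everywhere: 1 at every voxel
  g$values <- array(rep(rnorm(30), each = 27), c(3, 3, 3, 30))
  expect_equal(as.vector(volumetric_local_correlation(g)), rep(1, 27))
  # empty mask errors
  expect_error(volumetric_local_correlation(g, array(FALSE, c(3, 3, 3))),
               "empty")
})

test_that("autocorrelation profiles behave on white and smoothed noise", {
  p <- make_folded_sheet(small_params(seed = 6))
  x <- surface_noise(p$mesh, T = 200, seed = 7)
  edges <- c(0.5, 2.5, 4.5, 6.5)
  raw <- autocorr_profile(x, p$mesh, edges)
  expect_true(all(abs(raw$mean_r) < 4 / sqrt(200)))
  sm <- autocorr_profile(smooth_surface(x, build_kernel(p$mesh, 4)),
                         p$mesh, edges)
  expect_true(all(diff(sm$mean_r) < 0))   # decays with distance
  # single pair in a bin reproduces that pair's correlation
  m <- path_mesh(3)
  xs <- matrix(rnorm(15), 3)
  pr <- autocorr_profile(xs, m, c(0.9, 1.1), max_radius = 1.2)
  expect_equal(pr$count, 2L)  # edges (1,2) and (2,3) at distance 1
  one <- autocorr_profile(xs[, ], m, c(1.5, 2.5), max_radius = 2.5)
  expect_equal(one$count, 1L)
  expect_equal(one$mean_r, cor(xs[1, ], xs[3, ]), tolerance = 1e-10)
})

test_that("parcel time series average correctly", {
  x <- matrix(rnorm(6 * 10), 6)
  lab <- c(1L, 1L, 2L, 2L, 2L, 3L)
  areas <- runif(6, 0.5, 2)
  un <- parcel_timeseries(x, lab)
  expect_equal(un[1, ], colMeans(x[1:2, ]))
  eq <- parcel_timeseries(x, lab, rep(2, 6), weighted = TRUE)
  expect_equal(eq, un, ignore_attr = TRUE)
  w <- parcel_timeseries(x, lab, areas, weighted = TRUE)
  expect_equal(w[2, ],
               colSums(x[3:5, ] * areas[3:5]) / sum(areas[3:5]),
               tolerance = 1e-12)
  expect_equal(w[3, ], x[6, ])        # single-vertex parcel
  expect_error(parcel_timeseries(x, c(1L, 1L, 1L, 1L, 1L, 3L)), "empty")
})

test_that("vertex-parcel coupling is the per-vertex Pearson correlation", {
  x <- matrix(rnorm(5 * 30), 5)
  lab <- c(1L, 1L, 1L, 1L, 2L)
  ps <- parcel_timeseries(x, lab)
  got <- vertex_parcel_coupling(x, ps, lab)
  want <- vapply(1:5, function(v) cor(x[v, ], ps[lab[v], ]), 0)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(got[5], 1)             # single-vertex parcel: self correlation
  # two anti-correlated vertices in one parcel couple symmetrically
  a <- rnorm(40)
  xs <- rbind(a, -a + rnorm(40, 0, 1e-8), rnorm(40))
  labs <- c(1L, 1L, 2L)
  cp <- vertex_parcel_coupling(xs, parcel_timeseries(xs, labs), labs)
  expect_equal(abs(cp[1]), abs(cp[2]), tolerance = 1e-3)
})
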