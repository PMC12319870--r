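test_that("an unwarped, unfolded sheet is flat and uniform", {
  p <- make_folded_sheet(fold_params(grid_n = 16, coupling = 0, amplitude = 0,
                                     jitter = 0, seed = 3))
  sp <- inter_vertex_distance(p$mesh)
  expect_lt(sd(sp) / mean(sp), 0.01)
  expect_equal(unname(range(p$mesh$vertices[, 3])), c(0, 0))
  expect_equal(mean(p$depth), 0, tolerance = 1e-10)
  expect_equal(sd(p$depth), 1, tolerance = 1e-10)
})

test_that("default folded sheets hit the calibrated spacing-depth band", {
  p <- make_folded_sheet(fold_params(seed = 1))
  r <- weighted_pearson(inter_vertex_distance(p$mesh), p$depth,
                        vertex_areas(p$mesh))
  expect_gt(r, 0.35)
  expect_lt(r, 0.70)
})

test_that("depth maps are participant-specific", {
  p1 <- make_folded_sheet(fold_params(seed = 1))
  p2 <- make_folded_sheet(fold_params(seed = 2))
  expect_lt(abs(cor(p1$depth, p2$depth)), 0.3)
})

test_that("uniform control keeps the depth field but drops the warp", {
  pf <- make_folded_sheet(fold_params(seed = 5))
  pu <- make_uniform_mesh(fold_params(seed = 5))
  expect_equal(pu$depth, pf$depth)
  sp <- inter_vertex_distance(pu$mesh)
  expect_lt(abs(weighted_pearson(sp, pu$depth, vertex_areas(pu$mesh))), 0.05)
  expect_lt(sd(sp) / mean(sp), 0.05)
  # near-regular grid: edge lengths cluster at the spacing and the diagonal
  et <- foldbias:::.edge_table(pu$mesh)
  d_axis <- abs(et$lengths - 2)
  d_diag <- abs(et$lengths - 2 * sqrt(2))
  expect_true(all(pmin(d_axis, d_diag) < 0.3))
  expect_true(any(d_axis < 0.3) && any(d_diag < 0.3))
  # folded spacing is strictly more variable than uniform spacing
  expect_gt(sd(inter_vertex_distance(pf$mesh)), sd(sp))
})

test_that("spacing-depth coupling is monotone in the coupling parameter", {
  r <- vapply(c(0, 0.2, 0.4), function(b) {
    p <- make_folded_sheet(fold_params(coupling = b, seed = 4))
    weighted_pearson(inter_vertex_distance(p$mesh), p$depth,
                     vertex_areas(p$mesh))
  }, 0)
  expect_true(all(diff(r) > 0))
})

test_that("cohorts are deterministic, cyclic, and individual", {
  expect_error(make_cohort(1), "at least 2")
  c1 <- make_cohort(4, small_params(), master_seed = 0)
  c2 <- make_cohort(4, small_params(), master_seed = 0)
  expect_equal(c1$participants[[3]]$depth, c2$participants[[3]]$depth)
  expect_equal(length(unique(vapply(c1$participants, `[[`, "", "id"))), 4L)
  # pairwise depth correlations stay low
  dm <- vapply(c1$participants, `[[`, numeric(24^2), "depth")
  cc <- cor(dm)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)
})

test_that("voxel grids cover the mesh and the affine round-trips", {
  p <- make_folded_sheet(small_params(seed = 6))
  g <- make_voxel_grid(p$mesh, voxel_size = 2, pad = 2)
  inv <- solve(g$affine)
  u <- cbind(p$mesh$vertices, 1) %*% t(inv)
  expect_true(all(u[, 1:3] >= 0))
  expect_true(all(sweep(u[, 1:3], 2, g$shape - 1, "<=")))
  # round trip voxel -> world -> voxel
  ijk <- c(3, 4, 0, 1)
  world <- g$affine %*% ijk
  expect_equal(as.vector(inv %*% world), ijk, tolerance = 1e-12)
  # bounds arithmetic: 64 mm extent, 2 mm voxels, 2 mm pad
  v <- rbind(c(0, 0, 0), c(64, 0, 0), c(0, 64, 0), c(64, 64, 64))
  mcube <- fb_mesh(rbind(v, c(32, 32, 32)),
                   rbind(c(1, 2, 3), c(2, 4, 3), c(1, 2, 5)))
  gc <- make_voxel_grid(mcube, voxel_size = 2, pad = 2)
  expect_true(all(gc$shape >= 34))
})

test_that("region growing yields connected, covering, bounded parcels", {
  p <- make_folded_sheet(small_params(seed = 7))
  n <- nrow(p$mesh$vertices)
  expect_equal(sort(unique(make_contiguous_parcellation(p$mesh, n, 1))),
               seq_len(n))
  expect_equal(make_contiguous_parcellation(p$mesh, 1, 1), rep(1L, n))
  expect_error(make_contiguous_parcellation(p$mesh, n + 1, 1), "exceeds")
  K <- 50
  # a 4096-vertex sheet, as in the size-audit contract
  pbig <- make_folded_sheet(fold_params(seed = 8))
  lab <- make_contiguous_parcellation(pbig$mesh, K, seed = 2)
  expect_equal(sort(unique(lab)), seq_len(K))
  sizes <- table(lab)
  expect_true(all(sizes > 4096 / K / 10) && all(sizes < 4096 / K * 10))
  adj <- neighbours(pbig$mesh)
  for (k in seq_len(K)) {
    members <- which(lab == k)
    # BFS connectivity check within the parcel
    seen <- members[1]
    frontier <- seen
    repeat {
      nxt <- setdiff(intersect(unlist(adj[frontier]), members), seen)
      if (length(nxt) == 0) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    expect_equal(length(seen), length(members))
  }
})
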