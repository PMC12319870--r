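test_that("constrained Ward honours trivial contracts", {
  p <- make_folded_sheet(fold_params(grid_n = 8, seed = 1))
  x <- surface_noise(p$mesh, T = 5, seed = 1)
  n <- nrow(x)
  expect_equal(sort(unique(ward_parcellate(x, p$mesh, n))), seq_len(n))
  expect_error(ward_parcellate(x, p$mesh, n + 1), "exceeds")
  # two mesh components with K = 2 are recovered exactly
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(10, 0, 0), c(11, 0, 0), c(10, 1, 0))
  m2 <- fb_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  lab <- ward_parcellate(matrix(rnorm(6 * 4), 6), m2, 2)
  expect_equal(lab[1:3], rep(lab[1], 3))
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_true(lab[1] != lab[4])
})

test_that("constrained Ward matches the O(n^3) reference", {
  for (seed in 1:3) {
    m <- patch_mesh(5, 6, jitter = 0.1, seed = seed)   # 30 vertices
    x <- matrix(rnorm(30 * 10), 30)
    got <- ward_parcellate(x, m, 4)
    want <- oracle_ward(x, neighbours(m), 4)
    # compare up to relabelling
    expect_equal(length(unique(got)), 4)
    tab <- table(got, want)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("Ward parcels are edge-connected", {
  p <- make_folded_sheet(small_params(seed = 2))
  x <- smooth_surface(surface_noise(p$mesh, 60, seed = 3),
                      build_kernel(p$mesh, 2))
  lab <- ward_parcellate(x, p$mesh, 12)
  adj <- neighbours(p$mesh)
  for (k in seq_len(12)) {
    members <- which(lab == k)
    seen <- members[1]; frontier <- seen
    repeat {
      nxt <- setdiff(intersect(unlist(adj[frontier]), members), seen)
      if (length(nxt) == 0) break
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_equal(length(seen), length(members))
  }
})

test_that("border detection matches a neighbour scan", {
  p <- make_folded_sheet(fold_params(grid_n = 8, seed = 3))
  n <- nrow(p$mesh$vertices)
  expect_equal(border_vertices(rep(1L, n), p$mesh), rep(FALSE, n))
  # two-parcel split of a strip: exactly the rows flanking the cut
  m <- patch_mesh(6, 2)
  lab <- ifelse(rep(seq_len(6), 2) <= 3, 1L, 2L)
  b <- border_vertices(lab, m)
  expect_equal(which(b), c(3L, 4L, 9L, 10L))
  # random labels vs brute force
  labr <- sample(1:4, n, replace = TRUE)
  adj <- neighbours(p$mesh)
  want <- vapply(seq_len(n), function(v) any(labr[adj[[v]]] != labr[v]), TRUE)
  expect_equal(border_vertices(labr, p$mesh), want)
})

test_that("border-depth test is calibrated and detects construction", {
  p <- make_folded_sheet(small_params(seed = 4))
  n <- nrow(p$mesh$vertices)
  # borders placed on depth maxima -> positive t
  lab <- ifelse(p$depth > quantile(p$depth, 0.7), 1L, 2L)
  bt <- border_depth_test(lab, p$depth, p$mesh)
  expect_gt(bt$t, 0)
  expect_gt(bt$mean_border, bt$mean_nonborder)
  # constant depth: zero variance is an error, not t = 0
  expect_error(border_depth_test(lab, rep(1, n), p$mesh), "variance")
  # null calibration: random labels, random depth
  set.seed(5)
  tstats <- replicate(60, {
    labr <- make_contiguous_parcellation(p$mesh, 6,
                                         seed = sample.int(1e6, 1))
    border_depth_test(labr, rnorm(n), p$mesh)$t
  })
  expect_lt(abs(mean(tstats)), 3 / sqrt(60))
})

test_that("matched/mismatched wiring is cyclic and null-calibrated", {
  coh <- make_cohort(2, small_params(), master_seed = 3)
  seen <- list()
  mm <- matched_mismatched(coh,
    map_fn = function(p) p$depth,
    assoc_fn = function(map, depth, p) cor(map, depth))
  expect_equal(mm$matched, c(1, 1), tolerance = 1e-12)
  # n = 2: mismatch is the swap
  expect_equal(mm$mismatched[1], cor(coh$participants[[1]]$depth,
                                     coh$participants[[2]]$depth),
               tolerance = 1e-12)
  expect_equal(mm$mismatched[2], cor(coh$participants[[2]]$depth,
                                     coh$participants[[1]]$depth),
               tolerance = 1e-12)
  # depth-independent statistic: matched ~ mismatched
  coh4 <- make_cohort(4, small_params(), master_seed = 4)
  mm0 <- matched_mismatched(coh4,
    map_fn = function(p) surface_noise(p$mesh, 20, seed = p$seed + 7)[, 1],
    assoc_fn = function(map, depth, p) cor(map, depth))
  expect_lt(abs(mean(mm0$matched - mm0$mismatched)), 0.2)
})

test_that("parcel-mean bias is absent on uniform meshes", {
  p <- make_uniform_mesh(small_params(seed = 5))
  x <- smooth_surface(surface_noise(p$mesh, 300, seed = 6),
                      build_kernel(p$mesh, 2))
  lab <- make_contiguous_parcellation(p$mesh, 8, seed = 7)
  pb <- parcel_mean_bias(x, lab, p$depth, vertex_areas(p$mesh), p$mesh,
                         weighted = "both", n_perm = 99, seed = 8)
  expect_lt(abs(pb$unweighted$r), 0.08)
  expect_lt(abs(pb$weighted$r), 0.08)
})
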