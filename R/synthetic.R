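#' Fold-field parameters for synthetic cortical sheets
#'
#' Describes a participant-specific synthetic folded cortical sheet: a
#' regular triangulated grid on a periodic (toroidal) 2D domain, folded by a
#' sum of random sinusoidal waves. The standardised wave field plays the role
#' of sulcal depth (positive = gyrus); an in-plane warp couples local vertex
#' spacing to depth so that vertices are compressed in sulci and stretched on
#' gyral crests, which is the substrate of the gyral bias.
#'
#' Defaults give a 64 x 64 vertex sheet over a 128 mm period with 2 mm base
#' spacing, 6 wave components with 16-32 mm wavelengths (gyral-width scale),
#' 3 mm fold amplitude and spacing-depth coupling 0.4, bracketing the 1-3 mm
#' spacing range seen on real cortical meshes and their mid-0.5
#' spacing-depth correlation.
#'
#' @param grid_n vertices per side (>= 8).
#' @param base_spacing grid spacing in mm (> 0).
#' @param domain_length period length in mm; defaults to `grid_n * base_spacing`.
#' @param n_waves number of sinusoidal fold components.
#' @param amplitude out-of-plane fold height scale A in mm (>= 0).
#' @param coupling dimensionless spacing-depth coupling beta in [0, 0.9].
#' @param jitter misalignment of the spacing warp: the in-plane warp is
#'   driven by the unit-variance mixture `(d + jitter * e) / sqrt(1 +
#'   jitter^2)` of the depth field d with an independent smooth field e of
#'   the same spectrum. On real meshes spacing follows the
#'   sphere-registration distortion field, which tracks the folds only
#'   imperfectly; `jitter = 0` would tie spacing to depth almost exactly,
#'   which is implausibly strong. The default places the spacing-depth
#'   correlation near the mid-0.5 values seen on real cortical meshes.
#' @param seed integer RNG seed identifying the participant.
#' @return list of class `fb_fold_params`.
#' @export
fold_params <- function(grid_n = 64L, base_spacing = 2, domain_length = NULL,
                        n_waves = 6L, amplitude = 3, coupling = 0.4,
                        jitter = 0.9, seed = 1L) {
  if (is.null(domain_length)) domain_length <- grid_n * base_spacing
  stopifnot(grid_n >= 8L, amplitude >= 0, coupling >= 0, coupling <= 0.9,
            jitter >= 0, base_spacing > 0,
            isTRUE(all.equal(domain_length, grid_n * base_spacing)))
  structure(list(grid_n = as.integer(grid_n), base_spacing = base_spacing,
                 domain_length = domain_length, n_waves = as.integer(n_waves),
                 amplitude = amplitude, coupling = coupling, jitter = jitter,
                 seed = as.integer(seed)),
            class = "fb_fold_params")
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# integer wavevectors (cycles per period) with norm in [lo, hi], restricted
# to a half-plane so no two drawn waves share a spatial frequency (a +/-k
# pair would interfere and break the unit-variance normalisation)
.wave_candidates <- function(lo, hi) {
  m <- ceiling(hi)
  cand <- expand.grid(p = 0:m, q = -m:m)
  cand <- cand[cand$p > 0 | (cand$p == 0 & cand$q > 0), ]
  nr <- sqrt(cand$p^2 + cand$q^2)
  cand[nr >= lo & nr <= hi, ]
}

# participant-specific randomness, all drawn from one seeded stream: the
# depth wave set and a disjoint wave set of the same band for the
# independent distortion field. Uniform phases; amplitudes rescaled for
# unit field variance.
.draw_waves <- function(params) {
  cand <- .wave_candidates(4, 8)
  n <- params$n_waves
  .with_seed(params$seed, {
    pick <- cand[sample.int(nrow(cand), 2L * n), ]
    one <- function(rows) list(p = pick$p[rows], q = pick$q[rows],
                               phase = runif(n, 0, 2 * pi),
                               amp = rep(sqrt(2 / n), n))
    list(depth = one(seq_len(n)), indep = one(n + seq_len(n)))
  })
}

# field value d(x, y) and warp displacement -beta * sum a cos(k.x+phi) k/|k|^2
.fold_field <- function(waves, x, y, L) {
  d <- numeric(length(x))
  ux <- numeric(length(x))
  uy <- numeric(length(x))
  for (w in seq_along(waves$p)) {
    kx <- 2 * pi * waves$p[w] / L
    ky <- 2 * pi * waves$q[w] / L
    ph <- kx * x + ky * y + waves$phase[w]
    k2 <- kx^2 + ky^2
    d <- d + waves$amp[w] * sin(ph)
    ux <- ux - waves$amp[w] * cos(ph) * kx / k2
    uy <- uy - waves$amp[w] * cos(ph) * ky / k2
  }
  list(d = d, ux = ux, uy = uy)
}

.grid_faces <- function(n) {
  idx <- function(ix, iy) (iy - 1L) * n + ix       # ix fastest, 1-based
  ix <- rep(seq_len(n), n)
  iy <- rep(seq_len(n), each = n)
  ixp <- ix %% n + 1L
  iyp <- iy %% n + 1L
  v00 <- idx(ix, iy); v10 <- idx(ixp, iy)
  v01 <- idx(ix, iyp); v11 <- idx(ixp, iyp)
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

.face_inverted <- function(v, faces, L) {
  d1 <- v[faces[, 2], ] - v[faces[, 1], ]
  d2 <- v[faces[, 3], ] - v[faces[, 1], ]
  d1 <- d1 - L * round(d1 / L)
  d2 <- d2 - L * round(d2 / L)
  any(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1] <= 0)
}

.make_sheet <- function(params, coupling, jitter, flat) {
  n <- params$grid_n
  L <- params$domain_length
  h <- params$base_spacing
  ix <- rep(seq_len(n), n)
  iy <- rep(seq_len(n), each = n)
  x0 <- (ix - 1) * h
  y0 <- (iy - 1) * h
  faces <- .grid_faces(n)
  # draw wave sets until the *folded* warp (at the participant's nominal
  # coupling/jitter, whether or not this call builds the folded variant)
  # produces no face inversion; the retry is deterministic, so the folded
  # sheet and its uniform control accept the same fold field for a seed
  wave_seed <- params$seed
  for (attempt in seq_len(10L)) {
    wp <- params
    wp$seed <- wave_seed
    waves <- .draw_waves(wp)
    fd <- .fold_field(waves$depth, x0, y0, L)
    fe <- .fold_field(waves$indep, x0, y0, L)
    mix <- sqrt(1 + params$jitter^2)
    ux <- (fd$ux / sd(fd$d) + params$jitter * fe$ux / sd(fe$d)) / mix
    uy <- (fd$uy / sd(fd$d) + params$jitter * fe$uy / sd(fe$d)) / mix
    xf <- (x0 + params$coupling * ux) %% L
    yf <- (y0 + params$coupling * uy) %% L
    if (!(params$coupling > 0) || !.face_inverted(cbind(xf, yf), faces, L))
      break
    if (attempt == 10L)
      stop("coupling too large: in-plane warp inverts mesh faces")
    wave_seed <- .derive_seed(wave_seed, 997L)
  }
  depth <- (fd$d - mean(fd$d)) / sd(fd$d)  # standardised: zero mean, unit var
  mix <- sqrt(1 + jitter^2)
  ux <- (fd$ux / sd(fd$d) + jitter * fe$ux / sd(fe$d)) / mix
  uy <- (fd$uy / sd(fd$d) + jitter * fe$uy / sd(fe$d)) / mix
  x <- (x0 + coupling * ux) %% L
  y <- (y0 + coupling * uy) %% L
  if (flat) {
    nz <- .uniform_tessellation_noise(params)
    x <- (x + nz[, 1]) %% L
    y <- (y + nz[, 2]) %% L
  }
  z <- if (flat) numeric(length(x)) else params$amplitude * depth
  if ((coupling > 0 || jitter > 0) && .face_inverted(cbind(x, y), faces, L))
    stop("coupling too large: in-plane warp inverts mesh faces")
  mesh <- fb_mesh(cbind(x, y, z), faces, periodic_domain = c(L, L),
                  grid_dim = c(n, n))
  structure(list(mesh = mesh, depth = depth,
                 id = sprintf("sub-%d", params$seed), seed = params$seed,
                 params = params),
            class = "fb_participant")
}

#' Generate a synthetic folded cortical sheet
#'
#' Builds one synthetic participant: a triangulated toroidal sheet whose
#' out-of-plane folds follow a random sum of sinusoids (the sulcal-depth
#' analogue, standardised to zero mean and unit variance) and whose in-plane
#' vertex spacing scales approximately as `1 + coupling * depth`. The warp is
#' the gradient of an analytic solution of the Poisson equation driven by the
#' depth field, so the local areal compression matches the depth field by
#' construction.
#'
#' @param params an [fold_params()] object.
#' @return an `fb_participant`: list with `mesh` ([fb_mesh()]), `depth`
#'   (numeric per vertex, positive = gyrus), `id`, `seed`, `params`.
#' @export
make_folded_sheet <- function(params) {
  stopifnot(inherits(params, "fb_fold_params"))
  .make_sheet(params, coupling = params$coupling, jitter = params$jitter,
              flat = FALSE)
}

#' Generate a uniform-spacing control sheet
#'
#' Same depth field as [make_folded_sheet()] for the same seed, but with the
#' spacing-depth coupling forced to zero and no out-of-plane displacement:
#' vertex spacing is approximately uniform (a small truncated tessellation
#' noise, 0.2% of the base spacing, keeps spacing variance non-degenerate)
#' while a depth map still exists for
#' association tests. This is the analogue of templates built to minimise
#' inter-vertex distance variability (and of the evenly spaced sphere).
#'
#' @inheritParams make_folded_sheet
#' @return an `fb_participant` with uniform vertex spacing.
#' @export
make_uniform_mesh <- function(params) {
  stopifnot(inherits(params, "fb_fold_params"))
  .make_sheet(params, coupling = 0, jitter = 0, flat = TRUE)
}

# small i.i.d. in-plane displacement (truncated at 2 SD) so the "uniform"
# sheet has non-degenerate, depth-independent spacing variability. The
# amplitude (0.2% of base spacing) is chosen so that spacing variance is
# non-zero (associations with spacing stay well defined) but the
# smoothing-kernel response to it stays far below the sampling noise of a
# T = 500 local-correlation map, as on a genuinely uniform template
.uniform_tessellation_noise <- function(params) {
  nv <- params$grid_n^2
  nz <- .with_seed(.derive_seed(params$seed, 131L),
                   matrix(rnorm(2L * nv), ncol = 2))
  pmin(pmax(nz, -2), 2) * 0.002 * params$base_spacing
}

#' Generate a cohort of synthetic participants
#'
#' @param n number of participants (>= 2; mismatched designs need a "next"
#'   participant).
#' @param params shared [fold_params()]; each participant gets its own seed.
#' @param master_seed integer; participant seeds are
#'   `master_seed * 1e6 + index`, so cohorts are reproducible and participant
#'   streams do not collide across master seeds (master_seed < 2147).
#' @param uniform if TRUE, build uniform-spacing control participants.
#' @return an `fb_cohort`: list with `participants` (ordered list) and
#'   `master_seed`.
#' @export
make_cohort <- function(n, params = fold_params(), master_seed = 0L,
                        uniform = FALSE) {
  if (n < 2) stop("a cohort needs at least 2 participants")
  stopifnot(abs(master_seed) < 2147)
  build <- if (uniform) make_uniform_mesh else make_folded_sheet
  parts <- lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- as.integer(master_seed * 1e6 + i)
    build(p)
  })
  structure(list(participants = parts, master_seed = master_seed),
            class = "fb_cohort")
}

#' Axis-aligned voxel grid covering a mesh
#'
#' Builds the regular voxel grid (MNI-space analogue) used for
#' volume-to-surface projection tests. The affine maps 0-based voxel indices
#' to world mm at voxel centres.
#'
#' @param mesh an [fb_mesh()].
#' @param voxel_size edge length of cubic voxels in mm.
#' @param pad extra margin around the mesh bounding box in mm.
#' @return an `fb_voxel_grid`: list with `shape` (3 ints), `affine` (4 x 4),
#'   `values` (NULL or 4D array x,y,z,t).
#' @export
make_voxel_grid <- function(mesh, voxel_size = 2, pad = 2) {
  stopifnot(voxel_size > 0)
  lo <- apply(mesh$vertices, 2, min) - pad
  hi <- apply(mesh$vertices, 2, max) + pad
  shape <- as.integer(floor((hi - lo) / voxel_size)) + 1L
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- lo
  structure(list(shape = shape, affine = affine, values = NULL),
            class = "fb_voxel_grid")
}

#' Seeded contiguous parcellation by region growing
#'
#' Partitions the mesh into K edge-connected parcels by frontier expansion
#' from K randomly chosen seed vertices, always growing the currently
#' smallest parcel first; a synthetic stand-in for atlas parcellations,
#' which have roughly equal-sized contiguous parcels.
#'
#' @param mesh an [fb_mesh()].
#' @param K number of parcels (<= n_vertices).
#' @param seed RNG seed.
#' @return integer vector of labels in 1..K, one per vertex; every parcel is
#'   connected on the mesh edge graph.
#' @export
make_contiguous_parcellation <- function(mesh, K, seed = 1L) {
  n <- n_vertices(mesh)
  if (K > n) stop("K exceeds number of vertices")
  adj <- mesh$adjacency
  labels <- integer(n)
  seeds <- .with_seed(seed, sample.int(n, K))
  labels[seeds] <- seq_len(K)
  frontiers <- as.list(seeds)
  sizes <- rep(1L, K)
  alive <- rep(TRUE, K)
  remaining <- n - K
  while (remaining > 0L) {
    if (!any(alive)) stop("mesh appears disconnected: region growing stalled")
    k <- which(alive)[which.min(sizes[alive])]   # grow smallest parcel first
    cand <- unique(unlist(adj[frontiers[[k]]], use.names = FALSE))
    cand <- cand[labels[cand] == 0L]
    if (length(cand) == 0L) {
      alive[k] <- FALSE
      next
    }
    labels[cand] <- k
    sizes[k] <- sizes[k] + length(cand)
    remaining <- remaining - length(cand)
    frontiers[[k]] <- cand
  }
  labels
}
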