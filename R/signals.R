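#' Independent Gaussian noise time series on mesh vertices
#'
#' Standard-normal noise, i.i.d. across vertices and timepoints: the null
#' signal in which any spatial structure found downstream must have been
#' introduced by processing.
#'
#' @param mesh an [fb_mesh()].
#' @param T number of timepoints (>= 3).
#' @param seed RNG seed.
#' @return numeric matrix, n_vertices x T.
#' @export
surface_noise <- function(mesh, T = 500L, seed = 1L) {
  stopifnot(T >= 3)
  n <- n_vertices(mesh)
  .with_seed(seed, matrix(rnorm(n * T), nrow = n, ncol = T))
}

#' Independent Gaussian noise time series on voxels
#'
#' @param grid an `fb_voxel_grid` from [make_voxel_grid()].
#' @param T number of timepoints (>= 3).
#' @param seed RNG seed.
#' @return the grid with `values` set to a 4D array (x, y, z, t).
#' @export
volume_noise <- function(grid, T = 500L, seed = 1L) {
  stopifnot(inherits(grid, "fb_voxel_grid"), T >= 3)
  nv <- prod(grid$shape)
  grid$values <- .with_seed(seed, array(rnorm(nv * T), dim = c(grid$shape, T)))
  grid
}

# 0-based continuous voxel coordinates of mesh vertices
.voxel_coords <- function(grid, mesh) {
  v <- mesh$vertices
  inv <- solve(grid$affine)
  u <- cbind(v, 1) %*% t(inv)
  u[, 1:3, drop = FALSE]
}

#' Project a 4D volume onto mesh vertices
#'
#' Samples the volume at each vertex location, per timepoint, using either
#' trilinear interpolation over the 8 surrounding voxel centres or the
#' nearest voxel centre. Spatial weights are identical across timepoints.
#' Where vertex spacing is finer than the voxel size, neighbouring vertices
#' sample overlapping voxels and inherit correlated series: the
#' volume-to-surface upsampling mechanism of the gyral bias.
#'
#' @param grid an `fb_voxel_grid` with 4D `values`.
#' @param mesh an [fb_mesh()] whose vertices lie inside the grid.
#' @param method `"trilinear"` or `"nearest"`.
#' @return numeric matrix, n_vertices x T.
#' @export
project_volume_to_surface <- function(grid, mesh,
                                      method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(!is.null(grid$values))
  dm <- dim(grid$values)
  T <- dm[4]
  u <- .voxel_coords(grid, mesh)
  if (any(u < 0) || any(sweep(u, 2, dm[1:3] - 1, ">"))) {
    bad <- which(rowSums(u < 0 | sweep(u, 2, dm[1:3] - 1, ">")) > 0)[1]
    stop(sprintf("vertex %d lies outside the voxel grid", bad))
  }
  V <- matrix(grid$values, nrow = prod(dm[1:3]), ncol = T)
  lin <- function(i, j, k) 1L + i + dm[1] * (j + dm[2] * k)  # 0-based ijk
  if (method == "nearest") {
    i <- round(u[, 1]); j <- round(u[, 2]); k <- round(u[, 3])
    return(V[lin(i, j, k), , drop = FALSE])
  }
  i0 <- pmin(floor(u[, 1]), dm[1] - 2); fx <- u[, 1] - i0
  j0 <- pmin(floor(u[, 2]), dm[2] - 2); fy <- u[, 2] - j0
  k0 <- pmin(floor(u[, 3]), dm[3] - 2); fz <- u[, 3] - k0
  out <- matrix(0, nrow = nrow(u), ncol = T)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    out <- out + w * V[lin(i0 + dx, j0 + dy, k0 + dz), , drop = FALSE]
  }
  out
}

#' Geodesic Gaussian smoothing kernel
#'
#' Builds the sparse row-stochastic smoothing operator: unnormalised weight
#' `exp(-d^2 / (2 sigma^2))` for geodesic distance d up to a truncation
#' radius, then row normalisation (self-weight at d = 0 included, so
#' constants are preserved). `sigma = fwhm / (2 sqrt(2 log 2))`. The
#' truncation radius `r* = sigma * sqrt(2 log(1 / truncation_fraction))` is
#' the radius beyond which the discarded fraction of the 2D Gaussian integral
#' equals `truncation_fraction`.
#'
#' Because the radius is fixed in mm, the kernel covers many vertices where
#' spacing is small (sulci) and few where it is large (gyri) -- the smoothing
#' mechanism of the gyral bias.
#'
#' @param mesh an [fb_mesh()].
#' @param fwhm full width at half maximum in mm (> 0).
#' @param truncation_fraction discarded kernel integral fraction.
#' @return an `fb_kernel`: list with sparse matrix `W` (dgCMatrix, rows sum
#'   to 1), `fwhm`, `sigma`, `radius`, `truncation_fraction`.
#' @export
build_kernel <- function(mesh, fwhm, truncation_fraction = 0.01) {
  stopifnot(fwhm > 0, truncation_fraction > 0, truncation_fraction < 1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  radius <- sigma * sqrt(2 * log(1 / truncation_fraction))
  g <- geodesic_distances(mesh, max_radius = radius)
  w <- exp(-g$d^2 / (2 * sigma^2))
  n <- n_vertices(mesh)
  W <- Matrix::sparseMatrix(i = g$from, j = g$to, x = w, dims = c(n, n))
  W <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  structure(list(W = methods::as(W, "CsparseMatrix"), fwhm = fwhm,
                 sigma = sigma, radius = radius,
                 truncation_fraction = truncation_fraction),
            class = "fb_kernel")
}

#' Apply a smoothing kernel
#'
#' Multiplies the row-stochastic kernel into a per-vertex map or an
#' n_vertices x T time-series matrix (each timepoint independently).
#'
#' @param x numeric vector (one value per vertex) or matrix (vertices x T).
#' @param kernel an `fb_kernel` built on the same mesh.
#' @return smoothed object of the same shape as `x`.
#' @export
smooth_surface <- function(x, kernel) {
  stopifnot(inherits(kernel, "fb_kernel"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (nrow(x) != nrow(kernel$W))
    stop("data and kernel vertex counts differ")
  out <- as.matrix(kernel$W %*% x)
  if (vec) out[, 1] else out
}
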