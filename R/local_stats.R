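# clip correlations before the Fisher transform so atanh stays finite
.fisher_clip <- 1 - 1e-12

.atanh_clipped <- function(r) atanh(pmin(pmax(r, -.fisher_clip), .fisher_clip))

# rows scaled to zero mean, unit L2 norm; zero-variance rows become NaN
.row_standardise <- function(x) {
  x <- x - rowMeans(x)
  x / sqrt(rowSums(x^2))
}

#' Local correlation map
#'
#' For each vertex, the Pearson correlation between its time series and that
#' of each mesh neighbour is Fisher z-transformed (atanh), averaged across
#' neighbours, and transformed back (tanh). This is the package's core bias
#' statistic: on uneven meshes, processed noise shows higher local
#' correlation where vertices are closer together (sulci).
#'
#' @param series numeric matrix, n_vertices x T (T >= 3).
#' @param mesh an [fb_mesh()].
#' @return numeric vector, one local correlation per vertex; NaN (with a
#'   warning) where a vertex or all of its neighbours have zero variance.
#' @export
local_correlation <- function(series, mesh) {
  stopifnot(ncol(series) >= 3, nrow(series) == n_vertices(mesh))
  z <- .row_standardise(series)
  if (anyNA(z)) warning("zero-variance time series: NaN local correlation")
  et <- .edge_table(mesh)
  r <- rowSums(z[et$edges[, 1], , drop = FALSE] *
               z[et$edges[, 2], , drop = FALSE])
  fz <- .atanh_clipped(r)
  from <- c(et$edges[, 1], et$edges[, 2])
  vals <- c(fz, fz)
  ok <- !is.na(vals)
  n <- n_vertices(mesh)
  s <- rowsum(vals[ok], from[ok])
  cnt <- tabulate(from[ok], nbins = n)
  out <- rep(NaN, n)
  idx <- as.integer(rownames(s))
  out[idx] <- tanh(s[, 1] / cnt[idx])
  out[cnt == 0] <- NaN
  out
}

#' Normalise a map by its geodesic neighbourhood mean
#'
#' Subtracts from each vertex the unweighted mean of the map over all
#' vertices within `radius` mm geodesic distance (the vertex itself
#' included). Isolates fine-scale spatial variation, removing regional
#' trends.
#'
#' @param map numeric vector, one value per vertex.
#' @param mesh an [fb_mesh()].
#' @param radius neighbourhood radius in mm.
#' @return numeric vector of normalised values.
#' @export
normalise_local <- function(map, mesh, radius = 15) {
  stopifnot(length(map) == n_vertices(mesh))
  g <- geodesic_distances(mesh, max_radius = radius)
  s <- rowsum(map[g$to], g$from)
  cnt <- tabulate(g$from, nbins = n_vertices(mesh))
  means <- rep(NA_real_, n_vertices(mesh))
  means[as.integer(rownames(s))] <- s[, 1]
  map - means / cnt
}

#' Volumetric 6-neighbour local correlation
#'
#' Volume-space control statistic: for each in-mask voxel, the
#' Fisher-averaged Pearson correlation of its time series with its in-mask
#' face neighbours (anterior/posterior, superior/inferior, left/right). On a
#' uniform voxel grid this statistic carries no spacing bias.
#'
#' @param grid an `fb_voxel_grid` with 4D `values`.
#' @param mask logical 3D array, same spatial shape; default all TRUE.
#' @return 3D array of local correlations; NaN outside the mask or where a
#'   voxel has no in-mask neighbour.
#' @export
volumetric_local_correlation <- function(grid, mask = NULL) {
  stopifnot(!is.null(grid$values))
  dm <- dim(grid$values)
  sh <- dm[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = sh)
  if (!any(mask)) stop("mask is empty")
  V <- matrix(grid$values, nrow = prod(sh), ncol = dm[4])
  z <- .row_standardise(V)
  zsum <- numeric(prod(sh))
  cnt <- integer(prod(sh))
  idx3 <- arrayInd(seq_len(prod(sh)), sh)
  for (axis in 1:3) for (step in c(-1L, 1L)) {
    nb3 <- idx3
    nb3[, axis] <- nb3[, axis] + step
    ok <- nb3[, axis] >= 1L & nb3[, axis] <= sh[axis]
    a <- which(ok)
    b <- (nb3[ok, 1] - 1L) + sh[1] * ((nb3[ok, 2] - 1L) +
                                        sh[2] * (nb3[ok, 3] - 1L)) + 1L
    keep <- mask[a] & mask[b]
    a <- a[keep]; b <- b[keep]
    r <- rowSums(z[a, , drop = FALSE] * z[b, , drop = FALSE])
    zsum[a] <- zsum[a] + .atanh_clipped(r)
    cnt[a] <- cnt[a] + 1L
  }
  out <- rep(NaN, prod(sh))
  has <- cnt > 0L & as.vector(mask)
  out[has] <- tanh(zsum[has] / cnt[has])
  array(out, dim = sh)
}

#' Spatial autocorrelation as a function of geodesic distance
#'
#' Pools all vertex pairs with geodesic distance up to `max_radius`, bins
#' them by distance and reports the Fisher-averaged Pearson correlation and
#' pair count per bin.
#'
#' @param series numeric matrix, n_vertices x T.
#' @param mesh an [fb_mesh()].
#' @param bin_edges increasing numeric vector of bin edges in mm.
#' @param max_radius pair search radius in mm (>= max(bin_edges)).
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_r`, `count`; `mean_r`
#'   is NaN where a bin is empty.
#' @export
autocorr_profile <- function(series, mesh, bin_edges, max_radius = max(bin_edges)) {
  stopifnot(all(diff(bin_edges) > 0), max(bin_edges) <= max_radius)
  g <- geodesic_distances(mesh, max_radius = max_radius)
  g <- g[g$from < g$to, ]
  z <- .row_standardise(series)
  r <- rowSums(z[g$from, , drop = FALSE] * z[g$to, , drop = FALSE])
  bin <- findInterval(g$d, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  keep <- bin >= 1L & bin <= nb
  s <- rowsum(.atanh_clipped(r[keep]), bin[keep])
  cnt <- tabulate(bin[keep], nbins = nb)
  mean_r <- rep(NaN, nb)
  idx <- as.integer(rownames(s))
  mean_r[idx] <- tanh(s[, 1] / cnt[idx])
  data.frame(bin_lo = bin_edges[-length(bin_edges)], bin_hi = bin_edges[-1],
             mean_r = mean_r, count = cnt)
}

#' Parcel-mean time series
#'
#' Averages vertex time series within each parcel, optionally weighting each
#' vertex by its surface area (which corrects for the over-representation of
#' densely sampled sulcal vertices in the plain mean).
#'
#' @param series numeric matrix, n_vertices x T.
#' @param labels integer parcel labels in 1..K, one per vertex.
#' @param areas vertex areas (mm^2); required when `weighted = TRUE`.
#' @param weighted use area weighting?
#' @return numeric matrix, K x T, rows ordered by parcel label.
#' @export
parcel_timeseries <- function(series, labels, areas = NULL, weighted = FALSE) {
  K <- max(labels)
  if (!all(seq_len(K) %in% labels)) stop("empty parcel in labels")
  if (weighted) {
    stopifnot(!is.null(areas), length(areas) == nrow(series))
    num <- rowsum(series * areas, labels)
    den <- rowsum(areas, labels)[, 1]
    num / den
  } else {
    rowsum(series, labels) / as.vector(table(factor(labels, seq_len(K))))
  }
}

#' Vertex-to-parcel coupling
#'
#' Pearson correlation between each vertex's time series and the series of
#' its encompassing parcel: how much each vertex contributes to the parcel
#' mean.
#'
#' @param series numeric matrix, n_vertices x T.
#' @param parcel_series numeric matrix, K x T, from [parcel_timeseries()].
#' @param labels integer parcel labels in 1..K.
#' @return numeric vector of correlations, one per vertex (NaN on zero
#'   variance).
#' @export
vertex_parcel_coupling <- function(series, parcel_series, labels) {
  stopifnot(nrow(series) == length(labels), ncol(series) == ncol(parcel_series))
  zx <- .row_standardise(series)
  zp <- .row_standardise(parcel_series)
  unname(rowSums(zx * zp[labels, , drop = FALSE]))
}
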