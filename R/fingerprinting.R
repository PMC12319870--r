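#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation between node (vertex or parcel) time series.
#'
#' @param series numeric matrix, nodes x T (T >= 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(series) {
  stopifnot(ncol(series) >= 3)
  sds <- apply(series, 1, sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance node: %d", which(sds == 0)[1]))
  fc <- cor(t(series))
  diag(fc) <- 1
  fc
}

#' Vectorise a functional connectivity matrix
#'
#' Extracts the upper triangle (i < j, row-major order). When a node-pair
#' geodesic distance matrix and a threshold are supplied, pairs strictly
#' closer than the threshold are dropped; pairs at exactly the threshold are
#' retained. Pairs with unknown (e.g. beyond-radius) distance should carry
#' Inf and are always retained.
#'
#' @param fc symmetric matrix from [fc_matrix()].
#' @param dist optional symmetric node-pair distance matrix (mm).
#' @param threshold optional distance threshold (mm).
#' @return numeric vector of retained upper-triangle entries.
#' @export
vectorise_fc <- function(fc, dist = NULL, threshold = NULL) {
  n <- nrow(fc)
  ut <- which(upper.tri(fc))
  # column-major upper-triangle -> row-major (i < j by i, then j)
  rc <- arrayInd(ut, dim(fc))
  ord <- order(rc[, 1], rc[, 2])
  ut <- ut[ord]
  if (!is.null(threshold)) {
    if (is.null(dist)) stop("distance threshold requires a distance matrix")
    ut <- ut[!(dist[ut] < threshold)]
    if (length(ut) == 0) stop("distance threshold removed all pairs")
  }
  fc[ut]
}

#' Fingerprint identification
#'
#' Matches each participant's retest FC vector to the test FC vector with
#' which it is most highly Pearson-correlated; ties go to the lowest
#' participant index. Accuracy is the fraction of retest scans matched to
#' their own test scan; chance level is 1/n.
#'
#' @param test,retest numeric matrices, participants x vector length, rows
#'   aligned by participant.
#' @return list with `match` (chosen test index per retest row), `accuracy`,
#'   `similarity` (retest x test correlation matrix), `chance`.
#' @export
identify_participants <- function(test, retest) {
  stopifnot(ncol(test) == ncol(retest), nrow(test) >= 2,
            nrow(test) == nrow(retest))
  sim <- cor(t(retest), t(test))
  match <- apply(sim, 1, which.max)
  list(match = match,
       accuracy = mean(match == seq_len(nrow(retest))),
       similarity = sim, chance = 1 / nrow(test))
}

# min over cohort participants of within-parcel pair geodesic distances;
# absent (beyond-radius) pairs are Inf
.cohort_pair_distances <- function(cohort, labels, radius) {
  parts <- cohort$participants
  K <- max(labels)
  verts <- split(seq_along(labels), labels)
  dmin <- lapply(verts, function(v)
    matrix(Inf, length(v), length(v),
           dimnames = list(v, v)))
  for (p in parts) {
    g <- geodesic_distances(p$mesh, max_radius = radius)
    same <- labels[g$from] == labels[g$to] & g$from != g$to
    g <- g[same, ]
    lab <- labels[g$from]
    for (k in seq_len(K)) {
      gk <- g[lab == k, ]
      if (nrow(gk) == 0) next
      i <- match(gk$from, verts[[k]])
      j <- match(gk$to, verts[[k]])
      idx <- cbind(i, j)
      dmin[[k]][idx] <- pmin(dmin[[k]][idx], gk$d)
    }
  }
  dmin
}

#' Fingerprinting accuracy versus distance threshold
#'
#' The full vertex-level fingerprinting experiment: per participant, two
#' independent noise scans are generated and geodesically smoothed (test and
#' retest); per parcel, within-parcel vertex-level FC matrices are
#' vectorised at each distance threshold and identification accuracy is
#' computed across the cohort. Because real anatomy gives each participant
#' an idiosyncratic spacing pattern, accuracy is far above chance at
#' threshold 0 and collapses to chance once all pairs closer than the
#' threshold are removed.
#'
#' Pair distances vary across participants, but vectors must align, so a
#' pair is dropped when its geodesic distance is below the threshold in any
#' cohort participant (the cohort-minimum distance is thresholded).
#'
#' @param cohort an `fb_cohort`.
#' @param labels integer parcel labels shared across the cohort (meshes share
#'   topology).
#' @param thresholds ascending distance thresholds in mm (0 = no threshold).
#' @param fwhm smoothing kernel FWHM in mm.
#' @param T timepoints per scan.
#' @param scan_seed base seed; participant i uses `scan_seed + 2 i` (test)
#'   and `scan_seed + 2 i + 1` (retest).
#' @return list with `accuracy` (parcel x threshold matrix, NA where a
#'   parcel lost all pairs), `mean`, `sem`, `chance`, `thresholds`,
#'   `skipped` (parcel/threshold pairs without usable pairs).
#' @export
threshold_sweep <- function(cohort, labels, thresholds, fwhm = 2, T = 500L,
                            scan_seed = 1000L) {
  stopifnot(!is.unsorted(thresholds))
  parts <- cohort$participants
  n <- length(parts)
  K <- max(labels)
  verts <- split(seq_along(labels), labels)
  radius <- max(c(thresholds, 1e-6))
  dmin <- .cohort_pair_distances(cohort, labels, radius)
  fcs <- vector("list", n)
  for (i in seq_len(n)) {
    kern <- build_kernel(parts[[i]]$mesh, fwhm = fwhm)
    test <- smooth_surface(surface_noise(parts[[i]]$mesh, T,
                                         seed = scan_seed + 2L * i), kern)
    retest <- smooth_surface(surface_noise(parts[[i]]$mesh, T,
                                           seed = scan_seed + 2L * i + 1L),
                             kern)
    fcs[[i]] <- lapply(seq_len(K), function(k)
      list(test = fc_matrix(test[verts[[k]], , drop = FALSE]),
           retest = fc_matrix(retest[verts[[k]], , drop = FALSE])))
  }
  acc <- matrix(NA_real_, K, length(thresholds))
  skipped <- list()
  for (k in seq_len(K)) {
    for (ti in seq_along(thresholds)) {
      th <- thresholds[ti]
      vec <- try({
        tv <- t(vapply(seq_len(n), function(i)
          vectorise_fc(fcs[[i]][[k]]$test, dmin[[k]], th), numeric(
            length(vectorise_fc(fcs[[1]][[k]]$test, dmin[[k]], th)))))
        rv <- t(vapply(seq_len(n), function(i)
          vectorise_fc(fcs[[i]][[k]]$retest, dmin[[k]], th),
          numeric(ncol(tv))))
        identify_participants(tv, rv)$accuracy
      }, silent = TRUE)
      if (inherits(vec, "try-error")) {
        skipped[[length(skipped) + 1L]] <- c(parcel = k, threshold = th)
      } else acc[k, ti] <- vec
    }
  }
  m <- colMeans(acc, na.rm = TRUE)
  sem <- apply(acc, 2, function(a) {
    a <- a[!is.na(a)]
    if (length(a) < 2) NA_real_ else sd(a) / sqrt(length(a))
  })
  list(accuracy = acc, mean = m, sem = sem, chance = 1 / n,
       thresholds = thresholds, skipped = skipped)
}

#' Precompute smoothing kernels for a cohort
#'
#' @param cohort an `fb_cohort`.
#' @param fwhm kernel FWHM in mm.
#' @return list of `fb_kernel`, one per participant.
#' @export
cohort_kernels <- function(cohort, fwhm = 2) {
  lapply(cohort$participants, function(p) build_kernel(p$mesh, fwhm = fwhm))
}

#' Parcel-level fingerprinting of smoothed noise
#'
#' One replicate of the parcel-level identification experiment: per
#' participant, two independent noise scans are smoothed on that
#' participant's mesh, reduced to area-weighted parcel time series, and
#' turned into parcel FC matrices; retest scans are matched to test scans by
#' maximal correlation of the vectorised matrices. Parcel averaging washes
#' out the vertex-level spacing signature, so accuracy is expected at chance.
#'
#' @param cohort an `fb_cohort`.
#' @param labels integer parcel labels shared across the cohort.
#' @param fwhm smoothing FWHM in mm.
#' @param T timepoints per scan.
#' @param scan_seed base seed; participant i draws test/retest noise from
#'   seeds `scan_seed + 2 i` and `scan_seed + 2 i + 1`.
#' @param kernels optional precomputed [cohort_kernels()] result.
#' @return list with `accuracy`, `match`, `chance`.
#' @export
parcel_fingerprint <- function(cohort, labels, fwhm = 2, T = 500L,
                               scan_seed = 1L, kernels = NULL) {
  parts <- cohort$participants
  n <- length(parts)
  if (is.null(kernels)) kernels <- cohort_kernels(cohort, fwhm)
  vecs <- lapply(seq_len(n), function(i) {
    areas <- vertex_areas(parts[[i]]$mesh)
    one <- function(seed) {
      x <- smooth_surface(surface_noise(parts[[i]]$mesh, T, seed = seed),
                          kernels[[i]])
      vectorise_fc(fc_matrix(parcel_timeseries(x, labels, areas,
                                               weighted = TRUE)))
    }
    list(test = one(scan_seed + 2L * i), retest = one(scan_seed + 2L * i + 1L))
  })
  id <- identify_participants(do.call(rbind, lapply(vecs, `[[`, "test")),
                              do.call(rbind, lapply(vecs, `[[`, "retest")))
  list(accuracy = id$accuracy, match = id$match, chance = id$chance)
}
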