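#' Contiguity-constrained Ward parcellation
#'
#' Agglomerative clustering of vertex time series under the Ward
#' minimum-variance criterion, with candidate merges restricted to cluster
#' pairs joined by at least one mesh edge, so parcels are edge-connected by
#' construction. Ties in merge cost are broken by the lowest cluster-index
#' pair, making results deterministic. Applied to smoothed noise, parcel
#' borders gravitate to gyral crests, where local correlations are weakest.
#'
#' @param series numeric matrix, n_vertices x T (raw time series; no
#'   rescaling is applied).
#' @param mesh an [fb_mesh()].
#' @param K number of parcels.
#' @return integer labels in 1..K, relabelled in order of first occurrence
#'   by vertex index.
#' @export
ward_parcellate <- function(series, mesh, K) {
  stopifnot(nrow(series) == n_vertices(mesh))
  if (K > n_vertices(mesh)) stop("K exceeds number of vertices")
  csr <- .adjacency_csr(mesh)
  reps <- .ward_constrained(as.matrix(series), csr$ptr, csr$idx, as.integer(K))
  match(reps, unique(reps))
}

#' Border vertices of a parcellation
#'
#' A vertex is a border vertex when at least one of its mesh neighbours
#' carries a different parcel label.
#'
#' @param labels integer parcel labels, one per vertex.
#' @param mesh an [fb_mesh()].
#' @return logical vector, TRUE at border vertices.
#' @export
border_vertices <- function(labels, mesh) {
  stopifnot(length(labels) == n_vertices(mesh))
  et <- .edge_table(mesh)
  diff <- labels[et$edges[, 1]] != labels[et$edges[, 2]]
  out <- logical(length(labels))
  out[et$edges[diff, 1]] <- TRUE
  out[et$edges[diff, 2]] <- TRUE
  out
}

#' Border versus non-border sulcal depth test
#'
#' Two-sample (pooled) t-test of sulcal depth between border and non-border
#' vertices of a parcellation. A positive t means borders sit on more
#' positive depth, i.e. closer to gyral crests.
#'
#' @param labels integer parcel labels.
#' @param depth per-vertex sulcal depth (positive = gyrus).
#' @param mesh an [fb_mesh()].
#' @return list with `mean_border`, `mean_nonborder`, `t`, `df`, `p`,
#'   `cohens_d`.
#' @export
border_depth_test <- function(labels, depth, mesh) {
  b <- border_vertices(labels, mesh)
  if (!any(b) || all(b)) stop("border/non-border group is empty")
  gt <- group_tests(depth[b], depth[!b], type = "two_sample")
  list(mean_border = gt$mean_x, mean_nonborder = gt$mean_y,
       t = gt$t, df = gt$df, p = gt$p, cohens_d = gt$cohens_d)
}

#' Matched versus mismatched depth association across a cohort
#'
#' Two-level individuality design: a per-participant map is computed once
#' from that participant's own data (`map_fn`), then associated (`assoc_fn`)
#' with the participant's own depth map ("matched") and with the depth map of
#' the next participant in the cohort sequence, cyclically ("mismatched").
#' Because all synthetic meshes share vertex count and topology, maps
#' transfer across participants by vertex index. A paired t-test compares the
#' matched against the mismatched statistics.
#'
#' @param cohort an `fb_cohort`.
#' @param map_fn function(participant) -> per-vertex map (or any object
#'   `assoc_fn` understands).
#' @param assoc_fn function(map, depth, participant) -> scalar statistic.
#' @return list with `matched`, `mismatched` (numeric vectors) and `test`
#'   (paired [group_tests()] result).
#' @export
matched_mismatched <- function(cohort, map_fn, assoc_fn) {
  parts <- cohort$participants
  n <- length(parts)
  stopifnot(n >= 2)
  nv <- vapply(parts, function(p) n_vertices(p$mesh), 0L)
  if (length(unique(nv)) != 1L)
    stop("cohort meshes differ in vertex count; maps cannot transfer")
  maps <- lapply(parts, map_fn)
  matched <- vapply(seq_len(n), function(i)
    assoc_fn(maps[[i]], parts[[i]]$depth, parts[[i]]), 0)
  mismatched <- vapply(seq_len(n), function(i) {
    j <- i %% n + 1L
    assoc_fn(maps[[i]], parts[[j]]$depth, parts[[i]])
  }, 0)
  test <- tryCatch(group_tests(matched, mismatched, type = "paired"),
                   error = function(e) NULL)  # degenerate: zero-variance diffs
  list(matched = matched, mismatched = mismatched, test = test)
}

#' Parcel-mean representation bias
#'
#' Tests whether a vertex's coupling to its parcel-mean time series depends
#' on sulcal depth. On folded meshes, smoothed noise gives sulcal vertices
#' (many, closely spaced, mutually correlated) a larger share of the plain
#' parcel mean, so gyral vertices couple less: a negative depth association.
#' Area-weighted parcel means reduce, but do not abolish, the bias.
#'
#' @param series numeric matrix, n_vertices x T (smoothed noise or data).
#' @param labels integer parcel labels.
#' @param depth per-vertex sulcal depth.
#' @param areas per-vertex surface areas (weights and weighted mean).
#' @param mesh an [fb_mesh()].
#' @param weighted `"both"`, `"weighted"` or `"unweighted"` parcel means.
#' @param n_perm permutations for the shift test.
#' @param seed RNG seed for the permutation draw.
#' @return list with one element per requested variant, each holding `r`
#'   (area-weighted Pearson of coupling vs depth) and `p` (shift test).
#' @export
parcel_mean_bias <- function(series, labels, depth, areas, mesh,
                             weighted = c("both", "weighted", "unweighted"),
                             n_perm = 1000L, seed = 1L) {
  weighted <- match.arg(weighted)
  variants <- if (weighted == "both") c("unweighted", "weighted") else weighted
  out <- list()
  for (v in variants) {
    ps <- parcel_timeseries(series, labels, areas, weighted = v == "weighted")
    coup <- vertex_parcel_coupling(series, ps, labels)
    pt <- shift_permutation_test(coup, depth, mesh, w = areas,
                                 n_perm = n_perm, seed = seed)
    out[[v]] <- list(r = pt$observed, p = pt$p)
  }
  out
}
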