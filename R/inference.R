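#' Area-weighted Pearson correlation
#'
#' Pearson correlation between two per-vertex maps in which each vertex
#' contributes proportionally to a weight (normally its surface area), so
#' that densely sampled regions do not dominate the association. Vertices
#' with NA/NaN in either map are dropped pairwise.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, same length; default uniform.
#' @return correlation in [-1, 1].
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w >= 0, na.rm = TRUE))
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero")
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  min(1, max(-1, sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)))
}

#' Spatial shift permutation test
#'
#' Autocorrelation-preserving permutation test for the association between
#' two maps on a periodic (toroidal) sheet: the analogue of the spherical
#' "spin test". The null is built by applying random cyclic 2D grid
#' translations to `y` (the map's spatial structure is preserved exactly;
#' only its alignment with `x` is destroyed) and recomputing the weighted
#' Pearson correlation. The identity shift is excluded. Two-sided p with
#' add-one correction: `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`.
#'
#' For non-periodic meshes a random vertex permutation fallback is available
#' but is flagged: it ignores spatial autocorrelation and anticonservative
#' p-values should be expected.
#'
#' @param x,y numeric per-vertex maps.
#' @param mesh an [fb_mesh()]; the shift scheme needs `grid_dim`.
#' @param w weights for [weighted_pearson()].
#' @param n_perm number of permutations (ignored when `exhaustive`).
#' @param seed RNG seed.
#' @param exhaustive use all `grid_n^2 - 1` non-identity shifts.
#' @param fallback allow the naive random-permutation scheme on non-grid
#'   meshes.
#' @return list of class `fb_perm` with `observed`, `null`, `p`, `n_perm`,
#'   `scheme`.
#' @export
shift_permutation_test <- function(x, y, mesh, w = rep(1, length(x)),
                                   n_perm = 1000L, seed = 1L,
                                   exhaustive = FALSE, fallback = FALSE) {
  obs <- weighted_pearson(x, y, w)
  if (is.null(mesh$grid_dim)) {
    if (!fallback)
      stop("mesh has no grid structure; shift scheme unavailable ",
           "(set fallback = TRUE for a naive permutation null)")
    null <- .with_seed(seed, vapply(seq_len(n_perm), function(i)
      weighted_pearson(x, y[sample.int(length(y))], w), 0))
    scheme <- "random_permutation"
  } else {
    gx <- mesh$grid_dim[1]; gy <- mesh$grid_dim[2]
    ym <- matrix(y, nrow = gx)                # ix fastest
    shift_cor <- function(sx, sy) {
      ys <- ym[(seq_len(gx) - 1L - sx) %% gx + 1L,
               (seq_len(gy) - 1L - sy) %% gy + 1L, drop = FALSE]
      weighted_pearson(x, as.vector(ys), w)
    }
    if (exhaustive) {
      sh <- expand.grid(sx = 0:(gx - 1L), sy = 0:(gy - 1L))
      sh <- sh[!(sh$sx == 0 & sh$sy == 0), ]
      null <- mapply(shift_cor, sh$sx, sh$sy)
      n_perm <- nrow(sh)
    } else {
      null <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
        repeat {
          sx <- sample.int(gx, 1L) - 1L
          sy <- sample.int(gy, 1L) - 1L
          if (sx != 0L || sy != 0L) break
        }
        shift_cor(sx, sy)
      }, 0))
    }
    scheme <- "toroidal_shift"
  }
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  structure(list(observed = obs, null = null, p = p,
                 n_perm = as.integer(n_perm), scheme = scheme),
            class = "fb_perm")
}

#' @export
print.fb_perm <- function(x, ...) {
  cat(sprintf("shift permutation test (%s): r = %.4f, p = %.4g (%d perms)\n",
              x$scheme, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Classical t-tests with effect sizes
#'
#' One-sample, paired and two-sample (pooled variance) t statistics with the
#' matching Cohen's d: one-sample/paired d = mean / SD (of differences);
#' two-sample d = mean difference / pooled SD. Two-sided p.
#'
#' @param x numeric sample (for paired/two-sample: first sample).
#' @param y second sample (paired or two-sample).
#' @param mu null value for the one-sample test.
#' @param type `"one_sample"`, `"paired"` or `"two_sample"`.
#' @return list with `t`, `df`, `p`, `cohens_d`, `mean` (and `mean_x`,
#'   `mean_y` for two-sample).
#' @export
group_tests <- function(x, y = NULL, mu = 0,
                        type = c("one_sample", "paired", "two_sample")) {
  type <- match.arg(type)
  if (type == "paired") {
    stopifnot(!is.null(y), length(x) == length(y))
    x <- x - y
    mu <- 0
    type <- "one_sample"
    paired <- TRUE
  } else paired <- FALSE
  if (type == "one_sample") {
    n <- length(x)
    stopifnot(n >= 2)
    s <- sd(x)
    if (s == 0) stop("zero variance")
    t <- (mean(x) - mu) / (s / sqrt(n))
    df <- n - 1
    out <- list(t = t, df = df, p = 2 * pt(-abs(t), df),
                cohens_d = (mean(x) - mu) / s, mean = mean(x),
                type = if (paired) "paired" else "one_sample")
  } else {
    stopifnot(!is.null(y), length(x) >= 2, length(y) >= 2)
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    if (sp2 == 0) stop("zero variance")
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
    out <- list(t = t, df = df, p = 2 * pt(-abs(t), df),
                cohens_d = (mean(x) - mean(y)) / sqrt(sp2),
                mean_x = mean(x), mean_y = mean(y), type = "two_sample")
  }
  out
}
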