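# tiny meshes and reference implementations shared across tests

# single unit-ish triangle
triangle_mesh <- function(side = 1) {
  v <- rbind(c(0, 0, 0), c(side, 0, 0), c(side / 2, side * sqrt(3) / 2, 0))
  fb_mesh(v, rbind(c(1, 2, 3)))
}

# two triangles sharing edge (2,3)
two_triangle_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  fb_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)))
}

# open (non-periodic) triangulated nx x ny patch with optional vertex jitter
patch_mesh <- function(nx, ny, spacing = 1, jitter = 0, seed = 1) {
  set.seed(seed)
  ix <- rep(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  v <- cbind((ix - 1) * spacing + rnorm(nx * ny, 0, jitter),
             (iy - 1) * spacing + rnorm(nx * ny, 0, jitter),
             rnorm(nx * ny, 0, jitter))
  idx <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  fb_mesh(v, f)
}

# embedded path graph: n vertices on a line, thin triangles so the edge
# graph contains the path 1-2-...-n (plus long chords we keep away by
# building consecutive triangles sharing path edges)
path_mesh <- function(n, spacing = 1) {
  v <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  v <- rbind(v, cbind((seq_len(n - 1) - 0.5) * spacing, 1e3, 0))
  f <- cbind(seq_len(n - 1), 2:n, n + seq_len(n - 1))
  fb_mesh(v, f)
}

# brute-force adjacency by scanning all face edges
oracle_adjacency <- function(mesh) {
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- f[pr[1]]; b <- f[pr[2]]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  lapply(adj, sort)
}

edge_len <- function(mesh, a, b) {
  d <- mesh$vertices[a, ] - mesh$vertices[b, ]
  if (!is.null(mesh$periodic_domain)) {
    L <- mesh$periodic_domain
    d[1] <- d[1] - L[1] * round(d[1] / L[1])
    d[2] <- d[2] - L[2] * round(d[2] / L[2])
  }
  sqrt(sum(d^2))
}

# small default sheet for pipeline tests
small_params <- function(seed = 1, ...)
  fold_params(grid_n = 24L, base_spacing = 2, seed = seed, ...)

# brute-force constrained Ward: recompute all pairwise merge costs each step
oracle_ward <- function(x, adj, K) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  nbr <- lapply(seq_len(n), function(v) adj[[v]])
  while (length(clusters) > K) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      joined <- any(unlist(lapply(clusters[[i]], function(v)
        any(adj[[v]] %in% clusters[[j]]))))
      if (!joined) next
      ci <- colMeans(x[clusters[[i]], , drop = FALSE])
      cj <- colMeans(x[clusters[[j]], , drop = FALSE])
      ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
      cost <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      # tie-break: lowest (min-member i, min-member j) pair
      if (cost < best_cost - 1e-12) {
        best <- c(i, j); best_cost <- cost
      } else if (abs(cost - best_cost) <= 1e-12 && !is.null(best)) {
        key_new <- c(min(clusters[[i]]), min(clusters[[j]]))
        key_old <- c(min(clusters[[best[1]]]), min(clusters[[best[2]]]))
        key_new <- sort(key_new); key_old <- sort(key_old)
        if (key_new[1] < key_old[1] ||
            (key_new[1] == key_old[1] && key_new[2] < key_old[2]))
          best <- c(i, j)
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

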