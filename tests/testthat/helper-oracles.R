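# Independent brute-force oracles used to validate the package's spatial
# primitives. These deliberately use different algorithms from the
# implementation (winding number vs crossing number, O(n^2) scans vs grid
# index, monotone chain vs grDevices::chull).

# winding-number point-in-polygon, boundary-inclusive
oracle_pip <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    wn <- 0
    for (k in seq_len(n)) {
      j <- if (k == n) 1 else k + 1
      x1 <- vx[k]; y1 <- vy[k]; x2 <- vx[j]; y2 <- vy[j]
      cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cr) < 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)) &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9)
        return(TRUE)  # on boundary
      if (y1 <= y) {
        if (y2 > y && cr > 0) wn <- wn + 1
      } else {
        if (y2 <= y && cr < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# O(n^2) exclude-self / cross nearest-neighbor distances
oracle_nnd <- function(q, r, exclude_self = FALSE) {
  vapply(seq_len(nrow(q)), function(i) {
    d2 <- (r[, 1] - q[i, 1])^2 + (r[, 2] - q[i, 2])^2
    if (exclude_self) d2[i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
}

# brute-force DBSCAN with the same deterministic conventions as the
# implementation contract: cores by neighbor count (incl self), clusters
# as connected core components numbered by lowest core index, border
# points claimed by the lowest-index core within eps
oracle_dbscan <- function(m, eps, min_pts) {
  n <- nrow(m)
  d2 <- outer(m[, 1], m[, 1], "-")^2 + outer(m[, 2], m[, 2], "-")^2
  adj <- d2 <= eps^2
  core <- rowSums(adj) >= min_pts
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0) next
    nxt <- nxt + 1L
    queue <- i
    labels[i] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      nb <- which(adj[p, ] & core & labels == 0)
      labels[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cands <- which(adj[i, ] & core)
    labels[i] <- if (length(cands)) labels[min(cands)] else 0L
  }
  labels
}

# Andrew monotone-chain convex hull area
oracle_hull_area <- function(m) {
  m <- unique(m[order(m[, 1], m[, 2]), , drop = FALSE])
  n <- nrow(m)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(m[h[length(h) - 1], ], m[h[length(h)], ], m[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(n)), build(rev(seq_len(n))))
  hx <- m[hull, 1]; hy <- m[hull, 2]
  j <- c(length(hx), seq_len(length(hx) - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# the DoC score formula evaluated longhand with squared-distance
# comparisons (matching the closed-ball counting convention exactly)
oracle_doc <- function(src, other, dr = 20, r_max = 500) {
  radii <- seq(dr, r_max, by = dr)
  K <- length(radii)
  vapply(seq_len(nrow(src)), function(i) {
    ds2 <- (src[, 1] - src[i, 1])^2 + (src[, 2] - src[i, 2])^2
    ds2 <- ds2[-i]
    dc2 <- (other[, 1] - src[i, 1])^2 + (other[, 2] - src[i, 2])^2
    ns <- vapply(radii, function(r) sum(ds2 <= r^2), numeric(1))
    nc <- vapply(radii, function(r) sum(dc2 <= r^2), numeric(1))
    if (ns[K] == 0 || nc[K] == 0) return(0)
    # ranks of D(r) = (N(r)/N(R_max)) * R_max^2/r^2 equal ranks of N(r)/r^2
    # (positive constant factor); the one-division form preserves exact ties
    d_s <- ns / radii^2
    d_c <- nc / radii^2
    rho <- suppressWarnings(cor(d_s, d_c, method = "spearman"))
    if (is.na(rho)) return(0)
    rho * exp(-sqrt(min(dc2)) / r_max)
  }, numeric(1))
}

# naive untruncated fixed-bandwidth mean-shift
oracle_mean_shift <- function(m, h, tol = 0.1, max_iter = 500) {
  out <- m
  for (i in seq_len(nrow(m))) {
    cur <- m[i, ]
    for (it in seq_len(max_iter)) {
      w <- exp(-0.5 * ((m[, 1] - cur[1])^2 + (m[, 2] - cur[2])^2) / h^2)
      nxt <- c(sum(w * m[, 1]), sum(w * m[, 2])) / sum(w)
      moved <- sqrt(sum((nxt - cur)^2))
      cur <- nxt
      if (moved < tol) break
    }
    out[i, ] <- cur
  }
  out
}

# shared fixtures
unit_square_um <- function(side = 4000)
  roi_polygon(c(0, side, side, 0), c(0, 0, side, side))

# wrap raw coordinates as a minimal cluster record for metric functions
as_cluster_record <- function(coords, channel = "5-LO", id = 1L) {
  ca <- cluster_area(coords)
  structure(list(id = id, channel = channel,
                 members = seq_len(nrow(coords)) - 1L, coords = coords,
                 contour = ca$contour, area = ca$area,
                 n_locs = nrow(coords),
                 density = if (ca$degenerate) NA_real_
                           else nrow(coords) / ca$area,
                 degenerate = ca$degenerate),
            class = "cluster_record")
}
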