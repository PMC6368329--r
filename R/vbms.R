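#' DBSCAN pre-partitioning for unbiased cluster analysis
#'
#' Conservative pre-clustering before mean-shift: the DBSCAN distance
#' cutoff is set to the 99.9th percentile (linear-interpolation quantile)
#' of exclude-self nearest-neighbor distances over the dataset, with
#' `min_pts = 2`. Connected regions can then be processed independently,
#' and single isolated points (DBSCAN noise) are removed.
#'
#' @param points point set with at least 2 points.
#' @param nnd_quantile quantile of the NND distribution setting the
#'   cutoff.
#' @param min_pts DBSCAN minimum neighborhood size; 2 is the most
#'   conservative non-trivial choice and makes noise coincide with
#'   isolated single points.
#' @return List with `subsets` (list of integer index vectors into the
#'   input), `removed` (indices of isolated points), and `eps` (the
#'   cutoff used, nm).
#' @export
preclust_partition <- function(points, nnd_quantile = 0.999,
                               min_pts = 2) {
  m <- coord_matrix(points)
  if (nrow(m) < 2)
    stop("pre-partitioning needs at least 2 points", call. = FALSE)
  nnd <- cpp_nnd(m[, 1], m[, 2], m[, 1], m[, 2], TRUE)
  eps <- unname(quantile(nnd, nnd_quantile, type = 7))
  labels <- cpp_dbscan(m[, 1], m[, 2], eps, as.integer(min_pts))
  subsets <- split(seq_len(nrow(m)), labels)
  removed <- as.integer(subsets[["0"]] %||% integer(0))
  subsets[["0"]] <- NULL
  list(subsets = unname(subsets), removed = removed, eps = eps)
}

#' Per-point diagonal bandwidths for variable-bandwidth mean-shift
#'
#' In `fixed` mode every point receives the same isotropic bandwidth
#' (`fixed_h`, default 250 nm — the reference operating point). In
#' `auto` mode a k-nearest-neighbor pilot sets per-point, per-axis
#' bandwidths from the axis spread of each point's `k` nearest
#' neighbors; the pilot is then rescaled globally so its median matches
#' a scale selected from a geometric grid by cluster-count stability
#' (the scale whose retained-cluster count changes least across adjacent
#' grid points).
#'
#' @param points point set.
#' @param mode `"fixed"` or `"auto"`.
#' @param fixed_h fixed isotropic bandwidth, nm.
#' @param k pilot neighborhood size for auto mode.
#' @param grid_size number of candidate global scales.
#' @param grid_span candidate scales run from `median/grid_span` to
#'   `median * grid_span` geometrically.
#' @return n x 2 matrix of per-point (h_x, h_y) bandwidths in nm, with
#'   attribute `scale` (the selected global scale in auto mode). Axis
#'   bandwidths are floored at 1 nm so degenerate axes cannot divide by
#'   zero. With fewer than `k + 1` points auto mode falls back to fixed
#'   mode with a warning.
#' @export
estimate_bandwidths <- function(points, mode = c("fixed", "auto"),
                                fixed_h = 250, k = 50, grid_size = 5,
                                grid_span = 3) {
  mode <- match.arg(mode)
  m <- coord_matrix(points)
  n <- nrow(m)
  if (mode == "fixed" || n < k + 1) {
    if (mode == "auto")
      warning("too few points for auto bandwidths (need > k = ", k,
              "); falling back to fixed ", fixed_h, " nm", call. = FALSE)
    h <- matrix(fixed_h, n, 2)
    attr(h, "scale") <- fixed_h
    return(h)
  }
  # pilot: axis spread of each point's k nearest neighbors
  pilot <- matrix(NA_real_, n, 2)
  d2 <- as.matrix(dist(m))^2
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    pilot[i, 1] <- sd(m[nb, 1])
    pilot[i, 2] <- sd(m[nb, 2])
  }
  pilot[!is.finite(pilot) | pilot < 1] <- 1
  med <- median(pilot)
  scales <- exp(seq(log(med / grid_span), log(med * grid_span),
                    length.out = grid_size))
  counts <- vapply(scales, function(s) {
    h <- pmax(pilot * (s / med), 1)
    ms <- mean_shift(m, h)
    res <- modes_to_clusters(ms$modes, coords = m,
                             merge_tol = median(h) / 2)
    nrow(res$clusters)
  }, numeric(1))
  # stability: smallest change in cluster count across adjacent scales
  instab <- vapply(seq_along(scales), function(g) {
    nbrs <- c(if (g > 1) abs(counts[g] - counts[g - 1]),
              if (g < length(scales)) abs(counts[g] - counts[g + 1]))
    mean(nbrs)
  }, numeric(1))
  best <- which.min(instab)
  h <- pmax(pilot * (scales[best] / med), 1)
  attr(h, "scale") <- scales[best]
  h
}

#' Variable-bandwidth mean-shift
#'
#' Each point's mean iterates toward the local kernel-weighted average
#' `m <- sum(w_j x_j) / sum(w_j)` with Gaussian weights
#' `w_j = exp(-0.5 * ((dx / h_jx)^2 + (dy / h_jy)^2))`, using only data
#' points within `trunc_factor * max(h_jx, h_jy)` of the current mean
#' (exact radius queries on a spatial grid index; set
#' `trunc_factor = Inf` for untruncated kernels). Iteration stops when
#' the shift falls below `tol` or at `max_iter` (non-converged points
#' keep their last position and are flagged with a warning).
#'
#' @param points point set.
#' @param bandwidths n x 2 matrix of per-point bandwidths (nm), or a
#'   single number used isotropically for all points.
#' @param trunc_factor kernel truncation radius in bandwidth units.
#' @param tol convergence tolerance on the shift, nm.
#' @param max_iter iteration cap.
#' @return List with `modes` (n x 2 converged positions), `iterations`,
#'   `converged`.
#' @export
mean_shift <- function(points, bandwidths = 250, trunc_factor = 4,
                       tol = 0.1, max_iter = 500) {
  m <- coord_matrix(points)
  n <- nrow(m)
  if (length(bandwidths) == 1)
    bandwidths <- matrix(as.numeric(bandwidths), n, 2)
  bandwidths <- as.matrix(bandwidths)
  stopifnot(nrow(bandwidths) == n, ncol(bandwidths) == 2)
  if (any(bandwidths <= 0)) stop("bandwidths must be positive",
                                 call. = FALSE)
  if (n == 0)
    return(list(modes = m, iterations = integer(0),
                converged = logical(0)))
  res <- cpp_mean_shift(m[, 1], m[, 2], bandwidths[, 1], bandwidths[, 2],
                        trunc_factor, tol, as.integer(max_iter))
  if (!all(res$converged))
    warning(sum(!res$converged),
            " point(s) did not converge within max_iter; last position kept",
            call. = FALSE)
  res
}

#' Group converged mean-shift modes into clusters
#'
#' Modes within `merge_tol` of each other are merged by single linkage;
#' each merged mode's points form a candidate cluster, and clusters with
#' fewer than `min_size` localizations are discarded. Retained clusters
#' get a convex-hull contour, area and density (`n_locs / area`).
#'
#' @param modes n x 2 matrix of converged positions from [mean_shift()].
#' @param coords original n x 2 point coordinates (for hulls); defaults
#'   to the modes themselves.
#' @param ids optional per-point localization ids.
#' @param merge_tol single-linkage merge distance, nm.
#' @param min_size minimum localizations per retained cluster (default
#'   4, i.e. clusters of more than 3 localizations).
#' @return A `vbms_result`: `clusters` data.frame (`cluster`, `n_locs`,
#'   `area`, `density`), `members` (list of id vectors), `hulls` (list
#'   of contour matrices), `assignment` (per-point cluster id, `NA` for
#'   points of discarded clusters), `mode_centers`.
#' @export
modes_to_clusters <- function(modes, coords = NULL, ids = NULL,
                              merge_tol = 125, min_size = 4) {
  modes <- as.matrix(modes)
  n <- nrow(modes)
  coords <- if (is.null(coords)) modes else coord_matrix(coords)
  stopifnot(nrow(coords) == n)
  ids <- ids %||% (seq_len(n) - 1L)
  if (n == 0 || merge_tol <= 0)
    stop("need modes and a positive merge_tol", call. = FALSE)
  # single-linkage components at merge_tol == DBSCAN with min_pts = 1
  comp <- cpp_dbscan(modes[, 1], modes[, 2], merge_tol, 1L)
  assignment <- rep(NA_integer_, n)
  members <- list(); hulls <- list(); rows <- list()
  next_id <- 0L
  for (lab in sort(unique(comp))) {
    idx <- which(comp == lab)
    if (length(idx) < min_size) next
    next_id <- next_id + 1L
    ca <- cluster_area(coords[idx, , drop = FALSE])
    assignment[idx] <- next_id
    members[[next_id]] <- ids[idx]
    hulls[[next_id]] <- ca$contour
    rows[[next_id]] <- data.frame(
      cluster = next_id, n_locs = length(idx), area = ca$area,
      density = if (ca$degenerate) NA_real_ else length(idx) / ca$area)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), n_locs = integer(), area = numeric(),
               density = numeric())
  mode_centers <- if (length(members))
    t(vapply(seq_along(members), function(ci) {
      idx <- which(assignment == ci)
      c(mean(modes[idx, 1]), mean(modes[idx, 2]))
    }, numeric(2))) else matrix(numeric(0), 0, 2)
  structure(list(clusters = clusters, members = members, hulls = hulls,
                 assignment = assignment, mode_centers = mode_centers,
                 merge_tol = merge_tol, min_size = min_size),
            class = "vbms_result")
}

#' @export
print.vbms_result <- function(x, ...) {
  cat(sprintf("VBMS result: %d retained clusters, %d assigned of %d points\n",
              nrow(x$clusters), sum(!is.na(x$assignment)),
              length(x$assignment)))
  invisible(x)
}

#' Unbiased variable-bandwidth mean-shift cluster analysis
#'
#' The full pipeline: DBSCAN pre-partitioning at the 99.9th-percentile
#' nearest-neighbor distance (removing single isolated points), per-point
#' bandwidth assignment, truncated-kernel mean-shift within each
#' partition, and mode merging into clusters of more than `min_size - 1`
#' localizations with convex-hull areas.
#'
#' @param table a [loc_table()] (one channel) or any point set.
#' @param bandwidth_mode `"fixed"` or `"auto"` (see
#'   [estimate_bandwidths()]).
#' @param fixed_h fixed bandwidth, nm.
#' @param trunc_factor kernel truncation radius in bandwidth units.
#' @param tol,max_iter mean-shift convergence controls.
#' @param merge_tol mode-merge distance, nm; default half the median
#'   bandwidth.
#' @param min_size minimum localizations per retained cluster.
#' @return A `vbms_result` (see [modes_to_clusters()]); `assignment` and
#'   `removed` index the input points, and `params` records all settings.
#' @export
vbms_cluster <- function(table, bandwidth_mode = c("fixed", "auto"),
                         fixed_h = 250, trunc_factor = 4, tol = 0.1,
                         max_iter = 500, merge_tol = NULL, min_size = 4) {
  bandwidth_mode <- match.arg(bandwidth_mode)
  m <- coord_matrix(table)
  ids <- if (is.data.frame(table) && !is.null(table$id)) table$id
         else seq_len(nrow(m)) - 1L
  part <- preclust_partition(m)
  modes <- matrix(NA_real_, nrow(m), 2)
  h_all <- matrix(NA_real_, nrow(m), 2)
  for (idx in part$subsets) {
    sub <- m[idx, , drop = FALSE]
    h <- estimate_bandwidths(sub, bandwidth_mode, fixed_h = fixed_h)
    ms <- suppressWarnings(
      mean_shift(sub, h, trunc_factor, tol, max_iter))
    modes[idx, ] <- ms$modes
    h_all[idx, ] <- h
  }
  kept <- sort(unlist(part$subsets))
  merge_tol <- merge_tol %||% (median(h_all[kept, ]) / 2)
  res <- modes_to_clusters(modes[kept, , drop = FALSE],
                           coords = m[kept, , drop = FALSE],
                           ids = ids[kept], merge_tol = merge_tol,
                           min_size = min_size)
  assignment <- rep(NA_integer_, nrow(m))
  assignment[kept] <- res$assignment
  res$assignment <- assignment
  res$removed <- part$removed
  res$params <- list(bandwidth_mode = bandwidth_mode, fixed_h = fixed_h,
                     trunc_factor = trunc_factor, tol = tol,
                     max_iter = max_iter, merge_tol = merge_tol,
                     min_size = min_size, preclust_eps = part$eps)
  res
}
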