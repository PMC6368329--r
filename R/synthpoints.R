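#' @name synthetic_scene
#' @title Synthetic two-channel SMLM scenes with ground truth
#' @description
#' The simulator generates localization tables whose generative process is
#' fully known: each localization carries a molecule id and a
#' parent-cluster id (or `"background"`), so cluster detection,
#' colocalization scoring and interaction classification can all be
#' checked against planted truth. A scene is a list with elements
#' `locs` (a [loc_table()]), `truth` (per-localization molecule, parent
#' and channel), `parents` (parent-cluster centers, with shared-parent
#' flags for two-channel scenes), and `params`.
NULL

new_scene <- function(locs, truth, parents, params) {
  stopifnot(nrow(locs) == nrow(truth))
  structure(list(locs = locs, truth = truth, parents = parents,
                 params = params), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d localizations, %d parent clusters, channels: %s\n",
              nrow(x$locs), nrow(x$parents),
              paste(attr(x$locs, "channels"), collapse = ", ")))
  invisible(x)
}

# uniform points inside a polygon by rejection from its bounding box
runif_polygon <- function(n, region) {
  if (n == 0) return(cbind(numeric(0), numeric(0)))
  bx <- range(region$x); by <- range(region$y)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    cx <- runif(m, bx[1], bx[2])
    cy <- runif(m, by[1], by[2])
    keep <- points_in_polygon(cx, cy, region)
    k <- min(sum(keep), n - got)
    if (k > 0) {
      idx <- which(keep)[seq_len(k)]
      out[(got + 1):(got + k), ] <- cbind(cx[idx], cy[idx])
      got <- got + k
    }
  }
  out
}

#' Simulate complete spatial randomness (CSR) in a region
#'
#' The null model for colocalization calibration: `n` points uniform over
#' the polygon, all labeled `"background"`.
#'
#' @param region a [roi_polygon()].
#' @param n number of points (>= 0).
#' @param seed integer RNG seed; identical seed and parameters give a
#'   byte-identical scene.
#' @param channel channel label for the generated points.
#' @return A `synthetic_scene`.
#' @export
simulate_csr <- function(region, n, seed = NULL, channel = "ch1") {
  stopifnot(inherits(region, "roi_polygon"))
  if (length(n) != 1 || n < 0)
    stop("n must be a single non-negative count", call. = FALSE)
  xy <- with_seed(seed, runif_polygon(n, region))
  locs <- loc_table(xy[, 1], xy[, 2], channel = channel)
  truth <- data.frame(id = locs$id, molecule = locs$id,
                      parent = rep("background", n),
                      channel = rep(channel, n), stringsAsFactors = FALSE)
  parents <- data.frame(parent = character(), x = numeric(), y = numeric(),
                        channel = character(), stringsAsFactors = FALSE)
  new_scene(locs, truth, parents,
            list(model = "csr", n = n, seed = seed, channel = channel))
}

# parents uniform in region; each emits Poisson(mu) offspring with
# isotropic Gaussian spread sigma. Offspring outside the region are kept;
# ROI filtering is a separate explicit step.
thomas_points <- function(region, n_parents, mu_offspring, sigma_cluster,
                          parent_xy = NULL, label_prefix = "p") {
  if (is.null(parent_xy)) parent_xy <- runif_polygon(n_parents, region)
  n_parents <- nrow(parent_xy)
  counts <- rpois(n_parents, mu_offspring)
  total <- sum(counts)
  pidx <- rep(seq_len(n_parents), counts)
  x <- parent_xy[pidx, 1] + rnorm(total, 0, sigma_cluster)
  y <- parent_xy[pidx, 2] + rnorm(total, 0, sigma_cluster)
  list(x = x, y = y, parent = paste0(label_prefix, pidx),
       parent_xy = parent_xy,
       parent_ids = paste0(label_prefix, seq_len(n_parents)))
}

#' Simulate a Thomas cluster process
#'
#' Poisson-offspring clusters around uniformly placed parents: the planted
#' ground truth for cluster-recovery tests. Offspring that land outside
#' the region are kept (clusters may straddle the ROI edge).
#'
#' @param region a [roi_polygon()].
#' @param n_parents number of parent clusters (>= 0).
#' @param mu_offspring mean offspring per parent (> 0).
#' @param sigma_cluster per-axis Gaussian offspring spread, nm (>= 0).
#' @inheritParams simulate_csr
#' @return A `synthetic_scene` whose truth labels name each offspring's
#'   parent; no point is labeled `"background"`.
#' @export
simulate_thomas <- function(region, n_parents, mu_offspring, sigma_cluster,
                            seed = NULL, channel = "ch1") {
  stopifnot(inherits(region, "roi_polygon"))
  if (n_parents < 0) stop("n_parents must be >= 0", call. = FALSE)
  if (mu_offspring <= 0) stop("mu_offspring must be > 0", call. = FALSE)
  if (sigma_cluster < 0) stop("sigma_cluster must be >= 0", call. = FALSE)
  tp <- with_seed(seed,
    thomas_points(region, n_parents, mu_offspring, sigma_cluster))
  n <- length(tp$x)
  locs <- loc_table(tp$x, tp$y, channel = channel)
  truth <- data.frame(id = locs$id, molecule = locs$id, parent = tp$parent,
                      channel = rep(channel, n), stringsAsFactors = FALSE)
  parents <- data.frame(parent = tp$parent_ids, x = tp$parent_xy[, 1],
                        y = tp$parent_xy[, 2],
                        channel = rep(channel, n_parents),
                        stringsAsFactors = FALSE)
  new_scene(locs, truth, parents,
            list(model = "thomas", n_parents = n_parents,
                 mu_offspring = mu_offspring,
                 sigma_cluster = sigma_cluster, seed = seed,
                 channel = channel))
}

#' Per-channel parameters for the two-channel simulator
#'
#' @param n_parents parent clusters in this channel.
#' @param mu_offspring mean molecules per parent cluster.
#' @param sigma_cluster per-axis cluster spread, nm.
#' @param n_background CSR background molecules in this channel.
#' @return A parameter list for [simulate_two_channel()].
#' @export
channel_params <- function(n_parents = 20, mu_offspring = 50,
                           sigma_cluster = 50, n_background = 0) {
  list(n_parents = n_parents, mu_offspring = mu_offspring,
       sigma_cluster = sigma_cluster, n_background = n_background)
}

#' Simulate a two-channel dSTORM scene with controllable colocalization
#'
#' Emulates two-color SMLM of a pair of interacting membrane proteins:
#' each channel is a Thomas cluster process plus optional CSR background,
#' a fraction `coloc_fraction` of channel-B parent centers is reused from
#' channel A (shared parents are true colocalization), each molecule
#' blinks into a Geometric number of localizations (mean `blink_mean`),
#' and every localization is jittered by isotropic Gaussian localization
#' error `sigma_loc`.
#'
#' @param region a [roi_polygon()].
#' @param params_a,params_b per-channel [channel_params()].
#' @param coloc_fraction fraction of channel-B parents shared with
#'   channel A, in \[0, 1\].
#' @param blink_mean mean localizations per molecule (>= 1); counts are
#'   Geometric on \{1, 2, ...\}.
#' @param sigma_loc per-axis localization error, nm.
#' @param channels length-2 character vector of channel names.
#' @param seed integer seed; channel sub-streams are derived from it so
#'   the scene is reproducible.
#' @return A `synthetic_scene`; `parents$shared` flags parents common to
#'   both channels, and `truth$molecule` groups blinks of one molecule.
#' @export
simulate_two_channel <- function(region,
                                 params_a = channel_params(),
                                 params_b = channel_params(),
                                 coloc_fraction = 0,
                                 blink_mean = 4,
                                 sigma_loc = 10,
                                 channels = c("5-LO", "FLAP"),
                                 seed = NULL) {
  stopifnot(inherits(region, "roi_polygon"))
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]", call. = FALSE)
  if (blink_mean < 1) stop("blink_mean must be >= 1", call. = FALSE)
  stopifnot(length(channels) == 2)
  gen_channel <- function(params, parent_xy, prefix, sub_seed) {
    with_seed(sub_seed, {
      tp <- thomas_points(region, params$n_parents, params$mu_offspring,
                          params$sigma_cluster, parent_xy = parent_xy,
                          label_prefix = prefix)
      bg <- runif_polygon(params$n_background, region)
      mol_x <- c(tp$x, bg[, 1])
      mol_y <- c(tp$y, bg[, 2])
      parent <- c(tp$parent, rep("background", nrow(bg)))
      n_mol <- length(mol_x)
      blinks <- 1L + rgeom(n_mol, prob = 1 / blink_mean)
      midx <- rep(seq_len(n_mol), blinks)
      lx <- mol_x[midx] + rnorm(length(midx), 0, sigma_loc)
      ly <- mol_y[midx] + rnorm(length(midx), 0, sigma_loc)
      list(x = lx, y = ly, molecule = midx, parent = parent[midx],
           parent_xy = tp$parent_xy, parent_ids = tp$parent_ids)
    })
  }
  # channel A parents drawn in their own sub-stream so channel B's
  # existence never perturbs them
  pa <- with_seed(derive_seed(seed %||% 0L, 1L),
                  runif_polygon(params_a$n_parents, region))
  n_shared <- round(coloc_fraction * params_b$n_parents)
  n_shared <- min(n_shared, nrow(pa))
  pb_own <- with_seed(derive_seed(seed %||% 0L, 2L), {
    shared_idx <- if (n_shared > 0)
      sample(nrow(pa), n_shared) else integer(0)
    fresh <- runif_polygon(params_b$n_parents - n_shared, region)
    rbind(pa[shared_idx, , drop = FALSE], fresh)
  })
  ca <- gen_channel(params_a, pa, "A", derive_seed(seed %||% 0L, 3L))
  cb <- gen_channel(params_b, pb_own, "B", derive_seed(seed %||% 0L, 4L))

  # a B parent is shared iff its center equals some A parent center
  key <- function(m) paste(m[, 1], m[, 2])
  shared_b <- key(cb$parent_xy) %in% key(ca$parent_xy)

  n_a <- length(ca$x); n_b <- length(cb$x)
  locs <- loc_table(c(ca$x, cb$x), c(ca$y, cb$y),
                    channel = rep(channels, c(n_a, n_b)))
  truth <- data.frame(
    id = locs$id,
    molecule = c(paste0("A.m", ca$molecule), paste0("B.m", cb$molecule)),
    parent = c(ca$parent, cb$parent),
    channel = rep(channels, c(n_a, n_b)), stringsAsFactors = FALSE)
  parents <- rbind(
    data.frame(parent = ca$parent_ids, x = ca$parent_xy[, 1],
               y = ca$parent_xy[, 2], channel = channels[1],
               shared = key(ca$parent_xy) %in% key(cb$parent_xy),
               stringsAsFactors = FALSE),
    data.frame(parent = cb$parent_ids, x = cb$parent_xy[, 1],
               y = cb$parent_xy[, 2], channel = channels[2],
               shared = shared_b, stringsAsFactors = FALSE))
  new_scene(locs, truth, parents,
            list(model = "two_channel", params_a = params_a,
                 params_b = params_b, coloc_fraction = coloc_fraction,
                 blink_mean = blink_mean, sigma_loc = sigma_loc,
                 channels = channels, seed = seed))
}

#' Annular ROI approximating a nuclear envelope
#'
#' Builds a single non-convex polygon for the annulus between `r_inner`
#' and `r_outer`: the outer ring, a seam to the inner ring, the inner
#' ring traversed in reverse, and the seam back. For `n_vertices >= 64`
#' per ring the enclosed area is within 2\% of
#' `pi * (r_outer^2 - r_inner^2)`.
#'
#' @param center length-2 numeric, annulus center in nm.
#' @param r_inner,r_outer inner and outer radii, nm, `0 < r_inner <
#'   r_outer`.
#' @param n_vertices vertices per ring (>= 8).
#' @return A [roi_polygon()].
#' @export
ring_roi <- function(center = c(0, 0), r_inner, r_outer, n_vertices = 64) {
  if (!(r_inner > 0 && r_outer > r_inner))
    stop("need 0 < r_inner < r_outer", call. = FALSE)
  if (n_vertices < 8) stop("n_vertices must be >= 8", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ox <- center[1] + r_outer * cos(th); oy <- center[2] + r_outer * sin(th)
  ix <- center[1] + r_inner * cos(th); iy <- center[2] + r_inner * sin(th)
  rev_i <- c(1, rev(seq_len(n_vertices))[-n_vertices])  # 1, n, n-1, ..., 2
  roi_polygon(c(ox, ox[1], ix[rev_i], ix[1]),
              c(oy, oy[1], iy[rev_i], iy[1]))
}
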