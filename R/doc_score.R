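#' Nearest-neighbor distances between point sets
#'
#' Exact Euclidean distance from each query point to its nearest
#' reference point, computed with a uniform-grid spatial index.
#'
#' @param query,reference point sets: [loc_table()]s, data.frames with
#'   `x`/`y` columns, or 2-column matrices.
#' @param exclude_self if `TRUE`, `query` and `reference` are the same
#'   index-aligned set and each point's own entry is skipped, giving the
#'   distance to the nearest *other* point.
#' @return Numeric vector of distances in nm, one per query point.
#' @export
nearest_neighbor_distances <- function(query, reference,
                                       exclude_self = FALSE) {
  q <- coord_matrix(query)
  r <- coord_matrix(reference)
  if (exclude_self) {
    if (nrow(q) != nrow(r))
      stop("exclude_self requires index-aligned identical sets",
           call. = FALSE)
    if (nrow(r) < 2)
      stop("reference is empty after self-exclusion", call. = FALSE)
  } else if (nrow(r) < 1) {
    stop("reference point set is empty", call. = FALSE)
  }
  if (nrow(q) == 0) return(numeric(0))
  cpp_nnd(q[, 1], q[, 2], r[, 1], r[, 2], exclude_self)
}

# per-localization DoC scores in one direction:
# neighbor-count gradients at radii k*dr, area-normalized, rank-correlated
# between the same and the cross channel, damped by exp(-nnd / r_max)
doc_direction <- function(src, other, dr, r_max, threshold) {
  radii <- seq(dr, r_max, by = dr)
  K <- length(radii)
  n_same <- cpp_count_within(src[, 1], src[, 2], src[, 1], src[, 2],
                             radii, TRUE)
  n_cross <- cpp_count_within(src[, 1], src[, 2], other[, 1], other[, 2],
                              radii, FALSE)
  nnd <- cpp_nnd(src[, 1], src[, 2], other[, 1], other[, 2], FALSE)
  r2 <- radii^2
  n <- nrow(src)
  score <- numeric(n)
  for (i in seq_len(n)) {
    tot_s <- n_same[i, K]; tot_c <- n_cross[i, K]
    if (tot_s == 0 || tot_c == 0) next        # no gradient: neutral score
    # D(r_k) = (N(r_k)/N(R_max)) * R_max^2/r_k^2 is N(r_k)/r_k^2 times a
    # positive per-point constant, so the Spearman ranks are those of
    # N(r_k)/r_k^2; the single division keeps exact ties exactly tied
    d_s <- n_same[i, ] / r2
    d_c <- n_cross[i, ] / r2
    rho <- suppressWarnings(cor(d_s, d_c, method = "spearman"))
    if (is.na(rho)) next                      # zero-variance ranks: neutral
    score[i] <- rho * exp(-nnd[i] / r_max)
  }
  list(score = score, nnd = nnd,
       colocalized = score >= threshold)
}

#' Degree-of-colocalization (DoC) scores for a two-channel scene
#'
#' For every localization, same-channel and cross-channel neighbor counts
#' are taken in closed balls of radius `k * dr` up to `r_max`, normalized
#' by the count at `r_max` and by the ball area (`r_max^2 / r_k^2`). The
#' Spearman rank correlation between the two normalized gradients,
#' damped by `exp(-d_i / r_max)` with `d_i` the cross-channel
#' nearest-neighbor distance, is the localization's DoC score in
#' \[-1, 1\]. Scores are computed in both directions (A against B and B
#' against A). A localization with no same- or cross-channel neighbor
#' within `r_max`, or with a zero-variance rank vector, scores 0
#' (neutral).
#'
#' @param table a [loc_table()] holding both channels, or channel A only
#'   if `table_b` is given.
#' @param table_b optional second-channel [loc_table()].
#' @param dr radius step in nm.
#' @param r_max maximum radius in nm; must be a positive multiple of
#'   `dr`. No edge correction is applied at ROI boundaries, a known bias
#'   for points within `r_max` of the edge.
#' @param threshold score at or above which a localization is flagged
#'   colocalized ("interacting").
#' @return A `doc_result`: data.frame with columns `id`, `channel`,
#'   `direction`, `score`, `nnd`, `colocalized`, plus a `params`
#'   attribute.
#' @export
compute_doc <- function(table, table_b = NULL, dr = 20, r_max = 500,
                        threshold = 0.4) {
  if (dr <= 0 || r_max <= 0 || abs(r_max / dr - round(r_max / dr)) > 1e-9)
    stop("r_max must be a positive multiple of dr", call. = FALSE)
  if (is.null(table_b)) {
    chans <- attr(table, "channels") %||% sort(unique(table$channel))
    if (length(chans) != 2)
      stop("table must contain exactly two channels", call. = FALSE)
    a <- table[table$channel == chans[1], , drop = FALSE]
    b <- table[table$channel == chans[2], , drop = FALSE]
  } else {
    a <- table; b <- table_b
    chans <- c(unique(as.character(a$channel))[1] %||% "A",
               unique(as.character(b$channel))[1] %||% "B")
    if (is.na(chans[1])) chans[1] <- "A"
    if (is.na(chans[2])) chans[2] <- "B"
  }
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("both channels must be non-empty", call. = FALSE)
  ma <- coord_matrix(a); mb <- coord_matrix(b)
  fwd <- doc_direction(ma, mb, dr, r_max, threshold)
  rev <- doc_direction(mb, ma, dr, r_max, threshold)
  out <- rbind(
    data.frame(id = a$id %||% (seq_len(nrow(a)) - 1L), channel = chans[1],
               direction = paste0(chans[1], "->", chans[2]),
               score = fwd$score, nnd = fwd$nnd,
               colocalized = fwd$colocalized, stringsAsFactors = FALSE),
    data.frame(id = b$id %||% (seq_len(nrow(b)) - 1L), channel = chans[2],
               direction = paste0(chans[2], "->", chans[1]),
               score = rev$score, nnd = rev$nnd,
               colocalized = rev$colocalized, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  structure(out,
            params = list(dr = dr, r_max = r_max, threshold = threshold,
                          channels = chans),
            class = c("doc_result", "data.frame"))
}

#' Percent of colocalized localizations per direction
#'
#' The fraction of in-ROI localizations of each source channel whose DoC
#' score is at or above the threshold, times 100.
#'
#' @param result a `doc_result` from [compute_doc()].
#' @param threshold DoC score cutoff; defaults to the threshold stored in
#'   `result`.
#' @return Named numeric vector of percentages, one per direction.
#' @export
percent_colocalized <- function(result, threshold = NULL) {
  if (nrow(result) == 0) stop("empty DoC result", call. = FALSE)
  threshold <- threshold %||% attr(result, "params")$threshold %||% 0.4
  dirs <- unique(result$direction)
  out <- vapply(dirs, function(d) {
    s <- result$score[result$direction == d]
    100 * sum(s >= threshold) / length(s)
  }, numeric(1))
  names(out) <- dirs
  out
}

#' Histogram counts of DoC scores per direction
#'
#' Fixed-width binning over \[-1, 1\] for score-distribution plots.
#'
#' @param result a `doc_result`.
#' @param bin_width histogram bin width.
#' @return data.frame with `direction`, bin `mid`, and normalized
#'   `frequency` (sums to 1 within each direction).
#' @export
doc_histogram <- function(result, bin_width = 0.05) {
  edges <- seq(-1, 1, by = bin_width)
  do.call(rbind, lapply(unique(result$direction), function(d) {
    s <- result$score[result$direction == d]
    idx <- findInterval(s, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = length(edges) - 1)
    data.frame(direction = d,
               mid = (edges[-1] + edges[-length(edges)]) / 2,
               frequency = counts / sum(counts),
               stringsAsFactors = FALSE)
  }))
}
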