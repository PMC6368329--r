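#' DBSCAN cluster labels
#'
#' Density-based clustering with deterministic label assignment: a core
#' point has at least `min_pts` neighbors within `eps` (counting itself);
#' clusters are connected components of core points; border points join
#' the cluster of the lowest-id core point within reach; everything else
#' is noise.
#'
#' @param points a point set ([loc_table()], data.frame with `x`/`y`, or
#'   2-column matrix).
#' @param eps neighborhood radius in nm (> 0).
#' @param min_pts minimum neighbors (including self) for a core point.
#' @return Integer vector of labels: 0 for noise, clusters numbered from
#'   1 in order of their lowest core-point index.
#' @export
dbscan <- function(points, eps, min_pts) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (min_pts < 1) stop("min_pts must be >= 1", call. = FALSE)
  m <- coord_matrix(points)
  if (nrow(m) == 0) return(integer(0))
  cpp_dbscan(m[, 1], m[, 2], eps, as.integer(min_pts))
}

#' Convex-hull contour and area of a cluster
#'
#' The convex hull of a cluster's member localizations defines its
#' contour; the shoelace formula on the hull gives the cluster area.
#'
#' @param coords 2-column matrix or data.frame of member coordinates, nm.
#' @return List with `area` (nm^2), `contour` (hull vertices in
#'   counterclockwise order) and `degenerate` (`TRUE` when all members
#'   are collinear, area 0).
#' @export
cluster_area <- function(coords) {
  m <- coord_matrix(coords)
  if (nrow(m) < 3)
    return(list(area = 0, contour = m, degenerate = TRUE))
  h <- chull(m[, 1], m[, 2])
  hull <- m[h, , drop = FALSE]
  area <- shoelace_area(hull[, 1], hull[, 2])
  if (area < 0) {  # enforce counterclockwise contour order
    hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
    area <- -area
  }
  list(area = area, contour = hull, degenerate = !(area > 0))
}

#' Build cluster records from DBSCAN labels
#'
#' Applies the per-channel minimum-size thresholds that define a true
#' cluster (default: at least 5 localizations for "5-LO", at least 10 for
#' "FLAP" — the higher FLAP threshold reflects its homotrimeric
#' stoichiometry) and computes convex-hull area and density for each
#' retained cluster. Degenerate (collinear) clusters are retained for
#' counting and classification but carry `NA` density.
#'
#' @param labels integer labels from [dbscan()] for this channel's
#'   points, in table order.
#' @param table the channel's [loc_table()] (single channel).
#' @param channel channel name; must appear in `min_locs`.
#' @param min_locs named integer vector of per-channel minimum cluster
#'   sizes.
#' @return List of `cluster_record`s: `id`, `channel`, `members`
#'   (localization ids), `coords`, `contour`, `area`, `n_locs`,
#'   `density`, `degenerate`.
#' @export
make_clusters <- function(labels, table, channel,
                          min_locs = c("5-LO" = 5, "FLAP" = 10)) {
  if (!channel %in% names(min_locs))
    stop("config error: channel '", channel,
         "' has no entry in min_locs", call. = FALSE)
  stopifnot(length(labels) == nrow(table))
  keep_min <- min_locs[[channel]]
  out <- list()
  for (lab in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == lab)
    if (length(idx) < keep_min) next
    coords <- cbind(table$x[idx], table$y[idx])
    ca <- cluster_area(coords)
    out[[length(out) + 1]] <- structure(list(
      id = lab, channel = channel, members = table$id[idx],
      coords = coords, contour = ca$contour, area = ca$area,
      n_locs = length(idx),
      density = if (ca$degenerate) NA_real_ else length(idx) / ca$area,
      degenerate = ca$degenerate), class = "cluster_record")
  }
  out
}

#' Classify a cluster by its interacting-localization count
#'
#' Counts the cluster's own (founding-channel) members whose DoC score is
#' at or above `doc_threshold` and assigns the interaction class:
#' `NIC` (no interaction, 0 interacting members), `LIC` (low, 1 to
#' `hic_min - 1`), or `HIC` (high, `hic_min` or more).
#'
#' @param cluster a `cluster_record` from [make_clusters()].
#' @param doc a `doc_result` from [compute_doc()] covering the cluster's
#'   channel.
#' @param doc_threshold DoC cutoff defining an interacting localization.
#' @param hic_min minimum interacting members for the HIC class.
#' @return The cluster with `n_interacting` and `class` filled in.
#' @export
classify_interaction <- function(cluster, doc, doc_threshold = 0.4,
                                 hic_min = 5) {
  if (hic_min < 1) stop("hic_min must be >= 1", call. = FALSE)
  sc <- doc[doc$channel == cluster$channel, , drop = FALSE]
  pos <- match(cluster$members, sc$id)
  if (anyNA(pos))
    stop("validation error: ", sum(is.na(pos)),
         " cluster member(s) lack a DoC score", call. = FALSE)
  n_int <- sum(sc$score[pos] >= doc_threshold)
  cluster$n_interacting <- n_int
  cluster$class <- if (n_int == 0) "NIC"
                   else if (n_int < hic_min) "LIC"
                   else "HIC"
  cluster
}

#' Relative density of a cluster
#'
#' The local density within `r_local` of each member, averaged over
#' members, divided by the cluster's average density `n_locs / area`.
#' The focal member is not counted in its own neighborhood, making the
#' local density an unbiased estimate: internally uniform clusters score
#' near 1 regardless of size, while concentration hotspots score well
#' above 1.
#'
#' @param cluster a non-degenerate `cluster_record`.
#' @param r_local local neighborhood radius in nm.
#' @return The cluster with `relative_density` filled in (`NA` and a
#'   warning for degenerate clusters).
#' @export
relative_density <- function(cluster, r_local = 20) {
  if (isTRUE(cluster$degenerate) || !(cluster$area > 0)) {
    cluster$relative_density <- NA_real_
    warning("relative density undefined for degenerate cluster ",
            cluster$id, call. = FALSE)
    return(cluster)
  }
  m <- cluster$coords
  counts <- cpp_count_within(m[, 1], m[, 2], m[, 1], m[, 2],
                             r_local, TRUE)[, 1]
  rho_local <- counts / (pi * r_local^2)
  rho_bar <- cluster$n_locs / cluster$area
  cluster$relative_density <- mean(rho_local) / rho_bar
  cluster
}

#' Detect, filter and classify clusters for one channel
#'
#' Convenience wrapper chaining [dbscan()], [make_clusters()],
#' [classify_interaction()] and [relative_density()].
#'
#' @param table two-channel or single-channel [loc_table()].
#' @param doc a `doc_result` for the same localizations.
#' @param channel channel to cluster.
#' @param eps,min_pts DBSCAN parameters (nm, count).
#' @inheritParams make_clusters
#' @inheritParams classify_interaction
#' @inheritParams relative_density
#' @return List of fully annotated `cluster_record`s.
#' @export
detect_clusters <- function(table, doc, channel, eps = 20, min_pts = 3,
                            min_locs = c("5-LO" = 5, "FLAP" = 10),
                            doc_threshold = 0.4, hic_min = 5,
                            r_local = 20) {
  sub <- table[table$channel == channel, , drop = FALSE]
  labels <- dbscan(sub, eps, min_pts)
  cls <- make_clusters(labels, sub, channel, min_locs)
  lapply(cls, function(cl) {
    cl <- classify_interaction(cl, doc, doc_threshold, hic_min)
    suppressWarnings(relative_density(cl, r_local))
  })
}

#' Per-ROI cluster summary
#'
#' Counts clusters per interaction class and averages their metrics, and
#' computes, per channel, the percent of all interacting localizations
#' (DoC score at or above threshold) that are members of retained
#' clusters. With no interacting localizations in a channel the
#' percentage is undefined and reported as `NA`, not 0.
#'
#' @param clusters list of classified `cluster_record`s (both channels
#'   pooled is fine).
#' @param doc the `doc_result` used for classification.
#' @param doc_threshold DoC cutoff for an interacting localization.
#' @return A `roi_summary` list: `per_class` data.frame (class, n
#'   clusters, mean area over non-degenerate clusters, mean n_locs and
#'   mean relative density per channel) and `percent_interacting_in_clusters`
#'   named by channel.
#' @export
roi_summary <- function(clusters, doc, doc_threshold = NULL) {
  doc_threshold <- doc_threshold %||% attr(doc, "params")$threshold %||% 0.4
  classes <- c("NIC", "LIC", "HIC")
  channels <- unique(doc$channel)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    sel <- Filter(function(c) identical(c$class, cl), clusters)
    areas <- vapply(sel, function(c) if (c$degenerate) NA_real_ else c$area,
                    numeric(1))
    row <- data.frame(class = cl, n_clusters = length(sel),
                      mean_area = if (length(sel)) mean(areas, na.rm = TRUE)
                                  else NA_real_,
                      stringsAsFactors = FALSE)
    for (ch in channels) {
      chs <- Filter(function(c) identical(c$channel, ch), sel)
      row[[paste0("mean_n_locs.", ch)]] <-
        if (length(chs)) mean(vapply(chs, `[[`, numeric(1), "n_locs"))
        else NA_real_
      rd <- vapply(chs, function(c) c$relative_density %||% NA_real_,
                   numeric(1))
      row[[paste0("mean_relative_density.", ch)]] <-
        if (length(chs) && any(!is.na(rd))) mean(rd, na.rm = TRUE)
        else NA_real_
    }
    row
  }))
  pct <- vapply(channels, function(ch) {
    sc <- doc[doc$channel == ch, , drop = FALSE]
    interacting <- sc$id[sc$score >= doc_threshold]
    if (length(interacting) == 0) return(NA_real_)
    members <- unlist(lapply(
      Filter(function(c) identical(c$channel, ch), clusters),
      `[[`, "members"))
    100 * sum(interacting %in% members) / length(interacting)
  }, numeric(1))
  names(pct) <- channels
  structure(list(per_class = per_class,
                 percent_interacting_in_clusters = pct),
            class = "roi_summary")
}

#' Aggregate per-ROI summaries across ROIs
#'
#' Averages class-level metrics over ROIs and flags classes contributed
#' to by fewer than `min_rois` ROIs, which are conventionally excluded
#' from downstream comparisons.
#'
#' @param summaries list of [roi_summary()] objects.
#' @param min_rois minimum number of contributing ROIs for a class to be
#'   usable.
#' @return data.frame of per-class means across ROIs with an `excluded`
#'   flag.
#' @export
aggregate_roi_summaries <- function(summaries, min_rois = 3) {
  classes <- c("NIC", "LIC", "HIC")
  do.call(rbind, lapply(classes, function(cl) {
    rows <- lapply(summaries, function(s)
      s$per_class[s$per_class$class == cl, , drop = FALSE])
    counts <- vapply(rows, function(r) r$n_clusters, numeric(1))
    contributing <- sum(counts > 0)
    data.frame(class = cl,
               mean_clusters_per_roi = mean(counts),
               contributing_rois = contributing,
               excluded = contributing < min_rois,
               stringsAsFactors = FALSE)
  }))
}

#' Estimate trimer count from a localization count
#'
#' For a protein functioning as a homotrimer, a cluster of `n`
#' localizations corresponds to at most `floor(n / 3)` trimers (an upper
#' bound on complexes, since blinking makes localizations outnumber
#' molecules).
#'
#' @param n_locs non-negative localization count(s).
#' @return Integer trimer count(s), `floor(n_locs / 3)`.
#' @export
estimate_trimers <- function(n_locs) {
  if (any(n_locs < 0)) stop("n_locs must be >= 0", call. = FALSE)
  as.integer(floor(n_locs / 3))
}
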