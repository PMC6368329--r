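#' Describe the column layout of a localization text file
#'
#' Localization tables exported by acquisition software differ in column
#' names and units, so the reader is driven by a small dialect object
#' mapping the file's columns onto the fields the package needs. Columns
#' may be referenced by header name or by 1-based index.
#'
#' @param x,y column name or index of the x / y coordinate.
#' @param channel column name or index of the channel label, or `NULL` if
#'   the file holds a single unlabeled channel (all rows are then assigned
#'   `default_channel`).
#' @param frame column name or index of the acquisition frame, or `NULL`
#'   (frame 0 is then assigned).
#' @param scale multiplicative factor converting file coordinates to
#'   nanometres (e.g. `1000` for files in micrometres).
#' @param sep field separator; localization exports are tab-delimited.
#' @param default_channel channel label used when `channel` is `NULL`.
#' @return A `loc_dialect` list understood by [read_localizations()].
#' @export
loc_dialect <- function(x = "X", y = "Y", channel = "Channel",
                        frame = "Frame", scale = 1, sep = "\t",
                        default_channel = "ch1") {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  structure(list(x = x, y = y, channel = channel, frame = frame,
                 scale = scale, sep = sep,
                 default_channel = default_channel),
            class = "loc_dialect")
}

#' Construct a localization table
#'
#' The universal input record of the package: one row per localization
#' with coordinates in nanometres, a channel label, the acquisition frame
#' and a unique integer id.
#'
#' @param x,y numeric coordinates in nm; must be finite.
#' @param channel character channel labels; at most two distinct values.
#' @param frame non-negative integer acquisition frames.
#' @param id unique integer ids; defaults to `0:(n-1)`.
#' @return A data.frame of class `loc_table` with columns
#'   `id`, `x`, `y`, `channel`, `frame` and a `channels` attribute holding
#'   the declared channel set.
#' @export
loc_table <- function(x, y, channel = "ch1", frame = 0L,
                      id = seq_along(x) - 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  channel <- rep_len(as.character(channel), n)
  frame <- rep_len(as.integer(frame), n)
  id <- as.integer(id)
  if (n > 0) {
    if (!all(is.finite(x)) || !all(is.finite(y)))
      stop("all coordinates must be finite", call. = FALSE)
    if (anyDuplicated(id))
      stop("localization ids must be unique", call. = FALSE)
    if (any(frame < 0)) stop("frames must be non-negative", call. = FALSE)
  }
  chans <- sort(unique(channel))
  if (length(chans) > 2)
    stop("at most two channels are supported; got: ",
         paste(chans, collapse = ", "), call. = FALSE)
  out <- data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                    channel = channel, frame = frame,
                    stringsAsFactors = FALSE)
  structure(out, channels = chans, class = c("loc_table", "data.frame"))
}

#' Read a localization table from a delimited text file
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [loc_dialect()] mapping file columns to fields and
#'   giving the unit scale.
#' @return A [loc_table()] with coordinates in nm and ids assigned
#'   sequentially from 0 in file order.
#' @details A mapped column missing from the file is a format error. A
#'   non-finite or non-numeric coordinate is a row-level parse error
#'   naming the offending data row.
#' @export
read_localizations <- function(path, dialect = loc_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = dialect$sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  pick <- function(col, what) {
    if (is.null(col)) return(NULL)
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(raw))
        stop("format error: no column ", col, " for field '", what,
             "' in ", path, call. = FALSE)
      return(raw[[col]])
    }
    if (!col %in% names(raw))
      stop("format error: mapped column '", col, "' (field '", what,
           "') not found in ", path, call. = FALSE)
    raw[[col]]
  }
  xs <- pick(dialect$x, "x")
  ys <- pick(dialect$y, "y")
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(out))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s coordinate '%s' at row %d",
                   what, v[bad[1]], bad[1]), call. = FALSE)
    out
  }
  x <- num(xs, "x") * dialect$scale
  y <- num(ys, "y") * dialect$scale
  ch <- pick(dialect$channel, "channel") %||%
    rep(dialect$default_channel, length(x))
  fr <- pick(dialect$frame, "frame")
  fr <- if (is.null(fr)) rep(0L, length(x)) else {
    f <- suppressWarnings(as.integer(as.numeric(fr)))
    f[is.na(f)] <- 0L
    f
  }
  loc_table(x, y, channel = ch, frame = fr)
}

#' Write a localization table as tab-delimited text
#'
#' Writes the dialect the reader accepts by default
#' (`X`, `Y`, `Channel`, `Frame` columns, nm units).
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  out <- data.frame(X = table$x, Y = table$y, Channel = table$channel,
                    Frame = table$frame)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Construct a region-of-interest polygon
#'
#' A simple polygon in nm (implicit closure from the last vertex to the
#' first) delimiting the analysis region, typically drawn around the
#' nuclear envelope. Vertices must enclose a strictly positive area and
#' edges may not properly cross (edges that merely touch or overlap, as in
#' the seam of an annulus, are allowed).
#'
#' @param x,y numeric vertex coordinates in nm, at least 3 vertices.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("polygon vertices must be finite", call. = FALSE)
  if (polygon_self_intersects(x, y))
    stop("polygon edges cross: self-intersecting ROI", call. = FALSE)
  area <- shoelace_area(x, y)
  if (abs(area) <= 0)
    stop("degenerate polygon: enclosed area is zero", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("ROI polygon: %d vertices, area %.6g nm^2\n",
              length(x$x), polygon_area(x)))
  invisible(x)
}

#' Enclosed area of an ROI polygon
#'
#' Absolute shoelace area; for an annulus built with a seam this is the
#' outer area minus the hole.
#'
#' @param roi a [roi_polygon()].
#' @return Area in nm^2.
#' @export
polygon_area <- function(roi) abs(shoelace_area(roi$x, roi$y))

# TRUE if any two non-adjacent edges properly cross (transversal
# intersection of their interiors). Shared endpoints and collinear
# overlaps -- e.g. the seam of an annulus polygon -- are not crossings.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex), incl. the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      o1 <- orient(x[i], y[i], x2[i], y2[i], x[j], y[j])
      o2 <- orient(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      o3 <- orient(x[j], y[j], x2[j], y2[j], x[i], y[i])
      o4 <- orient(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

#' Test points for polygon membership (boundary-inclusive)
#'
#' Crossing-number test with an explicit on-segment check, so points on
#' the polygon boundary count as inside. Works for non-convex polygons,
#' including seam-constructed annuli.
#'
#' @param px,py numeric point coordinates in nm.
#' @param roi a [roi_polygon()].
#' @return Logical vector, `TRUE` for points inside or on the boundary.
#' @export
points_in_polygon <- function(px, py, roi) {
  vx <- roi$x; vy <- roi$y
  n <- length(vx)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  scale <- max(abs(c(vx, vy)), 1)
  tol <- 1e-9 * scale
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment: zero cross product and within the segment's bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on <- abs(cross) <= tol * max(abs(x2 - x1) + abs(y2 - y1), 1) &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    boundary <- boundary | on
    # half-open crossing rule avoids double-counting ray-through-vertex
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | boundary
}

#' Restrict a localization table to an ROI
#'
#' Keeps localizations inside or on the boundary of the polygon; ids are
#' preserved. Filtering is idempotent.
#'
#' @param table a [loc_table()].
#' @param roi a [roi_polygon()].
#' @return The filtered [loc_table()].
#' @export
filter_by_roi <- function(table, roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  if (nrow(table) == 0) return(table)
  keep <- points_in_polygon(table$x, table$y, roi)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, channels = attr(table, "channels"),
            class = c("loc_table", "data.frame"))
}

#' Read / write ROI vertex files
#'
#' ROI files hold one `x<TAB>y` vertex pair per line, in nm, no header.
#'
#' @param path file path.
#' @return [read_roi()] returns a [roi_polygon()]; [write_roi()] returns
#'   `path` invisibly.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- read.delim(path, header = FALSE, sep = "\t")
  if (ncol(m) < 2) stop("ROI file must have two tab-separated columns",
                        call. = FALSE)
  roi_polygon(as.numeric(m[[1]]), as.numeric(m[[2]]))
}

#' @rdname read_roi
#' @param roi a [roi_polygon()].
#' @export
write_roi <- function(roi, path) {
  write.table(data.frame(roi$x, roi$y), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a cluster table as CSV
#'
#' One row per cluster: id, channel, member count, interacting-member
#' count, interaction class, convex-hull area (nm^2), density (locs/nm^2)
#' and relative density. Numeric values round-trip through
#' [read_cluster_table()] to within 1e-6 relative.
#'
#' @param clusters a list of cluster records (see [make_clusters()]) or a
#'   data.frame in the output schema.
#' @param path output path.
#' @return `path` invisibly; [read_cluster_table()] returns a data.frame.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- if (is.data.frame(clusters)) clusters else cluster_table(clusters)
  ok <- tryCatch(write.csv(format_numeric(df), path, row.names = FALSE,
                           quote = FALSE),
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e),
                                          call. = FALSE))
  invisible(path)
}

# full-precision formatting so areas survive a round trip
format_numeric <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
  df
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Flatten cluster records into the cluster-table data.frame schema
#'
#' @param clusters list of cluster records.
#' @return data.frame with one row per cluster.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0)
    return(data.frame(id = integer(), channel = character(),
                      n_locs = integer(), n_interacting = integer(),
                      class = character(), area = numeric(),
                      density = numeric(), relative_density = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(id = cl$id, channel = cl$channel, n_locs = cl$n_locs,
               n_interacting = cl$n_interacting %||% NA_integer_,
               class = cl$class %||% NA_character_,
               area = cl$area,
               density = cl$density,
               relative_density = cl$relative_density %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
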