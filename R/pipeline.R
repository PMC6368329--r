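#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the package end to end: read (or simulate) a two-channel
#' localization table and ROI, restrict to the ROI, then run the
#' requested tracks — `"clusdoc"` (DoC scoring, DBSCAN clusters,
#' NIC/LIC/HIC classification, per-ROI summary) and/or `"vbms"`
#' (unbiased variable-bandwidth mean-shift clusters) — and write all
#' outputs plus a machine-readable run manifest. The configuration is
#' validated before any computation, and outputs are written only after
#' all computation succeeds, so a failing run leaves no partial outputs.
#'
#' @param config nested list (or path to a JSON/YAML file) with entries:
#'   \describe{
#'     \item{input}{`list(localizations =, roi =)` file paths, or
#'       `list(simulate = list(...))` with [simulate_two_channel()]
#'       arguments plus `region = list(center, r_inner, r_outer)`.}
#'     \item{tracks}{character subset of `c("clusdoc", "vbms")`.}
#'     \item{params}{optional overrides: `dr`, `r_max`, `doc_threshold`,
#'       `eps`, `min_pts`, `min_locs`, `hic_min`, `r_local`, `fixed_h`,
#'       `trunc_factor`, `min_size`, `bandwidth_mode`, `vbms_channel`.}
#'     \item{seed}{integer seed for simulated inputs.}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @param out_dir overrides `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return Invisibly, the result bundle: the filtered table, `doc`,
#'   `clusters`, `summary`, `vbms`, and `manifest` with the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- read_config(config)
  cfg <- validate_config(config, out_dir = out_dir, seed = seed)

  # ---- inputs ----
  if (!is.null(cfg$input$simulate)) {
    sim <- cfg$input$simulate
    region <- do.call(ring_roi, sim$region)
    args <- sim[setdiff(names(sim), "region")]
    args$region <- region
    args$seed <- args$seed %||% cfg$seed
    for (side in c("params_a", "params_b"))
      if (!is.null(args[[side]]))
        args[[side]] <- do.call(channel_params, args[[side]])
    scene <- do.call(simulate_two_channel, args)
    table <- scene$locs
    roi <- region
  } else {
    table <- read_localizations(cfg$input$localizations,
                                dialect = cfg$dialect)
    roi <- read_roi(cfg$input$roi)
    scene <- NULL
  }
  table <- filter_by_roi(table, roi)
  if (nrow(table) == 0) stop("no localizations inside ROI", call. = FALSE)
  p <- cfg$params
  chans <- attr(table, "channels")

  # ---- compute ----
  out <- list(table = table)
  if ("clusdoc" %in% cfg$tracks) {
    doc <- compute_doc(table, dr = p$dr, r_max = p$r_max,
                       threshold = p$doc_threshold)
    clusters <- unlist(lapply(intersect(chans, names(p$min_locs)),
      function(ch) detect_clusters(table, doc, ch, eps = p$eps,
                                   min_pts = p$min_pts,
                                   min_locs = p$min_locs,
                                   doc_threshold = p$doc_threshold,
                                   hic_min = p$hic_min,
                                   r_local = p$r_local)),
      recursive = FALSE)
    out$doc <- doc
    out$clusters <- clusters
    out$summary <- roi_summary(clusters, doc, p$doc_threshold)
  }
  if ("vbms" %in% cfg$tracks) {
    ch <- p$vbms_channel %||% chans[1]
    sub <- table[table$channel == ch, , drop = FALSE]
    out$vbms <- vbms_cluster(sub, bandwidth_mode = p$bandwidth_mode,
                             fixed_h = p$fixed_h,
                             trunc_factor = p$trunc_factor,
                             min_size = p$min_size)
    out$vbms_channel <- ch
  }

  # ---- write ----
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(scene)) {
    paths$localizations <- file.path(cfg$out_dir, "localizations.txt")
    write_localizations(scene$locs, paths$localizations)
    paths$roi <- file.path(cfg$out_dir, "roi.txt")
    write_roi(roi, paths$roi)
    paths$ground_truth <- file.path(cfg$out_dir, "ground_truth.csv")
    write.csv(scene$truth, paths$ground_truth, row.names = FALSE)
  }
  if (!is.null(out$doc)) {
    paths$doc_scores <- file.path(cfg$out_dir, "doc_scores.csv")
    write.csv(as.data.frame(out$doc), paths$doc_scores, row.names = FALSE)
    paths$clusters <- file.path(cfg$out_dir, "clusters.csv")
    write_cluster_table(out$clusters, paths$clusters)
    paths$summary <- file.path(cfg$out_dir, "summary.json")
    jsonlite::write_json(list(
      percent_colocalized = as.list(percent_colocalized(out$doc)),
      percent_interacting_in_clusters =
        as.list(out$summary$percent_interacting_in_clusters),
      per_class = out$summary$per_class),
      paths$summary, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(out$vbms)) {
    paths$vbms_clusters <- file.path(cfg$out_dir, "vbms_clusters.csv")
    write.csv(format_numeric(out$vbms$clusters), paths$vbms_clusters,
              row.names = FALSE, quote = FALSE)
    paths$vbms_assignment <- file.path(cfg$out_dir, "vbms_assignment.csv")
    sub <- out$table[out$table$channel == out$vbms_channel, , drop = FALSE]
    write.csv(data.frame(id = sub$id, cluster = out$vbms$assignment),
              paths$vbms_assignment, row.names = FALSE)
  }
  manifest <- list(package = "nanocluscol",
                   version = as.character(packageVersion("nanocluscol")),
                   seed = cfg$seed, tracks = cfg$tracks,
                   params = cfg$params, outputs = paths,
                   timestamp = format(Sys.time(), tz = "UTC"))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  out$manifest <- manifest
  out$paths <- paths
  invisible(out)
}

#' Read a pipeline configuration file
#'
#' Parses a JSON (default) or YAML (`.yaml`/`.yml`, requires the yaml
#' package) configuration for [run_pipeline()].
#'
#' @param path configuration file path.
#' @return The configuration as a nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

default_params <- function() {
  list(dr = 20, r_max = 500, doc_threshold = 0.4,
       eps = 20, min_pts = 3, min_locs = c("5-LO" = 5, "FLAP" = 10),
       hic_min = 5, r_local = 20,
       bandwidth_mode = "fixed", fixed_h = 250, trunc_factor = 4,
       min_size = 4, vbms_channel = NULL)
}

# config errors must surface before any computation or output
validate_config <- function(config, out_dir = NULL, seed = NULL) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  cfg <- config
  cfg$out_dir <- out_dir %||% cfg$out_dir %||%
    stop("config error: out_dir is required", call. = FALSE)
  cfg$seed <- seed %||% cfg$seed
  cfg$tracks <- cfg$tracks %||% c("clusdoc", "vbms")
  bad <- setdiff(cfg$tracks, c("clusdoc", "vbms"))
  if (length(bad))
    stop("config error: unknown track(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p <- default_params()
  for (nm in names(cfg$params)) {
    if (!nm %in% names(p))
      stop("config error: unknown parameter '", nm, "'", call. = FALSE)
    p[[nm]] <- cfg$params[[nm]]
  }
  if (!is.null(p$min_locs)) p$min_locs <- unlist(p$min_locs)
  if (p$hic_min < 1)
    stop("config error: hic_min must be >= 1", call. = FALSE)
  if (p$doc_threshold < -1 || p$doc_threshold > 1)
    stop("config error: doc_threshold must be in [-1, 1]", call. = FALSE)
  if (p$eps <= 0 || p$r_max <= 0 || p$dr <= 0 || p$fixed_h <= 0)
    stop("config error: length parameters must be positive", call. = FALSE)
  cfg$params <- p
  if (is.null(cfg$input) ||
      (is.null(cfg$input$simulate) &&
       (is.null(cfg$input$localizations) || is.null(cfg$input$roi))))
    stop("config error: input must name localizations + roi files or a ",
         "simulate block", call. = FALSE)
  if (!is.null(cfg$input$localizations) &&
      !file.exists(cfg$input$localizations))
    stop("config error: input file not found: ",
         cfg$input$localizations, call. = FALSE)
  if (!is.null(cfg$input$roi) && !file.exists(cfg$input$roi))
    stop("config error: ROI file not found: ", cfg$input$roi,
         call. = FALSE)
  cfg$dialect <- if (is.null(cfg$dialect)) loc_dialect()
                 else do.call(loc_dialect, cfg$dialect)
  cfg
}
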