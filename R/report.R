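#' Point-weighted histogram of cluster properties
#'
#' Each cluster contributes its weight (typically its localization
#' count) rather than 1, so the histogram reflects where the
#' localizations are, not where the clusters are. Bins are
#' `[edge_b, edge_b+1)` with the last bin closed on the right;
#' frequencies are normalized to sum to 1 over the in-range weight.
#' Values outside the edges are accumulated in an overflow tally and
#' reported with a message.
#'
#' @param values per-cluster property values (e.g. area, n_locs).
#' @param weights positive per-cluster weights, same length.
#' @param edges increasing bin edges; `NULL` for automatic
#'   Freedman-Diaconis edges on the weighted sample.
#' @return A `weighted_histogram` list: `edges`, `frequency` (sums to
#'   1), `total_weight` (in-range), `overflow_weight`.
#' @export
weighted_histogram <- function(values, weights, edges = NULL) {
  if (length(values) == 0)
    stop("empty input to weighted_histogram", call. = FALSE)
  if (length(values) != length(weights))
    stop("values and weights must have equal length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  edges <- edges %||% fd_edges(values, weights)
  stopifnot(length(edges) >= 2, !is.unsorted(edges))
  # findInterval with rightmost.closed keeps the last edge in the last
  # bin; index 0 (below) or length(edges) (above) is out of range
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  out_of_range <- idx == 0 | idx == length(edges)
  overflow <- sum(weights[out_of_range])
  if (overflow > 0)
    message(sum(out_of_range), " value(s) outside histogram edges; ",
            "weight ", format(overflow), " tallied as overflow")
  freq <- numeric(length(edges) - 1)
  keep <- !out_of_range
  if (!any(keep)) stop("all values fall outside the edges", call. = FALSE)
  acc <- tapply(weights[keep], factor(idx[keep],
                                      levels = seq_len(length(edges) - 1)),
                sum, default = 0)
  total <- sum(weights[keep])
  structure(list(edges = edges, frequency = as.numeric(acc) / total,
                 total_weight = total, overflow_weight = overflow),
            class = "weighted_histogram")
}

# Freedman-Diaconis bin width on the weight-expanded sample
fd_edges <- function(values, weights) {
  n_eff <- sum(weights)^2 / sum(weights^2)
  qs <- weighted_quantile(values, weights, c(0.25, 0.75))
  width <- 2 * (qs[2] - qs[1]) / n_eff^(1 / 3)
  if (!(width > 0)) width <- diff(range(values)) / 10
  if (!(width > 0)) width <- 1
  lo <- min(values); hi <- max(values)
  seq(lo, hi + width, by = width)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Compare groups of cluster metrics
#'
#' Off-the-shelf group statistics used by the reporting layer:
#' Welch's unequal-variance t test (`welch_t`, 2 groups),
#' one-way ANOVA with Bonferroni-adjusted pairwise t tests
#' (`anova_bonferroni`; pairwise p-values are multiplied by the number
#' of comparisons and capped at 1), one-way ANOVA with Tukey's HSD
#' (`anova_tukey`), and the two-sample Kolmogorov-Smirnov test (`ks`,
#' 2 groups).
#'
#' @param samples named list of 2 or more numeric vectors, each of
#'   length at least 2.
#' @param method one of `"welch_t"`, `"anova_bonferroni"`,
#'   `"anova_tukey"`, `"ks"`.
#' @return List with `method`, `statistic`, `p_value`, and for the
#'   ANOVA methods a `pairwise` data.frame of adjusted p-values.
#' @export
compare_groups <- function(samples,
                           method = c("welch_t", "anova_bonferroni",
                                      "anova_tukey", "ks")) {
  method <- match.arg(method)
  if (!is.list(samples) || length(samples) < 2)
    stop("samples must be a list of at least 2 groups", call. = FALSE)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  for (nm in names(samples))
    if (length(samples[[nm]]) < 2)
      stop("validation error: group '", nm,
           "' has fewer than 2 values", call. = FALSE)
  two <- function() {
    if (length(samples) != 2)
      stop(method, " requires exactly 2 groups", call. = FALSE)
  }
  if (method == "welch_t") {
    two()
    ht <- t.test(samples[[1]], samples[[2]], var.equal = FALSE)
    return(list(method = method, statistic = unname(ht$statistic),
                df = unname(ht$parameter), p_value = ht$p.value))
  }
  if (method == "ks") {
    two()
    ht <- suppressWarnings(ks.test(samples[[1]], samples[[2]]))
    return(list(method = method, statistic = unname(ht$statistic),
                p_value = ht$p.value))
  }
  value <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), lengths(samples)))
  fit <- aov(value ~ group)
  tab <- anova(fit)
  res <- list(method = method, statistic = tab[["F value"]][1],
              p_value = tab[["Pr(>F)"]][1])
  if (method == "anova_bonferroni") {
    pw <- pairwise.t.test(value, group, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)
    p <- pw$p.value
    pairs <- which(!is.na(p), arr.ind = TRUE)
    res$pairwise <- data.frame(
      group1 = rownames(p)[pairs[, 1]],
      group2 = colnames(p)[pairs[, 2]],
      p_adj = p[pairs], stringsAsFactors = FALSE)
  } else {
    tk <- TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    res$pairwise <- data.frame(
      group1 = vapply(nm, `[`, character(1), 1),
      group2 = vapply(nm, `[`, character(1), 2),
      estimate = tk[, "diff"], p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE)
    rownames(res$pairwise) <- NULL
  }
  res
}
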