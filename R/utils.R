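# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All simulator entry points draw inside this scope so that
# identical seed + parameters give byte-identical scenes.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a deterministic sub-stream seed from a base seed and an integer
# offset, kept inside 32-bit signed range. Adding later sub-streams never
# perturbs draws made from earlier ones.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + 104729 * offset) %% 2147483647)
}

# Extract an n x 2 coordinate matrix from a localization table, plain
# data.frame with x/y columns, or 2-column matrix.
coord_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    return(unname(points[, 1:2, drop = FALSE]))
  }
  if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points)))
      stop("points must have 'x' and 'y' columns", call. = FALSE)
    return(cbind(points$x, points$y))
  }
  stop("points must be a matrix or data.frame with x/y columns",
       call. = FALSE)
}

# Signed shoelace area of a closed polygon (implicit closure last->first);
# positive for counterclockwise vertex order.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
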