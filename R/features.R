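# Multi-scale feature construction: the scale ladder, focal-mean stacks,
# point extraction and the collinearity filter. Scale-tagged columns are
# named "var@scale" (e.g. "bio17@28000") throughout the package.

#' Default scale ladders
#'
#' `"full"` is the eight-step field ladder 3,500–28,000 m used on real
#' landscapes; `"reduced"` is a desk-scale ladder 270–2,430 m matched to the
#' default 300 x 300 synthetic landscape at 90 m; `"density"` is the line
#' density radius set (1–4 km).
#'
#' @param which One of `"full"`, `"reduced"`, `"density"`.
#' @return Numeric vector of radii in metres, strictly increasing.
#' @export
default_scales <- function(which = c("full", "reduced", "density")) {
  switch(match.arg(which),
         full = 3500 * (1:8),
         reduced = 90 * c(3, 6, 9, 12, 15, 18, 21, 27),
         density = c(1000, 2000, 3000, 4000))
}

scale_col <- function(var, scale) paste0(var, "@", scale)

split_scale_col <- function(cols) {
  parts <- strsplit(cols, "@", fixed = TRUE)
  data.frame(var = vapply(parts, `[`, "", 1L),
             scale = as.numeric(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Build a multi-scale covariate stack
#'
#' Focal mean of every raw layer at every scale of the ladder.
#'
#' @param raw Named list of `grd` layers (aligned).
#' @param scales Radii in metres.
#' @return Named list of `grd`s with `var@scale` names.
#' @export
build_multiscale_stack <- function(raw, scales) {
  if (any(diff(scales) <= 0) || any(scales <= 0))
    stop("scales must be positive and strictly increasing", call. = FALSE)
  stopifnot_aligned(raw)
  out <- list()
  for (nm in names(raw))
    for (s in scales)
      out[[scale_col(nm, s)]] <- focal_mean(raw[[nm]], s)
  out
}

#' Extract raster values at occurrence points
#'
#' One row per point, one column per layer; points outside the extent, or
#' hitting nodata in any layer, are dropped with a warning that counts them.
#'
#' @param stack Named list of `grd` layers (aligned).
#' @param points Occurrence data frame with `x`, `y` and optionally
#'   `presence`.
#' @return A feature data frame; the `presence` column is carried through
#'   when present. Attribute `"cells"` stores the extraction row/col indices.
#' @export
extract_features <- function(stack, points) {
  stopifnot_aligned(stack)
  tmpl <- stack[[1L]]
  rc <- xy_cell(tmpl, points$x, points$y)
  outside <- is.na(rc[, 1L])
  if (any(outside))
    warning(sum(outside), " point(s) outside the stack extent dropped",
            call. = FALSE)
  rc <- rc[!outside, , drop = FALSE]
  pts <- points[!outside, , drop = FALSE]
  mat <- matrix(NA_real_, nrow(rc), length(stack),
                dimnames = list(NULL, names(stack)))
  for (j in seq_along(stack)) mat[, j] <- stack[[j]]$values[rc]
  mat <- as.data.frame(mat)
  bad <- rowSums(is.na(mat)) > 0L
  if (any(bad))
    warning(sum(bad), " point(s) hitting nodata dropped", call. = FALSE)
  out <- mat[!bad, , drop = FALSE]
  if ("presence" %in% names(pts)) out$presence <- pts$presence[!bad]
  rownames(out) <- NULL
  attr(out, "cells") <- rc[!bad, , drop = FALSE]
  out
}

#' Pairwise collinearity filter
#'
#' Iteratively removes predictors until all pairwise absolute Pearson
#' correlations are at or below the threshold: at each step the worst pair is
#' found and its member with the larger mean absolute correlation against all
#' remaining variables is dropped. Zero-variance columns are removed first
#' with a warning. Removal order is deterministic (ties drop the later
#' column).
#'
#' @param x Data frame or matrix of numeric predictors (a `presence` column,
#'   if present, is ignored).
#' @param threshold Maximum allowed `|r|` (default 0.50).
#' @return Character vector of retained column names; attribute `"dropped"`
#'   lists removals in order.
#' @export
collinearity_filter <- function(x, threshold = 0.50) {
  x <- as.data.frame(x)
  x$presence <- NULL
  if (ncol(x) < 2L) stop("need at least two predictors", call. = FALSE)
  dropped <- character(0)
  sds <- vapply(x, stats::sd, 0)
  if (any(sds == 0 | is.na(sds))) {
    zv <- names(x)[sds == 0 | is.na(sds)]
    warning("zero-variance column(s) removed: ", paste(zv, collapse = ", "),
            call. = FALSE)
    dropped <- zv
    x <- x[, !(names(x) %in% zv), drop = FALSE]
  }
  r <- abs(stats::cor(as.matrix(x)))
  diag(r) <- 0
  while (ncol(r) > 1L && max(r) > threshold) {
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    m <- rowMeans(r)
    # drop the pair member with the larger mean |r|; ties drop the later column
    drop_i <- if (m[worst[1L]] > m[worst[2L]]) worst[1L]
              else if (m[worst[2L]] > m[worst[1L]]) worst[2L]
              else max(worst)
    dropped <- c(dropped, colnames(r)[drop_i])
    r <- r[-drop_i, -drop_i, drop = FALSE]
  }
  out <- colnames(r)
  attr(out, "dropped") <- dropped
  out
}
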