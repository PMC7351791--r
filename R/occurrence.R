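# Occurrence preparation: spatial rarefaction of presences and buffered
# pseudo-absence generation. Coordinates are Euclidean, projected metres.

#' Spatially thin occurrence points
#'
#' Greedy rarefaction: points are visited in input order (or a seeded random
#' order) and kept only if at least `min_dist` from every point already kept.
#' The result is a subset of the input with all pairwise distances
#' `>= min_dist`; thinning an already-thinned set is a no-op.
#'
#' @param points Occurrence data frame with `x` and `y` columns in metres.
#' @param min_dist Minimum inter-point distance in metres (default 1000).
#' @param order `"input"` (deterministic, default) or `"random"`.
#' @param seed Seed for `order = "random"`.
#' @return The retained rows of `points`.
#' @export
spatial_thin <- function(points, min_dist = 1000, order = c("input", "random"),
                         seed = 1) {
  order <- match.arg(order)
  if (min_dist <= 0) stop("min_dist must be positive", call. = FALSE)
  n <- nrow(points)
  if (n == 0) return(points)
  if (all(abs(points$x) <= 180) && all(abs(points$y) <= 90))
    warning("coordinate extent looks geographic (degrees); ",
            "distances assume projected metres", call. = FALSE)
  idx <- seq_len(n)
  if (order == "random") {
    set.seed(seed)
    idx <- sample(idx)
  }
  kept <- integer(0)
  for (i in idx) {
    if (length(kept) == 0L ||
        min((points$x[i] - points$x[kept])^2 +
            (points$y[i] - points$y[kept])^2) >= min_dist^2)
      kept <- c(kept, i)
  }
  points[sort(kept), , drop = FALSE]
}

#' Generate buffered pseudo-absences
#'
#' Uniform random candidate points within the extent; candidates within
#' `buffer` metres of any presence are discarded (strictly: survivors are
#' farther than `buffer` from every presence). If more candidates survive
#' than `n_target`, a seeded random subset of exactly `n_target` is returned.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` enclosing the presences.
#' @param presences Occurrence data frame with `x`, `y` columns.
#' @param n_candidates Number of uniform candidates (default 500).
#' @param buffer Exclusion radius around each presence in metres (default 500).
#' @param n_target Absences wanted (default: number of presences).
#' @param seed Integer seed.
#' @return An occurrence data frame (`presence = 0`); attribute
#'   `"n_survivors"` records how many candidates survived the buffer.
#' @export
generate_pseudo_absences <- function(extent, presences, n_candidates = 500,
                                     buffer = 500,
                                     n_target = nrow(presences), seed = 1) {
  if (buffer < 0) stop("buffer must be non-negative", call. = FALSE)
  if (nrow(presences) > 0 &&
      (any(presences$x < extent[1] | presences$x > extent[2]) ||
       any(presences$y < extent[3] | presences$y > extent[4])))
    stop("extent does not enclose the presences", call. = FALSE)
  set.seed(seed)
  cand <- data.frame(x = stats::runif(n_candidates, extent[1], extent[2]),
                     y = stats::runif(n_candidates, extent[3], extent[4]))
  keep <- rep(TRUE, n_candidates)
  if (nrow(presences) > 0 && buffer > 0) {
    for (i in seq_len(n_candidates)) {
      d2 <- (cand$x[i] - presences$x)^2 + (cand$y[i] - presences$y)^2
      keep[i] <- min(d2) > buffer^2
    }
  }
  surv <- cand[keep, , drop = FALSE]
  if (nrow(surv) < n_target)
    stop(sprintf(
      "too few pseudo-absences: %d candidates survived the %g m buffer, %d needed",
      nrow(surv), buffer, n_target), call. = FALSE)
  if (nrow(surv) > n_target)
    surv <- surv[sample(nrow(surv), n_target), , drop = FALSE]
  out <- data.frame(x = surv$x, y = surv$y,
                    species = if (nrow(presences) > 0 && "species" %in% names(presences))
                      presences$species[1] else "sp1",
                    presence = 0L, source = "pseudo-absence",
                    stringsAsFactors = FALSE)
  attr(out, "n_survivors") <- sum(keep)
  out
}

#' Merge presences and pseudo-absences into a modelling set
#'
#' @param presences,absences Occurrence data frames (`x`, `y`, ...).
#' @return A single data frame with a binary `presence` column; attribute
#'   `"prevalence"` holds the presence fraction.
#' @export
assemble_dataset <- function(presences, absences) {
  if (nrow(presences) == 0) stop("no presences supplied", call. = FALSE)
  if (nrow(absences) == 0) stop("no absences supplied", call. = FALSE)
  cols <- c("x", "y", "species", "presence", "source")
  fill <- function(d, p) {
    if (!"species" %in% names(d)) d$species <- "sp1"
    if (!"source" %in% names(d)) d$source <- if (p) "presence" else "pseudo-absence"
    d$presence <- if (p) 1L else 0L
    d[, cols]
  }
  out <- rbind(fill(presences, TRUE), fill(absences, FALSE))
  dup <- duplicated(out[, c("x", "y")])
  if (any(dup))
    warning(sum(dup), " duplicate coordinates across classes", call. = FALSE)
  attr(out, "prevalence") <- mean(out$presence)
  out
}
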