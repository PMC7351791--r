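# Synthetic landscapes with known ground truth: spatially autocorrelated
# covariate fields on a 90 m grid, a logistic suitability surface driven by
# focal means at known scales, and Bernoulli-style presence sampling. The
# generator exists so that every downstream stage (scale optimization, MIR
# selection, projection, niche tests) can be validated against a truth the
# field data of a real study never provides.

#' Derive a per-stage child seed from a master seed
#'
#' Each pipeline stage draws randomness from its own child seed so stages are
#' independently reproducible under one master seed. The arithmetic is fixed
#' (not itself random) and keeps the result inside the 32-bit integer range.
#'
#' @param seed Master seed (integer).
#' @param stage Stage index (non-negative integer).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483647)
}

#' Stationary Gaussian random field
#'
#' White noise smoothed by a Gaussian kernel on a torus (FFT convolution) and
#' re-standardized to mean 0, variance 1. `corr_length` is the kernel sigma in
#' metres; 0 yields i.i.d. standard noise.
#'
#' @param nrow,ncol Grid dimensions.
#' @param cellsize Cell size in metres.
#' @param corr_length Autocorrelation length (kernel sigma) in metres, >= 0.
#' @param seed Integer seed; fixed seed gives a bitwise-identical field.
#' @param xmin,ymin Grid origin.
#' @return A `grd` with mean exactly 0 and variance exactly 1.
#' @export
gaussian_field <- function(nrow, ncol, cellsize = 90, corr_length = 0, seed = 1,
                           xmin = 0, ymin = 0) {
  if (nrow < 1 || ncol < 1) stop("grid shape must be positive", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  if (corr_length < 0) stop("corr_length must be non-negative", call. = FALSE)
  set.seed(seed)
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (corr_length > 0) {
    sigma <- corr_length / cellsize
    # toroidal distances to the (1,1) kernel origin
    dr <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
    dc <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
    k <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nrow * ncol)
  }
  z <- (z - mean(z)) / stats::sd(z)
  grd(z, cellsize, xmin, ymin)
}

#' Describe a synthetic landscape's generating truth
#'
#' The truth records, per covariate, the autocorrelation length used to
#' generate its field and — for influential covariates — the "true" focal
#' scale and logistic coefficient that drive the suitability surface. True
#' scales must sit on the configured scale ladder.
#'
#' The default emulates a reserve-sized landscape: 300 x 300 cells at 90 m
#' (27 km on a side) with a reduced scale ladder of 270–2,430 m so focal
#' windows stay desk-scale; the full 3,500–28,000 m ladder used for real
#' landscapes remains configurable via `scales`.
#'
#' @param covariates Data frame with columns `name`, `corr_length` (m),
#'   `coef` (logistic coefficient; 0 = not influential) and `true_scale`
#'   (m, `NA` for non-influential covariates).
#' @param intercept Logistic intercept. The default (-3) makes suitable
#'   habitat a minority fraction of the landscape, as in real reserves,
#'   concentrating occupancy toward the favourable covariate extremes.
#' @param nrow,ncol Grid shape.
#' @param cellsize Cell size (m).
#' @param scales Scale ladder (m) the landscape is analysed at.
#' @param seed Master seed.
#' @return An object of class `landscape_truth`.
#' @export
landscape_truth <- function(covariates = NULL, intercept = -3,
                            nrow = 300, ncol = 300, cellsize = 90,
                            scales = default_scales("reduced"), seed = 1) {
  if (is.null(covariates))
    covariates <- data.frame(
      name = c("bio1", "bio12", "forest", "rough"),
      corr_length = c(450, 630, 270, 180),
      coef = c(40, 0, -30, 0),
      true_scale = c(1350, NA, 810, NA),
      stringsAsFactors = FALSE)
  if (nrow < 1 || ncol < 1) stop("grid shape must be positive", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  infl <- !is.na(covariates$true_scale) & covariates$coef != 0
  if (any(infl & !(covariates$true_scale %in% scales)))
    stop("every true scale must be a member of the scale ladder", call. = FALSE)
  structure(list(covariates = covariates, intercept = intercept,
                 nrow = nrow, ncol = ncol, cellsize = cellsize,
                 scales = scales, seed = as.integer(seed)),
            class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf("landscape_truth: %d x %d cells at %g m, seed %d\n",
              x$nrow, x$ncol, x$cellsize, x$seed))
  cat("scale ladder (m):", paste(x$scales, collapse = ", "), "\n")
  print(x$covariates)
  invisible(x)
}

#' Simulate the covariate stack of a landscape
#'
#' One Gaussian random field per covariate, each from a deterministic child
#' of the master seed.
#'
#' @param truth A [landscape_truth()].
#' @return Named list of `grd` covariate layers.
#' @export
simulate_landscape <- function(truth) {
  stopifnot(inherits(truth, "landscape_truth"))
  cov <- truth$covariates
  stack <- lapply(seq_len(nrow(cov)), function(i)
    gaussian_field(truth$nrow, truth$ncol, truth$cellsize,
                   corr_length = cov$corr_length[i],
                   seed = child_seed(truth$seed, i)))
  names(stack) <- cov$name
  stack
}

#' True suitability surface
#'
#' Cellwise `plogis(intercept + sum(coef_v * focal_mean_v at its true scale))`
#' over the influential covariates. Coefficients act on raw focal means; note
#' that focal averaging shrinks the variance of a unit-variance field, which
#' is why sensible generating coefficients are large relative to a plain
#' logistic regression on standardized predictors.
#'
#' @param stack Named list of `grd` covariate layers, aligned to one spec.
#' @param truth A [landscape_truth()].
#' @return A `grd` of probabilities in (0, 1).
#' @export
true_suitability <- function(stack, truth) {
  stopifnot(inherits(truth, "landscape_truth"))
  stopifnot_aligned(stack)
  tmpl <- stack[[1L]]
  eta <- matrix(truth$intercept, nrow(tmpl$values), ncol(tmpl$values))
  cov <- truth$covariates
  for (i in seq_len(nrow(cov))) {
    if (is.na(cov$true_scale[i]) || cov$coef[i] == 0) next
    nm <- cov$name[i]
    if (is.null(stack[[nm]])) stop("stack is missing covariate ", nm, call. = FALSE)
    f <- focal_mean(stack[[nm]], cov$true_scale[i])
    eta <- eta + cov$coef[i] * f$values
  }
  grd(stats::plogis(eta), tmpl$cellsize, tmpl$xmin, tmpl$ymin)
}

#' Sample presence points from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability and the point
#' is jittered uniformly within its cell.
#'
#' @param suitability A `grd` with values in `[0, 1]`.
#' @param n Number of presences.
#' @param seed Integer seed.
#' @param species,source Labels carried through to the occurrence table.
#' @return An occurrence data frame with columns `x`, `y`, `species`,
#'   `presence` (all 1) and `source`.
#' @export
sample_occurrences <- function(suitability, n, seed = 1, species = "sp1",
                               source = "simulated") {
  v <- suitability$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  p <- as.vector(v)
  p[is.na(p)] <- 0
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), species = character(0),
                      presence = integer(0), source = character(0),
                      stringsAsFactors = FALSE))
  if (sum(p) <= 0)
    stop("cannot sample occurrences: suitability is zero everywhere", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(length(p), n, replace = TRUE, prob = p)
  nr <- nrow(v)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  ctr <- cell_xy(suitability, row, col)
  cs <- suitability$cellsize
  data.frame(x = ctr[, 1] + stats::runif(n, -cs / 2, cs / 2),
             y = ctr[, 2] + stats::runif(n, -cs / 2, cs / 2),
             species = species, presence = 1L, source = source,
             stringsAsFactors = FALSE)
}

#' Habitat axes of a landscape truth
#'
#' Focal-mean layers of the influential covariates at their true scales: the
#' environmental axes along which the generated species actually select
#' habitat. This is the natural environment stack for E-space niche analyses
#' of synthetic scenarios (raw point values decorrelate from the focal means
#' that drive occupancy, which would dilute any niche contrast built into a
#' scenario).
#'
#' @param stack Named list of raw covariate `grd` layers.
#' @param truth The generating [landscape_truth()].
#' @return Named list of `grd` layers, one per influential covariate.
#' @export
truth_env_stack <- function(stack, truth) {
  cov <- truth$covariates
  out <- list()
  for (i in seq_len(nrow(cov))) {
    if (is.na(cov$true_scale[i]) || cov$coef[i] == 0) next
    out[[cov$name[i]]] <- focal_mean(stack[[cov$name[i]]], cov$true_scale[i])
  }
  if (!length(out)) stop("truth has no influential covariates", call. = FALSE)
  out
}

#' Build a two-species scenario with a controllable niche offset
#'
#' Both species share one covariate stack. Species 1 uses the truth's
#' coefficients; species 2 uses `coef * (1 - delta)`, so `delta = 0` gives
#' identical suitability surfaces, `delta = 1` an indifferent species and
#' `delta = 2` optima at the opposite covariate extremes. Increasing `delta`
#' therefore moves the two species apart in environmental space without
#' touching the shared landscape.
#'
#' @param truth A [landscape_truth()].
#' @param delta Niche offset, >= 0.
#' @param n1,n2 Occurrences sampled per species.
#' @param seed Master seed for this scenario (fields, then each species'
#'   sampling, use fixed child seeds).
#' @return A list of class `two_species_scenario` with the stack, both
#'   suitability surfaces and both occurrence sets.
#' @export
two_species_scenario <- function(truth, delta = 0, n1 = 500, n2 = 500, seed = 1) {
  if (delta < 0) stop("delta must be non-negative", call. = FALSE)
  truth$seed <- as.integer(seed)
  stack <- simulate_landscape(truth)
  suit1 <- true_suitability(stack, truth)
  truth2 <- truth
  truth2$covariates$coef <- truth$covariates$coef * (1 - delta)
  suit2 <- true_suitability(stack, truth2)
  occ1 <- sample_occurrences(suit1, n1, seed = child_seed(seed, 101), species = "sp1")
  occ2 <- sample_occurrences(suit2, n2, seed = child_seed(seed, 102), species = "sp2")
  structure(list(stack = stack, suitability1 = suit1, suitability2 = suit2,
                 occ1 = occ1, occ2 = occ2, delta = delta, seed = as.integer(seed)),
            class = "two_species_scenario")
}
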