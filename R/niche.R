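# Niche comparison in environmental space (E-space): PCA ordination of
# pooled backgrounds, Gaussian kernel occurrence densities on an R x R grid,
# Schoener's D and Warren's I, equivalency (identity) and background
# randomization tests, the Potential Niche Truncation Index (PNTI) and the
# Niche E-space Correlation Index (NECI).

#' Build a two-dimensional environmental space
#'
#' PCA fitted on the pooled, standardized background environments of both
#' species; the first two components are retained and an `R x R` grid spans
#' the pooled score range (expanded by a small margin so later occurrence
#' scores usually fall inside; points outside are clamped with a warning by
#' [density_surface()]).
#'
#' @param bg1,bg2 Data frames of background environment rows (same columns).
#' @param R Grid resolution per axis (default 100).
#' @param expand Fractional margin added around the pooled score range.
#' @return An object of class `espace`: loadings, explained variance
#'   fractions, grid axes, background scores and the Scott's-rule kernel
#'   bandwidth of the pooled scores.
#' @export
build_espace <- function(bg1, bg2, R = 100, expand = 0.1) {
  vars <- names(bg1)
  if (!identical(vars, names(bg2)))
    stop("background tables must share the same variable columns", call. = FALSE)
  pooled <- rbind(as.data.frame(bg1), as.data.frame(bg2))
  if (nrow(pooled) < ncol(pooled))
    stop("fewer background rows than variables", call. = FALSE)
  # zero-variance (spatially constant) variables are centred but not scaled,
  # so degenerate landscapes still yield a usable (point-mass) E-space
  sds <- vapply(pooled, stats::sd, 0)
  pca <- stats::prcomp(pooled, center = TRUE,
                       scale. = ifelse(sds > 0, sds, 1))
  tot <- sum(pca$sdev^2)
  expl <- if (tot > 0) pca$sdev^2 / tot else rep(0, length(pca$sdev))
  sc <- pca$x[, 1:2, drop = FALSE]
  rng <- apply(sc, 2L, range)
  pad <- expand * (rng[2L, ] - rng[1L, ])
  pad[pad == 0] <- 1                     # zero-width score range: pad by 1
  gx <- seq(rng[1L, 1L] - pad[1L], rng[2L, 1L] + pad[1L], length.out = R)
  gy <- seq(rng[1L, 2L] - pad[2L], rng[2L, 2L] + pad[2L], length.out = R)
  n <- nrow(sc)
  bw <- n^(-1 / 6) * apply(sc, 2L, stats::sd)          # Scott's rule, d = 2
  bw <- pmax(bw, 1e-3 * (c(max(gx) - min(gx), max(gy) - min(gy))))
  structure(list(center = pca$center, scale = pca$scale,
                 rotation = pca$rotation[, 1:2, drop = FALSE],
                 explained = expl, R = R, gx = gx, gy = gy, bw = bw,
                 scores1 = sc[seq_len(nrow(bg1)), , drop = FALSE],
                 scores2 = sc[nrow(bg1) + seq_len(nrow(bg2)), , drop = FALSE]),
            class = "espace")
}

#' @export
print.espace <- function(x, ...) {
  cat(sprintf("espace: %d x %d grid; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$R, x$R, 100 * x$explained[1L], 100 * x$explained[2L]))
  invisible(x)
}

#' Project environment rows into an E-space
#'
#' @param espace An [build_espace()] result.
#' @param env Data frame of environment rows on the original variables.
#' @return A two-column score matrix.
#' @export
espace_scores <- function(espace, env) {
  env <- as.matrix(env[, names(espace$center), drop = FALSE])
  scale(env, center = espace$center, scale = espace$scale) %*% espace$rotation
}

#' Kernel density surface in E-space
#'
#' Product-Gaussian kernel density of score points evaluated on the E-space
#' grid and normalized to sum 1. Points outside the grid are clamped to the
#' bounds with a warning.
#'
#' @param scores Two-column matrix of E-space scores (>= 5 points).
#' @param espace The [build_espace()] grid.
#' @param bw Kernel bandwidth per axis (default: the espace's Scott's-rule
#'   bandwidth).
#' @param source Tag stored on the result (`"occurrence"` or `"background"`).
#' @return An object of class `density_surface`: an `R x R` matrix of
#'   non-negative weights summing to 1 (rows index the x axis).
#' @export
density_surface <- function(scores, espace, bw = espace$bw,
                            source = "occurrence") {
  scores <- as.matrix(scores)
  if (nrow(scores) < 5L) stop("need at least 5 points", call. = FALSE)
  x <- scores[, 1L]; y <- scores[, 2L]
  out_of <- x < min(espace$gx) | x > max(espace$gx) |
            y < min(espace$gy) | y > max(espace$gy)
  if (any(out_of)) {
    warning(sum(out_of), " point(s) outside the E-space grid clamped",
            call. = FALSE)
    x <- pmin(pmax(x, min(espace$gx)), max(espace$gx))
    y <- pmin(pmax(y, min(espace$gy)), max(espace$gy))
  }
  Ax <- outer(espace$gx, x, function(g, p) stats::dnorm((g - p) / bw[1L]))
  Ay <- outer(espace$gy, y, function(g, p) stats::dnorm((g - p) / bw[2L]))
  z <- Ax %*% t(Ay)
  z <- z / sum(z)
  structure(list(z = z, gx = espace$gx, gy = espace$gy, source = source,
                 bw = bw), class = "density_surface")
}

check_density <- function(p) {
  if (!inherits(p, "density_surface")) {
    if (is.numeric(p)) p <- structure(list(z = as.matrix(p)),
                                      class = "density_surface")
    else stop("expected a density_surface", call. = FALSE)
  }
  if (any(p$z < 0)) stop("density has negative entries", call. = FALSE)
  if (abs(sum(p$z) - 1) > 1e-6)
    stop("density is not normalized to sum 1", call. = FALSE)
  p
}

#' Schoener's D and Warren's I niche overlap
#'
#' `D = 1 - 0.5 * sum(|p1 - p2|)` and `I = 1 - 0.5 * sum((sqrt(p1) -
#' sqrt(p2))^2)` over two normalized density surfaces on the same grid; both
#' lie in `[0, 1]` and `I >= D` always.
#'
#' @param p1,p2 `density_surface` objects (or bare matrices summing to 1).
#' @return Named numeric vector `c(D = , I = )`.
#' @export
overlap_stats <- function(p1, p2) {
  p1 <- check_density(p1); p2 <- check_density(p2)
  if (!identical(dim(p1$z), dim(p2$z)))
    stop("density surfaces are on different grids", call. = FALSE)
  c(D = 1 - 0.5 * sum(abs(p1$z - p2$z)),
    I = 1 - 0.5 * sum((sqrt(p1$z) - sqrt(p2$z))^2))
}

#' Niche equivalency (identity) test
#'
#' One-tailed randomization test of the null that two species' occupied
#' niches are identical. Occurrence scores are pooled and reshuffled into
#' groups of the original sizes; D is recomputed per replicate;
#' `p = (1 + #\{D_null <= D_obs\}) / (reps + 1)`, so a small observed D
#' relative to the null gives a small p and rejects equivalence.
#'
#' @param scores1,scores2 E-space score matrices of the two species'
#'   occurrences (>= 5 rows each).
#' @param espace The shared E-space.
#' @param reps Replicates (>= 99; default 199).
#' @param seed Integer seed.
#' @return An object of class `niche_test`: `D_obs`, `I_obs`, `null`
#'   (length-`reps` D values), `p`, `reps`, `seed`.
#' @export
equivalency_test <- function(scores1, scores2, espace, reps = 199, seed = 1) {
  scores1 <- as.matrix(scores1); scores2 <- as.matrix(scores2)
  n1 <- nrow(scores1); n2 <- nrow(scores2)
  if (n1 < 5L || n2 < 5L) stop("need at least 5 occurrences per species", call. = FALSE)
  if (reps < 99L) stop("reps must be at least 99", call. = FALSE)
  obs <- overlap_stats(density_surface(scores1, espace),
                       density_surface(scores2, espace))
  pool <- rbind(scores1, scores2)
  set.seed(seed)
  null <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(n1 + n2, n1)
    overlap_stats(density_surface(pool[idx, , drop = FALSE], espace),
                  density_surface(pool[-idx, , drop = FALSE], espace))[["D"]]
  }, 0)
  structure(list(D_obs = obs[["D"]], I_obs = obs[["I"]], null = null,
                 p = (1 + sum(null <= obs[["D"]])) / (reps + 1),
                 reps = reps, seed = as.integer(seed), type = "equivalency"),
            class = "niche_test")
}

#' Niche background (divergence) test
#'
#' Randomization test asking whether the observed overlap between species 1's
#' occurrences and species 2's exceeds what random placement of species 2 in
#' the shared landscape would give. Each replicate rigidly translates species
#' 2's coordinates by a random toroidal shift within the extent, re-extracts
#' environments from the raw stack, and recomputes D against species 1;
#' `p = (1 + #\{D_null >= D_obs\}) / (reps + 1)` — a small p means the two
#' species are more similar than expected by chance. Replicates whose shifted
#' points hit nodata are re-drawn (up to 25 attempts each).
#'
#' @param occ1,occ2 Occurrence data frames with `x`, `y`.
#' @param extent `c(xmin, xmax, ymin, ymax)` enclosing `occ2`.
#' @param stack Named list of raw environment `grd` layers (the E-space
#'   variables).
#' @param espace The shared E-space.
#' @param reps,seed Replicates (>= 99) and seed.
#' @return A `niche_test` (type `"background"`).
#' @export
background_test <- function(occ1, occ2, extent, stack, espace,
                            reps = 199, seed = 1) {
  if (reps < 99L) stop("reps must be at least 99", call. = FALSE)
  if (any(occ2$x < extent[1] | occ2$x > extent[2] |
          occ2$y < extent[3] | occ2$y > extent[4]))
    stop("extent does not enclose occ2", call. = FALSE)
  env1 <- extract_features(stack, occ1)
  env2 <- extract_features(stack, occ2)
  d1 <- density_surface(espace_scores(espace, env1), espace)
  obs <- overlap_stats(d1, density_surface(espace_scores(espace, env2), espace))
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  set.seed(seed)
  null <- vapply(seq_len(reps), function(i) {
    for (try in 1:25) {
      dx <- stats::runif(1, 0, w); dy <- stats::runif(1, 0, h)
      sx <- extent[1] + (occ2$x - extent[1] + dx) %% w
      sy <- extent[3] + (occ2$y - extent[3] + dy) %% h
      env <- suppressWarnings(
        extract_features(stack, data.frame(x = sx, y = sy)))
      if (nrow(env) >= 5L)
        return(overlap_stats(d1, density_surface(espace_scores(espace, env),
                                                 espace))[["D"]])
    }
    stop("background test: shifted points persistently hit nodata", call. = FALSE)
  }, 0)
  structure(list(D_obs = obs[["D"]], I_obs = obs[["I"]], null = null,
                 p = (1 + sum(null >= obs[["D"]])) / (reps + 1),
                 reps = reps, seed = as.integer(seed), type = "background"),
            class = "niche_test")
}

#' @export
print.niche_test <- function(x, ...) {
  cat(sprintf("niche %s test: D_obs = %.4f (I_obs = %.4f), p = %.4f (%d reps)\n",
              x$type, x$D_obs, x$I_obs, x$p, x$reps))
  cat(sprintf("null D: [%.4f, %.4f], median %.4f\n",
              min(x$null), max(x$null), stats::median(x$null)))
  invisible(x)
}

# smallest set of cells holding `mass` of the total density (an isopleth
# region at level 1 - mass)
isopleth_region <- function(p, mass) {
  z <- p$z
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(z[ord])
  k <- which(cum >= mass - 1e-12)[1L]
  reg <- matrix(FALSE, nrow(z), ncol(z))
  reg[ord[seq_len(k)]] <- TRUE
  reg
}

# cells of a region with at least one 4-neighbour outside it (grid-edge
# region cells count as boundary)
region_boundary <- function(reg) {
  nr <- nrow(reg); nc <- ncol(reg)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- reg
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
           pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  reg & !inner
}

#' Potential Niche Truncation Index
#'
#' Fraction of the species' outer (5%) kernel-density isopleth boundary that
#' lies outside the background's 10% isopleth region: the extent to which the
#' occupied E-space abuts or crosses the margin of the accessible E-space. A
#' "q% isopleth" here is the smallest cell set containing `1 - q` of the
#' total mass, so the 5% isopleth bounds 95% of the species density. Risk
#' that the occupied niche misrepresents the fundamental niche is classed
#' low (< 0.15), moderate (0.15–0.3) or high (> 0.3).
#'
#' @param species_density,background_density `density_surface`s on one grid.
#' @param species_level,background_level Isopleth levels (defaults 0.05 and
#'   0.10).
#' @return An object of class `pnti_result`: `pnti`, `risk`, boundary cell
#'   counts.
#' @export
pnti <- function(species_density, background_density,
                 species_level = 0.05, background_level = 0.10) {
  sp <- check_density(species_density)
  bg <- check_density(background_density)
  if (!identical(dim(sp$z), dim(bg$z)))
    stop("density surfaces are on different grids", call. = FALSE)
  sp_reg <- isopleth_region(sp, 1 - species_level)
  bg_reg <- isopleth_region(bg, 1 - background_level)
  if (!any(sp_reg) || !any(bg_reg)) stop("empty isopleth", call. = FALSE)
  bnd <- region_boundary(sp_reg)
  n_b <- sum(bnd)
  n_out <- sum(bnd & !bg_reg)
  val <- n_out / n_b
  structure(list(pnti = val,
                 risk = if (val > 0.3) "high" else if (val >= 0.15) "moderate"
                        else "low",
                 n_boundary = n_b, n_outside = n_out),
            class = "pnti_result")
}

#' @export
print.pnti_result <- function(x, ...) {
  cat(sprintf("PNTI = %.3f (%s risk): %d of %d isopleth boundary cells outside the accessible E-space\n",
              x$pnti, x$risk, x$n_outside, x$n_boundary))
  invisible(x)
}

#' Niche E-space Correlation Index
#'
#' Pearson correlation between the two species' background density surfaces
#' (flattened). A value above 0.5 (strictly) flags that the species share
#' essentially the same accessible E-space, in which case occurrence
#' densities may be corrected by environmental prevalence before overlap
#' statistics to reduce type-I error.
#'
#' @param bg1_density,bg2_density `density_surface`s on one grid.
#' @return An object of class `neci_result`: `neci` and `correction`
#'   (logical flag).
#' @export
neci <- function(bg1_density, bg2_density) {
  p1 <- check_density(bg1_density); p2 <- check_density(bg2_density)
  if (!identical(dim(p1$z), dim(p2$z)))
    stop("density surfaces are on different grids", call. = FALSE)
  if (stats::sd(p1$z) == 0 || stats::sd(p2$z) == 0)
    stop("undefined correlation: zero-variance density surface", call. = FALSE)
  v <- stats::cor(as.vector(p1$z), as.vector(p2$z))
  structure(list(neci = v, correction = v > 0.5), class = "neci_result")
}

#' @export
print.neci_result <- function(x, ...) {
  cat(sprintf("NECI = %.3f; prevalence correction %s\n", x$neci,
              if (x$correction) "recommended" else "not required"))
  invisible(x)
}
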