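# E-space construction, kernel densities, overlap statistics, randomization
# tests, PNTI and NECI.

test_that("E-space PCA bookkeeping behaves", {
  set.seed(61)
  # two identical variables: PC1 carries everything
  v <- rnorm(300)
  esp <- build_espace(data.frame(a = v, b = v), data.frame(a = v, b = v), R = 40)
  expect_equal(esp$explained[1], 1)
  # two independent standardized variables split the variance evenly
  big <- data.frame(a = rnorm(5000), b = rnorm(5000))
  esp2 <- build_espace(big, big, R = 40)
  expect_lt(abs(esp2$explained[1] - 0.5), 0.03)
  expect_lt(abs(esp2$explained[2] - 0.5), 0.03)
  # eigenvalue ordering
  expect_true(all(diff(esp2$explained) <= 1e-12))
  expect_error(build_espace(data.frame(a = 1, b = 2, c = 3),
                            data.frame(a = 1, b = 2, c = 3)), "fewer")
  # projection reproduces the stored background scores
  back <- espace_scores(esp2, big)
  expect_equal(unname(back[1:10, ]), unname(esp2$scores1[1:10, ]))
})

test_that("density surfaces are normalized with mass where the points are", {
  set.seed(62)
  bg <- data.frame(a = rnorm(500), b = rnorm(500))
  esp <- build_espace(bg, bg, R = 60)
  d <- density_surface(esp$scores1, esp)
  expect_equal(sum(d$z), 1, tolerance = 1e-9)
  expect_true(all(d$z >= 0))
  # all points at one location: argmax at that location's cell
  one <- matrix(rep(c(0.5, -0.25), each = 8), ncol = 2)
  d1 <- density_surface(one, esp)
  am <- which(d1$z == max(d1$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(d1$gx[am[1]] - 0.5), diff(d1$gx[1:2]))
  expect_lt(abs(d1$gy[am[2]] + 0.25), diff(d1$gy[1:2]))
  # two well-separated clusters: local maxima near both centres
  two <- rbind(matrix(rnorm(200, -2, 0.1), ncol = 2),
               matrix(rnorm(200, 2, 0.1), ncol = 2))
  d2 <- density_surface(two, esp, bw = c(0.2, 0.2))
  zmax <- which(d2$z == max(d2$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(d2$gx[zmax[1]]) - 2, 0.3)
  # clamping points outside the grid warns
  expect_warning(density_surface(matrix(c(99, 99, 99, 99, 99, 0, 0, 0, 0, 0),
                                        ncol = 2), esp), "clamped")
  expect_error(density_surface(one[1:3, ], esp), "at least 5")
})

test_that("a hand-rolled KDE cross-checks against MASS::kde2d", {
  skip_if_not_installed("MASS")
  set.seed(63)
  pts <- cbind(rnorm(200), rnorm(200))
  esp <- list(gx = seq(-4, 4, length.out = 50), gy = seq(-4, 4, length.out = 50),
              bw = c(0.5, 0.7))
  class(esp) <- "espace"
  d <- density_surface(pts, esp)
  # kde2d's h is 4x the Gaussian sd used here
  ref <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * esp$bw, n = 50,
                     lims = c(-4, 4, -4, 4))
  expect_equal(d$z, ref$z / sum(ref$z), tolerance = 1e-8)
})

test_that("Schoener's D and Warren's I follow their definitions", {
  p <- random_density(10, seed = 1)
  expect_equal(unname(overlap_stats(p, p)), c(1, 1))
  q <- matrix(0, 10, 10); q[1, 1] <- 1
  r <- matrix(0, 10, 10); r[10, 10] <- 1
  expect_equal(unname(overlap_stats(q, r)), c(0, 0))
  # 3-cell hand arithmetic
  expect_equal(unname(overlap_stats(matrix(c(0.5, 0.5, 0), 1),
                                    matrix(c(0, 0.5, 0.5), 1))), c(0.5, 0.5))
  expect_error(overlap_stats(matrix(c(0.5, 0.4), 1), matrix(c(0.5, 0.5), 1)),
               "not normalized")
})

test_that("I >= D and both are symmetric on random surfaces", {
  for (rep in 1:200) {
    p <- random_density(9, seed = rep, concentrated = rep %% 2 == 0)
    q <- random_density(9, seed = rep + 1000, concentrated = rep %% 3 == 0)
    st <- overlap_stats(p, q)
    expect_gte(st[["I"]], st[["D"]] - 1e-12)
    expect_true(all(st >= -1e-12 & st <= 1 + 1e-12))
    expect_equal(st, overlap_stats(q, p)[c("D", "I")])
  }
})

test_that("the equivalency test accepts copies and sizes its null", {
  set.seed(64)
  bg <- data.frame(a = rnorm(400), b = rnorm(400))
  esp <- build_espace(bg, bg, R = 50)
  occ <- espace_scores(esp, data.frame(a = rnorm(60, 1), b = rnorm(60, -1)))
  eq <- equivalency_test(occ, occ, esp, reps = 99, seed = 5)
  expect_gte(eq$p, 0.9)                  # a copy cannot reject equivalence
  expect_length(eq$null, 99L)
  eq2 <- equivalency_test(occ, occ, esp, reps = 99, seed = 5)
  expect_identical(eq$null, eq2$null)    # seeded determinism
  expect_error(equivalency_test(occ[1:3, ], occ, esp), "at least 5")
  expect_error(equivalency_test(occ, occ, esp, reps = 50), "at least 99")
})

test_that("widely separated niches are rejected by the equivalency test", {
  truth <- landscape_truth(nrow = 120, ncol = 120, seed = 65)
  sc <- two_species_scenario(truth, delta = 2, n1 = 200, n2 = 200, seed = 65)
  es <- scenario_espace(sc, truth, seed = 65)
  eq <- suppressWarnings(
    equivalency_test(es$s1, es$s2, es$espace, reps = 199, seed = 66))
  expect_lte(eq$p, 0.05)
})

test_that("the background test is exact on constant environments and seeded", {
  const <- list(a = grd(matrix(5, 30, 30), 90), b = grd(matrix(-2, 30, 30), 90))
  ext <- c(0, 2700, 0, 2700)
  set.seed(67)
  p1 <- data.frame(x = runif(40, 0, 2700), y = runif(40, 0, 2700))
  p2 <- data.frame(x = runif(40, 0, 2700), y = runif(40, 0, 2700))
  bgp <- data.frame(x = runif(150, 0, 2700), y = runif(150, 0, 2700))
  esp <- build_espace(extract_features(const, bgp), extract_features(const, bgp),
                      R = 30)
  bt <- background_test(p1, p2, ext, const, esp, reps = 99, seed = 2)
  expect_equal(bt$p, 1)                  # shifts change nothing
  expect_true(all(bt$null == bt$D_obs))
  bt2 <- background_test(p1, p2, ext, const, esp, reps = 99, seed = 2)
  expect_identical(bt$null, bt2$null)
})

test_that("shared localized habitat gives a significant background test", {
  truth <- landscape_truth(nrow = 120, ncol = 120, seed = 68)
  sc <- two_species_scenario(truth, delta = 0, n1 = 150, n2 = 150, seed = 68)
  es <- scenario_espace(sc, truth, seed = 68)
  bt <- suppressWarnings(
    background_test(sc$occ1, sc$occ2, es$extent, es$env, es$espace,
                    reps = 199, seed = 69))
  expect_lte(bt$p, 0.05)
})

test_that("PNTI measures truncation of the occupied E-space", {
  R <- 120
  gx <- seq(-6, 6, length.out = R)
  gauss2 <- function(cx, cy, s) {
    z <- exp(-(outer((gx - cx)^2, (gx - cy)^2, "+")) / (2 * s^2))
    z / sum(z)
  }
  mk <- function(z) structure(list(z = z, gx = gx, gy = gx),
                              class = "density_surface")
  broad <- mk(gauss2(0, 0, 1.2))
  inside <- mk(gauss2(0, 0, 0.2))
  expect_equal(pnti(inside, broad)$pnti, 0)
  expect_equal(pnti(inside, broad)$risk, "low")
  outside <- mk(gauss2(5, 5, 0.15))
  po <- pnti(outside, broad)
  expect_equal(po$pnti, 1)
  expect_equal(po$risk, "high")
  # geometric oracle: isopleths of round Gaussians are discs, so the rim
  # fraction outside the background disc follows from circle-circle geometry.
  # Species centred ON the background's 90% radius r1; its 95% radius is r2;
  # the rim is outside where cos(theta) > -r2 / (2 r1).
  s1 <- 1.2; s2 <- 0.4
  r1 <- s1 * sqrt(2 * log(10))        # 90% mass radius of the background
  r2 <- s2 * sqrt(2 * log(20))        # 95% mass radius of the species
  frac <- acos(-r2 / (2 * r1)) / pi
  straddle <- mk(gauss2(r1, 0, s2))
  ph <- pnti(straddle, broad)
  expect_lt(abs(ph$pnti - frac), 0.12)
  expect_equal(ph$risk, "high")
})

test_that("NECI correlates background E-spaces with a strict 0.5 trigger", {
  p <- random_density(20, seed = 70)
  expect_equal(neci(p, p)$neci, 1)
  expect_true(neci(p, p)$correction)
  # complementary (anti-structured) surfaces correlate negatively
  q <- max(p) + min(p) - p
  q <- q / sum(q)
  expect_lt(neci(p, q)$neci, 0)
  expect_error(neci(matrix(1 / 400, 20, 20), p), "zero-variance")
  # exactly 0.5 does not trigger the correction flag
  res <- structure(list(neci = 0.5, correction = 0.5 > 0.5), class = "neci_result")
  expect_false(res$correction)
})
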