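# Synthetic landscape generator: fields, truth surfaces, occurrence sampling
# and two-species scenarios.

test_that("gaussian fields are standardized, reproducible and autocorrelated", {
  f <- gaussian_field(100, 100, 90, corr_length = 0, seed = 7)
  expect_lt(abs(mean(f$values)), 3 / 100)      # i.i.d. standard noise
  expect_equal(stats::var(as.vector(f$values)), 1, tolerance = 1e-9)
  expect_identical(f$values,
                   gaussian_field(100, 100, 90, corr_length = 0, seed = 7)$values)
  g <- gaussian_field(100, 100, 90, corr_length = 20 * 90, seed = 7)
  lag_cor <- function(m, l) cor(as.vector(m[, 1:(100 - l)]),
                                as.vector(m[, (1 + l):100]))
  expect_gt(lag_cor(g$values, 1), lag_cor(g$values, 10))
  expect_error(gaussian_field(0, 10, 90), "positive")
  expect_error(gaussian_field(10, 10, -1), "positive")
})

test_that("true suitability is the logistic of focal means at the true scales", {
  truth0 <- landscape_truth(
    data.frame(name = "a", corr_length = 270, coef = 0, true_scale = NA),
    intercept = 0, nrow = 20, ncol = 20)
  stack <- simulate_landscape(truth0)
  expect_true(all(true_suitability(stack, truth0)$values == 0.5))  # logistic(0)
  truth_hi <- truth0; truth_hi$intercept <- 50
  expect_true(all(true_suitability(stack, truth_hi)$values > 0.999))  # saturation
  # one covariate, coef 1: cellwise equality with an independent focal+logistic
  truth1 <- landscape_truth(
    data.frame(name = "a", corr_length = 270, coef = 1, true_scale = 1350),
    intercept = 0.3, nrow = 25, ncol = 25, scales = 90 * c(3, 9, 15))
  stack1 <- simulate_landscape(truth1)
  suit <- true_suitability(stack1, truth1)
  oracle <- plogis(0.3 + focal_mean(stack1$a, 1350)$values)
  expect_equal(suit$values, oracle, tolerance = 1e-12)
  # misaligned stacks refuse
  truth2 <- landscape_truth(
    data.frame(name = c("a", "b"), corr_length = 270, coef = c(1, 1),
               true_scale = 810), intercept = 0,
    nrow = 25, ncol = 25, scales = 90 * c(3, 9, 15))
  stack2 <- simulate_landscape(truth2)
  stack2$b <- grd(stack2$b$values, 90, xmin = 500)
  expect_error(true_suitability(stack2, truth2), "aligned")
})

test_that("occurrence sampling follows the suitability surface", {
  # uniform suitability: quadrant counts pass a chi-square uniformity check
  u <- grd(matrix(1, 60, 60), 90)
  occ <- sample_occurrences(u, 2000, seed = 5)
  ext <- grd_extent(u)
  qx <- occ$x > mean(ext[1:2]); qy <- occ$y > mean(ext[3:4])
  tab <- table(qx, qy)
  expect_gt(chisq.test(as.vector(tab))$p.value, 0.01)
  # mass on the left half only
  h <- grd(cbind(matrix(1, 40, 20), matrix(0, 40, 20)), 90)
  occ2 <- sample_occurrences(h, 300, seed = 6)
  expect_true(all(occ2$x < grd_extent(h)[1] + 20 * 90))
  expect_equal(nrow(sample_occurrences(u, 0)), 0L)
  z <- grd(matrix(0, 10, 10), 90)
  expect_error(sample_occurrences(z, 10), "zero everywhere")
  # points always fall inside the extent
  expect_true(all(occ$x >= ext[1] & occ$x <= ext[2] &
                  occ$y >= ext[3] & occ$y <= ext[4]))
})

test_that("two-species scenarios honour the niche offset", {
  truth <- tiny_truth(seed = 3)
  sc0 <- two_species_scenario(truth, delta = 0, n1 = 50, n2 = 50, seed = 3)
  expect_identical(sc0$suitability1$values, sc0$suitability2$values)
  expect_error(two_species_scenario(truth, delta = -1), "non-negative")
  # bitwise reproducibility of the whole scenario under a fixed seed
  sc0b <- two_species_scenario(truth, delta = 0, n1 = 50, n2 = 50, seed = 3)
  expect_identical(sc0$occ1, sc0b$occ1)
  expect_identical(sc0$stack$bio1$values, sc0b$stack$bio1$values)
})

test_that("downstream D decreases from ~1 toward 0 as the offset grows", {
  # Monte-Carlo: D(0) high, D(2) low, expected D non-increasing over {0,1,2}
  truth <- landscape_truth(nrow = 150, ncol = 150, seed = 99)
  d_at <- function(delta, rep) {
    sc <- two_species_scenario(truth, delta = delta, n1 = 300, n2 = 300,
                               seed = rep)
    es <- scenario_espace(sc, truth, seed = rep)
    suppressWarnings(overlap_stats(density_surface(es$s1, es$espace),
                                   density_surface(es$s2, es$espace))[["D"]])
  }
  reps <- 1:6
  d0 <- vapply(reps, function(r) d_at(0, r), 0)
  d1 <- vapply(reps, function(r) d_at(1, r), 0)
  d2 <- vapply(reps, function(r) d_at(2, r), 0)
  expect_gt(mean(d0), 0.8)
  expect_lt(mean(d2), 0.3)
  expect_true(mean(d0) >= mean(d1) && mean(d1) >= mean(d2))
})

test_that("child seeds are deterministic and within integer range", {
  expect_identical(child_seed(1, 2), child_seed(1, 2))
  expect_false(child_seed(1, 2) == child_seed(1, 3))
  s <- vapply(1:50, function(i) child_seed(2147483646, i), 0L)
  expect_true(all(s >= 0 & s < 2^31))
})
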