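# Surfaces, AUC/TSS, binarization, scenario projection, change accounting.

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUC equals brute-force pair counting, ties included", {
  expect_equal(evaluate_model(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0))$auc, 0.875)
  em <- evaluate_model(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(em$auc, 1)
  expect_equal(em$tss, 1)
  for (rep in 1:25) {
    set.seed(rep)
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)            # heavy ties
    expect_equal(evaluate_model(scores, labels)$auc, brute_auc(scores, labels))
  }
  # permuted labels sit near chance
  set.seed(100)
  sc <- runif(1000); lb <- sample(rep(0:1, 500))
  expect_lt(abs(evaluate_model(sc, lb)$auc - 0.5), 0.05)
  expect_error(evaluate_model(sc, rep(1, 1000)), "both classes")
})

test_that("pROC agrees with the rank-statistic AUC", {
  skip_if_not_installed("pROC")
  set.seed(41)
  sc <- round(runif(150), 2); lb <- rbinom(150, 1, 0.5)
  expect_equal(evaluate_model(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("binarization is consistent with the evaluated confusion matrix", {
  surf <- grd(matrix(runif(100), 10, 10), 90)
  expect_true(all(binarize(surf, 0)$values == 1))
  expect_true(all(binarize(surf, max(surf$values) + 0.01)$values == 0))
  set.seed(42)
  scores <- runif(200); labels <- rbinom(200, 1, 0.5)
  em <- evaluate_model(scores, labels)
  pos <- scores >= em$threshold
  expect_equal(sum(pos & labels == 1) / sum(labels == 1), em$sensitivity)
  expect_equal(sum(!pos & labels == 0) / sum(labels == 0), em$specificity)
  expect_equal(em$tss, em$sensitivity + em$specificity - 1)
})

test_that("predicted surfaces equal row-wise predictions", {
  truth <- tiny_truth(seed = 51)
  feats <- sampled_features(truth, n = 150, seed = 51)
  fit <- fit_rf(feats[, c("bio1@810", "forest@810", "presence")],
                ntree = 100, seed = 2)
  # a tiny stack whose cells enumerate the first 12 training rows
  v1 <- matrix(feats[["bio1@810"]][1:12], 3, 4)
  v2 <- matrix(feats[["forest@810"]][1:12], 3, 4)
  stack <- list(`bio1@810` = grd(v1, 90), `forest@810` = grd(v2, 90))
  surf <- predict_surface(fit, stack)
  rowwise <- predict(fit$forest,
                     data.frame(`bio1@810` = as.vector(v1),
                                `forest@810` = as.vector(v2),
                                check.names = FALSE), type = "prob")[, "1"]
  expect_equal(as.vector(surf$values), unname(rowwise))
  # nodata propagates; constant stacks give constant surfaces
  stack$`bio1@810`$values[2, 2] <- NA
  surf2 <- predict_surface(fit, stack)
  expect_true(is.na(surf2$values[2, 2]))
  cstack <- list(`bio1@810` = grd(matrix(0.1, 3, 3), 90),
                 `forest@810` = grd(matrix(0.2, 3, 3), 90))
  expect_equal(length(unique(as.vector(predict_surface(fit, cstack)$values))), 1L)
  expect_error(predict_surface(fit, cstack[1]), "forest@810")
})

test_that("scenario projection replaces climate layers at fitted scales", {
  truth <- tiny_truth(seed = 52)
  raw <- simulate_landscape(truth)
  feats <- sampled_features(truth, n = 150, seed = 52)
  m <- msrf(feats, truth$scales, ntree = 150, seed = 3, select = FALSE)
  stack <- build_multiscale_stack(raw, truth$scales)
  current <- predict_surface(m, stack)
  # scenario identical to current: surface identical
  same <- project_scenario(m, raw, list(bio1 = raw$bio1))
  expect_equal(same$values, current$values)
  # a model with no climate variables ignores the scenario (message notes it)
  nc_cols <- grep("^(forest|rough)@", names(feats), value = TRUE)
  m2 <- fit_rf(feats[, c(nc_cols, "presence")], ntree = 150, seed = 3)
  cur2 <- predict_surface(m2, stack)
  expect_message(fut2 <- project_scenario(m2, raw,
                                          list(bio1 = grd(raw$bio1$values + 1, 90))),
                 "not used")
  expect_equal(fut2$values, cur2$values)
  # warming a positively influential layer never decreases mean suitability.
  # Built so the partial dependence is monotone: the response is a Bernoulli
  # draw from an increasing logistic in the single climate feature.
  set.seed(53)
  xtr <- rnorm(400)
  mono <- data.frame(`clim@270` = xtr,
                     presence = rbinom(400, 1, plogis(2 * xtr)),
                     check.names = FALSE)
  m3 <- fit_rf(mono, ntree = 300, seed = 5)
  fld <- gaussian_field(40, 40, 90, corr_length = 270, seed = 54)
  cur3 <- predict_surface(m3, list(`clim@270` = focal_mean(fld, 270)))
  warm <- project_scenario(m3, list(clim = fld),
                           list(clim = grd(fld$values + 0.5, 90)))
  expect_gte(mean(warm$values), mean(cur3$values))
})

test_that("change accounting reproduces its identities on random map pairs", {
  for (rep in 1:100) {
    set.seed(rep)
    a <- grd(matrix(rbinom(64, 1, runif(1)), 8, 8), 90)
    b <- grd(matrix(rbinom(64, 1, runif(1)), 8, 8), 90)
    ch <- change_accounting(a, b)
    cell <- 0.81
    expect_equal(ch$stable_ha + ch$loss_ha, ch$current_ha)
    expect_equal(ch$stable_ha + ch$gain_ha, ch$scenario_ha)
    expect_equal(ch$net_ha, ch$gain_ha - ch$loss_ha)
    expect_equal(ch$current_ha, sum(a$values) * cell)
    expect_equal(ch$scenario_ha, sum(b$values) * cell)
  }
  g <- grd(matrix(c(1, 1, 0, 0), 2, 2), 90)
  ident <- change_accounting(g, g)
  expect_equal(ident$stable_pct, 100)
  expect_equal(ident$gain_ha, 0)
  expect_equal(ident$loss_ha, 0)
  expect_equal(ident$net_ha, 0)
  # change map codes: 0 never, 1 stable, 2 gain, 3 loss
  a <- grd(matrix(c(1, 1, 0, 0), 2, 2), 90)
  b <- grd(matrix(c(1, 0, 1, 0), 2, 2), 90)
  map <- attr(change_accounting(a, b), "map")$values
  expect_equal(as.vector(map), c(1, 3, 2, 0))
  expect_error(change_accounting(a, grd(matrix(0, 3, 3), 90)), "aligned")
})
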