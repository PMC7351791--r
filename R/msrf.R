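# The core estimator: a multi-scale random forest habitat model. `fit_rf`
# fits the classification forest with permutation importance; MIR (Model
# Improvement Ratio) rescales importance to [0, 1] by the top variable; the
# stepwise selector refits at MIR thresholds 0.0-0.9 and keeps the most
# parsimonious model by OOB error. `msrf()` wraps scale optimization,
# the full fit and the MIR selection into one classed model object.

#' Fit a random forest habitat model
#'
#' Classification forest on a binary presence/absence response with unscaled
#' permutation importance (mean decrease in OOB accuracy, the classification
#' analogue of %IncMSE). Deterministic under a fixed seed.
#'
#' @param data Feature data frame: predictor columns plus binary `presence`.
#' @param ntree Number of trees (default 500).
#' @param mtry Variables tried per split (default `floor(sqrt(p))`).
#' @param seed Integer seed.
#' @return An object of class `rf_fit`: the forest, out-of-bag vote
#'   fractions (`votes`, for honest training-set evaluation), OOB error,
#'   per-class error rates, permutation importance and MIR per variable.
#' @export
fit_rf <- function(data, ntree = 500, mtry = NULL, seed = 1) {
  if (!"presence" %in% names(data)) stop("data must have a presence column", call. = FALSE)
  y <- as.factor(data$presence)
  if (nlevels(droplevels(y)) < 2L) stop("response has a single class", call. = FALSE)
  x <- data[, setdiff(names(data), "presence"), drop = FALSE]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                                       importance = TRUE)
  err <- forest$err.rate[ntree, ]
  imp <- randomForest::importance(forest, type = 1, scale = FALSE)[, 1L]
  structure(list(forest = forest,
                 votes = unname(forest$votes[, "1"]),  # OOB vote fractions
                 oob = unname(err["OOB"]),
                 class_error = err[setdiff(names(err), "OOB")],
                 importance = imp,
                 mir = model_improvement_ratio(imp),
                 vars = colnames(x),
                 ntree = ntree, mtry = mtry, seed = as.integer(seed)),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("rf_fit: %d trees, %d variable(s), OOB error %.4f\n",
              x$ntree, length(x$vars), x$oob))
  cat("class errors:", paste(sprintf("%s=%.4f", names(x$class_error),
                                     x$class_error), collapse = ", "), "\n")
  invisible(x)
}

#' Model Improvement Ratio
#'
#' Importance of each variable divided by the maximum importance; negative
#' importances are floored at zero, so MIR lies in `[0, 1]` with the top
#' variable at exactly 1.
#'
#' @param importances Named numeric vector of permutation importances with at
#'   least one positive entry.
#' @return MIR vector in `[0, 1]`.
#' @examples
#' model_improvement_ratio(c(a = 4, b = 2, c = 1))  # 1.0 0.5 0.25
#' @export
model_improvement_ratio <- function(importances) {
  if (max(importances) <= 0)
    stop("degenerate model: no variable has positive importance", call. = FALSE)
  pmax(importances, 0) / max(importances)
}

#' Stepwise MIR variable selection
#'
#' Subsets variables at MIR thresholds 0.0, 0.1, ..., 0.9 (MIR always taken
#' from the original full model, guarding against overfitting), refits at
#' each threshold, and keeps the model with the lowest OOB error, ties broken
#' by lowest maximum within-class error, then by fewest variables. Thresholds
#' yielding an already-evaluated subset are recorded but not refit.
#'
#' @param data Feature data frame used for the base fit.
#' @param base An `rf_fit` on the full candidate set (fitted from `data` when
#'   omitted).
#' @param ntree,seed Forest settings for the refits.
#' @param thresholds MIR thresholds (default `seq(0, 0.9, 0.1)`).
#' @return An object of class `mir_trace`: the per-threshold trace, the
#'   winning threshold and the final `rf_fit`.
#' @export
mir_stepwise_select <- function(data, base = NULL, ntree = 500, seed = 1,
                                thresholds = seq(0, 0.9, by = 0.1)) {
  if (is.null(base)) base <- fit_rf(data, ntree = ntree, seed = seed)
  mir <- base$mir
  trace <- data.frame(threshold = thresholds, n_vars = NA_integer_,
                      oob = NA_real_, max_class_error = NA_real_,
                      duplicate = FALSE, skipped = FALSE)
  fits <- list()
  subsets <- character(0)
  retained <- list()
  for (i in seq_along(thresholds)) {
    keep <- names(mir)[mir >= thresholds[i]]
    retained[[i]] <- keep
    trace$n_vars[i] <- length(keep)
    if (length(keep) < 1L) {          # cannot fit an empty model
      trace$skipped[i] <- TRUE
      next
    }
    key <- paste(sort(keep), collapse = "|")
    prev <- match(key, subsets)
    if (!is.na(prev)) {
      trace$duplicate[i] <- TRUE
      trace$oob[i] <- trace$oob[prev]
      trace$max_class_error[i] <- trace$max_class_error[prev]
      next
    }
    subsets[i] <- key
    fit <- fit_rf(data[, c(keep, "presence"), drop = FALSE],
                  ntree = ntree, seed = seed)
    fits[[i]] <- fit
    trace$oob[i] <- fit$oob
    trace$max_class_error[i] <- max(fit$class_error)
  }
  cand <- which(!trace$skipped & !trace$duplicate)
  ord <- cand[order(trace$oob[cand], trace$max_class_error[cand],
                    trace$n_vars[cand])]
  win <- ord[1L]
  structure(list(trace = trace, retained = retained,
                 winner_threshold = thresholds[win],
                 winner_vars = retained[[win]],
                 fit = fits[[win]], mir = mir),
            class = "mir_trace")
}

#' @export
print.mir_trace <- function(x, ...) {
  cat(sprintf("mir_trace: winner at threshold %.1f with %d variable(s), OOB %.4f\n",
              x$winner_threshold, length(x$winner_vars), x$fit$oob))
  print(x$trace)
  invisible(x)
}

#' Multi-scale random forest habitat model
#'
#' The package's central fit. Given a feature matrix holding every candidate
#' variable at every rung of the scale ladder, `msrf` (i) selects each
#' variable's best scale by univariate OOB error, (ii) optionally filters the
#' scale-optimized candidates for collinearity, (iii) fits the multivariate
#' forest with permutation importance, and (iv) runs stepwise MIR selection
#' to the most parsimonious model.
#'
#' @param data Feature data frame with `var@scale` columns for every scale in
#'   `scales`, plus binary `presence`.
#' @param scales The scale ladder the columns cover.
#' @param ntree Trees per forest (default 500).
#' @param seed Master seed; scale optimization, the full fit and the
#'   selection refits each use fixed children.
#' @param collinearity `|r|` threshold applied to the scale-optimized
#'   candidates before the multivariate fit; `NULL` disables the filter.
#' @param select Run MIR stepwise selection (default `TRUE`).
#' @return An object of class `msrf` with components `scales` (the
#'   [optimize_scales()] result), `full_fit`, `selection` (the `mir_trace`)
#'   and `fit` (the final `rf_fit`).
#' @seealso [predict.msrf()], [predict_surface()], [evaluate_model()]
#' @export
msrf <- function(data, scales, ntree = 500, seed = 1, collinearity = 0.50,
                 select = TRUE) {
  sel <- optimize_scales(data, scales, ntree = ntree, seed = child_seed(seed, 1))
  cols <- scale_col(sel$var, sel$scale)
  sub <- data[, c(cols, "presence"), drop = FALSE]
  if (!is.null(collinearity) && length(cols) > 1L) {
    keep <- collinearity_filter(sub, threshold = collinearity)
    sub <- sub[, c(keep, "presence"), drop = FALSE]
  }
  full <- fit_rf(sub, ntree = ntree, seed = child_seed(seed, 2))
  trace <- NULL
  fit <- full
  if (select && length(full$vars) > 1L) {
    trace <- mir_stepwise_select(sub, base = full, ntree = ntree,
                                 seed = child_seed(seed, 3))
    fit <- trace$fit
  }
  structure(list(scales = sel, full_fit = full, selection = trace, fit = fit,
                 ladder = scales, seed = as.integer(seed)),
            class = "msrf")
}

#' @export
print.msrf <- function(x, ...) {
  cat("Multi-scale random forest habitat model\n")
  cat(sprintf("  %d base variable(s) scale-optimized over ladder {%s} m\n",
              nrow(x$scales), paste(x$ladder, collapse = ", ")))
  cat(sprintf("  final model: %d variable(s), OOB error %.4f\n",
              length(x$fit$vars), x$fit$oob))
  if (!is.null(x$selection))
    cat(sprintf("  MIR winner threshold: %.1f\n", x$selection$winner_threshold))
  invisible(x)
}

#' @export
summary.msrf <- function(object, ...) {
  cat("Multi-scale random forest habitat model\n\nSelected scales:\n")
  print.data.frame(object$scales)
  cat("\nFinal model variables (MIR from the full model):\n")
  mir <- object$full_fit$mir[object$fit$vars]
  print(data.frame(variable = object$fit$vars,
                   importance = unname(object$full_fit$importance[object$fit$vars]),
                   mir = unname(mir))[order(-mir), ])
  cat(sprintf("\nOOB error %.4f; class errors: %s\n", object$fit$oob,
              paste(sprintf("%s=%.4f", names(object$fit$class_error),
                            object$fit$class_error), collapse = ", ")))
  invisible(object)
}

#' Predict from a multi-scale habitat model
#'
#' @param object An `msrf`.
#' @param newdata A feature data frame holding the model's `var@scale`
#'   columns, or a named list of `grd` layers (in which case a suitability
#'   surface is returned via [predict_surface()]).
#' @param ... Unused.
#' @return Numeric vector of presence vote fractions, or a `grd`.
#' @export
predict.msrf <- function(object, newdata, ...) {
  if (is.list(newdata) && length(newdata) && inherits(newdata[[1L]], "grd"))
    return(predict_surface(object, newdata))
  rf_votes(object$fit, newdata)
}

#' MIR plot of the final model
#'
#' Horizontal bar plot of Model Improvement Ratio for the variables retained
#' in the final model, most important at the top.
#'
#' @param x An `msrf`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.msrf <- function(x, ...) {
  mir <- sort(x$full_fit$mir[x$fit$vars])
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(mir, horiz = TRUE, las = 1, xlab = "Model Improvement Ratio",
                    main = "MIR of retained variables", ...)
  invisible(x)
}

# presence vote fraction for a feature table; NA rows propagate
rf_votes <- function(fit, newdata) {
  stopifnot(inherits(fit, "rf_fit"))
  miss <- setdiff(fit$vars, names(newdata))
  if (length(miss))
    stop("newdata is missing layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nd <- newdata[, fit$vars, drop = FALSE]
  ok <- rowSums(is.na(nd)) == 0L
  out <- rep(NA_real_, nrow(nd))
  if (any(ok))
    out[ok] <- stats::predict(fit$forest, nd[ok, , drop = FALSE],
                              type = "prob")[, "1"]
  out
}
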