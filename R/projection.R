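# Suitability surfaces, AUC/TSS evaluation, binarization, climate-scenario
# projection and stable/gain/loss change accounting.

#' Predict a suitability surface
#'
#' Cellwise ensemble vote fraction for presence over a stack of `var@scale`
#' layers covering every variable in the fit. Nodata propagates.
#'
#' @param fit An `rf_fit` or `msrf`.
#' @param stack Named list of `grd` layers keyed `var@scale`.
#' @param scenario Tag stored on the result (e.g. `"current"`).
#' @return A `grd` of probabilities with attribute `"scenario"`.
#' @export
predict_surface <- function(fit, stack, scenario = "current") {
  if (inherits(fit, "msrf")) fit <- fit$fit
  stopifnot_aligned(stack)
  miss <- setdiff(fit$vars, names(stack))
  if (length(miss))
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tmpl <- stack[[1L]]
  nd <- as.data.frame(lapply(stack[fit$vars], function(g) as.vector(g$values)))
  names(nd) <- fit$vars
  p <- rf_votes(fit, nd)
  out <- grd(matrix(p, nrow(tmpl$values), ncol(tmpl$values)),
             tmpl$cellsize, tmpl$xmin, tmpl$ymin)
  attr(out, "scenario") <- scenario
  out
}

#' Evaluate presence/absence predictions
#'
#' AUC by the rank statistic (ties get half credit) and the True Skill
#' Statistic maximized over all observed score thresholds (prediction
#' positive when `score >= threshold`).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return An object of class `eval_metrics`: `auc`, `tss`, `threshold`
#'   (score at which TSS peaks), `sensitivity`, `specificity`.
#' @export
evaluate_model <- function(scores, labels) {
  labels <- as.integer(as.character(factor(labels)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                       # midranks give ties half credit
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  best <- list(tss = -Inf)
  for (t in thr) {
    pos <- scores >= t
    sens <- sum(pos & labels == 1L) / n1
    spec <- sum(!pos & labels == 0L) / n0
    if (sens + spec - 1 > best$tss)
      best <- list(tss = sens + spec - 1, threshold = t,
                   sensitivity = sens, specificity = spec)
  }
  structure(c(list(auc = auc), best[c("tss", "threshold", "sensitivity",
                                      "specificity")]),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f | TSS %.4f at threshold %.4f (sens %.4f, spec %.4f)\n",
              x$auc, x$tss, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Binarize a suitability surface
#'
#' @param surface A `grd` of probabilities.
#' @param threshold Cut-point in `(0, 1)` or 0/1 for the degenerate all/none
#'   maps; cells with probability `>= threshold` are suitable (1). Nodata is
#'   preserved. The package default policy is the max-TSS threshold from
#'   [evaluate_model()] on training data.
#' @return A binary `grd`.
#' @export
binarize <- function(surface, threshold) {
  v <- (surface$values >= threshold) * 1
  grd(v, surface$cellsize, surface$xmin, surface$ymin)
}

#' Project a fitted model under scenario climate layers
#'
#' Raw climate layers named in `scenario_layers` replace their counterparts
#' in `raw_current`; focal means are recomputed at each variable's fitted
#' scale; non-climate layers are untouched; the model then predicts the
#' scenario surface. Supplying a scenario identical to the current layers
#' reproduces the current surface exactly.
#'
#' @param fit An `rf_fit` or `msrf` whose variables are `var@scale` columns.
#' @param raw_current Named list of raw (unsmoothed) `grd` layers for every
#'   base variable in the fit.
#' @param scenario_layers Named list of raw replacement layers (typically the
#'   bioclim subset); every name must be a base variable of the fit or it is
#'   ignored with a message; a fitted climate variable missing from
#'   `raw_current` is an error.
#' @param scenario Tag for the output surface.
#' @return A `grd` suitability surface.
#' @export
project_scenario <- function(fit, raw_current, scenario_layers,
                             scenario = "scenario") {
  if (inherits(fit, "msrf")) fit <- fit$fit
  info <- split_scale_col(fit$vars)
  miss <- setdiff(unique(info$var), names(raw_current))
  if (length(miss))
    stop("raw_current is missing base layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(scenario_layers), unique(info$var))
  if (length(extra))
    message("scenario layer(s) not used by the model: ",
            paste(extra, collapse = ", "))
  raw <- raw_current
  for (nm in intersect(names(scenario_layers), names(raw)))
    raw[[nm]] <- scenario_layers[[nm]]
  stack <- list()
  for (i in seq_len(nrow(info)))
    stack[[fit$vars[i]]] <- focal_mean(raw[[info$var[i]]], info$scale[i])
  predict_surface(fit, stack, scenario = scenario)
}

#' Stable/gain/loss change accounting between two binary maps
#'
#' Each cell is classed stable (1 -> 1), loss (1 -> 0), gain (0 -> 1) or
#' never (0 -> 0); areas are cell counts times the cell area. The identities
#' `stable + loss = current`, `stable + gain = scenario` and
#' `net = gain - loss` hold exactly in cell counts. Percentages are relative
#' to the CURRENT suitable area.
#'
#' @param current_bin,scenario_bin Aligned binary `grd`s.
#' @param cell_area_ha Cell area in hectares (default from the cell size;
#'   a 90 m cell is 0.81 ha).
#' @return A `change_summary`; its `"map"` attribute is a `grd` coded
#'   0 = never, 1 = stable, 2 = gain, 3 = loss.
#' @export
change_accounting <- function(current_bin, scenario_bin,
                              cell_area_ha = current_bin$cellsize^2 / 1e4) {
  if (!same_spec(current_bin, scenario_bin))
    stop("grids are not aligned", call. = FALSE)
  a <- current_bin$values; b <- scenario_bin$values
  ok <- !is.na(a) & !is.na(b)
  stable <- sum(a == 1 & b == 1 & ok)
  gain <- sum(a == 0 & b == 1 & ok)
  loss <- sum(a == 1 & b == 0 & ok)
  out <- change_summary(current_ha = (stable + loss) * cell_area_ha,
                        stable_ha = stable * cell_area_ha,
                        gain_ha = gain * cell_area_ha,
                        cell_area_ha = cell_area_ha)
  cls <- matrix(NA_real_, nrow(a), ncol(a))
  cls[ok] <- 0
  cls[a == 1 & b == 1 & ok] <- 1
  cls[a == 0 & b == 1 & ok] <- 2
  cls[a == 1 & b == 0 & ok] <- 3
  attr(out, "map") <- grd(cls, current_bin$cellsize, current_bin$xmin,
                          current_bin$ymin)
  out
}

#' Change summary from suitable-area components
#'
#' The bookkeeping behind the change table: given the current suitable area,
#' the stable area and the gained area (hectares), derives the scenario
#' total (`stable + gain`), the loss (`current - stable`), the net change
#' (`gain - loss`) and the stable/gain/loss percentages of the current
#' suitable area.
#'
#' @param current_ha,stable_ha,gain_ha Areas in hectares.
#' @param cell_area_ha Optional cell area carried on the result.
#' @return An object of class `change_summary`.
#' @export
change_summary <- function(current_ha, stable_ha, gain_ha, cell_area_ha = NA) {
  if (stable_ha > current_ha + 1e-9)
    stop("stable area cannot exceed the current suitable area", call. = FALSE)
  loss_ha <- current_ha - stable_ha
  scenario_ha <- stable_ha + gain_ha
  pct <- function(x) if (current_ha > 0) 100 * x / current_ha else NA_real_
  structure(list(current_ha = current_ha, scenario_ha = scenario_ha,
                 stable_ha = stable_ha, gain_ha = gain_ha, loss_ha = loss_ha,
                 net_ha = gain_ha - loss_ha,
                 stable_pct = pct(stable_ha), gain_pct = pct(gain_ha),
                 loss_pct = pct(loss_ha), net_pct = pct(gain_ha - loss_ha),
                 cell_area_ha = cell_area_ha),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("current %.2f ha -> scenario %.2f ha\n", x$current_ha, x$scenario_ha))
  cat(sprintf("stable %.2f ha (%.2f%%) | gain %.2f ha (%.2f%%) | loss %.2f ha (%.2f%%)\n",
              x$stable_ha, x$stable_pct, x$gain_ha, x$gain_pct,
              x$loss_ha, x$loss_pct))
  cat(sprintf("net %.2f ha (%.2f%% of current)\n", x$net_ha, x$net_pct))
  invisible(x)
}
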