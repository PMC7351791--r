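# Out-of-bag scale optimization: univariate random forests per variable at
# every rung of the scale ladder, keeping the scale with minimum OOB error.

#' Out-of-bag error of a univariate random forest
#'
#' Fits a classification forest on a single predictor and returns the OOB
#' misclassification proportion (majority vote over out-of-bag trees).
#' Deterministic under a fixed seed.
#'
#' @param x Numeric predictor vector.
#' @param y Binary response (0/1 vector or factor with two levels).
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return OOB error in `[0, 1]`.
#' @export
univariate_oob <- function(x, y, ntree = 500, seed = 1) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("response has a single class", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = data.frame(x = x), y = y,
                                    ntree = ntree, mtry = 1)
  unname(fit$err.rate[ntree, "OOB"])
}

#' Select the best scale per variable by OOB error
#'
#' For each base variable present as `var@scale` columns, fits a univariate
#' forest at every scale and keeps the scale with the minimum OOB error. Ties
#' are broken toward the smaller scale (parsimony) and flagged.
#'
#' @param data Feature data frame with `var@scale` columns and a binary
#'   `presence` column.
#' @param scales Scale ladder; every variable must be present at every scale.
#' @param ntree Trees per univariate forest.
#' @param seed Master seed (each variable-scale fit uses a fixed child).
#' @return An object of class `scale_selection`: a data frame with one row
#'   per variable (`var`, `scale`, `oob`, `tie`) and an `"oob"` attribute
#'   holding the full variable-by-scale OOB matrix.
#' @export
optimize_scales <- function(data, scales, ntree = 500, seed = 1) {
  if (!"presence" %in% names(data)) stop("data must have a presence column", call. = FALSE)
  info <- split_scale_col(setdiff(names(data), "presence"))
  vars <- unique(info$var)
  oob <- matrix(NA_real_, length(vars), length(scales),
                dimnames = list(vars, as.character(scales)))
  y <- data$presence
  k <- 0L
  for (v in vars) for (s in scales) {
    k <- k + 1L
    col <- scale_col(v, s)
    if (!col %in% names(data))
      stop("missing variable-scale column: ", col, call. = FALSE)
    oob[v, as.character(s)] <- univariate_oob(data[[col]], y, ntree = ntree,
                                              seed = child_seed(seed, k))
  }
  sel <- data.frame(var = vars, scale = NA_real_, oob = NA_real_, tie = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(vars)) {
    e <- oob[i, ]
    best <- which(e == min(e))
    sel$scale[i] <- scales[best[1L]]     # ties -> smaller scale
    sel$oob[i] <- e[best[1L]]
    sel$tie[i] <- length(best) > 1L
  }
  attr(sel, "oob") <- oob
  class(sel) <- c("scale_selection", "data.frame")
  sel
}

#' @export
print.scale_selection <- function(x, ...) {
  cat("scale_selection:", nrow(x), "variable(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Frequency of selected scales
#'
#' Tally of how often each scale of the ladder was selected across variables
#' (the histogram plotted in multi-scale habitat studies).
#'
#' @param selections A `scale_selection` from [optimize_scales()].
#' @return Named integer vector (scale -> count); counts sum to the number of
#'   variables.
#' @export
scale_frequency <- function(selections) {
  if (nrow(selections) == 0) stop("empty selection list", call. = FALSE)
  tab <- table(selections$scale)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
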