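# End-to-end orchestration from a single structured (YAML) config: simulate a
# landscape with known truth, prepare occurrences, build multi-scale
# features, optimize scales, select variables, fit, evaluate, project under
# a scenario, account change, and run the niche comparison. All randomness
# flows from the master seed through fixed child seeds.

#' Write a demo pipeline configuration
#'
#' A small synthetic run (150 x 150 cells at 90 m, reduced scale ladder)
#' exercising every stage, sized to finish in well under a minute.
#'
#' @param path Output YAML path.
#' @param seed Master seed stored in the config.
#' @param outdir Output directory the pipeline writes into.
#' @return `path`, invisibly.
#' @export
demo_config <- function(path, seed = 1, outdir = tempfile("scalehab_run")) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    grid = list(nrow = 150, ncol = 150, cellsize = 90),
    covariates = list(
      list(name = "bio1", corr_length = 450, coef = 18, true_scale = 1350),
      list(name = "bio12", corr_length = 630, coef = 0),
      list(name = "forest", corr_length = 270, coef = -12, true_scale = 810),
      list(name = "rough", corr_length = 180, coef = 0)),
    intercept = 0,
    scales = 90 * c(3, 6, 9, 12, 15),
    n_occurrences = 400,
    thinning = list(min_dist = 200),
    pseudo_absence = list(n_candidates = 2000, buffer = 200),
    rf = list(ntree = 200),
    scenario = list(vars = list("bio1"), shift = 0.75),
    niche = list(R = 80, reps = 99, delta = 1.5, n2 = 200, n_background = 500))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list) and reports every problem at once
#' rather than failing at the first.
#'
#' @param config Path to a YAML file or a config list.
#' @return A list with `ok` (logical), `errors` (character vector) and
#'   `config` (the parsed list, with defaults filled).
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  errors <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  need(!is.null(cfg$seed), "seed: missing")
  need(!is.null(cfg$grid) && all(c("nrow", "ncol", "cellsize") %in% names(cfg$grid)),
       "grid: needs nrow, ncol, cellsize")
  if (!is.null(cfg$grid$cellsize)) need(cfg$grid$cellsize > 0, "grid: cellsize must be > 0")
  if (!is.null(cfg$grid$nrow)) need(cfg$grid$nrow > 0 && cfg$grid$ncol > 0,
                                    "grid: shape must be positive")
  scales <- unlist(cfg$scales)
  need(length(scales) >= 1 && all(scales > 0) && !is.unsorted(scales, strictly = TRUE),
       "scales: must be positive and strictly increasing")
  need(length(cfg$covariates) >= 1, "covariates: at least one required")
  for (cv in cfg$covariates) {
    need(!is.null(cv$name), "covariates: every entry needs a name")
    if (!is.null(cv$true_scale) && !is.na(cv$true_scale))
      need(cv$true_scale %in% scales,
           sprintf("covariates: true_scale %s of %s is not on the scale ladder",
                   format(cv$true_scale), if (is.null(cv$name)) "?" else cv$name))
  }
  if (!is.null(cfg$pseudo_absence$buffer))
    need(cfg$pseudo_absence$buffer >= 0, "pseudo_absence: buffer must be >= 0")
  if (!is.null(cfg$thinning$min_dist))
    need(cfg$thinning$min_dist > 0, "thinning: min_dist must be > 0")
  if (!is.null(cfg$niche$reps))
    need(cfg$niche$reps >= 99, "niche: reps must be >= 99")
  need(!is.null(cfg$n_occurrences) && cfg$n_occurrences >= 20,
       "n_occurrences: must be at least 20")
  list(ok = length(errors) == 0L, errors = errors, config = cfg)
}

cfg_truth <- function(cfg) {
  cov <- do.call(rbind, lapply(cfg$covariates, function(cv)
    data.frame(name = cv$name,
               corr_length = cv$corr_length,
               coef = if (is.null(cv$coef)) 0 else cv$coef,
               true_scale = if (is.null(cv$true_scale)) NA_real_ else cv$true_scale,
               stringsAsFactors = FALSE)))
  landscape_truth(cov, intercept = if (is.null(cfg$intercept)) 0 else cfg$intercept,
                  nrow = cfg$grid$nrow, ncol = cfg$grid$ncol,
                  cellsize = cfg$grid$cellsize,
                  scales = unlist(cfg$scales), seed = cfg$seed)
}

#' Run the full pipeline
#'
#' Executes prepare, features, scales, select, fit, project, change and niche
#' on a synthetic landscape generated from the config's truth, persists
#' intermediates under `outdir` (ASCII grids, CSV tables, a JSON report) and
#' returns the report. Without a `scenario` section the projection and
#' change stages are skipped with a note. Reruns with the same config and
#' seed are numerically identical.
#'
#' @param config Path to a YAML config or a config list (see [demo_config()]).
#' @return The run report (list), invisibly also written to
#'   `outdir/report.json`.
#' @export
run_pipeline <- function(config) {
  val <- validate_config(config)
  if (!val$ok)
    stop("invalid config:\n  ", paste(val$errors, collapse = "\n  "), call. = FALSE)
  cfg <- val$config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  report <- list(seed = seed, stages = list())
  stage <- function(name) message("scalehab pipeline: ", name)

  # -- simulate + prepare -----------------------------------------------
  stage("prepare")
  truth <- cfg_truth(cfg)
  raw <- simulate_landscape(truth)
  suit <- true_suitability(raw, truth)
  write_asc(suit, file.path(cfg$outdir, "true_suitability.asc"))
  ext <- grd_extent(suit)
  occ_raw <- sample_occurrences(suit, cfg$n_occurrences,
                                seed = child_seed(seed, 11))
  occ <- suppressWarnings(spatial_thin(occ_raw, cfg$thinning$min_dist))
  pa <- generate_pseudo_absences(ext, occ,
                                 n_candidates = cfg$pseudo_absence$n_candidates,
                                 buffer = cfg$pseudo_absence$buffer,
                                 seed = child_seed(seed, 12))
  dat_xy <- assemble_dataset(occ, pa)
  utils::write.csv(dat_xy, file.path(cfg$outdir, "occurrences.csv"),
                   row.names = FALSE)
  report$stages$prepare <- list(
    seed = child_seed(seed, 11), n_raw = nrow(occ_raw), n_thinned = nrow(occ),
    n_absences = nrow(pa), prevalence = attr(dat_xy, "prevalence"))

  # -- features ----------------------------------------------------------
  stage("features")
  stack <- build_multiscale_stack(raw, truth$scales)
  feats <- extract_features(stack, dat_xy)
  utils::write.csv(feats, file.path(cfg$outdir, "features.csv"),
                   row.names = FALSE)
  report$stages$features <- list(n_rows = nrow(feats),
                                 n_columns = ncol(feats) - 1L)

  # -- scales / select / fit (the msrf core) -----------------------------
  stage("scales + select + fit")
  ntree <- if (is.null(cfg$rf$ntree)) 500 else cfg$rf$ntree
  model <- msrf(feats, truth$scales, ntree = ntree, seed = child_seed(seed, 13))
  utils::write.csv(as.data.frame(model$scales),
                   file.path(cfg$outdir, "scale_selection.csv"),
                   row.names = FALSE)
  report$stages$scales <- list(
    seed = child_seed(seed, 13),
    selected = stats::setNames(model$scales$scale, model$scales$var),
    frequency = scale_frequency(model$scales))
  report$stages$select <- list(
    winner_threshold = if (is.null(model$selection)) NA
                       else model$selection$winner_threshold,
    variables = model$fit$vars,
    mir = model$full_fit$mir[model$fit$vars])
  met <- evaluate_model(model$fit$votes, feats$presence)  # OOB votes: honest
  report$stages$fit <- list(oob = model$fit$oob,
                            class_error = model$fit$class_error,
                            auc = met$auc, tss = met$tss,
                            threshold = met$threshold)

  # -- project + change --------------------------------------------------
  if (is.null(cfg$scenario)) {
    report$stages$project <- list(skipped = "no scenario layers in config")
    report$stages$change <- list(skipped = "no scenario layers in config")
  } else {
    stage("project")
    current <- predict_surface(model, stack, scenario = "current")
    write_asc(current, file.path(cfg$outdir, "suitability_current.asc"))
    shift <- cfg$scenario$shift
    scen_raw <- list()
    for (v in unlist(cfg$scenario$vars))
      scen_raw[[v]] <- grd(raw[[v]]$values + shift, raw[[v]]$cellsize,
                           raw[[v]]$xmin, raw[[v]]$ymin)
    future <- project_scenario(model, raw, scen_raw, scenario = "future")
    write_asc(future, file.path(cfg$outdir, "suitability_future.asc"))
    report$stages$project <- list(
      scenario_vars = unlist(cfg$scenario$vars), shift = shift,
      mean_current = mean(current$values, na.rm = TRUE),
      mean_future = mean(future$values, na.rm = TRUE))
    stage("change")
    thr <- met$threshold
    chg <- change_accounting(binarize(current, thr), binarize(future, thr))
    write_asc(attr(chg, "map"), file.path(cfg$outdir, "change_map.asc"))
    report$stages$change <- list(threshold = thr,
                                 summary = unclass(chg)[c(
                                   "current_ha", "scenario_ha", "stable_ha",
                                   "gain_ha", "loss_ha", "net_ha", "stable_pct",
                                   "gain_pct", "loss_pct", "net_pct")])
  }

  # -- niche -------------------------------------------------------------
  stage("niche")
  nc <- cfg$niche
  scen2 <- two_species_scenario(truth, delta = nc$delta,
                                n1 = min(cfg$n_occurrences, 300), n2 = nc$n2,
                                seed = child_seed(seed, 14))
  set.seed(child_seed(seed, 15))
  bg_pts <- data.frame(x = stats::runif(nc$n_background, ext[1], ext[2]),
                       y = stats::runif(nc$n_background, ext[3], ext[4]))
  env <- truth_env_stack(raw, truth)   # the axes the species select on
  bg_env <- extract_features(env, bg_pts)
  esp <- build_espace(bg_env, bg_env, R = nc$R)
  s1 <- espace_scores(esp, extract_features(env, scen2$occ1))
  s2 <- espace_scores(esp, extract_features(env, scen2$occ2))
  eq <- suppressWarnings(
    equivalency_test(s1, s2, esp, reps = nc$reps, seed = child_seed(seed, 16)))
  d1 <- suppressWarnings(density_surface(s1, esp))
  d2 <- suppressWarnings(density_surface(s2, esp))
  bgd <- suppressWarnings(density_surface(esp$scores1, esp,
                                          source = "background"))
  pn1 <- pnti(d1, bgd); pn2 <- pnti(d2, bgd)
  nec <- neci(bgd, bgd)
  report$stages$niche <- list(
    seed = child_seed(seed, 16), delta = nc$delta,
    explained = esp$explained[1:2],
    D = eq$D_obs, I = eq$I_obs, equivalency_p = eq$p, reps = eq$reps,
    pnti = c(sp1 = pn1$pnti, sp2 = pn2$pnti),
    neci = nec$neci)

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
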