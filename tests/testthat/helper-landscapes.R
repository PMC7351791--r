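# Shared fixtures, all generated in code.

# small landscape with two influential covariates (the package defaults,
# shrunk) for fast end-to-end tests
tiny_truth <- function(seed = 1, nrow = 120, ncol = 120) {
  landscape_truth(nrow = nrow, ncol = ncol, seed = seed,
                  scales = 90 * c(3, 6, 9, 12, 15))
}

# the single-covariate scale-recovery construction: a nearly uncorrelated
# field (90 m) whose focal mean at one ladder scale drives occupancy, with
# the effect strength set so the univariate forest at the true scale sits
# near 0.25-0.3 OOB error
recovery_truth <- function(seed, s_true = 1350) {
  landscape_truth(
    data.frame(name = "bio1", corr_length = 90, coef = 200,
               true_scale = s_true, stringsAsFactors = FALSE),
    intercept = 0, nrow = 300, ncol = 300, seed = seed)
}

# presence/absence feature matrix sampled from a truth's landscape
sampled_features <- function(truth, n = 300, seed = 1, n_candidates = 4000) {
  raw <- simulate_landscape(truth)
  suit <- true_suitability(raw, truth)
  occ <- sample_occurrences(suit, n, seed = child_seed(seed, 21))
  pa <- generate_pseudo_absences(grd_extent(suit), occ,
                                 n_candidates = n_candidates, buffer = 500,
                                 seed = child_seed(seed, 22))
  dat <- assemble_dataset(occ, pa)
  stack <- build_multiscale_stack(raw, truth$scales)
  extract_features(stack, dat)
}

# E-space + occurrence scores for a two-species scenario, analysed on the
# habitat axes the generator actually uses
scenario_espace <- function(scen, truth, n_background = 600, R = 80,
                            seed = 1) {
  env <- truth_env_stack(scen$stack, truth)
  ext <- grd_extent(env[[1L]])
  set.seed(child_seed(seed, 55))
  bg <- data.frame(x = runif(n_background, ext[1], ext[2]),
                   y = runif(n_background, ext[3], ext[4]))
  bg_env <- extract_features(env, bg)
  esp <- build_espace(bg_env, bg_env, R = R)
  list(espace = esp, env = env, extent = ext,
       s1 = espace_scores(esp, extract_features(env, scen$occ1)),
       s2 = espace_scores(esp, extract_features(env, scen$occ2)))
}

# random normalized density surface (for overlap property tests)
random_density <- function(R = 12, seed = 1, concentrated = FALSE) {
  set.seed(seed)
  z <- matrix(rexp(R * R), R, R)
  if (concentrated) z <- z * (matrix(runif(R * R), R, R) < 0.2)
  if (sum(z) == 0) z[1L] <- 1
  z / sum(z)
}
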