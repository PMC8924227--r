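#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic cohort: group sizes, the stimulus
#' grid (identities x examples organised into modules), the planted
#' factor structure behind the personality subscales, the
#' personality-to-judgment couplings per group, the neuronal population,
#' and the nuisance processes (reaction times, contamination).
#'
#' The two group-difference mechanisms are:
#' * `attenuation_asd` multiplies the control couplings for the ASD-like
#'   group; `0` plants an absent personality-judgment association.
#' * `distortion_lambda` mixes the identity-trait signal driving ASD
#'   ratings with an independent draw, `(1 - lambda) * tau + lambda *
#'   tau_tilde`, weakening rating-neural alignment without changing
#'   marginal rating distributions.
#'
#' @param n_asd,n_control Group sizes (defaults mirror the study cohort:
#'   89 ASD-like, 307 control-like).
#' @param n_identities,n_examples,n_traits,n_modules Stimulus grid: 50
#'   face identities x 10 examples shown across 10 modules, rated on 10
#'   social traits.
#' @param n_subscales,n_factors 33 questionnaire subscales generated
#'   from a planted 4-factor structure.
#' @param loading_range Range of uniform primary loadings.
#' @param cross_loading_sd SD of the Normal cross-loadings.
#' @param factor_corr Common off-diagonal factor correlation.
#' @param group_shift_f1 ASD-group mean shift on factor 1, in factor-SD
#'   units.
#' @param coupling_control `n_factors x n_traits` matrix of judgment
#'   units per factor SD for the control group (a default planting a
#'   prosocial pattern is supplied).
#' @param attenuation_asd Multiplier in `[0, 1]` applied to the control
#'   couplings for the ASD group (`1` = identical mechanism).
#' @param distortion_lambda Mixing weight in `[0, 1]` of the independent
#'   identity-trait draw used for ASD ratings.
#' @param n_neurons Number of simulated units.
#' @param region_probs Sampling probabilities for amygdala / anterior /
#'   posterior hippocampus (defaults proportional to 340/222/105).
#' @param baseline_rate_range Log-uniform range of baseline rates (Hz).
#' @param response_window_s,baseline_window_s Lengths (s) of the
#'   response and baseline counting windows.
#' @param response_gain Multiplicative elevation of tuned neurons'
#'   central response rate over baseline.
#' @param tuning_mean,tuning_sd Mean and SD of tuned neurons' per-trait
#'   weights (softplus input units). `tuning_mean` may be a length
#'   `n_traits` vector; its default weights approach-related traits
#'   (trustworthy 0.5, warm 0.35, others 0.1), the preferential coding
#'   of facial trustworthiness and warmth reported for amygdala and
#'   hippocampal populations. The positive mean is the
#'   population-consensus component of trait coding: averaging
#'   responses across neurons (how the population matrix is built)
#'   cancels zero-mean idiosyncratic tuning, so only this shared
#'   component survives into the population geometry.
#' @param prop_untuned Fraction of neurons with zero tuning and no
#'   response elevation (screened out downstream).
#' @param example_jitter_sd SD of per-example jitter around each
#'   identity's latent trait value.
#' @param rating_intercept,rating_slope,rating_noise_sd Likert
#'   propensity model: intercept (scale midpoint-ish), slope on the
#'   example trait value, and residual SD before round-and-clip to 1..7.
#' @param modules_range Integer range of modules completed per
#'   participant (uniform).
#' @param rt_lognorm_params `c(meanlog, sdlog)` of reaction times in ms.
#' @param contamination_rate Fraction of trials with RT forced outside
#'   `[100, 5000]` ms.
#' @param seed Root RNG seed; every generator derives its own stream.
#'
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_asd = 10, n_control = 20, seed = 1)
#' cfg$n_identities
sim_config <- function(n_asd = 89L,
                       n_control = 307L,
                       n_identities = 50L,
                       n_examples = 10L,
                       n_traits = 10L,
                       n_modules = 10L,
                       n_subscales = 33L,
                       n_factors = 4L,
                       loading_range = c(0.5, 0.8),
                       cross_loading_sd = 0.05,
                       factor_corr = 0.2,
                       group_shift_f1 = 0.6,
                       coupling_control = NULL,
                       attenuation_asd = 0.0,
                       distortion_lambda = 0.5,
                       n_neurons = 120L,
                       region_probs = c(340, 222, 105) / 667,
                       baseline_rate_range = c(0.05, 10),
                       response_window_s = 1.0,
                       baseline_window_s = 0.5,
                       response_gain = 1.5,
                       tuning_mean = NULL,
                       tuning_sd = 0.3,
                       prop_untuned = 0.3,
                       example_jitter_sd = 1.0,
                       rating_intercept = 4,
                       rating_slope = 0.8,
                       rating_noise_sd = 1.0,
                       modules_range = c(1L, 3L),
                       rt_lognorm_params = c(6.9, 0.4),
                       contamination_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_asd = n_asd, n_control = n_control,
    n_identities = n_identities, n_examples = n_examples,
    n_traits = n_traits, n_modules = n_modules,
    n_subscales = n_subscales, n_factors = n_factors,
    loading_range = loading_range, cross_loading_sd = cross_loading_sd,
    factor_corr = factor_corr, group_shift_f1 = group_shift_f1,
    coupling_control = coupling_control,
    attenuation_asd = attenuation_asd,
    distortion_lambda = distortion_lambda,
    n_neurons = n_neurons, region_probs = region_probs,
    baseline_rate_range = baseline_rate_range,
    response_window_s = response_window_s,
    baseline_window_s = baseline_window_s,
    response_gain = response_gain, tuning_mean = tuning_mean,
    tuning_sd = tuning_sd,
    prop_untuned = prop_untuned,
    example_jitter_sd = example_jitter_sd,
    rating_intercept = rating_intercept, rating_slope = rating_slope,
    rating_noise_sd = rating_noise_sd,
    modules_range = modules_range,
    rt_lognorm_params = rt_lognorm_params,
    contamination_rate = contamination_rate,
    seed = seed
  )
  if (is.null(cfg$coupling_control)) {
    cfg$coupling_control <- default_couplings(cfg$n_factors, cfg$n_traits)
  }
  if (is.null(cfg$tuning_mean)) {
    cfg$tuning_mean <- default_tuning_mean(cfg$n_traits)
  } else if (length(cfg$tuning_mean) == 1) {
    cfg$tuning_mean <- rep(cfg$tuning_mean, cfg$n_traits)
  }
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Default control-group couplings: a prosocial pattern (empathy and
# agreeableness raise trustworthy/warm judgments, antisociality lowers
# them slightly), in judgment units per factor SD.
default_couplings <- function(n_factors, n_traits) {
  gamma <- matrix(0, n_factors, n_traits,
    dimnames = list(
      paste0("factor", seq_len(n_factors)),
      if (n_traits == length(TRAIT_NAMES)) TRAIT_NAMES else paste0("trait", seq_len(n_traits))
    )
  )
  if (n_factors >= 4 && n_traits == length(TRAIT_NAMES)) {
    gamma["factor2", "trustworthy"] <- 0.15
    gamma["factor2", "warm"] <- 0.10
    gamma["factor2", "charismatic"] <- 0.12
    gamma["factor3", "trustworthy"] <- -0.05
    gamma["factor3", "warm"] <- -0.10
    gamma["factor4", "warm"] <- 0.12
    gamma["factor4", "trustworthy"] <- 0.10
  }
  gamma
}

# Consensus tuning weights across the population: approach-related
# traits dominate, mirroring preferential amygdala/hippocampal coding
# of facial trustworthiness and warmth.
default_tuning_mean <- function(n_traits) {
  if (n_traits == length(TRAIT_NAMES)) {
    w <- rep(0.1, n_traits)
    names(w) <- TRAIT_NAMES
    w["trustworthy"] <- 0.5
    w["warm"] <- 0.35
    w
  } else {
    rep(0.3, n_traits)
  }
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    abort(sprintf("invalid sim_config: `%s` %s", field, msg),
      class = "traitspace_config_error"
    )
  }
  counts <- c(
    "n_asd", "n_control", "n_identities", "n_examples", "n_traits",
    "n_modules", "n_subscales", "n_factors", "n_neurons"
  )
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v != round(v)) {
      stop_cfg(f, "must be a positive integer")
    }
  }
  for (f in c("attenuation_asd", "distortion_lambda", "contamination_rate",
              "prop_untuned")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_cfg(f, "must lie in [0, 1]")
    }
  }
  if (cfg$n_modules != cfg$n_examples) {
    stop_cfg("n_modules", "must equal n_examples (one example per identity per module)")
  }
  if (length(cfg$loading_range) != 2 || diff(cfg$loading_range) < 0) {
    stop_cfg("loading_range", "must be an increasing interval")
  }
  if (abs(cfg$factor_corr) >= 1) stop_cfg("factor_corr", "must be in (-1, 1)")
  if (cfg$response_window_s <= 0) stop_cfg("response_window_s", "must be positive")
  if (cfg$baseline_window_s <= 0) stop_cfg("baseline_window_s", "must be positive")
  if (length(cfg$baseline_rate_range) != 2 || any(cfg$baseline_rate_range <= 0) ||
      diff(cfg$baseline_rate_range) < 0) {
    stop_cfg("baseline_rate_range", "must be a positive increasing interval (Hz)")
  }
  gc_ <- cfg$coupling_control
  if (!is.matrix(gc_) || nrow(gc_) != cfg$n_factors || ncol(gc_) != cfg$n_traits) {
    stop_cfg("coupling_control", sprintf(
      "must be a %d x %d matrix", cfg$n_factors, cfg$n_traits
    ))
  }
  mr <- cfg$modules_range
  if (length(mr) != 2 || any(mr < 1) || mr[2] > cfg$n_modules || mr[1] > mr[2]) {
    stop_cfg("modules_range", "must be within [1, n_modules] and increasing")
  }
  if (length(cfg$rt_lognorm_params) != 2 || cfg$rt_lognorm_params[2] <= 0) {
    stop_cfg("rt_lognorm_params", "must be c(meanlog, sdlog) with sdlog > 0")
  }
  if (length(cfg$tuning_mean) != cfg$n_traits) {
    stop_cfg("tuning_mean", "must be a scalar or length n_traits")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop_cfg("seed", "must be a single number")
  }
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' Field names mirror [sim_config()] arguments; the matrix-valued
#' coupling field round-trips as a nested list. A config written and
#' re-read compares equal.
#'
#' @param path File path.
#' @param cfg A `sim_config`.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("tuning_mean", "region_probs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$coupling_control)) {
    raw$coupling_control <- do.call(rbind, lapply(raw$coupling_control, unlist))
    rownames(raw$coupling_control) <- paste0("factor", seq_len(nrow(raw$coupling_control)))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$coupling_control <- apply(out$coupling_control, 1, as.list, simplify = FALSE)
  out$tuning_mean <- as.list(out$tuning_mean)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
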