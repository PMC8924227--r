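#' Generate a synthetic participant cohort with planted ground truth
#'
#' Draws the ASD-like and control-like participants (demographics
#' emulate the study cohort), the planted factor structure (block
#' simple-structure loadings, correlated factors), per-participant
#' factor scores (ASD mean shifted on factor 1 by `group_shift_f1`),
#' the latent identity-trait values driving both ratings and neuronal
#' tuning, the independent "distorted" identity-trait draw used for the
#' ASD group's ratings, and the neuronal tuning weights. Everything
#' downstream (subscales, trials, neurons) is a deterministic function
#' of this truth plus its own derived RNG stream.
#'
#' @param config A [sim_config()].
#' @return A list with `participants` (tibble: `participant_id`,
#'   `group`, `sex`, `age`, `ses`) and `truth` (see Details).
#' @details `truth` is a list holding: `loadings` (subscales x factors),
#'   `phi` (factor correlation), `uniquenesses`, `factor_scores`
#'   (participants x factors), `identity_traits` and
#'   `identity_traits_distorted` (identities x traits),
#'   `example_traits` and `example_traits_distorted` (images x traits,
#'   image order lexicographic in identity then example),
#'   `module_of` (identities x examples -> module),
#'   `neuron_tuning` (neurons x traits), `neuron_baseline`,
#'   `neuron_untuned`, and per-group coupling matrices.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_asd = 5, n_control = 10, seed = 2))
#' nrow(cohort$participants)
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(derive_seed(cfg$seed, "cohort"), {
    p <- cfg$n_subscales
    k <- cfg$n_factors
    n <- cfg$n_asd + cfg$n_control

    # Block simple structure: subscales split into near-equal blocks
    # (10/9/7/7 at the 33/4 default), primaries uniform on
    # loading_range, cross-loadings Normal(0, cross_loading_sd^2).
    blocks <- block_sizes(p, k)
    loadings <- matrix(rnorm(p * k, 0, cfg$cross_loading_sd), p, k)
    owner <- rep(seq_len(k), blocks)
    loadings[cbind(seq_len(p), owner)] <-
      runif(p, cfg$loading_range[1], cfg$loading_range[2])
    dimnames(loadings) <- list(
      sprintf("sub%02d", seq_len(p)), paste0("factor", seq_len(k))
    )

    phi <- matrix(cfg$factor_corr, k, k)
    diag(phi) <- 1
    communal <- rowSums((loadings %*% phi) * loadings)
    if (any(communal >= 1)) {
      abort("planted loadings imply communality >= 1; lower loading_range",
        class = "traitspace_config_error"
      )
    }
    uniquenesses <- 1 - communal

    group <- c(rep("asd", cfg$n_asd), rep("control", cfg$n_control))
    scores <- matrix(rnorm(n * k), n, k) %*% chol(phi)
    scores[group == "asd", 1] <- scores[group == "asd", 1] + cfg$group_shift_f1
    colnames(scores) <- paste0("factor", seq_len(k))

    # Demographics emulate the reported cohort: sex ratios 47/89 and
    # 117/307 female, ages ~N(29.2, 8.5) / N(26.3, 6.9) floored at 18,
    # SES 1..10 ~ round N(4.3, 2.8) / N(5.3, 1.5).
    is_asd <- group == "asd"
    sex <- ifelse(runif(n) < ifelse(is_asd, 47 / 89, 117 / 307), "F", "M")
    age <- round(pmax(18, rnorm(n, ifelse(is_asd, 29.2, 26.3),
                                ifelse(is_asd, 8.54, 6.94))))
    ses <- pmin(10, pmax(1, round(rnorm(n, ifelse(is_asd, 4.29, 5.29),
                                        ifelse(is_asd, 2.78, 1.52)))))
    participants <- tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      group = group, sex = sex, age = as.numeric(age), ses = as.numeric(ses)
    )
    rownames(scores) <- participants$participant_id

    # Latent identity-trait values tau and the independent draw
    # tau_tilde used to distort ASD ratings; per-example jitter.
    ni <- cfg$n_identities; ne <- cfg$n_examples; nt <- cfg$n_traits
    trait_names <- if (nt == length(TRAIT_NAMES)) TRAIT_NAMES else paste0("trait", seq_len(nt))
    identity_traits <- matrix(rnorm(ni * nt), ni, nt,
      dimnames = list(sprintf("id%02d", seq_len(ni)), trait_names)
    )
    identity_traits_distorted <- matrix(rnorm(ni * nt), ni, nt,
      dimnames = dimnames(identity_traits)
    )
    jitter <- matrix(rnorm(ni * ne * nt, 0, cfg$example_jitter_sd), ni * ne, nt)
    idx_identity <- rep(seq_len(ni), each = ne)
    example_traits <- identity_traits[idx_identity, , drop = FALSE] + jitter
    jitter2 <- matrix(rnorm(ni * ne * nt, 0, cfg$example_jitter_sd), ni * ne, nt)
    example_traits_distorted <-
      identity_traits_distorted[idx_identity, , drop = FALSE] + jitter2
    image_labels <- sprintf("id%02d_ex%02d", idx_identity, rep(seq_len(ne), ni))
    rownames(example_traits) <- image_labels
    rownames(example_traits_distorted) <- image_labels

    # Module layout: per identity a random bijection example -> module,
    # so each module shows exactly one example of every identity.
    module_of <- t(vapply(seq_len(ni), function(i) sample(ne), integer(ne)))
    dimnames(module_of) <- list(rownames(identity_traits),
                                sprintf("ex%02d", seq_len(ne)))

    # Neuronal tuning: a prop_untuned fraction has zero weights and no
    # gain (response == baseline in expectation); tuned neurons elevate
    # their central rate by response_gain and carry Normal weights.
    nn <- cfg$n_neurons
    untuned <- runif(nn) < cfg$prop_untuned
    tuning <- matrix(rnorm(nn * nt, rep(cfg$tuning_mean, each = nn),
                           cfg$tuning_sd), nn, nt)
    tuning[untuned, ] <- 0
    baseline <- exp(runif(nn, log(cfg$baseline_rate_range[1]),
                          log(cfg$baseline_rate_range[2])))
    colnames(tuning) <- trait_names

    couplings <- list(
      control = cfg$coupling_control,
      asd = cfg$coupling_control * cfg$attenuation_asd
    )

    truth <- list(
      loadings = loadings, phi = phi, uniquenesses = uniquenesses,
      factor_scores = scores,
      identity_traits = identity_traits,
      identity_traits_distorted = identity_traits_distorted,
      example_traits = example_traits,
      example_traits_distorted = example_traits_distorted,
      module_of = module_of,
      neuron_tuning = tuning, neuron_baseline = baseline,
      neuron_untuned = untuned,
      couplings = couplings
    )
    list(participants = participants, truth = truth)
  })
}

block_sizes <- function(p, k) {
  base <- rep(p %/% k, k)
  extra <- p %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

#' Generate personality subscale scores from the planted factor model
#'
#' `subscale = factor_scores %*% t(loadings) + e`, with `Var(e_i)` equal
#' to the planted uniqueness, so the population correlation structure is
#' `L Phi L' + Psi` with unit implied variances.
#'
#' @param participants,truth From [generate_cohort()].
#' @param config The same [sim_config()].
#' @return Tibble: `participant_id` plus one column per subscale
#'   (`sub01`..`sub33` at defaults).
#' @export
generate_subscales <- function(participants, truth, config) {
  validate_sim_config(config)
  L <- truth$loadings
  psi <- truth$uniquenesses
  if (nrow(L) != config$n_subscales || ncol(L) != config$n_factors) {
    abort("truth$loadings has the wrong shape for this config",
      class = "traitspace_data_error"
    )
  }
  if (any(psi < 0)) {
    abort("negative uniqueness in truth; implied variances invalid",
      class = "traitspace_data_error"
    )
  }
  scores <- truth$factor_scores[participants$participant_id, , drop = FALSE]
  with_seed(derive_seed(config$seed, "subscales"), {
    n <- nrow(scores)
    p <- nrow(L)
    noise <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi), p)
    x <- scores %*% t(L) + noise
    colnames(x) <- rownames(L)
    dplyr::bind_cols(
      tibble(participant_id = participants$participant_id),
      as_tibble(x)
    )
  })
}

#' Generate trial-level face ratings
#'
#' Each participant completes a uniform number of modules in
#' `modules_range`; within a (participant, module, trait) block there is
#' exactly one trial per identity, showing that module's example. The
#' latent propensity is
#' `intercept + slope * example_trait + sum_k gamma[group, k, trait] *
#' factor_score_k + Normal noise`, rounded and clipped to 1..7. For the
#' ASD group the example trait value is the mixture
#' `(1 - lambda) * tau + lambda * tau_tilde`. Reaction times are
#' lognormal; a `contamination_rate` fraction is forced outside
#' `[100, 5000]` ms.
#'
#' @inheritParams generate_subscales
#' @return Tibble of trial records: `participant_id`, `module`, `trait`,
#'   `identity_id`, `example_id`, `rating`, `rt_ms`.
#' @export
generate_rating_trials <- function(participants, truth, config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(derive_seed(cfg$seed, "trials"), {
    ni <- cfg$n_identities; ne <- cfg$n_examples; nt <- cfg$n_traits
    trait_names <- colnames(truth$example_traits)
    # example index shown for identity i in module m
    example_in_module <- matrix(0L, ni, cfg$n_modules)
    for (i in seq_len(ni)) example_in_module[i, truth$module_of[i, ]] <- seq_len(ne)

    n_mod <- sample(seq(cfg$modules_range[1], cfg$modules_range[2]),
                    nrow(participants), replace = TRUE)
    rows <- vector("list", nrow(participants))
    lambda <- cfg$distortion_lambda
    mix <- (1 - lambda) * truth$example_traits +
      lambda * truth$example_traits_distorted
    for (pi in seq_len(nrow(participants))) {
      grp <- participants$group[pi]
      mods <- sort(sample(cfg$n_modules, n_mod[pi]))
      gamma <- truth$couplings[[grp]]
      fs <- truth$factor_scores[participants$participant_id[pi], ]
      pers <- as.numeric(fs %*% gamma) # per-trait personality offset
      ex_tr <- if (grp == "asd") mix else truth$example_traits
      blk <- vector("list", length(mods))
      for (mi in seq_along(mods)) {
        m <- mods[mi]
        ex_idx <- example_in_module[, m]
        img <- (seq_len(ni) - 1L) * ne + ex_idx
        # identities in randomized presentation order, per trait block
        ord <- unlist(lapply(seq_len(nt), function(t) sample(ni)))
        trait_i <- rep(seq_len(nt), each = ni)
        tau <- ex_tr[cbind(img[ord], trait_i)]
        prop <- cfg$rating_intercept + cfg$rating_slope * tau +
          pers[trait_i] + rnorm(ni * nt, 0, cfg$rating_noise_sd)
        blk[[mi]] <- tibble(
          participant_id = participants$participant_id[pi],
          module = m,
          trait = trait_names[trait_i],
          identity_id = ord,
          example_id = ex_idx[ord],
          rating = pmin(7, pmax(1, round(prop)))
        )
      }
      rows[[pi]] <- dplyr::bind_rows(blk)
    }
    trials <- dplyr::bind_rows(rows)
    ntr <- nrow(trials)
    rt <- rlnorm(ntr, cfg$rt_lognorm_params[1], cfg$rt_lognorm_params[2])
    bad <- runif(ntr) < cfg$contamination_rate
    n_bad <- sum(bad)
    if (n_bad > 0) {
      low <- runif(n_bad) < 0.5
      rt[bad] <- ifelse(low, runif(n_bad, 1, 99), runif(n_bad, 5001, 9000))
    }
    trials$rt_ms <- round(rt, 1) # 0.1 ms resolution
    trials
  })
}

#' Generate per-neuron, per-image firing rates
#'
#' Expected response rate per image is
#' `softplus(b_n + w_n' example_trait)` with `b_n` set so an untuned
#' neuron's central rate equals its baseline and a tuned neuron's equals
#' `response_gain * baseline`. Observed rates are Poisson counts over
#' the response window divided by its length; baseline-window rates are
#' Poisson at the baseline rate over `baseline_window_s`.
#'
#' @param truth From [generate_cohort()].
#' @param config The same [sim_config()].
#' @return Long tibble: `neuron_id`, `region`, `baseline_rate`,
#'   `identity_id`, `example_id`, `response_rate`, `baseline_window_rate`
#'   (one row per neuron x image; image order lexicographic).
#' @export
generate_neurons <- function(truth, config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(derive_seed(cfg$seed, "neurons"), {
    nn <- cfg$n_neurons
    n_img <- cfg$n_identities * cfg$n_examples
    regions <- sample(c("amygdala", "ant_hippocampus", "post_hippocampus"),
                      nn, replace = TRUE, prob = cfg$region_probs)
    gain <- ifelse(truth$neuron_untuned, 1, cfg$response_gain)
    b <- softplus_inv(truth$neuron_baseline * gain)
    eta <- truth$neuron_tuning %*% t(truth$example_traits) # neurons x images
    mu <- softplus(sweep(eta, 1, b, `+`))
    resp <- matrix(
      rpois(nn * n_img, as.numeric(mu) * cfg$response_window_s),
      nn, n_img
    ) / cfg$response_window_s
    base <- matrix(
      rpois(nn * n_img, rep(truth$neuron_baseline, n_img) * cfg$baseline_window_s),
      nn, n_img
    ) / cfg$baseline_window_s
    tibble(
      neuron_id = rep(sprintf("N%03d", seq_len(nn)), each = n_img),
      region = rep(regions, each = n_img),
      baseline_rate = rep(truth$neuron_baseline, each = n_img),
      identity_id = rep(rep(seq_len(cfg$n_identities), each = cfg$n_examples), nn),
      example_id = rep(rep(seq_len(cfg$n_examples), cfg$n_identities), nn),
      response_rate = as.numeric(t(resp)),
      baseline_window_rate = as.numeric(t(base))
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [generate_cohort()],
#' [generate_subscales()], [generate_rating_trials()] and
#' [generate_neurons()] under one config.
#'
#' @param config A [sim_config()].
#' @return List: `participants`, `subscales`, `trials`, `neurons`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config) {
  ch <- generate_cohort(config)
  subscales <- generate_subscales(ch$participants, ch$truth, config)
  trials <- generate_rating_trials(ch$participants, ch$truth, config)
  neurons <- generate_neurons(ch$truth, config)
  list(
    participants = ch$participants, subscales = subscales,
    trials = trials, neurons = neurons, truth = ch$truth, config = config
  )
}

#' Write a simulated study to disk
#'
#' Writes `participants.csv`, `subscales.csv`, `trials.csv`,
#' `neurons.csv` (RFC-4180, UTF-8, header row), `truth.json` (nested
#' JSON of the ground-truth parameters) and `config.yaml`.
#'
#' @param study From [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    subscales = file.path(dir, "subscales.csv"),
    trials = file.path(dir, "trials.csv"),
    neurons = file.path(dir, "neurons.csv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  readr::write_csv(study$participants, paths["participants"])
  readr::write_csv(study$subscales, paths["subscales"])
  readr::write_csv(study$trials, paths["trials"])
  readr::write_csv(study$neurons, paths["neurons"])
  truth_json <- lapply(study$truth, function(x) {
    if (is.matrix(x)) unname(apply(x, 1, as.list, simplify = FALSE)) else x
  })
  jsonlite::write_json(truth_json, paths["truth"], digits = NA, auto_unbox = TRUE)
  write_sim_config(study$config, paths["config"])
  invisible(paths)
}
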