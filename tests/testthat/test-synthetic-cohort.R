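test_that("cohort has the requested composition and is reproducible", {
  cfg <- sim_config(n_asd = 89, n_control = 307, seed = 42)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$participants), 396)
  expect_equal(sum(ch$participants$group == "asd"), 89)
  expect_true(all(ch$participants$ses >= 1 & ch$participants$ses <= 10))
  expect_false(anyDuplicated(ch$participants$participant_id) > 0)
  # byte-identical rerun
  ch2 <- generate_cohort(cfg)
  expect_identical(ch, ch2)
  # distinct seed changes the draw
  ch3 <- generate_cohort(sim_config(n_asd = 89, n_control = 307, seed = 43))
  expect_false(identical(ch$truth$factor_scores, ch3$truth$factor_scores))
})

test_that("planted factor-1 shift is recovered at scale and absent when zero", {
  cfg <- sim_config(n_asd = 10000, n_control = 10000, seed = 7)
  ch <- generate_cohort(cfg)
  g <- ch$participants$group
  diff <- mean(ch$truth$factor_scores[g == "asd", 1]) -
    mean(ch$truth$factor_scores[g == "control", 1])
  expect_equal(diff, 0.6, tolerance = 0.05)
  # null case over seeds: |diff| < 3 SE
  diffs0 <- vapply(1:50, function(s) {
    ch0 <- generate_cohort(sim_config(n_asd = 50, n_control = 50,
                                      group_shift_f1 = 0, seed = s))
    g0 <- ch0$participants$group
    mean(ch0$truth$factor_scores[g0 == "asd", 1]) -
      mean(ch0$truth$factor_scores[g0 == "control", 1])
  }, numeric(1))
  se <- sqrt(2 / 50)
  expect_lt(abs(mean(diffs0)), 3 * se / sqrt(50))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(n_asd = 0), "n_asd", class = "traitspace_config_error")
  expect_error(sim_config(attenuation_asd = 1.5), "attenuation_asd",
               class = "traitspace_config_error")
  expect_error(sim_config(response_window_s = -1), "response_window_s",
               class = "traitspace_config_error")
  expect_error(sim_config(distortion_lambda = -0.1), "distortion_lambda",
               class = "traitspace_config_error")
})

test_that("subscales reproduce the implied covariance L Phi L' + Psi", {
  cfg <- sim_config(n_asd = 2500, n_control = 2500, group_shift_f1 = 0,
                    seed = 11)
  ch <- generate_cohort(cfg)
  ss <- generate_subscales(ch$participants, ch$truth, cfg)
  emp <- cor(as.matrix(ss[, -1]))
  implied <- ch$truth$loadings %*% ch$truth$phi %*% t(ch$truth$loadings) +
    diag(ch$truth$uniquenesses)
  expect_lt(max(abs(emp - implied)), 0.05)
  # unit implied variances (communality + uniqueness = 1)
  expect_equal(
    unname(rowSums((ch$truth$loadings %*% ch$truth$phi) * ch$truth$loadings) +
             ch$truth$uniquenesses),
    rep(1, cfg$n_subscales),
    tolerance = 1e-8
  )
})

test_that("noiseless subscales equal the loading column for a unit factor score", {
  cfg <- tiny_config(seed = 2)
  ch <- generate_cohort(cfg)
  truth <- ch$truth
  truth$uniquenesses <- rep(0, cfg$n_subscales)
  truth$factor_scores[1, ] <- c(1, 0, 0, 0)
  ss <- generate_subscales(ch$participants, truth, cfg)
  expect_equal(unname(as.numeric(ss[1, -1])), unname(truth$loadings[, 1]),
               tolerance = 1e-12)
  # negative uniqueness is an invalid variance
  truth$uniquenesses[3] <- -0.1
  expect_error(generate_subscales(ch$participants, truth, cfg),
               class = "traitspace_data_error")
})

test_that("trial blocks are complete, ratings bounded, and RT contamination calibrated", {
  cfg <- small_config(seed = 5)
  st <- simulate_study(cfg)
  expect_true(all(st$trials$rating %in% 1:7))
  # exactly one trial per identity within each block
  blocks <- dplyr::count(st$trials, participant_id, module, trait)
  expect_true(all(blocks$n == cfg$n_identities))
  per_identity <- dplyr::count(st$trials, participant_id, module, trait,
                               identity_id)
  expect_true(all(per_identity$n == 1))
  # each module shows one example per identity, consistently
  mod_ex <- dplyr::distinct(st$trials, module, identity_id, example_id)
  expect_true(all(dplyr::count(mod_ex, module, identity_id)$n == 1))
  # contamination fraction ~ 2% (binomial check, absolute band)
  frac <- mean(st$trials$rt_ms < 100 | st$trials$rt_ms > 5000)
  expect_lt(abs(frac - 0.02), 0.005)
})

test_that("degenerate propensity settings give constant ratings", {
  cfg <- tiny_config(
    seed = 3, rating_noise_sd = 0, rating_slope = 0,
    coupling_control = matrix(0, 4, 10), rating_intercept = 4
  )
  st <- simulate_study(cfg)
  expect_true(all(st$trials$rating == 4))
})

test_that("identical generative mechanisms give matching group consensus", {
  cfg <- sim_config(n_asd = 100, n_control = 100, n_neurons = 20,
                    attenuation_asd = 1, distortion_lambda = 0, seed = 9)
  st <- simulate_study(cfg)
  ca <- consensus_ratings(st$trials, st$participants, "asd", "trustworthy")
  cc <- consensus_ratings(st$trials, st$participants, "control", "trustworthy")
  ok <- !is.na(ca$consensus) & !is.na(cc$consensus)
  expect_gt(cor(ca$consensus[ok], cc$consensus[ok]), 0.9)
})

test_that("untuned populations carry no identity-trait structure", {
  cors <- vapply(1:20, function(s) {
    cfg <- sim_config(n_asd = 5, n_control = 5, n_neurons = 30,
                      prop_untuned = 1, seed = 100 + s)
    ch <- generate_cohort(cfg)
    ne <- generate_neurons(ch$truth, cfg)
    ndm <- tryCatch(neural_population_dm(ne), error = function(e) NULL)
    if (is.null(ndm)) return(0)
    tdm <- identity_dm_from_values(
      as.numeric(ch$truth$example_traits %*% cfg$tuning_mean)
    )
    dm_spearman(ndm, tdm)
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.1)
})

test_that("screening retains nearly all well-behaved tuned neurons", {
  kept_frac <- vapply(1:5, function(s) {
    cfg <- sim_config(n_asd = 5, n_control = 5, n_neurons = 60,
                      baseline_rate_range = c(0.2, 5), prop_untuned = 0,
                      seed = 200 + s)
    ch <- generate_cohort(cfg)
    ne <- generate_neurons(ch$truth, cfg)
    sc <- screen_neurons(ne)
    sc$report$n_kept / sc$report$n_in
  }, numeric(1))
  expect_gte(mean(kept_frac), 0.9)
})

test_that("a full study round-trips to disk deterministically", {
  cfg <- tiny_config(seed = 13)
  st <- simulate_study(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(st, d1)
  write_study(simulate_study(cfg), d2)
  for (f in c("participants.csv", "subscales.csv", "trials.csv",
              "neurons.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  cfg2 <- read_sim_config(file.path(d1, "config.yaml"))
  expect_equal(unclass(cfg2)[order(names(cfg2))],
               unclass(cfg)[order(names(unclass(cfg)))],
               tolerance = 1e-12)
})
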