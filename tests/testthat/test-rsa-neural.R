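test_that("dissimilarity matrices enforce symmetry and zero diagonal", {
  m <- matrix(c(0, 1, 1, 0), 2)
  expect_s3_class(new_dm(m, c("a", "b")), "trait_dm")
  bad <- m; bad[1, 2] <- 2
  expect_error(new_dm(bad, c("a", "b")), class = "traitspace_data_error")
  bad2 <- m; diag(bad2) <- 0.5
  expect_error(new_dm(bad2, c("a", "b")), class = "traitspace_data_error")
})

test_that("consensus ratings equal brute-force per-image means", {
  tr <- tibble::tibble(
    participant_id = c("P1", "P2", "P3", "P1", "P2"),
    module = 1L, trait = "warm",
    identity_id = c(1L, 1L, 1L, 2L, 2L),
    example_id = c(1L, 1L, 1L, 1L, 1L),
    rating = c(2L, 4L, 6L, 3L, 5L), rt_ms = 1000
  )
  parts <- tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    group = c("asd", "asd", "control")
  )
  cons <- consensus_ratings(tr, parts, "asd", "warm",
                            n_identities = 2, n_examples = 2)
  expect_equal(cons$consensus[cons$identity_id == 1 & cons$example_id == 1], 3)
  expect_equal(cons$consensus[cons$identity_id == 2 & cons$example_id == 1], 4)
  expect_true(is.na(cons$consensus[cons$identity_id == 1 & cons$example_id == 2]))
  # single participant: consensus equals that participant's ratings
  cons1 <- consensus_ratings(tr, parts, "control", "warm",
                             n_identities = 2, n_examples = 2)
  expect_equal(cons1$consensus[cons1$identity_id == 1 & cons1$example_id == 1], 6)
  expect_error(consensus_ratings(tr, parts, "nogroup", "warm"),
               class = "traitspace_data_error")
})

test_that("identity matrix construction matches hand-computed 1 - Pearson entries", {
  # 3 identities x 4 examples, fixed printed values
  vals <- c(
    1.0, 2.0, 3.0, 4.0,   # identity 1
    2.0, 4.0, 6.0, 8.0,   # identity 2: proportional to identity 1 -> r = 1
    4.0, 3.0, 2.0, 1.0    # identity 3: reversed -> r = -1 vs identity 1
  )
  dm <- identity_dm_from_values(vals, n_identities = 3, n_examples = 4,
                                min_examples = 4)
  # z-scoring is a global affine map; Pearson is affine-invariant
  expect_equal(dm[1, 2], 0, tolerance = 1e-12)
  expect_equal(dm[1, 3], 2, tolerance = 1e-12)
  expect_equal(dm[2, 3], 2, tolerance = 1e-12)
  expect_equal(unname(diag(unclass(dm))), rep(0, 3))
  # general hand-computed entry
  v2 <- c(1, 5, 2, 7,  2, 1, 6, 3,  8, 2, 4, 1)
  dm2 <- identity_dm_from_values(v2, 3, 4, min_examples = 4)
  hand <- function(a, b) 1 - cor(a, b)
  expect_equal(dm2[1, 2], hand(v2[1:4], v2[5:8]), tolerance = 1e-12)
  expect_equal(dm2[1, 3], hand(v2[1:4], v2[9:12]), tolerance = 1e-12)
  expect_equal(dm2[2, 3], hand(v2[5:8], v2[9:12]), tolerance = 1e-12)
  # constant example vector is an error naming the identity
  expect_error(
    identity_dm_from_values(c(1, 1, 1, 1, v2[5:12]), 3, 4, min_examples = 4),
    "1", class = "traitspace_data_error"
  )
  expect_error(identity_dm_from_values(v2[1:8], 3, 4),
               class = "traitspace_data_error")
})

test_that("Spearman correspondence is monotone-invariant and matches hand ranks", {
  set.seed(2)
  v <- rnorm(16)
  dm_a <- identity_dm_from_values(v, 4, 4, min_examples = 4)
  expect_equal(dm_spearman(dm_a, dm_a), 1)
  # strictly increasing transform leaves rho at 1
  dm_b <- new_dm(exp(unclass(dm_a)) - diag(exp(0), 4), rownames(dm_a))
  diag_fix <- unclass(dm_b); diag(diag_fix) <- 0
  dm_b <- new_dm(diag_fix, rownames(dm_a))
  expect_equal(dm_spearman(dm_a, dm_b), 1)
  expect_equal(dm_spearman(dm_a, dm_b), dm_spearman(dm_b, dm_a))
  # 4x4 toy pair against the rank formula on the 6 lower-triangle entries
  m1 <- matrix(0, 4, 4); m1[lower.tri(m1)] <- c(1, 2, 3, 4, 5, 6)
  m1 <- m1 + t(m1)
  m2 <- matrix(0, 4, 4); m2[lower.tri(m2)] <- c(2, 1, 4, 3, 6, 5)
  m2 <- m2 + t(m2)
  d1 <- new_dm(m1, letters[1:4]); d2 <- new_dm(m2, letters[1:4])
  r_hand <- 1 - 6 * sum((c(1, 2, 3, 4, 5, 6) - c(2, 1, 4, 3, 6, 5))^2) /
    (6 * (36 - 1))
  expect_equal(dm_spearman(d1, d2), r_hand, tolerance = 1e-12)
  d3 <- new_dm(m2, letters[5:8])
  expect_error(dm_spearman(d1, d3), class = "traitspace_data_error")
})

test_that("population matrix averages baseline-normalized responses", {
  base <- tibble::tibble(
    identity_id = rep(1:3, each = 4), example_id = rep(1:4, 3)
  )
  set.seed(6)
  resp <- runif(12, 1, 5)
  one <- dplyr::bind_cols(
    tibble::tibble(neuron_id = "N1", region = "amygdala", baseline_rate = 2),
    base, tibble::tibble(response_rate = resp, baseline_window_rate = 2)
  )
  two <- dplyr::mutate(one, neuron_id = "N2")
  dm1 <- neural_population_dm(one, 3, 4, min_examples = 4)
  dm12 <- neural_population_dm(dplyr::bind_rows(one, two), 3, 4,
                               min_examples = 4)
  expect_equal(unclass(dm1), unclass(dm12), tolerance = 1e-12)
  # response identical to baseline -> constant population vector -> error
  flat <- dplyr::mutate(one, response_rate = 2, baseline_window_rate = 2)
  expect_error(neural_population_dm(flat, 3, 4, min_examples = 4),
               class = "traitspace_data_error")
  zero <- dplyr::mutate(one, baseline_window_rate = 0)
  expect_error(neural_population_dm(zero, 3, 4, min_examples = 4),
               class = "traitspace_data_error")
})

test_that("tuned populations produce trait-aligned geometry", {
  rhos <- vapply(1:20, function(s) {
    cfg <- sim_config(n_asd = 5, n_control = 5, seed = 500 + s)
    ch <- generate_cohort(cfg)
    ne <- generate_neurons(ch$truth, cfg)
    sc <- screen_neurons(ne)
    ndm <- neural_population_dm(sc$kept)
    tdm <- identity_dm_from_values(
      as.numeric(ch$truth$example_traits %*% cfg$tuning_mean)
    )
    dm_spearman(ndm, tdm)
  }, numeric(1))
  expect_gt(median(rhos), 0.5)
})

test_that("the group permutation test is deterministic and add-one corrected", {
  cfg <- small_config(seed = 33, distortion_lambda = 0.8)
  st <- simulate_study(cfg)
  qb <- qc_behavior(st$trials)
  ns <- screen_neurons(st$neurons)
  ndm <- neural_population_dm(ns$kept)
  p1 <- group_correspondence_permutation(qb$kept_trials, st$participants,
                                         ndm, "trustworthy",
                                         n_perm = 150, seed = 5)
  p2 <- group_correspondence_permutation(qb$kept_trials, st$participants,
                                         ndm, "trustworthy",
                                         n_perm = 150, seed = 5)
  expect_identical(p1$null, p2$null)
  expect_identical(p1$p, p2$p)
  expect_equal(length(p1$null), 150)
  expect_gt(p1$p, 0)
  expect_lte(p1$p, 1)
  # observed statistic is consistent with its two group correspondences
  expect_equal(p1$observed, p1$rho_control - p1$rho_asd, tolerance = 1e-12)
  expect_warning(
    group_correspondence_permutation(qb$kept_trials, st$participants,
                                     ndm, "trustworthy", n_perm = 50, seed = 1),
    "n_perm"
  )
})
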