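test_that("subscale correlations match hand-computed Pearson values", {
  ss <- tibble::tibble(
    participant_id = paste0("P", 1:5),
    a = c(1, 2, 3, 4, 5),
    b = c(2, 4, 6, 8, 10),   # identical up to scale -> r = 1
    c = c(5, 4, 3, 2, 1),    # negation -> r = -1
    d = c(1, 3, 2, 5, 4)
  )
  R <- subscale_correlations(ss)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)
  r_ad <- sum((ss$a - 3) * (ss$d - 3)) /
    sqrt(sum((ss$a - 3)^2) * sum((ss$d - 3)^2))
  expect_equal(R["a", "d"], r_ad, tolerance = 1e-12)
  expect_true(isSymmetric(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  ss$e <- 7
  expect_error(subscale_correlations(ss), "e",
               class = "traitspace_data_error")
})

test_that("CNG returns the planted dimension on an ideal scree and rejects degenerate input", {
  set.seed(1)
  for (k in 2:5) {
    p <- 33
    blocks <- rep(p %/% k, k); blocks[seq_len(p %% k)] <- blocks[seq_len(p %% k)] + 1
    L <- matrix(rnorm(p * k, 0, 0.05), p, k)
    L[cbind(1:p, rep(seq_len(k), blocks))] <- runif(p, 0.5, 0.8)
    S <- L %*% t(L)
    diag(S) <- 1
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(cng_factor_count(ev), k, info = k)
  }
  expect_error(cng_factor_count(rep(1, 33)), "no scree",
               class = "traitspace_data_error")
  expect_error(cng_factor_count(c(3, 2, 1, 1, 1)),
               class = "traitspace_data_error")
  expect_error(cng_factor_count(c(1, 2, 3, 3, 3, 3, 3)),
               class = "traitspace_data_error")
})

test_that("ML step agrees with the reference ML factor engine", {
  cfg <- sim_config(seed = 31)
  ch <- generate_cohort(cfg)
  ss <- generate_subscales(ch$participants, ch$truth, cfg)
  R <- subscale_correlations(ss)
  sol <- fit_efa(ss, 4)
  ref <- stats::factanal(covmat = R, factors = 4, rotation = "none",
                         n.obs = nrow(ss))
  expect_equal(unname(sol$uniquenesses), unname(ref$uniquenesses),
               tolerance = 1e-4)
  # objective only improved over the optimization
  expect_lte(sol$objective, sol$objective_trace[1])
  # variance explained is a pure function of the uniquenesses
  expect_equal(variance_explained(sol),
               sum(1 - sol$uniquenesses) / length(sol$uniquenesses))
})

test_that("EFA recovers planted oblique loadings", {
  # noiseless: orthogonal exact simple structure, negligible uniqueness
  cfg <- sim_config(n_asd = 100, n_control = 296, factor_corr = 0,
                    cross_loading_sd = 0, seed = 17)
  ch <- generate_cohort(cfg)
  truth <- ch$truth
  truth$uniquenesses <- rep(0.01, cfg$n_subscales)
  ss <- generate_subscales(ch$participants, truth, cfg)
  sol <- suppressWarnings(fit_efa(ss, 4))
  m <- match_factors(sol$loadings, truth$loadings)
  expect_true(all(m$congruence >= 0.99))
  # default noise at n = 396
  cfgd <- sim_config(seed = 17)
  chd <- generate_cohort(cfgd)
  ss2 <- generate_subscales(chd$participants, chd$truth, cfgd)
  sol2 <- fit_efa(ss2, 4)
  m2 <- match_factors(sol2$loadings, chd$truth$loadings)
  expect_true(all(m2$congruence >= 0.90))
  expect_equal(sol2$variance_explained_total,
               mean(1 - chd$truth$uniquenesses), tolerance = 0.06)
  # one-factor model recovers a planted single dimension
  L1 <- matrix(runif(12, 0.5, 0.8), 12, 1,
               dimnames = list(sprintf("s%02d", 1:12), "factor1"))
  set.seed(4)
  f <- rnorm(4000)
  x <- f %*% t(L1) + matrix(rnorm(4000 * 12), 4000, 12) %*%
    diag(sqrt(1 - as.numeric(L1)^2))
  colnames(x) <- rownames(L1)
  ss1 <- dplyr::bind_cols(tibble::tibble(participant_id = paste0("P", 1:4000)),
                          tibble::as_tibble(x))
  sol1 <- fit_efa(ss1, 1)
  expect_gte(abs(tucker_congruence(sol1$loadings[, 1], L1[, 1])), 0.99)
})

test_that("infeasible factor counts and Heywood cases are handled", {
  cfg <- sim_config(n_asd = 40, n_control = 60, seed = 23)
  ch <- generate_cohort(cfg)
  ss <- generate_subscales(ch$participants, ch$truth, cfg)
  expect_error(fit_efa(ss, 30), "Ledermann",
               class = "traitspace_estimation_error")
  # near-duplicate column forces a communality toward 1 -> Heywood
  set.seed(8)
  ssh <- ss
  ssh$dup <- ssh$sub01 + rnorm(nrow(ssh), 0, 0.03)
  expect_warning(solh <- fit_efa(ssh, 4), "Heywood")
  expect_true(all(solh$uniquenesses >= 0.005 - 1e-12))
})

test_that("factor scores are centered, equivariant, and recover planted scores", {
  cfg <- sim_config(n_asd = 100, n_control = 296, seed = 19)
  ch <- generate_cohort(cfg)
  ss <- generate_subscales(ch$participants, ch$truth, cfg)
  sol <- fit_efa(ss, 4)
  sc <- score_factors(sol, ss)
  expect_lt(max(abs(colMeans(as.matrix(sc[, -1])))), 1e-8)
  # row permutation permutes scores identically
  perm <- sample(nrow(ss))
  sc_p <- score_factors(sol, ss[perm, ])
  expect_equal(sc_p$factor1, sc$factor1[perm])
  # estimated scores track the planted ones after column matching
  m <- match_factors(sol$loadings, ch$truth$loadings)
  for (j in 1:4) {
    r <- cor(sc[[paste0("factor", m$order[j])]] * m$signs[j],
             ch$truth$factor_scores[, j])
    expect_gt(r, 0.85)
  }
  # near-noiseless data gives near-exact scores
  truth <- ch$truth
  truth$uniquenesses <- rep(1e-4, cfg$n_subscales)
  ss0 <- generate_subscales(ch$participants, truth, cfg)
  sol0 <- suppressWarnings(fit_efa(ss0, 4))
  sc0 <- score_factors(sol0, ss0)
  m0 <- match_factors(sol0$loadings, truth$loadings)
  r0 <- abs(cor(sc0[[paste0("factor", m0$order[1])]],
                truth$factor_scores[, 1]))
  expect_gte(r0, 0.999)
})

test_that("group model recovers the planted shift with covariate adjustment", {
  cfg <- sim_config(seed = 29)
  ch <- generate_cohort(cfg)
  ss <- generate_subscales(ch$participants, ch$truth, cfg)
  sol <- fit_efa(ss, 4)
  sc <- score_factors(sol, ss)
  gm <- group_factor_model(sc, ch$participants)
  # recovered factor order may differ from planted; match first
  m <- match_factors(sol$loadings, ch$truth$loadings)
  b1 <- gm$B[gm$factor == paste0("factor", m$order[1])] * m$signs[1]
  se1 <- gm$se[gm$factor == paste0("factor", m$order[1])]
  expect_lt(abs(b1 - 0.6), 2.5 * se1)
  expect_equal(gm$t, gm$B / gm$se, tolerance = 1e-10)
  # duplicated covariate -> rank-deficient design
  bad <- ch$participants
  bad$age <- 30
  expect_error(group_factor_model(sc, bad),
               class = "traitspace_estimation_error")
})
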