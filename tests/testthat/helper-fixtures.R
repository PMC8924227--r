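# Small study configurations used across the suite.

tiny_config <- function(seed = 1, ...) {
  sim_config(
    n_asd = 8, n_control = 12, n_neurons = 15,
    modules_range = c(2L, 3L), seed = seed, ...
  )
}

small_config <- function(seed = 1, ...) {
  sim_config(n_asd = 30, n_control = 30, n_neurons = 20, seed = seed, ...)
}

# Brute-force QC oracle: literal row scans re-deriving every filter
# verdict independently of the vectorized implementation.
oracle_qc <- function(trials) {
  out <- trials$rt_ms < 100 | trials$rt_ms > 5000
  keys <- unique(trials[, c("participant_id", "module", "trait")])
  block <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- trials$participant_id == keys$participant_id[i] &
      trials$module == keys$module[i] & trials$trait == keys$trait[i]
    n_exc <- sum(out[sel])
    kept_ratings <- trials$rating[sel & !out]
    frac <- n_exc / sum(sel)
    fail_rt <- frac > 0.30
    fail_div <- length(unique(kept_ratings)) < 3
    data.frame(
      participant_id = keys$participant_id[i], module = keys$module[i],
      trait = keys$trait[i], excluded = fail_rt | fail_div,
      fail_rt = fail_rt, fail_div = fail_div
    )
  })
  block <- do.call(rbind, block)
  parts <- unique(trials$participant_id)
  part <- data.frame(
    participant_id = parts,
    excluded = vapply(parts, function(p) {
      sum(block$excluded[block$participant_id == p]) > 3
    }, logical(1))
  )
  list(trial_excluded = out, blocks = block, participants = part)
}

# Random toy trial table exercising all QC boundaries.
random_toy_trials <- function(n_participants = 4, n_modules = 3,
                              n_traits = 2, n_trials = 10) {
  grid <- expand.grid(
    participant_id = paste0("P", seq_len(n_participants)),
    module = seq_len(n_modules),
    trait = paste0("t", seq_len(n_traits)),
    idx = seq_len(n_trials),
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  tibble::tibble(
    participant_id = grid$participant_id,
    module = grid$module,
    trait = grid$trait,
    identity_id = grid$idx,
    example_id = 1L,
    # rating values concentrated so diversity failures happen often
    rating = sample(c(3L, 3L, 3L, 5L, 5L, 2L, 7L), n, replace = TRUE),
    # mass at and around the RT boundaries
    rt_ms = sample(c(50, 99, 100, 101, 2500, 4999, 5000, 5001, 6000),
                   n, replace = TRUE,
                   prob = c(3, 2, 2, 1, 6, 1, 2, 2, 3) / 22)
  )
}
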