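#' Dissimilarity matrix constructor
#'
#' Internal-facing helper wrapping a symmetric, zero-diagonal matrix
#' with its labels. Symmetry and zero diagonal are asserted on
#' construction.
#'
#' @param values Square numeric matrix.
#' @param labels Row/column labels.
#' @param type Free-form description (e.g. `"1 - Pearson"`).
#' @return Object of class `trait_dm`.
#' @export
new_dm <- function(values, labels = rownames(values), type = "dissimilarity") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort("dissimilarity matrix must be square", class = "traitspace_data_error")
  }
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8) {
    abort("dissimilarity matrix must be symmetric", class = "traitspace_data_error")
  }
  if (max(abs(diag(values))) > 1e-8) {
    abort("dissimilarity matrix must have a zero diagonal",
      class = "traitspace_data_error"
    )
  }
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("trait_dm", class(values)), type = type)
}

#' @export
print.trait_dm <- function(x, ...) {
  cat(sprintf("<trait_dm> %d x %d (%s)\n", nrow(x), ncol(x), attr(x, "type")))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))], digits = 3)
  invisible(x)
}

lower_tri <- function(m) m[lower.tri(m)]

#' Group consensus ratings of the image set
#'
#' Per-image mean of all kept ratings of one trait by one group's
#' participants, in lexicographic (identity, example) image order.
#' Images no participant of the group rated carry `NA` consensus, which
#' downstream dissimilarity construction drops pairwise.
#'
#' @param trials_kept QC-filtered trials.
#' @param participants Participant tibble with `group`.
#' @param group `"asd"` or `"control"`.
#' @param trait Trait name.
#' @param n_identities,n_examples Stimulus grid (defaults 50 x 10).
#' @return Tibble: `identity_id`, `example_id`, `consensus`, `n_ratings`.
#' @export
consensus_ratings <- function(trials_kept, participants, group, trait,
                              n_identities = 50, n_examples = 10) {
  ids <- participants$participant_id[participants$group == group]
  if (length(ids) == 0) {
    abort(sprintf("no participants in group `%s`", group),
      class = "traitspace_data_error"
    )
  }
  sub <- trials_kept %>%
    filter(.data$participant_id %in% ids, .data$trait == .env$trait)
  grid <- tidyr::expand_grid(
    identity_id = seq_len(n_identities), example_id = seq_len(n_examples)
  )
  agg <- sub %>%
    group_by(.data$identity_id, .data$example_id) %>%
    summarise(consensus = mean(.data$rating), n_ratings = n(), .groups = "drop")
  grid %>%
    left_join(agg, by = c("identity_id", "example_id")) %>%
    mutate(n_ratings = dplyr::coalesce(.data$n_ratings, 0L)) %>%
    arrange(.data$identity_id, .data$example_id)
}

#' Identity-level dissimilarity matrix from per-image values
#'
#' Values are z-scored globally across all images, sliced into one
#' vector of examples per identity (examples paired across identities by
#' example index), and the dissimilarity between identities A and B is
#' `1 - Pearson(vec_A, vec_B)`. Missing images are dropped pairwise;
#' every identity must retain at least `min_examples` non-missing
#' examples and a non-constant vector.
#'
#' @param values Numeric vector of length identities x examples in
#'   lexicographic (identity, example) order, or a tibble from
#'   [consensus_ratings()].
#' @param n_identities,n_examples Stimulus grid.
#' @param min_examples Minimum non-missing examples per identity
#'   (default 5).
#' @return A `trait_dm` over identities (values in `[0, 2]`).
#' @export
identity_dm_from_values <- function(values, n_identities = 50, n_examples = 10,
                                    min_examples = 5) {
  if (is.data.frame(values)) {
    values <- values$consensus
  }
  if (length(values) != n_identities * n_examples) {
    abort(sprintf("expected %d values, got %d",
                  n_identities * n_examples, length(values)),
      class = "traitspace_data_error"
    )
  }
  z <- as.numeric(scale(values))
  m <- matrix(z, nrow = n_examples, ncol = n_identities) # column = identity
  n_ok <- colSums(!is.na(m))
  if (any(n_ok < min_examples)) {
    abort(
      sprintf("identity(ies) with fewer than %d non-missing examples: %s",
              min_examples, paste(which(n_ok < min_examples), collapse = ", ")),
      class = "traitspace_data_error"
    )
  }
  const <- vapply(seq_len(n_identities), function(i) {
    v <- m[, i]
    sd(v, na.rm = TRUE) == 0
  }, logical(1))
  if (any(const)) {
    abort(
      sprintf("constant example vector for identity(ies): %s (correlation undefined)",
              paste(which(const), collapse = ", ")),
      class = "traitspace_data_error"
    )
  }
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(r)) {
    abort("undefined identity-pair correlation (insufficient pairwise overlap)",
      class = "traitspace_data_error"
    )
  }
  d <- 1 - r
  diag(d) <- 0
  new_dm(d, labels = sprintf("id%02d", seq_len(n_identities)),
         type = "1 - Pearson (identity x identity)")
}

#' Neuronal population dissimilarity matrix
#'
#' Each neuron's per-image response rate is normalized by its mean
#' baseline-window rate; the population value per image is the mean of
#' these normalized responses across neurons; the identity-level matrix
#' is then built exactly as for ratings via [identity_dm_from_values()].
#'
#' @param neurons_kept Screened long neuron table.
#' @param n_identities,n_examples Stimulus grid.
#' @param min_examples Passed to [identity_dm_from_values()].
#' @return A `trait_dm` over identities.
#' @export
neural_population_dm <- function(neurons_kept, n_identities = 50,
                                 n_examples = 10, min_examples = 5) {
  norm <- neurons_kept %>%
    group_by(.data$neuron_id) %>%
    mutate(mean_baseline = mean(.data$baseline_window_rate)) %>%
    ungroup()
  if (any(norm$mean_baseline <= 0)) {
    abort("neuron(s) with zero mean baseline; cannot normalize",
      class = "traitspace_data_error"
    )
  }
  pop <- norm %>%
    mutate(norm_rate = .data$response_rate / .data$mean_baseline) %>%
    group_by(.data$identity_id, .data$example_id) %>%
    summarise(value = mean(.data$norm_rate), .groups = "drop") %>%
    arrange(.data$identity_id, .data$example_id)
  identity_dm_from_values(pop$value, n_identities, n_examples,
                          min_examples = min_examples)
}

#' Spearman correspondence between two dissimilarity matrices
#'
#' Rank correlation over the strictly-lower-triangle entries (1225
#' pairs for 50 identities). Invariant to any strictly increasing
#' transform of either matrix's entries.
#'
#' @param dm_a,dm_b `trait_dm`s with identical labels.
#' @return Spearman's rho.
#' @export
dm_spearman <- function(dm_a, dm_b) {
  if (!identical(rownames(dm_a), rownames(dm_b))) {
    abort("dissimilarity matrices have mismatched labels",
      class = "traitspace_data_error"
    )
  }
  if (nrow(dm_a) < 4) {
    abort("need at least 4 items for a meaningful correspondence",
      class = "traitspace_data_error"
    )
  }
  cor(lower_tri(dm_a), lower_tri(dm_b), method = "spearman")
}

# Per-participant x image mean-rating matrix for one trait, used by the
# permutation machinery so group consensus reduces to a column mean.
participant_image_matrix <- function(trials_kept, trait, participant_ids,
                                     n_identities, n_examples) {
  n_img <- n_identities * n_examples
  sub <- trials_kept[trials_kept$trait == trait &
                       trials_kept$participant_id %in% participant_ids, ]
  img <- (sub$identity_id - 1L) * n_examples + sub$example_id
  pidx <- match(sub$participant_id, participant_ids)
  np <- length(participant_ids)
  cell <- (img - 1L) * np + pidx # column-major cell index
  sums <- numeric(np * n_img)
  cnts <- numeric(np * n_img)
  add <- rowsum(cbind(sub$rating, 1), cell)
  at <- as.integer(rownames(add))
  sums[at] <- add[, 1]
  cnts[at] <- add[, 2]
  m <- matrix(sums / cnts, np, n_img)
  m[cnts == 0] <- NA
  rownames(m) <- participant_ids
  m
}

fast_identity_lower_tri <- function(values, n_identities, n_examples,
                                    min_examples = 5) {
  z <- (values - mean(values, na.rm = TRUE)) / sd(values, na.rm = TRUE)
  m <- matrix(z, nrow = n_examples, ncol = n_identities)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(r)) {
    abort("undefined identity-pair correlation under permutation",
      class = "traitspace_data_error"
    )
  }
  (1 - r)[lower.tri(r)]
}

#' Permutation test for the group difference in rating-neural
#' correspondence
#'
#' The observed statistic is `delta_rho = rho_control - rho_asd`, each
#' rho the Spearman correspondence between a group's consensus-rating
#' identity matrix and the fixed neuronal matrix. Each permutation
#' reassigns participants to groups uniformly at random (preserving
#' group sizes), recomputes both consensus matrices and the difference.
#' The p-value uses the add-one correction and so is never exactly 0.
#'
#' @param trials_kept QC-filtered trials.
#' @param participants Participant tibble with `group`.
#' @param neural_dm `trait_dm` from [neural_population_dm()].
#' @param trait Trait name.
#' @param n_perm Number of permutation runs (default 1000; < 100 warns).
#' @param seed RNG seed for the permutation stream.
#' @param sidedness `"two"` (default) or `"greater"` (control > ASD).
#' @param n_identities,n_examples Stimulus grid.
#' @return Object of class `perm_test`: list with `observed`,
#'   `rho_control`, `rho_asd`, `null` (length `n_perm`), `p`, `n_perm`,
#'   `seed`, `sidedness`.
#' @export
group_correspondence_permutation <- function(trials_kept, participants,
                                             neural_dm, trait,
                                             n_perm = 1000, seed = 1,
                                             sidedness = c("two", "greater"),
                                             n_identities = 50,
                                             n_examples = 10) {
  sidedness <- match.arg(sidedness)
  if (n_perm < 100) warn("n_perm < 100 gives a coarse permutation p-value")
  grp <- participants$group
  if (!all(c("asd", "control") %in% grp)) {
    abort("both groups must be non-empty", class = "traitspace_data_error")
  }
  pim <- participant_image_matrix(
    trials_kept, trait, participants$participant_id, n_identities, n_examples
  )
  neural_rank <- rank(lower_tri(neural_dm))
  stat_for <- function(asd_rows) {
    cons_a <- colMeans(pim[asd_rows, , drop = FALSE], na.rm = TRUE)
    cons_c <- colMeans(pim[!asd_rows, , drop = FALSE], na.rm = TRUE)
    cons_a[is.nan(cons_a)] <- NA
    cons_c[is.nan(cons_c)] <- NA
    lt_a <- fast_identity_lower_tri(cons_a, n_identities, n_examples)
    lt_c <- fast_identity_lower_tri(cons_c, n_identities, n_examples)
    rho_a <- cor(rank(lt_a), neural_rank)
    rho_c <- cor(rank(lt_c), neural_rank)
    c(rho_c - rho_a, rho_c, rho_a)
  }
  is_asd <- grp == "asd"
  obs <- stat_for(is_asd)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_for(sample(is_asd))[1]
    }, numeric(1))
  })
  p <- switch(sidedness,
    two = (1 + sum(abs(null) >= abs(obs[1]))) / (1 + n_perm),
    greater = (1 + sum(null >= obs[1])) / (1 + n_perm)
  )
  structure(
    list(
      observed = obs[1], rho_control = obs[2], rho_asd = obs[3],
      null = null, p = p, n_perm = n_perm, seed = seed,
      sidedness = sidedness, trait = trait
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s): delta rho = %.4f (control %.4f, ASD %.4f)\n",
    x$trait, x$observed, x$rho_control, x$rho_asd
  ))
  cat(sprintf("p = %.4f (%s-sided, %d runs, seed %s)\n",
              x$p, x$sidedness, x$n_perm, format(x$seed)))
  invisible(x)
}
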