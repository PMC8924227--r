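#' Absolute-difference dissimilarity matrix over participants
#'
#' `d(i, j) = |v_i - v_j|` for one scalar value per participant
#' (translation invariant, zero diagonal).
#'
#' @param values Named numeric vector (names = participant ids) or a
#'   two-column tibble `participant_id`, value.
#' @return A `trait_dm` over participants.
#' @export
#' @examples
#' pairwise_abs_dm(c(P1 = 1, P2 = 3, P3 = 6))
pairwise_abs_dm <- function(values) {
  if (is.data.frame(values)) {
    v <- values[[2]]
    names(v) <- values$participant_id
    values <- v
  }
  if (anyNA(values)) {
    abort(
      sprintf("missing values for participant(s): %s",
              paste(names(values)[is.na(values)], collapse = ", ")),
      class = "traitspace_data_error"
    )
  }
  d <- abs(outer(values, values, `-`))
  new_dm(d, labels = names(values), type = "absolute difference (dyadic)")
}

#' Build the dyad table for inter-subject RSA
#'
#' One row per unordered within-group participant pair (cross-group
#' dyads optionally included as a third `group_dyad` level), with the
#' absolute-difference distance for every trait judgment column and
#' every factor score. Distance columns are z-standardized across the
#' stacked table (scaling parameters stored as an attribute) so that
#' regression coefficients are comparable across factors.
#'
#' @param judgments Participant-level trait means (wide tibble from
#'   [unit_trait_means()] with `unit = "participant"`).
#' @param scores Factor scores from [score_factors()].
#' @param participants Participant tibble with `group`.
#' @param include_cross_group Include mixed dyads as level
#'   `"asd_control"` (default `FALSE`: the binary group regressor is
#'   undefined for mixed pairs).
#' @param standardize Z-standardize the distance columns (default
#'   `TRUE`).
#' @return Tibble of class `dyad_table`: `participant_a`,
#'   `participant_b` (a < b), `group_dyad`, `dist_<trait>` and
#'   `dist_factor*` columns.
#' @export
build_dyad_table <- function(judgments, scores, participants,
                             include_cross_group = FALSE,
                             standardize = TRUE) {
  if (anyDuplicated(participants$participant_id) > 0) {
    abort("duplicate participant ids", class = "traitspace_data_error")
  }
  dat <- participants %>%
    dplyr::select("participant_id", "group") %>%
    dplyr::inner_join(judgments, by = "participant_id") %>%
    dplyr::inner_join(scores, by = "participant_id") %>%
    arrange(.data$participant_id)
  counts <- table(dat$group)
  if (any(counts < 2)) {
    abort("each group needs at least 2 participants for dyads",
      class = "traitspace_data_error"
    )
  }
  value_cols <- setdiff(names(dat), c("participant_id", "group", "module"))
  pair_idx <- function(idx) {
    if (length(idx) < 2) return(NULL)
    cb <- combn(idx, 2)
    tibble(a = cb[1, ], b = cb[2, ])
  }
  groups <- sort(unique(dat$group))
  pairs <- purrr::map_dfr(groups, function(g) {
    pr <- pair_idx(which(dat$group == g))
    pr$group_dyad <- paste(g, g, sep = "_")
    pr
  })
  if (include_cross_group) {
    ia <- which(dat$group == "asd")
    ic <- which(dat$group == "control")
    cross <- tidyr::expand_grid(a = ia, b = ic) %>%
      mutate(group_dyad = "asd_control")
    pairs <- bind_rows(pairs, cross)
  }
  out <- tibble(
    participant_a = dat$participant_id[pairs$a],
    participant_b = dat$participant_id[pairs$b],
    group_dyad = pairs$group_dyad
  )
  scaling <- list()
  for (col in value_cols) {
    d <- abs(dat[[col]][pairs$a] - dat[[col]][pairs$b])
    nm <- paste0("dist_", col)
    if (standardize) {
      mu <- mean(d)
      sdv <- sd(d)
      if (is.na(sdv) || sdv == 0) {
        abort(sprintf("distance column `%s` is constant; cannot standardize", nm),
          class = "traitspace_estimation_error"
        )
      }
      scaling[[nm]] <- c(mean = mu, sd = sdv)
      d <- (d - mu) / sdv
    }
    out[[nm]] <- d
  }
  attr(out, "scaling") <- scaling
  attr(out, "standardized") <- standardize
  class(out) <- c("dyad_table", class(out))
  out
}

#' Inter-subject RSA regression for one trait
#'
#' OLS of the dyadic judgment distance on the four factor-score
#' distances, the dyad group indicator (ASD dyad = 1, control dyad =
#' 0), and the group x factor interactions, with within-group simple
#' slopes. Analytic OLS p-values are reported; note dyadic observations
#' are not independent, so [isrsa_permutation()] offers Mantel-style
#' inference.
#'
#' @param dyads A `dyad_table` (within-group dyads).
#' @param trait Trait name (its `dist_<trait>` column is the outcome).
#' @return An `interaction_fit` (see
#'   [trait_factor_interaction_model()]), class also `isrsa_fit`.
#' @export
isrsa_fit <- function(dyads, trait) {
  outcome <- paste0("dist_", trait)
  if (!outcome %in% names(dyads)) {
    abort(sprintf("no column `%s` in dyad table", outcome),
      class = "traitspace_data_error"
    )
  }
  factors <- grep("^dist_factor", names(dyads), value = TRUE)
  if ("asd_control" %in% dyads$group_dyad) {
    abort("isrsa_fit expects within-group dyads only (binary group term)",
      class = "traitspace_data_error"
    )
  }
  dyads <- dplyr::mutate(dyads, group_asd = as.numeric(.data$group_dyad == "asd_asd"))
  consts <- factors[vapply(factors, function(f) sd(dyads[[f]]) == 0, logical(1))]
  if (length(consts) > 0) {
    abort(sprintf("constant distance column(s): %s", paste(consts, collapse = ", ")),
      class = "traitspace_estimation_error"
    )
  }
  rhs <- c(factors, "group_asd", paste0("group_asd:", factors))
  fit <- lm(stats::reformulate(rhs, response = outcome), data = dyads)
  if (any(is.na(coef(fit)))) {
    abort(
      sprintf("rank-deficient dyadic design; aliased: %s",
              paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
      class = "traitspace_estimation_error"
    )
  }
  interaction_fit(fit, trait, factors, n = nrow(dyads),
                  extra_class = "isrsa_fit")
}

#' Permutation inference for the inter-subject RSA model
#'
#' Dyads sharing a participant are not independent, so each term's |t|
#' is compared to a permutation distribution built at the participant
#' level, with the scheme matched to the term's null hypothesis:
#'
#' * factor-distance main effects: trait judgment values are shuffled
#'   among participants *within* each group, breaking every
#'   judgment-personality linkage while preserving group composition;
#' * the dyad group term and the group x factor interactions:
#'   participant *group labels* are shuffled (preserving group sizes)
#'   and the within-group dyad set is rebuilt, which preserves the
#'   judgment-personality linkage and destroys only its group
#'   structure — shuffling values instead would generate these terms'
#'   nulls under "no association in either group" and over-reject
#'   whenever a shared coupling exists.
#'
#' All p-values carry the add-one correction.
#'
#' @param judgments,scores,participants As [build_dyad_table()].
#' @param trait Trait name.
#' @param n_perm Permutation runs per scheme (default 1000; < 100
#'   warns).
#' @param seed RNG seed.
#' @return Tibble: `term`, `B`, `t`, `scheme`, `p_perm`, plus
#'   attributes `n_perm`, `seed`.
#' @export
isrsa_permutation <- function(judgments, scores, participants, trait,
                              n_perm = 1000, seed = 1) {
  if (n_perm < 100) warn("n_perm < 100 gives a coarse permutation p-value")
  judg <- dplyr::select(judgments, "participant_id", dplyr::all_of(trait))
  dat <- participants %>%
    dplyr::select("participant_id", "group") %>%
    dplyr::inner_join(judg, by = "participant_id") %>%
    dplyr::inner_join(scores, by = "participant_id") %>%
    arrange(.data$participant_id)
  v <- dat[[trait]]
  fmat <- as.matrix(dat[, grep("^factor", names(dat)), drop = FALSE])
  grp <- dat$group
  n <- length(v)
  kf <- ncol(fmat)

  # t-statistics of the dyadic OLS for participant-level inputs
  # (distances z-standardized within each rebuilt table, mirroring
  # build_dyad_table)
  t_for <- function(values, labels) {
    pairs <- within_group_pairs(labels)
    y <- scale01(abs(values[pairs$a] - values[pairs$b]))
    xf <- vapply(seq_len(kf), function(j) {
      scale01(abs(fmat[pairs$a, j] - fmat[pairs$b, j]))
    }, numeric(nrow(pairs)))
    gdy <- as.numeric(labels[pairs$a] == "asd")
    X <- cbind(1, xf, gdy, xf * gdy)
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    res <- y - as.numeric(X %*% beta)
    s2 <- sum(res^2) / (length(y) - ncol(X))
    list(t = beta / sqrt(s2 * diag(chol2inv(qr.R(qrX)))), beta = beta)
  }
  obs <- t_for(v, grp)
  term_names <- c("(Intercept)", paste0("dist_factor", seq_len(kf)),
                  "group_asd", paste0("dist_factor", seq_len(kf),
                                      ":group_asd"))
  is_group_term <- c(FALSE, rep(FALSE, kf), TRUE, rep(TRUE, kf))
  exceed <- numeric(length(obs$t))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      # scheme A: values shuffled within group (factor main effects)
      vp <- v
      for (g in unique(grp)) {
        idx <- which(grp == g)
        vp[idx] <- v[sample(idx)]
      }
      ta <- t_for(vp, grp)$t
      # scheme B: group labels shuffled (group + interactions)
      tb <- t_for(v, sample(grp))$t
      tp <- ifelse(is_group_term, tb, ta)
      exceed <- exceed + (abs(tp) >= abs(obs$t))
    }
  })
  out <- tibble(
    term = term_names,
    B = unname(obs$beta),
    t = unname(obs$t),
    scheme = ifelse(is_group_term, "group_label", "within_group_values"),
    p_perm = unname((1 + exceed) / (1 + n_perm))
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

within_group_pairs <- function(labels) {
  idx <- seq_along(labels)
  parts <- lapply(sort(unique(labels)), function(g) {
    i <- idx[labels == g]
    if (length(i) < 2) return(NULL)
    cb <- combn(i, 2)
    data.frame(a = cb[1, ], b = cb[2, ])
  })
  do.call(rbind, parts)
}

scale01 <- function(x) (x - mean(x)) / sd(x)
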