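#' Per-unit mean trait ratings
#'
#' Averages each trait's kept ratings within the analysis unit: by
#' default one row per participant x module (the module-level means the
#' group comparisons use), optionally per participant.
#'
#' @param trials_kept QC-filtered trial table.
#' @param unit `"participant_module"` (default) or `"participant"`.
#' @return Wide tibble: `participant_id` (and `module`), one mean column
#'   per trait present.
#' @export
unit_trait_means <- function(trials_kept,
                             unit = c("participant_module", "participant")) {
  unit <- match.arg(unit)
  keys <- if (unit == "participant_module") {
    c("participant_id", "module")
  } else {
    "participant_id"
  }
  long <- trials_kept %>%
    group_by(dplyr::across(dplyr::all_of(c(keys, "trait")))) %>%
    summarise(mean_rating = mean(.data$rating), .groups = "drop")
  long %>%
    tidyr::pivot_wider(names_from = "trait", values_from = "mean_rating") %>%
    arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Unpaired group comparison of trait means
#'
#' Pooled-variance (Student) two-tailed t-test per trait comparing the
#' unit-level means between groups, with `df = n1 + n2 - 2`. The t
#' statistic is signed ASD minus control.
#'
#' @param means Tibble from [unit_trait_means()].
#' @param participants Participant tibble with `group`.
#' @return Tibble: `trait`, `mean_asd`, `mean_control`, `t`, `df`, `p`.
#' @export
group_trait_tests <- function(means, participants) {
  dat <- dplyr::inner_join(
    means, dplyr::select(participants, "participant_id", "group"),
    by = "participant_id"
  )
  traits <- setdiff(names(means), c("participant_id", "module"))
  counts <- table(dat$group)
  if (any(!c("asd", "control") %in% names(counts)) || any(counts < 2)) {
    abort("each group needs at least 2 analysis units",
      class = "traitspace_data_error"
    )
  }
  purrr::map_dfr(traits, function(tr) {
    a <- dat[[tr]][dat$group == "asd"]
    b <- dat[[tr]][dat$group == "control"]
    tt <- t.test(a, b, var.equal = TRUE)
    tibble(
      trait = tr, mean_asd = mean(a), mean_control = mean(b),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = unname(tt$p.value)
    )
  })
}

#' Group-stratified factor-trait correlations
#'
#' Pearson correlation, within each group, between every factor score
#' and every trait's unit-level mean judgment, with two-sided p-values.
#'
#' @param scores Factor scores from [score_factors()].
#' @param means Trait means from [unit_trait_means()].
#' @param participants Participant tibble with `group`.
#' @return Tibble: `group`, `factor`, `trait`, `r`, `p`, `n`.
#' @export
factor_trait_correlations <- function(scores, means, participants) {
  dat <- means %>%
    dplyr::inner_join(scores, by = "participant_id") %>%
    dplyr::inner_join(
      dplyr::select(participants, "participant_id", "group"),
      by = "participant_id"
    )
  traits <- setdiff(names(means), c("participant_id", "module"))
  factors <- grep("^factor", names(scores), value = TRUE)
  counts <- table(dat$group)
  if (!all(c("asd", "control") %in% names(counts)) || any(counts < 3)) {
    abort("each group needs at least 3 units for correlations",
      class = "traitspace_data_error"
    )
  }
  grid <- tidyr::expand_grid(
    group = sort(unique(dat$group)), factor = factors, trait = traits
  )
  purrr::pmap_dfr(grid, function(group, factor, trait) {
    d <- dat[dat$group == group, ]
    ct <- cor.test(d[[factor]], d[[trait]])
    tibble(
      group = group, factor = factor, trait = trait,
      r = unname(ct$estimate), p = unname(ct$p.value), n = nrow(d)
    )
  })
}

#' Group x factor interaction model for one trait judgment
#'
#' OLS of a trait's unit-level mean rating on the four factor scores,
#' the group indicator (ASD = 1), the group x factor interactions, and
#' the sex/age/SES covariates. Also reports within-group simple slopes
#' for every factor (control slope = factor main effect; ASD slope =
#' main effect + interaction, with delta-method SE).
#'
#' @param trait Trait name (a column of `means`).
#' @param scores,means,participants As in [factor_trait_correlations()].
#' @return Object of class `interaction_fit`: list with `trait`,
#'   `terms` (tibble: term, B, se, t, p, conf.low, conf.high),
#'   `simple_slopes` (tibble: factor, group, B, se, t, p), `n`, `fit`.
#' @export
trait_factor_interaction_model <- function(trait, scores, means, participants) {
  dat <- means %>%
    dplyr::inner_join(scores, by = "participant_id") %>%
    dplyr::inner_join(participants, by = "participant_id") %>%
    mutate(group_asd = as.numeric(.data$group == "asd"))
  if (!trait %in% names(dat)) {
    abort(sprintf("trait `%s` not found in means", trait),
      class = "traitspace_data_error"
    )
  }
  if (sd(dat[[trait]]) == 0) {
    abort(sprintf("outcome `%s` is constant; nothing to model", trait),
      class = "traitspace_estimation_error"
    )
  }
  factors <- grep("^factor", names(scores), value = TRUE)
  rhs <- c(factors, "group_asd",
           paste0("group_asd:", factors), "sex", "age", "ses")
  fml <- stats::reformulate(rhs, response = trait)
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    abort(
      sprintf("rank-deficient design; aliased term(s): %s",
              paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
      class = "traitspace_estimation_error"
    )
  }
  interaction_fit(fit, trait, factors, n = nrow(dat))
}

# Shared assembly of coefficient table + within-group simple slopes for
# models of the form y ~ factors * group (+ covariates).
interaction_fit <- function(fit, trait, factors, n,
                            group_term = "group_asd", extra_class = NULL) {
  sm <- suppressWarnings(summary(fit))$coefficients
  ci <- stats::confint(fit)
  terms <- tibble(
    term = rownames(sm),
    B = unname(sm[, 1]), se = unname(sm[, 2]),
    t = unname(sm[, 3]), p = unname(sm[, 4]),
    conf.low = unname(ci[rownames(sm), 1]),
    conf.high = unname(ci[rownames(sm), 2])
  )
  V <- vcov(fit)
  dfree <- fit$df.residual
  slopes <- purrr::map_dfr(factors, function(f) {
    int_name <- intersect(
      c(paste0(group_term, ":", f), paste0(f, ":", group_term)),
      rownames(sm)
    )[1]
    b_ctl <- unname(sm[f, 1])
    se_ctl <- unname(sm[f, 2])
    b_asd <- b_ctl + unname(sm[int_name, 1])
    se_asd <- sqrt(V[f, f] + V[int_name, int_name] + 2 * V[f, int_name])
    bb <- c(b_ctl, b_asd)
    ss <- c(se_ctl, se_asd)
    tv <- bb / ss
    tibble(
      factor = f,
      group = c("control", "asd"),
      B = bb, se = ss, t = tv,
      p = 2 * pt(abs(tv), dfree, lower.tail = FALSE)
    )
  })
  structure(
    list(trait = trait, terms = terms, simple_slopes = slopes,
         n = n, fit = fit),
    class = c(extra_class, "interaction_fit")
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Group x factor interaction model for `%s` (n = %d units)\n",
              x$trait, x$n))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}
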