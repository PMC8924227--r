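#' Tidy a factor solution into long loadings
#'
#' @param x An `efa_fit`.
#' @param ... Unused.
#' @return Tibble: `subscale`, `factor`, `loading`, `communality`,
#'   `uniqueness`.
#' @export
tidy.efa_fit <- function(x, ...) {
  as_tibble(x$loadings, rownames = "subscale") %>%
    tidyr::pivot_longer(-"subscale", names_to = "factor",
                        values_to = "loading") %>%
    left_join(
      tibble(
        subscale = names(x$communalities),
        communality = unname(x$communalities),
        uniqueness = unname(x$uniquenesses)
      ),
      by = "subscale"
    )
}

#' One-row summary of a factor solution
#'
#' @inheritParams tidy.efa_fit
#' @return Tibble: `k`, `n`, `variance_explained_total`, `heywood`,
#'   `objective`.
#' @export
glance.efa_fit <- function(x, ...) {
  tibble(
    k = x$k, n = x$n,
    variance_explained_total = x$variance_explained_total,
    heywood = x$heywood, objective = x$objective
  )
}

#' Tidy an interaction / IS-RSA model's coefficients
#'
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @return The per-term coefficient tibble.
#' @export
tidy.interaction_fit <- function(x, ...) x$terms

#' @export
glance.interaction_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    trait = x$trait, n = x$n, r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared, sigma = s$sigma
  )
}

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `observed`, `rho_control`,
#'   `rho_asd`, `p`, `n_perm`, `sidedness`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(
    trait = x$trait, observed = x$observed, rho_control = x$rho_control,
    rho_asd = x$rho_asd, p = x$p, n_perm = x$n_perm, sidedness = x$sidedness
  )
}

#' @export
glance.perm_test <- tidy.perm_test
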