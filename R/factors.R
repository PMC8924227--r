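#' Pearson correlation matrix of personality subscales
#'
#' @param subscales Tibble with `participant_id` plus one numeric column
#'   per subscale (the id column is dropped if present).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
subscale_correlations <- function(subscales) {
  x <- as.matrix(dplyr::select(subscales, -dplyr::any_of("participant_id")))
  if (nrow(x) < 3) {
    abort("need at least 3 participants for a correlation matrix",
      class = "traitspace_data_error"
    )
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(
      sprintf(
        "constant subscale column(s): %s",
        paste(colnames(x)[sds == 0], collapse = ", ")
      ),
      class = "traitspace_data_error"
    )
  }
  cor(x)
}

#' Cattell-Nelson-Gorsuch factor count
#'
#' Scans the descending eigenvalue scree: for each start index `i` up to
#' `p - 5`, fits least-squares slopes to the eigenvalue triples `i..i+2`
#' and `i+3..i+5`; the window maximizing `slope2 - slope1` localizes the
#' elbow. Because the maximizing window's leading triple typically
#' straddles the structure-to-noise cliff, the retained count is
#' attributed within the window as the number of eigenvalues before its
#' largest consecutive drop (shape-independent attribution; on an ideal
#' k-factor scree this returns k).
#'
#' @param eigenvalues Numeric vector, descending.
#' @return Integer factor count.
#' @export
#' @examples
#' L <- matrix(0, 12, 3); L[cbind(1:12, rep(1:3, each = 4))] <- 0.7
#' S <- L %*% t(L); diag(S) <- 1
#' cng_factor_count(eigen(S, symmetric = TRUE)$values)
cng_factor_count <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  p <- length(ev)
  if (p < 6) {
    abort("CNG needs at least 6 eigenvalues", class = "traitspace_data_error")
  }
  if (any(diff(ev) > 1e-10 * max(abs(ev), 1))) {
    abort("eigenvalues must be in descending order",
      class = "traitspace_data_error"
    )
  }
  ls_slope <- function(y) {
    x <- seq_along(y)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  diffs <- vapply(seq_len(p - 5), function(i) {
    ls_slope(ev[(i + 3):(i + 5)]) - ls_slope(ev[i:(i + 2)])
  }, numeric(1))
  if (max(diffs) <= 1e-10 * max(abs(ev), 1)) {
    abort("no scree structure: all slope differences are zero",
      class = "traitspace_data_error"
    )
  }
  i <- which.max(diffs)
  gaps <- ev[i:(i + 4)] - ev[(i + 1):(i + 5)]
  as.integer(i + which.max(gaps) - 1L)
}

# Maximum-likelihood discrepancy for an EFA with k factors,
# parameterized by the uniquenesses psi (Lawley/Joreskog profile
# likelihood): given psi, the optimal loadings come from the leading
# eigenpairs of Psi^-1/2 R Psi^-1/2 and the objective reduces to a sum
# over the trailing eigenvalues.
efa_objective <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  Rs <- R * tcrossprod(sc)
  e <- eigen(Rs, symmetric = TRUE, only.values = TRUE)$values
  tail_e <- e[-seq_len(k)]
  if (any(tail_e <= 0)) return(1e10) # outside the PD region
  sum(tail_e - log(tail_e)) - length(tail_e)
}

efa_gradient <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  Rs <- R * tcrossprod(sc)
  E <- eigen(Rs, symmetric = TRUE)
  lam <- pmax(E$values[seq_len(k)] - 1, 0)
  L <- E$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  L <- L / sc
  g <- tcrossprod(L) + diag(psi) - R
  diag(g) / psi^2
}

efa_ml <- function(R, k, psi_lower = 0.005) {
  p <- nrow(R)
  trace_env <- new.env()
  trace_env$vals <- numeric(0)
  fn <- function(psi) {
    v <- efa_objective(psi, R, k)
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  start <- tryCatch(
    pmin(1, pmax(psi_lower, 0.5 / diag(solve(R)))),
    error = function(e) rep(0.5, p) # near-singular R: neutral start
  )
  opt <- optim(
    par = start, fn = fn, gr = function(psi) efa_gradient(psi, R, k),
    method = "L-BFGS-B", lower = psi_lower, upper = 1
  )
  if (opt$convergence != 0 && opt$convergence != 52) {
    abort(
      sprintf(
        "EFA did not converge (optim code %d, %s); objective trace length %d",
        opt$convergence, opt$message %||% "", length(trace_env$vals)
      ),
      class = "traitspace_estimation_error"
    )
  }
  psi <- opt$par
  heywood <- any(psi <= psi_lower + 1e-12)
  sc <- 1 / sqrt(psi)
  Rs <- R * tcrossprod(sc)
  E <- eigen(Rs, symmetric = TRUE)
  lam <- pmax(E$values[seq_len(k)] - 1, 0)
  L <- E$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  L <- L / sc
  rownames(L) <- rownames(R)
  list(
    loadings = L, uniquenesses = pmax(psi, psi_lower),
    objective = opt$value, heywood = heywood,
    objective_trace = trace_env$vals
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quartimin criterion and gradient (oblimin with gamma = 0).
vgq_quartimin <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Oblique gradient-projection rotation (Jennrich 2002) minimizing the
# quartimin criterion. Returns the rotated pattern matrix and the
# factor correlation Phi = T'T.
rotate_oblimin <- function(A, maxit = 500, eps = 1e-6) {
  k <- ncol(A)
  if (k == 1) {
    return(list(loadings = A, phi = matrix(1, 1, 1), iterations = 0L))
  }
  Tmat <- diag(k)
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:12) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)))
      L <- A %*% t(solve(Tt))
      vgt <- vgq_quartimin(L)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  list(loadings = A %*% t(solve(Tmat)), phi = t(Tmat) %*% Tmat,
       iterations = iter)
}

ledermann_ok <- function(p, k) {
  ((p - k)^2 - p - k) / 2 >= 0
}

#' Maximum-likelihood exploratory factor analysis with oblimin rotation
#'
#' Fits a k-factor ML solution to the subscale correlation matrix
#' (profile likelihood over uniquenesses, L-BFGS-B with analytic
#' gradient), rotates with direct quartimin (oblimin, gamma = 0) by
#' gradient projection, orders factors by explained variance and fixes
#' signs so each factor's largest-magnitude loading is positive.
#' Uniquenesses that hit the lower bound (Heywood cases) are clamped at
#' 0.005 and flagged with a warning.
#'
#' @param subscales Tibble of subscale scores (see
#'   [subscale_correlations()]).
#' @param k Number of factors; must satisfy the Ledermann bound.
#' @param loading_label_cutoff Absolute pattern loading above which a
#'   subscale is listed as labeling a factor (default 0.35).
#' @return An object of class `efa_fit`: list with `k`, `loadings`
#'   (p x k oblique pattern matrix), `phi` (factor correlations),
#'   `uniquenesses`, `communalities`, `variance_explained_total`,
#'   `labeling` (per-factor character vectors), `heywood`, `objective`,
#'   `objective_trace`, `n`, `correlation`.
#' @export
fit_efa <- function(subscales, k, loading_label_cutoff = 0.35) {
  R <- subscale_correlations(subscales)
  p <- nrow(R)
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1", class = "traitspace_estimation_error")
  if (!ledermann_ok(p, k)) {
    abort(
      sprintf("k = %d exceeds the Ledermann bound for p = %d variables", k, p),
      class = "traitspace_estimation_error"
    )
  }
  n <- nrow(subscales)
  fit <- efa_ml(R, k)
  if (fit$heywood) {
    warn("Heywood case: uniqueness(es) at lower bound, clamped at 0.005")
  }
  rot <- rotate_oblimin(fit$loadings)
  L <- rot$loadings
  phi <- rot$phi
  # order by explained variance (sum of squared structure loadings),
  # then sign so the largest |loading| per factor is positive
  ssl <- colSums((L %*% phi) * L)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, `*`)
  phi <- diag(flip, k) %*% phi %*% diag(flip, k)
  colnames(L) <- paste0("factor", seq_len(k))
  dimnames(phi) <- list(colnames(L), colnames(L))
  communal <- 1 - fit$uniquenesses
  labeling <- lapply(seq_len(k), function(j) {
    rownames(L)[abs(L[, j]) > loading_label_cutoff]
  })
  names(labeling) <- colnames(L)
  structure(
    list(
      k = k, loadings = L, phi = phi,
      uniquenesses = setNames(fit$uniquenesses, rownames(R)),
      communalities = setNames(communal, rownames(R)),
      variance_explained_total = sum(communal) / p,
      labeling = labeling, heywood = fit$heywood,
      objective = fit$objective, objective_trace = fit$objective_trace,
      n = n, correlation = R,
      rotation = "oblimin (gamma = 0, direct quartimin)",
      loading_label_cutoff = loading_label_cutoff
    ),
    class = "efa_fit"
  )
}

#' @export
print.efa_fit <- function(x, ...) {
  cat(sprintf(
    "ML EFA: %d factors on %d subscales (n = %d), %s\n",
    x$k, nrow(x$loadings), x$n, x$rotation
  ))
  cat(sprintf(
    "Total variance explained: %.1f%%%s\n",
    100 * x$variance_explained_total,
    if (x$heywood) " [Heywood case clamped]" else ""
  ))
  invisible(x)
}

#' Proportion of total variance explained by a factor solution
#'
#' Sum of communalities over the number of subscales; invariant to
#' rotation since communalities depend only on the uniquenesses.
#'
#' @param solution An `efa_fit`.
#' @return A proportion in `[0, 1]`.
#' @export
variance_explained <- function(solution) {
  stopifnot(inherits(solution, "efa_fit"))
  unname(sum(solution$communalities) / length(solution$communalities))
}

#' Thurstone (regression) factor scores
#'
#' Scores are `Z W` with `W = Sigma^-1 L Phi`, where `Z` are the
#' standardized subscales and `Sigma = L Phi L' + Psi` is the
#' model-implied correlation matrix. Columns have exactly zero mean.
#'
#' @param solution An `efa_fit` fitted on the same subscale set.
#' @param subscales Subscale tibble (with `participant_id`).
#' @return Tibble: `participant_id` plus `factor1..k` score columns.
#' @export
score_factors <- function(solution, subscales) {
  stopifnot(inherits(solution, "efa_fit"))
  x <- as.matrix(dplyr::select(subscales, -dplyr::any_of("participant_id")))
  if (!identical(colnames(x), rownames(solution$loadings))) {
    abort("subscale columns do not match the fitted solution",
      class = "traitspace_data_error"
    )
  }
  L <- solution$loadings
  phi <- solution$phi
  sigma <- L %*% phi %*% t(L) + diag(solution$uniquenesses)
  w <- tryCatch(
    solve(sigma, L %*% phi),
    error = function(e) {
      abort("implied correlation matrix is singular; cannot score",
        class = "traitspace_estimation_error"
      )
    }
  )
  z <- scale(x)
  s <- z %*% w
  colnames(s) <- colnames(L)
  dplyr::bind_cols(
    tibble(participant_id = subscales$participant_id),
    as_tibble(s)
  )
}

#' Covariate-adjusted group comparison of factor scores
#'
#' Per factor, ordinary least squares of the factor score on a group
#' indicator (ASD = 1, control = 0) plus sex, age and subjective
#' socioeconomic status, reporting the group coefficient.
#'
#' @param scores Factor-score tibble from [score_factors()].
#' @param participants Participant tibble (columns `participant_id`,
#'   `group`, `sex`, `age`, `ses`).
#' @return Tibble with one row per factor: `factor`, `B`, `se`, `t`,
#'   `p`, `n`; attribute `covariates` lists the adjustment set.
#' @export
group_factor_model <- function(scores, participants) {
  dat <- dplyr::inner_join(scores, participants, by = "participant_id") %>%
    mutate(group_asd = as.numeric(.data$group == "asd"))
  factors <- grep("^factor", names(scores), value = TRUE)
  X <- stats::model.matrix(~ group_asd + sex + age + ses, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(
      sprintf("design is rank deficient; collinear column(s): %s",
              paste(dropped, collapse = ", ")),
      class = "traitspace_estimation_error"
    )
  }
  res <- purrr::map_dfr(factors, function(f) {
    fit <- lm(stats::reformulate(c("group_asd", "sex", "age", "ses"), f),
              data = dat)
    sm <- summary(fit)$coefficients["group_asd", ]
    tibble(
      factor = f, B = unname(sm[1]), se = unname(sm[2]),
      t = unname(sm[3]), p = unname(sm[4]), n = nrow(dat)
    )
  })
  attr(res, "covariates") <- c("sex", "age", "ses")
  res
}

#' Tucker congruence between two loading columns
#'
#' @param a,b Numeric vectors.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match recovered factors to planted factors
#'
#' Factor order and sign are not identified, so recovery checks greedily
#' pair each planted column with the unmatched recovered column of
#' highest absolute Tucker congruence and align its sign.
#'
#' @param recovered,planted Loading matrices with equal dimensions.
#' @return List: `congruence` (per planted factor, after sign
#'   alignment), `order` (recovered column matched to each planted
#'   column), `signs`.
#' @export
match_factors <- function(recovered, planted) {
  k <- ncol(planted)
  stopifnot(ncol(recovered) == k, nrow(recovered) == nrow(planted))
  cg <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cg[i, j] <- tucker_congruence(planted[, i], recovered[, j])
    }
  }
  ord <- integer(k)
  signs <- numeric(k)
  congr <- numeric(k)
  avail <- rep(TRUE, k)
  for (step in seq_len(k)) {
    m <- abs(cg)
    m[, !avail] <- -Inf
    m[setdiff(seq_len(k), which(ord == 0L)), ] <- -Inf
    pos <- which(m == max(m), arr.ind = TRUE)[1, ]
    i <- pos[1]; j <- pos[2]
    ord[i] <- j
    signs[i] <- sign(cg[i, j])
    congr[i] <- abs(cg[i, j])
    avail[j] <- FALSE
  }
  list(congruence = congr, order = ord, signs = signs)
}
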