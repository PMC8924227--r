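#' One-command pipeline over a synthetic or loaded study
#'
#' Chains the full analysis in study order: simulate (or load) ->
#' behavioral & neuronal QC -> factor analysis (CNG count, ML EFA with
#' oblimin, scores, covariate-adjusted group comparison) -> judgment
#' statistics (trait means, group t-tests, factor-trait correlations,
#' interaction models) -> identity-level RSA against the neuronal
#' population matrix with the group permutation test -> inter-subject
#' dyadic RSA. All outputs are written under `out_dir` together with a
#' `manifest.json` listing file MD5 hashes, the seeds used and the
#' package version; a rerun with the same config and seed reproduces
#' the manifest byte-for-byte.
#'
#' @param config A [sim_config()] (simulated study) — the root seed
#'   inside it drives every stage.
#' @param out_dir Output directory.
#' @param k Factor count, or `"auto"` for the CNG rule.
#' @param n_perm Permutation runs for the neural RSA test.
#' @param rsa_traits Traits to run the neural RSA and IS-RSA for.
#' @param alpha Neuronal responsiveness alpha.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir, k = "auto", n_perm = 1000,
                         rsa_traits = c("trustworthy", "warm"),
                         alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jf <- function(...) file.path(out_dir, ...)
  wj <- function(x, path) {
    jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
        class = "traitspace_pipeline_error"
      )
    })
  }

  study <- stage("simulate", {
    s <- simulate_study(config)
    write_study(s, jf("sim"))
    s
  })

  qc <- stage("qc", {
    beh <- qc_behavior(study$trials)
    neu <- screen_neurons(study$neurons, alpha = alpha)
    write_table(beh$kept_trials, jf("kept_trials.csv"))
    write_table(neu$neuron_verdicts, jf("neuron_verdicts.csv"))
    wj(c(beh$report, neu$report), jf("qc_report.json"))
    list(beh = beh, neu = neu)
  })

  fct <- stage("factors", {
    R <- subscale_correlations(study$subscales)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    k_used <- if (identical(k, "auto")) cng_factor_count(ev) else as.integer(k)
    sol <- fit_efa(study$subscales, k_used)
    scores <- score_factors(sol, study$subscales)
    gm <- group_factor_model(scores, study$participants)
    write_table(tidy(sol), jf("loadings.csv"))
    write_table(scores, jf("scores.csv"))
    wj(
      list(
        k = sol$k, variance_explained_total = sol$variance_explained_total,
        rotation = sol$rotation, heywood = sol$heywood,
        labeling = sol$labeling, phi = apply(sol$phi, 1, as.list, simplify = FALSE)
      ),
      jf("solution.json")
    )
    wj(purrr::transpose(as.list(gm)), jf("group_model.json"))
    list(solution = sol, scores = scores, group_model = gm, k = k_used)
  })

  judge <- stage("judgment", {
    means_unit <- unit_trait_means(qc$beh$kept_trials)
    means_part <- unit_trait_means(qc$beh$kept_trials, unit = "participant")
    tests <- group_trait_tests(means_unit, study$participants)
    cors <- factor_trait_correlations(fct$scores, means_unit, study$participants)
    write_table(means_unit, jf("trait_means.csv"))
    write_table(means_part, jf("trait_means_participant.csv"))
    write_table(tests, jf("trait_tests.csv"))
    write_table(cors, jf("factor_trait_correlations.csv"))
    inter <- list()
    for (tr in rsa_traits) {
      im <- trait_factor_interaction_model(tr, fct$scores, means_unit,
                                           study$participants)
      wj(
        list(trait = tr, terms = purrr::transpose(as.list(im$terms)),
             simple_slopes = purrr::transpose(as.list(im$simple_slopes))),
        jf(sprintf("interaction_%s.json", tr))
      )
      inter[[tr]] <- im
    }
    list(means_unit = means_unit, means_part = means_part,
         tests = tests, correlations = cors, interactions = inter)
  })

  rsa <- stage("rsa_neural", {
    ndm <- neural_population_dm(qc$neu$kept,
                                n_identities = config$n_identities,
                                n_examples = config$n_examples)
    write_dm_csv(ndm, jf("neural_dm.csv"))
    out <- list()
    for (tr in rsa_traits) {
      for (g in c("asd", "control")) {
        cons <- consensus_ratings(qc$beh$kept_trials, study$participants, g, tr,
                                  config$n_identities, config$n_examples)
        dmg <- identity_dm_from_values(cons, config$n_identities,
                                       config$n_examples)
        write_dm_csv(dmg, jf(sprintf("rating_dm_%s_%s.csv", tr, g)))
      }
      pt <- group_correspondence_permutation(
        qc$beh$kept_trials, study$participants, ndm, tr,
        n_perm = n_perm, seed = derive_seed(config$seed, "perm"),
        n_identities = config$n_identities, n_examples = config$n_examples
      )
      wj(
        list(trait = tr, observed = pt$observed, rho_control = pt$rho_control,
             rho_asd = pt$rho_asd, p = pt$p, n_perm = pt$n_perm,
             seed = pt$seed, sidedness = pt$sidedness),
        jf(sprintf("perm_result_%s.json", tr))
      )
      out[[tr]] <- pt
    }
    out
  })

  isr <- stage("isrsa", {
    out <- list()
    dy <- build_dyad_table(judge$means_part, fct$scores, study$participants)
    for (tr in rsa_traits) {
      f <- isrsa_fit(dy, tr)
      wj(
        list(trait = tr, inference = "ols (dyadic dependence unadjusted)",
             terms = purrr::transpose(as.list(f$terms)),
             simple_slopes = purrr::transpose(as.list(f$simple_slopes)),
             n_dyads = f$n),
        jf(sprintf("isrsa_%s.json", tr))
      )
      out[[tr]] <- f
    }
    out
  })

  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    "manifest.json"
  ))
  manifest <- list(
    package_version = as.character(utils::packageVersion("traitspace")),
    root_seed = config$seed,
    stage_seeds = list(
      cohort = derive_seed(config$seed, "cohort"),
      subscales = derive_seed(config$seed, "subscales"),
      trials = derive_seed(config$seed, "trials"),
      neurons = derive_seed(config$seed, "neurons"),
      perm = derive_seed(config$seed, "perm")
    ),
    n_perm = n_perm, k = fct$k,
    files = lapply(setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  wj(manifest, jf("manifest.json"))
  invisible(manifest)
}
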