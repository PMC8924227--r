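#' Trial-level reaction-time filter
#'
#' Excludes trials with reaction times shorter than 100 ms or longer
#' than 5000 ms (strict inequalities: 100 and 5000 are kept). Row order
#' is preserved in both outputs.
#'
#' @param trials Trial table with an `rt_ms` column.
#' @return List with tibbles `kept` and `excluded`.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   participant_id = "P1", module = 1, trait = "warm",
#'   identity_id = 1:3, example_id = 1, rating = c(2, 4, 6),
#'   rt_ms = c(99, 100, 6000)
#' )
#' filter_trials(tr)$kept$rt_ms
filter_trials <- function(trials) {
  if (!"rt_ms" %in% names(trials)) {
    abort("trials must contain an `rt_ms` column", class = "traitspace_data_error")
  }
  bad <- which(!is.finite(trials$rt_ms))
  if (length(bad) > 0) {
    abort(
      sprintf(
        "rt_ms missing or non-finite in rows: %s",
        paste(head(bad, 10), collapse = ", ")
      ),
      class = "traitspace_data_error"
    )
  }
  out <- trials$rt_ms < 100 | trials$rt_ms > 5000
  list(kept = trials[!out, , drop = FALSE], excluded = trials[out, , drop = FALSE])
}

#' Block-level exclusion verdicts
#'
#' A block is one (participant, module, trait) rating run of all
#' identities. A block is excluded if strictly more than 30% of its
#' trials were removed by the reaction-time filter, or if the kept
#' trials use fewer than three distinct rating values. When both hold,
#' both reasons are recorded and the primary reason is `rt_fraction`. A
#' block with no kept trials is excluded with primary reason
#' `rating_diversity`.
#'
#' @param kept,excluded Tibbles from [filter_trials()].
#' @return Tibble with one row per block: `participant_id`, `module`,
#'   `trait`, `n_kept`, `n_excluded`, `frac_excluded`, `n_rating_values`,
#'   `fail_rt_fraction`, `fail_rating_diversity`, `block_excluded`,
#'   `primary_reason` (NA when kept).
#' @export
filter_blocks <- function(kept, excluded) {
  key <- c("participant_id", "module", "trait")
  k <- kept %>%
    group_by(dplyr::across(dplyr::all_of(key))) %>%
    summarise(
      n_kept = n(),
      n_rating_values = n_distinct(.data$rating),
      .groups = "drop"
    )
  e <- excluded %>%
    group_by(dplyr::across(dplyr::all_of(key))) %>%
    summarise(n_excluded = n(), .groups = "drop")
  verdicts <- dplyr::full_join(k, e, by = key) %>%
    mutate(
      n_kept = dplyr::coalesce(.data$n_kept, 0L),
      n_excluded = dplyr::coalesce(.data$n_excluded, 0L),
      n_rating_values = dplyr::coalesce(.data$n_rating_values, 0L),
      frac_excluded = .data$n_excluded / (.data$n_kept + .data$n_excluded),
      fail_rt_fraction = .data$frac_excluded > 0.30,
      fail_rating_diversity = .data$n_rating_values < 3,
      block_excluded = .data$fail_rt_fraction | .data$fail_rating_diversity,
      primary_reason = dplyr::case_when(
        .data$fail_rt_fraction ~ "rt_fraction",
        .data$fail_rating_diversity ~ "rating_diversity",
        TRUE ~ NA_character_
      )
    ) %>%
    arrange(.data$participant_id, .data$module, .data$trait)
  verdicts
}

#' Participant-level exclusion
#'
#' A participant is excluded when strictly more than three of their
#' blocks were excluded (four or more); exactly three is kept.
#'
#' @param verdicts Tibble from [filter_blocks()].
#' @return Tibble: `participant_id`, `n_blocks`, `n_blocks_excluded`,
#'   `participant_excluded`.
#' @export
filter_participants <- function(verdicts) {
  verdicts %>%
    group_by(.data$participant_id) %>%
    summarise(
      n_blocks = n(),
      n_blocks_excluded = sum(.data$block_excluded),
      .groups = "drop"
    ) %>%
    mutate(participant_excluded = .data$n_blocks_excluded > 3)
}

#' Run the full behavioral QC cascade
#'
#' Applies the trial, block and participant filters in sequence and
#' assembles an auditable report. The surviving trial table contains
#' only kept trials from kept blocks of kept participants.
#'
#' @param trials Raw trial table.
#' @return List: `kept_trials`, `trial_filter` (kept/excluded),
#'   `block_verdicts`, `participant_verdicts`, `report` (named list of
#'   counts).
#' @export
qc_behavior <- function(trials) {
  tf <- filter_trials(trials)
  verdicts <- filter_blocks(tf$kept, tf$excluded)
  pv <- filter_participants(verdicts)
  bad_part <- pv$participant_id[pv$participant_excluded]
  good_blocks <- verdicts %>%
    filter(!.data$block_excluded, !.data$participant_id %in% bad_part)
  kept_trials <- tf$kept %>%
    dplyr::semi_join(good_blocks, by = c("participant_id", "module", "trait"))
  report <- list(
    n_trials_in = nrow(trials),
    n_trials_rt_excluded = nrow(tf$excluded),
    n_blocks = nrow(verdicts),
    n_blocks_excluded = sum(verdicts$block_excluded),
    n_blocks_excluded_rt_fraction = sum(verdicts$primary_reason %in% "rt_fraction"),
    n_blocks_excluded_rating_diversity =
      sum(verdicts$primary_reason %in% "rating_diversity"),
    n_participants_in = nrow(pv),
    n_participants_excluded = sum(pv$participant_excluded),
    n_trials_out = nrow(kept_trials)
  )
  list(
    kept_trials = kept_trials, trial_filter = tf,
    block_verdicts = verdicts, participant_verdicts = pv,
    report = report
  )
}

#' Screen neurons for rate and face-responsiveness
#'
#' Stage 1 keeps neurons whose session-mean response-window rate exceeds
#' 0.15 Hz (strict). Stage 2 keeps neurons whose per-image response
#' rates exceed their per-image baseline-window rates by a one-sided
#' paired t-test at `alpha`. A neuron whose paired differences have zero
#' variance (e.g. response identical to baseline) is not responsive.
#'
#' @param neurons Long neuron table from [generate_neurons()] (columns
#'   `neuron_id`, `response_rate`, `baseline_window_rate`, one row per
#'   neuron x image).
#' @param alpha One-sided significance level (default 0.05).
#' @param min_rate_hz Stage-1 rate threshold in Hz (default 0.15).
#' @return List: `kept` (neuron table restricted to surviving neurons),
#'   `neuron_verdicts` (per-neuron tibble), `report` (counts:
#'   `n_in`, `n_low_rate`, `n_nonresponsive`, `n_kept`, plus the test
#'   and alpha used, which are stated assumptions).
#' @export
screen_neurons <- function(neurons, alpha = 0.05, min_rate_hz = 0.15) {
  per <- neurons %>%
    group_by(.data$neuron_id) %>%
    summarise(
      n_images = n(),
      overall_rate = mean(.data$response_rate),
      .groups = "drop"
    )
  if (any(per$n_images < 2)) {
    abort("each neuron needs at least 2 images to screen",
      class = "traitspace_data_error"
    )
  }
  pvals <- neurons %>%
    group_by(.data$neuron_id) %>%
    summarise(
      p_responsive = paired_greater_p(.data$response_rate,
                                      .data$baseline_window_rate),
      .groups = "drop"
    )
  verdicts <- per %>%
    left_join(pvals, by = "neuron_id") %>%
    mutate(
      pass_rate = .data$overall_rate > min_rate_hz,
      pass_responsive = !is.na(.data$p_responsive) & .data$p_responsive < alpha,
      neuron_kept = .data$pass_rate & .data$pass_responsive
    )
  kept_ids <- verdicts$neuron_id[verdicts$neuron_kept]
  report <- list(
    n_in = nrow(verdicts),
    n_low_rate = sum(!verdicts$pass_rate),
    n_nonresponsive = sum(verdicts$pass_rate & !verdicts$pass_responsive),
    n_kept = length(kept_ids),
    test = "one-sided paired t (response > baseline), assumed form",
    alpha = alpha, min_rate_hz = min_rate_hz
  )
  list(
    kept = neurons %>% filter(.data$neuron_id %in% kept_ids),
    neuron_verdicts = verdicts,
    report = report
  )
}

paired_greater_p <- function(resp, base) {
  d <- resp - base
  if (length(d) < 2 || sd(d) == 0) return(NA_real_)
  tt <- t.test(d, alternative = "greater")
  unname(tt$p.value)
}
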