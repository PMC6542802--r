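#' Preference index of T-maze trials
#'
#' The preference index of one trial is `(N_E - N_C) / (N_E + N_C)`, where
#' `N_E` and `N_C` are the counts of flies trapped in the exposed and
#' control arms; it ranges from -1 (all choosers avoided the exposed arm)
#' to +1 (all chose it). A trial in which no fly made a choice has no
#' defined preference index and raises an error rather than silently
#' contributing 0; exclude such trials upstream.
#'
#' @param n_exposed,n_control Non-negative integer counts per trial
#'   (vectorized).
#' @return Numeric vector of preference indices in [-1, 1].
#' @examples
#' preference_index(5, 15)
#' @export
preference_index <- function(n_exposed, n_control) {
  check_counts_vec(n_exposed, n_control)
  choosers <- n_exposed + n_control
  if (any(choosers == 0)) {
    stop_deathcue(
      "preference index undefined: trial(s) with no choosing flies.",
      "undefined_pi"
    )
  }
  (n_exposed - n_control) / choosers
}

#' Participation fraction of T-maze trials
#'
#' Fraction of loaded flies that entered either trap arm:
#' `(N_E + N_C) / flies_loaded`.
#'
#' @inheritParams preference_index
#' @param flies_loaded Flies loaded into the maze (assay standard 20).
#' @return Numeric vector in [0, 1].
#' @examples
#' participation_fraction(6, 5)
#' @export
participation_fraction <- function(n_exposed, n_control, flies_loaded = 20) {
  check_counts_vec(n_exposed, n_control)
  if (any(flies_loaded < 1)) {
    stop_deathcue("`flies_loaded` must be >= 1.", "bad_param")
  }
  frac <- (n_exposed + n_control) / flies_loaded
  if (any(frac > 1 + 1e-12)) {
    stop_deathcue("arm counts exceed `flies_loaded`.", "bad_param")
  }
  frac
}

check_counts_vec <- function(n_exposed, n_control) {
  ok <- function(x) is.numeric(x) && all(!is.na(x) & x >= 0 & x == floor(x))
  if (!ok(n_exposed) || !ok(n_control)) {
    stop_deathcue("arm counts must be non-negative integers.", "bad_param")
  }
  invisible(NULL)
}

# Columns + per-trial derived quantities; drops zero-chooser trials with a
# message. Shared by the summary and randomization functions.
prepare_trials <- function(trials) {
  trials <- as_tibble(trials)
  required <- c("treatment", "n_exposed_arm", "n_control_arm")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop_deathcue(
      sprintf("`trials` is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "bad_param"
    )
  }
  check_counts_vec(trials$n_exposed_arm, trials$n_control_arm)
  if (!"flies_loaded" %in% names(trials)) trials$flies_loaded <- 20L
  if (!"block" %in% names(trials)) trials$block <- NA_character_
  choosers <- trials$n_exposed_arm + trials$n_control_arm
  n_empty <- sum(choosers == 0)
  if (n_empty > 0) {
    rlang::inform(sprintf(
      "Excluding %d trial(s) with no choosing flies (preference index undefined).",
      n_empty
    ))
    trials <- trials[choosers > 0, , drop = FALSE]
  }
  if (nrow(trials) == 0) {
    stop_deathcue("no trials with choosing flies; summary undefined.", "undefined_pi")
  }
  dplyr::mutate(trials,
    pi = preference_index(.data$n_exposed_arm, .data$n_control_arm),
    choosers = .data$n_exposed_arm + .data$n_control_arm,
    participation = participation_fraction(
      .data$n_exposed_arm, .data$n_control_arm, .data$flies_loaded
    )
  )
}

#' Chooser-weighted mean preference index
#'
#' Averages per-trial preference indices with weights equal to the number of
#' choosing flies in each trial, so trials in which more animals expressed a
#' choice count for more. The weighted standard error uses the linearized
#' variance of the weighted mean.
#'
#' @param trials Tibble of trials with columns `treatment`,
#'   `n_exposed_arm`, `n_control_arm` and optionally `block`,
#'   `flies_loaded`. Trials with zero choosers are excluded with a message.
#' @return A one-row tibble (class `preference_summary`) with
#'   `weighted_mean_pi`, `weighted_sem`, `total_choosers`, `n_trials`,
#'   `mean_participation`, and list-columns `per_trial_pi`,
#'   `participation_fractions`.
#' @examples
#' trials <- simulate_choice_trials(6, p_exposed_arm = 0.3, seed = 1)
#' weighted_mean_pi(trials)
#' @export
weighted_mean_pi <- function(trials) {
  out <- pi_summary_core(prepare_trials(trials))
  class(out) <- c("preference_summary", class(out))
  out
}

pi_summary_core <- function(prepared) {
  w <- prepared$choosers
  x <- prepared$pi
  wm <- sum(w * x) / sum(w)
  sem <- sqrt(sum(w^2 * (x - wm)^2)) / sum(w)
  tibble(
    weighted_mean_pi = wm,
    weighted_sem = sem,
    total_choosers = sum(w),
    n_trials = nrow(prepared),
    mean_participation = mean(prepared$participation),
    per_trial_pi = list(x),
    participation_fractions = list(prepared$participation)
  )
}

#' Per-treatment preference summary
#'
#' [weighted_mean_pi()] applied within each treatment group.
#'
#' @inheritParams weighted_mean_pi
#' @return A tibble (class `preference_summary`) with one row per treatment.
#' @examples
#' trials <- dplyr::bind_rows(
#'   simulate_choice_trials(6, p_exposed_arm = 0.3, treatment = "exposed", seed = 1),
#'   simulate_choice_trials(6, p_exposed_arm = 0.5, treatment = "unexposed", seed = 2)
#' )
#' summarize_preference(trials)
#' @export
summarize_preference <- function(trials) {
  trials <- prepare_trials(trials)
  out <- trials |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(~ pi_summary_core(.x)) |>
    dplyr::ungroup()
  class(out) <- c("preference_summary", class(out))
  out
}
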