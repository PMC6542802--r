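#' Simulate binary-choice T-maze trials
#'
#' Generates replicate T-maze trials with the structure the preference
#' analysis assumes: out of `flies_loaded` flies per trial, a binomial number
#' participate (enter either trap arm), and each participant independently
#' chooses the exposed arm with probability `p_exposed_arm`. A trial with
#' `p_exposed_arm = 0.5` is a null trial (no aversion); values below 0.5
#' produce avoidance of the exposed arm (negative preference index).
#'
#' @param n_trials Number of replicate trials to generate.
#' @param flies_loaded Flies loaded into the maze per trial (assay standard
#'   is 20 naive choosers).
#' @param p_exposed_arm Probability that a participating fly enters the
#'   exposed arm.
#' @param participation_rate Probability that a loaded fly makes a choice at
#'   all. Must be in (0, 1]; participation in the assay is typically above
#'   0.5.
#' @param treatment Treatment label attached to every generated trial.
#' @param blocks Optional vector of block labels, recycled to `n_trials`.
#' @param seed Optional integer seed; identical seeds give identical trials.
#'
#' @return A tibble with columns `trial_id`, `treatment`, `block`,
#'   `n_exposed_arm`, `n_control_arm`, `flies_loaded`.
#'
#' @examples
#' simulate_choice_trials(5, p_exposed_arm = 0.3, seed = 1)
#' @export
simulate_choice_trials <- function(n_trials,
                                   flies_loaded = 20,
                                   p_exposed_arm = 0.5,
                                   participation_rate = 0.9,
                                   treatment = "exposed",
                                   blocks = NULL,
                                   seed = NULL) {
  n_trials <- check_count(n_trials, "n_trials")
  flies_loaded <- check_count(flies_loaded, "flies_loaded")
  check_prob(p_exposed_arm, "p_exposed_arm")
  check_prob(participation_rate, "participation_rate", open_left = TRUE)
  local_seed(seed)

  participants <- rbinom(n_trials, flies_loaded, participation_rate)
  n_exposed <- rbinom(n_trials, participants, p_exposed_arm)
  tibble(
    trial_id = sprintf("trial_%03d", seq_len(n_trials)),
    treatment = as.character(treatment),
    block = if (is.null(blocks)) NA_character_ else as.character(rep_len(blocks, n_trials)),
    n_exposed_arm = n_exposed,
    n_control_arm = participants - n_exposed,
    flies_loaded = flies_loaded
  )
}
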