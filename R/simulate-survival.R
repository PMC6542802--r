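#' Simulate lifespan cohorts under a 2 x 2 factorial hazard model
#'
#' Draws per-fly ages at death from a Gompertz (default; the classical model
#' for insect mortality, with hazard `a * exp(b * t)`) or exponential
#' baseline, multiplied by `exp()` of main-effect and interaction log-hazard
#' coefficients for exposure and genotype. Times beyond `censoring_time` are
#' right-censored.
#'
#' @param n_per_arm Flies per design cell.
#' @param baseline `"gompertz"` or `"exponential"`.
#' @param gompertz_a,gompertz_b Gompertz baseline parameters (hazard at age
#'   0, in deaths/day, and its exponential ageing rate per day).
#' @param exp_rate Exponential baseline hazard (deaths/day).
#' @param beta_exposure,beta_genotype,beta_interaction Log hazard ratios for
#'   exposure (exposed vs unexposed), genotype (mutant vs control), and
#'   their interaction.
#' @param censoring_time Optional administrative right-censoring age.
#' @param genotype_levels,exposure_levels Factor levels to generate; drop a
#'   level for a single-factor cohort.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `fly_id`, `genotype`, `exposure`,
#'   `event_time`, `event_observed`; the factor reference levels are the
#'   first entries of `genotype_levels` / `exposure_levels`.
#'
#' @examples
#' simulate_cohorts(n_per_arm = 5, beta_exposure = 0.4, seed = 1)
#' @export
simulate_cohorts <- function(n_per_arm = 150,
                             baseline = c("gompertz", "exponential"),
                             gompertz_a = 0.001,
                             gompertz_b = 0.1,
                             exp_rate = 0.02,
                             beta_exposure = 0,
                             beta_genotype = 0,
                             beta_interaction = 0,
                             censoring_time = NULL,
                             genotype_levels = c("control", "mutant"),
                             exposure_levels = c("unexposed", "exposed"),
                             seed = NULL) {
  baseline <- rlang::arg_match(baseline)
  n_per_arm <- check_count(n_per_arm, "n_per_arm", min = 2L)
  if (baseline == "gompertz" && (gompertz_a <= 0 || gompertz_b <= 0)) {
    stop_deathcue("Gompertz parameters must be strictly positive.", "bad_param")
  }
  if (baseline == "exponential" && exp_rate <= 0) {
    stop_deathcue("`exp_rate` must be strictly positive.", "bad_param")
  }
  if (!is.null(censoring_time) && censoring_time <= 0) {
    stop_deathcue("`censoring_time` must be positive.", "bad_param")
  }
  local_seed(seed)

  design <- tidyr::expand_grid(
    genotype = factor(genotype_levels, levels = genotype_levels),
    exposure = factor(exposure_levels, levels = exposure_levels)
  )
  cohort <- tidyr::uncount(design, n_per_arm)
  n <- nrow(cohort)
  is_exposed <- as.integer(cohort$exposure == exposure_levels[min(2, length(exposure_levels))] &
                             length(exposure_levels) > 1)
  is_mutant <- as.integer(cohort$genotype == genotype_levels[min(2, length(genotype_levels))] &
                            length(genotype_levels) > 1)
  mult <- exp(beta_exposure * is_exposed + beta_genotype * is_mutant +
                beta_interaction * is_exposed * is_mutant)

  u <- runif(n)
  death_time <- if (baseline == "exponential") {
    -log(u) / (exp_rate * mult)
  } else {
    # Invert the Gompertz cumulative hazard (a * mult / b) * (exp(b t) - 1).
    log1p(gompertz_b * (-log(u)) / (gompertz_a * mult)) / gompertz_b
  }

  cohort <- dplyr::mutate(cohort,
    fly_id = sprintf("fly_%05d", seq_len(n)),
    event_time = death_time,
    event_observed = TRUE,
    .before = 1L
  )
  if (!is.null(censoring_time)) {
    cohort$event_observed <- cohort$event_time <= censoring_time
    cohort$event_time <- pmin(cohort$event_time, censoring_time)
  }
  dplyr::select(cohort, "fly_id", "genotype", "exposure", "event_time", "event_observed")
}
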