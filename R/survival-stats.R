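# Survival comparisons for lifespan and starvation cohorts, built on the
# survival package: Kaplan-Meier curves, log-rank tests, and
# exposure x genotype interaction tests (Cox regression with Breslow ties
# when proportional hazards hold; two-way ANOVA on age at death otherwise).

check_cohort <- function(cohort, require_genotype = FALSE) {
  cohort <- as_tibble(cohort)
  required <- c("event_time", "event_observed", "exposure")
  if (require_genotype) required <- c(required, "genotype")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop_deathcue(
      sprintf("cohort is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "bad_param"
    )
  }
  if (any(is.na(cohort$event_time)) || any(cohort$event_time <= 0)) {
    stop_deathcue("`event_time` must be positive.", "bad_param")
  }
  cohort$event_observed <- as.logical(cohort$event_observed)
  cohort
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survivor function, optionally stratified
#' by a grouping column. Censored individuals leave the risk set at their
#' censoring time.
#'
#' @param cohort Tibble with columns `event_time`, `event_observed`
#'   (logical), plus any grouping columns.
#' @param by Optional name of a grouping column (e.g. `"exposure"`).
#' @return A tibble of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; each group starts at
#'   survival 1 at time 0 and is a right-continuous step function.
#' @examples
#' cohort <- simulate_cohorts(n_per_arm = 30, seed = 1)
#' km_estimate(cohort, by = "exposure")
#' @export
km_estimate <- function(cohort, by = NULL) {
  cohort <- check_cohort(cohort)
  if (sum(cohort$event_observed) == 0) {
    stop_deathcue("no observed events; survival curve degenerate.", "no_events")
  }
  if (!is.null(by) && !by %in% names(cohort)) {
    stop_deathcue(sprintf("grouping column '%s' not found.", by), "bad_param")
  }
  fml <- if (is.null(by)) {
    survival::Surv(event_time, event_observed) ~ 1
  } else {
    stats::as.formula(paste("survival::Surv(event_time, event_observed) ~", by))
  }
  fit <- survival::survfit(fml, data = cohort)
  strata <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^[^=]*=", "", names(fit$strata)), fit$strata)
  }
  curve <- tibble(
    group = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  origin <- curve |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      time = 0, n_risk = max(.data$n_risk), n_event = 0L, n_censor = 0L,
      survival = 1, .groups = "drop"
    )
  out <- dplyr::arrange(dplyr::bind_rows(origin, curve), .data$group, .data$time)
  new_tibble(out, class = "km_curve")
}

#' Log-rank comparison of survival curves
#'
#' Standard log-rank chi-square test (1 degree of freedom for two groups)
#' comparing observed and expected event counts across the shared risk
#' sets.
#'
#' @param cohort Tibble with `event_time`, `event_observed`, and the
#'   grouping column.
#' @param group Name of the grouping column (default `"exposure"`).
#' @return An object of class `logrank_test`: `statistic`, `df`,
#'   `p_value`, and the per-group observed/expected table.
#' @examples
#' cohort <- simulate_cohorts(n_per_arm = 50, beta_exposure = 0.7, seed = 1)
#' logrank_test(cohort)
#' @export
logrank_test <- function(cohort, group = "exposure") {
  cohort <- check_cohort(cohort)
  if (!group %in% names(cohort)) {
    stop_deathcue(sprintf("grouping column '%s' not found.", group), "bad_param")
  }
  cohort$..group <- factor(cohort[[group]])
  events_by_group <- tapply(cohort$event_observed, cohort$..group, sum)
  if (any(events_by_group == 0)) {
    stop_deathcue("every compared group needs at least one observed event.", "no_events")
  }
  sd_fit <- survival::survdiff(
    survival::Surv(event_time, event_observed) ~ ..group,
    data = cohort
  )
  df <- length(sd_fit$n) - 1L
  structure(
    list(
      statistic = as.numeric(sd_fit$chisq),
      df = df,
      p_value = as.numeric(pchisq(sd_fit$chisq, df, lower.tail = FALSE)),
      observed = as.numeric(sd_fit$obs),
      expected = as.numeric(sd_fit$exp),
      groups = sub("^\\.\\.group=", "", names(sd_fit$n))
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test (%s): chisq = %.4f on %d df, p = %.4g\n",
              paste(x$groups, collapse = " vs "), x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(
    group = x$groups,
    observed = x$observed,
    expected = x$expected
  )
}

#' @rdname logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value)
}

interaction_result <- function(method, term, estimate, std_error, statistic, p_value) {
  out <- tibble(
    method = method, term = term, estimate = estimate,
    std_error = std_error, statistic = statistic, p_value = p_value
  )
  new_tibble(out, class = "interaction_result")
}

check_2x2 <- function(cohort, require_events = TRUE) {
  cells <- table(cohort$exposure, cohort$genotype)
  if (!all(dim(cells) == c(2L, 2L)) || any(cells == 0)) {
    stop_deathcue("a complete 2 x 2 exposure x genotype design is required.", "design_error")
  }
  if (require_events) {
    ev <- tapply(cohort$event_observed, list(cohort$exposure, cohort$genotype), sum)
    if (any(ev == 0)) {
      stop_deathcue("every design cell needs at least one observed event.", "design_error")
    }
  }
  invisible(NULL)
}

#' Exposure x genotype interaction via Cox regression
#'
#' Fits a proportional-hazards model with exposure, genotype, and their
#' interaction (Breslow tie handling by default) and reports the
#' interaction log hazard ratio. Use [check_proportional_hazards()] to
#' assess the proportional-hazards assumption; when it fails and no
#' censoring is present, [anova_interaction_age_at_death()] is the
#' fallback.
#'
#' @param cohort Tibble with `event_time`, `event_observed`, `exposure`,
#'   `genotype` (2 levels each, all four cells populated with events).
#'   Supply factors to control the reference levels; characters are
#'   converted with alphabetical ordering.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return A one-row tibble of class `interaction_result` with the
#'   interaction `estimate` (log HR), `std_error`, Wald `statistic`, and
#'   `p_value`.
#' @examples
#' cohort <- simulate_cohorts(n_per_arm = 80, beta_interaction = -0.5, seed = 1)
#' cox_interaction(cohort)
#' @export
cox_interaction <- function(cohort, ties = c("breslow", "efron")) {
  ties <- rlang::arg_match(ties)
  cohort <- check_cohort(cohort, require_genotype = TRUE)
  cohort$exposure <- as.factor(cohort$exposure)
  cohort$genotype <- as.factor(cohort$genotype)
  check_2x2(cohort)
  fit <- survival::coxph(
    survival::Surv(event_time, event_observed) ~ exposure * genotype,
    data = cohort, ties = ties
  )
  cf <- coef(fit)
  term <- grep(":", names(cf), value = TRUE)
  est <- cf[term]
  se <- sqrt(diag(fit$var))[match(term, names(cf))]
  if (!is.finite(est) || !is.finite(se) || se <= 0) {
    stop_deathcue(
      sprintf("Cox fit did not converge (estimate %.3g, SE %.3g).", est, se),
      "fit_error"
    )
  }
  zstat <- est / se
  interaction_result(
    method = "cox", term = term, estimate = as.numeric(est),
    std_error = as.numeric(se), statistic = as.numeric(zstat),
    p_value = as.numeric(2 * stats::pnorm(-abs(zstat)))
  )
}

#' Exposure x genotype interaction via ANOVA on age at death
#'
#' Two-way fixed-effects ANOVA F test of the exposure x genotype
#' interaction on age at death, for cohorts in which every fly's death was
#' observed. Any censored record is an error: use [cox_interaction()] for
#' censored data.
#'
#' @inheritParams cox_interaction
#' @return A one-row tibble of class `interaction_result`; `estimate` is
#'   the interaction mean-difference contrast (the difference of exposure
#'   effects between genotypes) and `statistic` is the ANOVA F.
#' @export
anova_interaction_age_at_death <- function(cohort) {
  cohort <- check_cohort(cohort, require_genotype = TRUE)
  if (!all(cohort$event_observed)) {
    stop_deathcue(
      "censored records present; ANOVA on age at death requires observed deaths only. Use cox_interaction().",
      "censored"
    )
  }
  cohort$exposure <- as.factor(cohort$exposure)
  cohort$genotype <- as.factor(cohort$genotype)
  check_2x2(cohort, require_events = FALSE)
  fit <- lm(event_time ~ exposure * genotype, data = cohort)
  an <- anova(fit)
  row <- grep(":", rownames(an))
  cf <- summary(fit)$coefficients
  term <- grep(":", rownames(cf), value = TRUE)
  interaction_result(
    method = "anova_age_at_death", term = term,
    estimate = as.numeric(cf[term, "Estimate"]),
    std_error = as.numeric(cf[term, "Std. Error"]),
    statistic = as.numeric(an[row, "F value"]),
    p_value = as.numeric(an[row, "Pr(>F)"])
  )
}

#' Schoenfeld-residual check of proportional hazards
#'
#' Diagnostic for choosing between [cox_interaction()] and
#' [anova_interaction_age_at_death()]: tests for a time trend in the
#' scaled Schoenfeld residuals of the interaction Cox model.
#'
#' @inheritParams cox_interaction
#' @return A tibble with one row per model term plus `GLOBAL`:
#'   `term`, `chisq`, `df`, `p_value`. Small p-values indicate departure
#'   from proportional hazards.
#' @export
check_proportional_hazards <- function(cohort, ties = c("breslow", "efron")) {
  ties <- rlang::arg_match(ties)
  cohort <- check_cohort(cohort, require_genotype = TRUE)
  cohort$exposure <- as.factor(cohort$exposure)
  cohort$genotype <- as.factor(cohort$genotype)
  check_2x2(cohort)
  fit <- survival::coxph(
    survival::Surv(event_time, event_observed) ~ exposure * genotype,
    data = cohort, ties = ties
  )
  zp <- survival::cox.zph(fit)
  tab <- zp$table
  tibble(
    term = rownames(tab),
    chisq = as.numeric(tab[, "chisq"]),
    df = as.numeric(tab[, "df"]),
    p_value = as.numeric(tab[, "p"])
  )
}
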