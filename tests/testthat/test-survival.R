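test_that("KM estimate equals the empirical survivor function without censoring", {
  co <- tibble::tibble(
    fly_id = as.character(1:5), exposure = "unexposed",
    event_time = 1:5, event_observed = TRUE
  )
  km <- km_estimate(co)
  expect_equal(km$time, 0:5)
  expect_equal(km$survival, seq(1, 0, by = -0.2))
  expect_true(all(diff(km$survival) <= 0))

  # all censored but one death: single step
  co2 <- co
  co2$event_observed <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  km2 <- km_estimate(co2)
  expect_equal(sum(km2$n_event), 1)
  expect_equal(min(km2$survival), 0.8)

  co3 <- co
  co3$event_observed <- FALSE
  expect_error(km_estimate(co3), class = "deathcue_no_events")
})

test_that("log-rank statistic matches an explicit risk-set computation", {
  # two 3-fly arms, no censoring, alternating deaths
  co <- tibble::tibble(
    fly_id = as.character(1:6),
    exposure = rep(c("a", "b"), each = 3),
    event_time = c(2, 4, 6, 1, 3, 5),
    event_observed = TRUE
  )
  # independent oracle: O - E and hypergeometric variance per event time
  times <- sort(unique(co$event_time))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- co$event_time >= t
    n1 <- sum(at_risk & co$exposure == "a")
    n <- sum(at_risk)
    d <- sum(co$event_time == t)
    d1 <- sum(co$event_time == t & co$exposure == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- o_minus_e^2 / v
  lr <- logrank_test(co)
  expect_equal(lr$statistic, oracle, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(oracle, 1, lower.tail = FALSE))

  # identical cohorts: statistic 0, p = 1
  same <- dplyr::bind_rows(
    dplyr::mutate(co, exposure = "x"),
    dplyr::mutate(co, exposure = "y", fly_id = paste0("b", fly_id))
  )
  lr0 <- logrank_test(same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
})

test_that("log-rank is invariant to monotone time transformation", {
  co <- simulate_cohorts(n_per_arm = 60, beta_exposure = 0.5,
                         genotype_levels = "control", seed = 12)
  s1 <- logrank_test(co)$statistic
  co$event_time <- co$event_time^2
  expect_equal(logrank_test(co)$statistic, s1, tolerance = 1e-12)
  co$event_time <- log1p(co$event_time)
  expect_equal(logrank_test(co)$statistic, s1, tolerance = 1e-12)
})

test_that("log-rank detects a twofold hazard ratio at n = 150 per arm", {
  rejections <- logical(100)
  for (i in seq_along(rejections)) {
    co <- simulate_cohorts(
      n_per_arm = 150, baseline = "exponential", exp_rate = 0.05,
      beta_exposure = log(2), genotype_levels = "control", seed = 5000 + i
    )
    rejections[i] <- logrank_test(co)$p_value < 0.05
  }
  expect_gte(mean(rejections), 0.95)
})

test_that("Cox interaction recovers simulated log hazard ratios", {
  est <- numeric(100)
  for (i in seq_along(est)) {
    co <- simulate_cohorts(n_per_arm = 150, beta_exposure = 0.3,
                           beta_genotype = -0.2, beta_interaction = 0.4,
                           seed = 600 + i)
    est[i] <- cox_interaction(co)$estimate
  }
  expect_lt(abs(mean(est) - 0.4), 0.1)
})

test_that("duplicated data as a fake factor yields a null interaction", {
  co <- simulate_cohorts(n_per_arm = 100, beta_exposure = 0.5,
                         genotype_levels = "control", seed = 44)
  fake <- dplyr::bind_rows(
    dplyr::mutate(co, genotype = "g1"),
    dplyr::mutate(co, genotype = "g2", fly_id = paste0("dup", fly_id))
  )
  fit <- cox_interaction(fake)
  expect_lt(abs(fit$estimate), 1e-6)
})

test_that("Cox estimates on exponential data are consistent as n grows", {
  bias_at <- function(n, seed) {
    co <- simulate_cohorts(n_per_arm = n, baseline = "exponential",
                           exp_rate = 0.05, beta_interaction = 0.5, seed = seed)
    abs(cox_interaction(co)$estimate - 0.5)
  }
  small <- mean(vapply(1:8, function(i) bias_at(100, 80 + i), numeric(1)))
  big <- mean(vapply(1:8, function(i) bias_at(5000, 90 + i), numeric(1)))
  expect_lt(big, small)
  expect_lt(big, 0.05)
})

test_that("age-at-death ANOVA handles nulls, power, and censoring guard", {
  co <- simulate_cohorts(n_per_arm = 100, beta_exposure = 0.2, seed = 5)
  res <- anova_interaction_age_at_death(co)
  expect_s3_class(res, "interaction_result")
  expect_true(res$p_value > 0 && res$p_value <= 1)

  cens <- co
  cens$event_observed[1] <- FALSE
  expect_error(anova_interaction_age_at_death(cens), class = "deathcue_censored")

  # equal cell means: F ~ 0 is false in noise, but a crossed design with a
  # 5-day contrast at SD 10 and n = 100/cell is detected reliably
  rejections <- logical(60)
  for (i in seq_along(rejections)) {
    set.seed(7000 + i)
    cells <- tidyr::expand_grid(
      genotype = c("control", "mutant"), exposure = c("unexposed", "exposed")
    )
    ages <- purrr::pmap(cells, function(genotype, exposure) {
      # crossed pattern: exposure shifts age by -5 days in controls and
      # +5 days in mutants
      mu <- 60 + ifelse(exposure == "exposed",
                        ifelse(genotype == "control", -2.5, 2.5),
                        ifelse(genotype == "control", 2.5, -2.5))
      tibble::tibble(genotype, exposure, event_time = pmax(1, rnorm(100, mu, 10)),
                     event_observed = TRUE)
    })
    d <- dplyr::bind_rows(ages)
    d$fly_id <- as.character(seq_len(nrow(d)))
    rejections[i] <- anova_interaction_age_at_death(d)$p_value < 0.05
  }
  expect_gte(mean(rejections), 0.9)
})

test_that("interaction preconditions reject incomplete designs", {
  co <- simulate_cohorts(n_per_arm = 50, seed = 2)
  incomplete <- dplyr::filter(co, !(genotype == "mutant" & exposure == "exposed"))
  expect_error(cox_interaction(incomplete), class = "deathcue_design_error")
  expect_error(anova_interaction_age_at_death(incomplete), class = "deathcue_design_error")
})

test_that("proportional-hazards diagnostic returns a term table", {
  co <- simulate_cohorts(n_per_arm = 100, beta_exposure = 0.4, seed = 31)
  tab <- check_proportional_hazards(co)
  expect_true("GLOBAL" %in% tab$term)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})
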