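# Randomization inference on trial-level preference indices.
#
# The observed statistic for two groups is a chooser-weighted Welch-style t:
# the difference of weighted mean PIs over the square root of the summed
# variances of the two weighted means. For three or more groups it is a
# chooser-weighted F ratio (between-group over within-group mean square).
# The null is built by permuting trial-level PIs, with their chooser weights
# attached, across group labels; when block labels are present, permutation
# is restricted to within-block exchanges.

wt_two_group_stat <- function(x, w, in_a) {
  xa <- x[in_a]; wa <- w[in_a]
  xb <- x[!in_a]; wb <- w[!in_a]
  ma <- sum(wa * xa) / sum(wa)
  mb <- sum(wb * xb) / sum(wb)
  va <- sum(wa^2 * (xa - ma)^2) / sum(wa)^2
  vb <- sum(wb^2 * (xb - mb)^2) / sum(wb)^2
  d <- ma - mb
  se <- sqrt(va + vb)
  if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / se
  }
}

wt_anova_stat <- function(x, w, g) {
  # g: integer group index 1..G
  ng <- tabulate(g)
  wg <- as.numeric(rowsum(w, g))
  mg <- as.numeric(rowsum(w * x, g)) / wg
  grand <- sum(w * x) / sum(w)
  between <- sum(wg * (mg - grand)^2) / (length(ng) - 1)
  within <- sum(w * (x - mg[g])^2) / (length(x) - length(ng))
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else {
    between / within
  }
}

# Shuffle a label vector, independently within blocks when given.
permute_labels <- function(labels, block) {
  if (is.null(block)) {
    return(sample(labels))
  }
  out <- labels
  for (idx in split(seq_along(labels), block)) {
    out[idx] <- labels[idx][sample.int(length(idx))]
  }
  out
}

count_extreme <- function(null, obs, sidedness) {
  tol <- if (is.finite(obs)) 1e-10 * max(1, abs(obs)) else 0
  switch(sidedness,
    two_sided = sum(abs(null) >= abs(obs) - tol),
    one_sided_greater = sum(null >= obs - tol),
    one_sided_less = sum(null <= obs + tol)
  )
}

new_randomization_result <- function(statistic, kind, p_value, null_sample,
                                     n_permutations, sidedness, exhaustive,
                                     groups, n_trials, weighted) {
  structure(
    list(
      statistic = statistic,
      statistic_kind = kind,
      p_value = p_value,
      null_sample = null_sample,
      n_permutations = n_permutations,
      sidedness = sidedness,
      exhaustive = exhaustive,
      groups = groups,
      n_trials = n_trials,
      weighted = weighted
    ),
    class = "pi_randomization"
  )
}

#' Two-group randomization test on preference indices
#'
#' Compares the chooser-weighted mean preference index between two treatment
#' groups by randomization: trial-level PIs (with their chooser weights
#' attached) are permuted across group labels, a weighted Welch-style t
#' statistic is recomputed for each permutation, and the p-value is the
#' fraction of null statistics equal to or more extreme than the observed
#' one. Monte-Carlo p-values use the add-one smoothing `(b + 1) / (m + 1)`,
#' so they are never exactly zero; when the number of distinct label
#' assignments is at most `n_permutations` (and no blocks are present), the
#' full assignment set is enumerated instead and the exact unsmoothed
#' fraction is reported. With block labels, permutation is restricted to
#' within-block exchanges; every block must contain trials from both
#' groups.
#'
#' @param trials Tibble of trials (`treatment`, `n_exposed_arm`,
#'   `n_control_arm`, optional `block`, `flies_loaded`).
#' @param groups Length-2 character vector naming the treatments to
#'   compare; defaults to the two treatments present.
#' @param n_permutations Number of Monte-Carlo permutations.
#' @param sidedness `"two_sided"` (default), `"one_sided_greater"`
#'   (evidence that the first group's mean PI exceeds the second's), or
#'   `"one_sided_less"`.
#' @param weighted Weight trials by chooser counts (default) or treat all
#'   trials equally.
#' @param exact `"auto"` (enumerate when feasible), `"never"`, or
#'   `"always"` (error if blocks are present or enumeration is infeasible).
#' @param seed Optional integer seed for the Monte-Carlo null.
#' @return A `pi_randomization` object; see [tidy()] and [autoplot()]
#'   methods.
#' @examples
#' trials <- dplyr::bind_rows(
#'   simulate_choice_trials(6, p_exposed_arm = 0.25, treatment = "exposed", seed = 1),
#'   simulate_choice_trials(6, p_exposed_arm = 0.5, treatment = "unexposed", seed = 2)
#' )
#' pi_randomization_test(trials, n_permutations = 999, seed = 3)
#' @export
pi_randomization_test <- function(trials,
                                  groups = NULL,
                                  n_permutations = 100000,
                                  sidedness = c("two_sided", "one_sided_greater", "one_sided_less"),
                                  weighted = TRUE,
                                  exact = c("auto", "never", "always"),
                                  seed = NULL) {
  sidedness <- rlang::arg_match(sidedness)
  exact <- rlang::arg_match(exact)
  n_permutations <- check_count(n_permutations, "n_permutations")
  trials <- prepare_trials(trials)

  if (is.null(groups)) {
    groups <- unique(trials$treatment)
    if (length(groups) != 2) {
      stop_deathcue(
        sprintf(
          "found %d treatment groups; pass `groups` to pick two, or use pi_randomization_anova() for multi-group comparisons.",
          length(groups)
        ),
        "bad_param"
      )
    }
  }
  if (length(groups) != 2 || !all(groups %in% trials$treatment)) {
    stop_deathcue("`groups` must name two treatments present in `trials`.", "bad_param")
  }
  trials <- trials[trials$treatment %in% groups, , drop = FALSE]
  n_by_group <- table(factor(trials$treatment, levels = groups))
  if (any(n_by_group < 2)) {
    stop_deathcue("each group needs at least 2 trials with choosing flies.", "insufficient_data")
  }

  block <- trials$block
  has_blocks <- any(!is.na(block))
  if (has_blocks) {
    if (anyNA(block)) {
      stop_deathcue("`block` must be set for all trials or none.", "block_error")
    }
    bad <- names(which(tapply(trials$treatment, block, function(tr) {
      !all(groups %in% tr)
    })))
    if (length(bad) > 0) {
      stop_deathcue(
        sprintf("block(s) without both groups: %s.", paste(bad, collapse = ", ")),
        "block_error"
      )
    }
  } else {
    block <- NULL
  }

  x <- trials$pi
  w <- if (weighted) trials$choosers else rep(1, nrow(trials))
  in_a <- trials$treatment == groups[1]
  obs <- wt_two_group_stat(x, w, in_a)

  n <- length(x)
  n_a <- sum(in_a)
  n_assignments <- choose(n, n_a)
  use_exact <- switch(exact,
    never = FALSE,
    always = TRUE,
    auto = !has_blocks && n_assignments <= n_permutations
  )
  if (use_exact && has_blocks) {
    stop_deathcue("exact enumeration is not available with blocks; use Monte Carlo.", "bad_param")
  }
  if (use_exact && n_assignments > 5e6) {
    stop_deathcue("too many assignments to enumerate; use exact = \"never\".", "bad_param")
  }

  if (use_exact) {
    assignments <- combn(n, n_a)
    null_sample <- apply(assignments, 2L, function(idx) {
      wt_two_group_stat(x, w, seq_len(n) %in% idx)
    })
    b <- count_extreme(null_sample, obs, sidedness)
    p <- b / length(null_sample) # observed assignment is one of them: p > 0
    result_perms <- length(null_sample)
  } else {
    local_seed(seed)
    null_sample <- vapply(seq_len(n_permutations), function(i) {
      wt_two_group_stat(x, w, permute_labels(in_a, block))
    }, numeric(1))
    b <- count_extreme(null_sample, obs, sidedness)
    p <- (1 + b) / (1 + n_permutations)
    result_perms <- n_permutations
  }

  new_randomization_result(
    statistic = obs, kind = "t_like", p_value = p, null_sample = null_sample,
    n_permutations = result_perms, sidedness = sidedness,
    exhaustive = use_exact, groups = groups,
    n_trials = as.integer(n_by_group), weighted = weighted
  )
}

#' Multi-group randomization ANOVA on preference indices
#'
#' Randomization analogue of a one-way ANOVA on trial-level preference
#' indices for three or more treatment groups: the observed statistic is
#' the chooser-weighted between-group mean square over the within-group
#' mean square, the null is built by permuting PIs (with weights attached)
#' across all group labels, and the upper-tail p-value uses add-one
#' smoothing.
#'
#' @inheritParams pi_randomization_test
#' @return A `pi_randomization` object with `statistic_kind = "F_like"`.
#' @examples
#' trials <- dplyr::bind_rows(lapply(1:3, function(i) {
#'   simulate_choice_trials(4, treatment = paste0("g", i), seed = i)
#' }))
#' pi_randomization_anova(trials, n_permutations = 999, seed = 9)
#' @export
pi_randomization_anova <- function(trials,
                                   n_permutations = 100000,
                                   weighted = TRUE,
                                   seed = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations")
  trials <- prepare_trials(trials)
  groups <- unique(trials$treatment)
  if (length(groups) < 3) {
    stop_deathcue(
      "fewer than 3 groups; use pi_randomization_test() for a two-group comparison.",
      "bad_param"
    )
  }
  n_by_group <- table(factor(trials$treatment, levels = groups))
  if (any(n_by_group < 2)) {
    stop_deathcue("each group needs at least 2 trials with choosing flies.", "insufficient_data")
  }

  block <- trials$block
  has_blocks <- any(!is.na(block))
  if (has_blocks && anyNA(block)) {
    stop_deathcue("`block` must be set for all trials or none.", "block_error")
  }
  if (!has_blocks) block <- NULL

  x <- trials$pi
  w <- if (weighted) trials$choosers else rep(1, nrow(trials))
  g <- as.integer(factor(trials$treatment, levels = groups))
  obs <- wt_anova_stat(x, w, g)

  local_seed(seed)
  null_sample <- vapply(seq_len(n_permutations), function(i) {
    wt_anova_stat(x, w, permute_labels(g, block))
  }, numeric(1))
  b <- count_extreme(null_sample, obs, "one_sided_greater")
  p <- (1 + b) / (1 + n_permutations)

  new_randomization_result(
    statistic = obs, kind = "F_like", p_value = p, null_sample = null_sample,
    n_permutations = n_permutations, sidedness = "one_sided_greater",
    exhaustive = FALSE, groups = groups,
    n_trials = as.integer(n_by_group), weighted = weighted
  )
}

#' @export
print.pi_randomization <- function(x, ...) {
  cat(sprintf(
    "Randomization %s test (%s)\n",
    if (x$statistic_kind == "t_like") "t" else "F",
    paste(x$groups, collapse = " vs ")
  ))
  cat(sprintf(
    "  observed %s = %.4f, p = %.4g (%s, %s%d permutations)\n",
    if (x$statistic_kind == "t_like") "t" else "F",
    x$statistic, x$p_value, x$sidedness,
    if (x$exhaustive) "exhaustive: " else "", x$n_permutations
  ))
  invisible(x)
}

#' @rdname pi_randomization_test
#' @param x,object A `pi_randomization` object.
#' @param ... Unused.
#' @export
tidy.pi_randomization <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    statistic_kind = x$statistic_kind,
    p.value = x$p_value,
    sidedness = x$sidedness,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive,
    groups = paste(x$groups, collapse = " vs "),
    weighted = x$weighted
  )
}

#' @rdname pi_randomization_test
#' @export
glance.pi_randomization <- function(x, ...) tidy(x)
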