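# Group-separation Z score on principal component projections and its
# permutation calibration.

#' Between/within-group separation Z score
#'
#' For sample projections on one principal component, measures how strongly
#' a grouping factor separates the samples:
#' `Z = between / within`, with
#' `between = sum_k n_k * (Mean_total - Mean_k)^2` over the `N` groups and
#' `within` the pooled within-group sum of squared deviations (ANOVA-style;
#' set `within = "ms"` to divide by `sum(n_k - 1)`, which rescales Z by a
#' constant and leaves permutation p-values unchanged). Z is invariant
#' under affine transformation of the projections and under relabeling of
#' the groups.
#'
#' @param x Numeric vector of projections (scores) of all samples on one
#'   component.
#' @param groups Group label per sample (at least 2 groups, each with at
#'   least 2 samples).
#' @param within `"ss"` (pooled sum of squares, default) or `"ms"` (mean
#'   square).
#' @return An object of class `z_separation`: `z`, `between`, `within`,
#'   `group_means`, `grand_mean`, `group_sizes`, `n_groups`.
#' @examples
#' z_separation(c(0, 1, 2, 3), c("a", "a", "b", "b"))
#' @export
z_separation <- function(x, groups, within = c("ss", "ms")) {
  within <- rlang::arg_match(within)
  if (length(x) != length(groups)) {
    stop_deathcue("`x` and `groups` must have equal length.", "bad_param")
  }
  g <- factor(groups)
  nk <- table(g)
  if (nlevels(g) < 2 || any(nk < 2)) {
    stop_deathcue("need at least 2 groups with at least 2 samples each.", "insufficient_data")
  }
  mk <- tapply(x, g, mean)
  m_tot <- mean(x)
  between <- sum(nk * (m_tot - mk)^2)
  within_ss <- sum((x - mk[g])^2)
  denom <- if (within == "ss") within_ss else within_ss / sum(nk - 1)
  if (denom == 0) {
    stop_deathcue("within-group variance is zero; separation degenerate.", "degenerate")
  }
  structure(
    list(
      z = between / denom,
      between = between,
      within = denom,
      group_means = as.numeric(mk) |> setNames(levels(g)),
      grand_mean = m_tot,
      group_sizes = as.integer(nk) |> setNames(levels(g)),
      n_groups = nlevels(g)
    ),
    class = "z_separation"
  )
}

#' @export
print.z_separation <- function(x, ...) {
  cat(sprintf("Z separation: %.4f (between %.4f / within %.4f, %d groups)\n",
              x$z, x$between, x$within, x$n_groups))
  invisible(x)
}

# Permutation upper-tail test of the separation Z for every component of a
# score matrix at once.
perm_z_test <- function(scores, g, n_permutations, within = "ss", seed = NULL) {
  tot_ss <- colSums(sweep(scores, 2L, colMeans(scores))^2)
  z_obs <- z_all_components(scores, g, tot_ss, within)
  local_seed(seed)
  null_z <- matrix(NA_real_, n_permutations, ncol(scores))
  for (b in seq_len(n_permutations)) {
    null_z[b, ] <- z_all_components(scores, sample(g), tot_ss, within)
  }
  tol <- 1e-10
  p <- (1 + colSums(null_z >= rep(z_obs * (1 - tol), each = n_permutations))) /
    (1 + n_permutations)
  list(z_observed = as.numeric(z_obs), p_value = as.numeric(p), null_z = null_z)
}

# Z for every component at once (columns of a score matrix), given integer
# group labels. Total SS per component is permutation-invariant, so the
# permutation loop only recomputes group means.
z_all_components <- function(scores, g, tot_ss = NULL, within = "ss") {
  nk <- tabulate(g)
  m_tot <- colMeans(scores)
  if (is.null(tot_ss)) {
    tot_ss <- colSums(sweep(scores, 2L, m_tot)^2)
  }
  mk <- rowsum(scores, g) / nk
  between <- colSums(nk * sweep(mk, 2L, m_tot)^2)
  within_ss <- tot_ss - between
  denom <- if (within == "ss") within_ss else within_ss / sum(nk - 1)
  between / denom
}

#' Permutation test for group-separating principal components
#'
#' Identifies the principal components along which a grouping factor
#' separates samples more than expected by chance. Because PCA of the
#' (unchanged) matrix is identical under any relabeling of samples, the
#' permutation null is built by shuffling the group labels and recomputing
#' the separation Z score of every component from the permuted labels'
#' projections; the per-component upper-tail p-value is
#' `(1 + #(null Z >= observed Z)) / (1 + n_permutations)`.
#'
#' @param m A processed [metab_matrix()] (filtered, logged, imputed,
#'   standardized) or a fitted `metab_pca`.
#' @param grouping `"composite"` (the 4-level genotype x exposure factor,
#'   default), `"exposure"`, or `"genotype"`.
#' @param n_permutations Number of label permutations (study default
#'   10,000).
#' @param within Within-group variance definition, see [z_separation()].
#' @param seed Optional integer seed.
#' @return A tibble of class `pc_separation` with one row per component
#'   (`component`, `z_observed`, `p_value`, `explained_variance`); the
#'   permutation null sample is kept in the `"null_z"` attribute
#'   (permutations x components).
#' @examples
#' m <- simulate_metabolome(n_metabolites = 30, seed = 1) |>
#'   filter_missingness() |> log_transform() |> knn_impute() |> standardize()
#' permutation_pc_test(m, "exposure", n_permutations = 99, seed = 2)
#' @export
permutation_pc_test <- function(m,
                                grouping = c("composite", "exposure", "genotype"),
                                n_permutations = 10000,
                                within = c("ss", "ms"),
                                seed = NULL) {
  grouping <- rlang::arg_match(grouping)
  within <- rlang::arg_match(within)
  n_permutations <- check_count(n_permutations, "n_permutations")
  pca <- if (inherits(m, "metab_pca")) m else run_pca(m)
  samples <- pca$samples
  labels <- switch(grouping,
    composite = paste(samples$genotype, samples$exposure, sep = ":"),
    exposure = as.character(samples$exposure),
    genotype = as.character(samples$genotype)
  )
  if (anyNA(labels) || length(unique(labels)) < 2) {
    stop_deathcue(sprintf("grouping factor '%s' is missing or constant.", grouping), "label_error")
  }
  g <- as.integer(factor(labels))
  scores <- pca$scores
  tot_ss <- colSums(sweep(scores, 2L, colMeans(scores))^2)

  perm <- perm_z_test(scores, g, n_permutations, within, seed)
  null_z <- perm$null_z

  out <- tibble(
    component = colnames(scores),
    z_observed = perm$z_observed,
    p_value = perm$p_value,
    explained_variance = pca$explained_variance
  )
  out <- new_tibble(out, class = "pc_separation")
  attr(out, "null_z") <- null_z
  attr(out, "grouping") <- grouping
  attr(out, "n_permutations") <- n_permutations
  out
}

#' @rdname permutation_pc_test
#' @param x A `pc_separation` table.
#' @param ... Unused.
#' @export
tidy.pc_separation <- function(x, ...) {
  as_tibble(x)
}

#' @rdname permutation_pc_test
#' @param alpha Significance level used to count separating components.
#' @export
glance.pc_separation <- function(x, alpha = 0.05, ...) {
  tibble(
    grouping = attr(x, "grouping"),
    n_components = nrow(x),
    n_significant = sum(x$p_value < alpha),
    n_permutations = attr(x, "n_permutations")
  )
}

#' Rank metabolites by loading on one component
#'
#' Sorts metabolites by the absolute value of their loading on the chosen
#' component, descending, with exact ties broken lexicographically by
#' metabolite name, and returns the first `top_n`.
#'
#' @param pca A `metab_pca` object.
#' @param component Component index (integer) or name (e.g. `"PC10"`).
#' @param top_n Number of metabolites to return (default 10).
#' @return A tibble with `rank`, `metabolite`, `loading`, `abs_loading`.
#' @export
rank_loadings <- function(pca, component, top_n = 10) {
  if (!inherits(pca, "metab_pca")) {
    stop_deathcue("expected a `metab_pca` object.", "bad_param")
  }
  top_n <- check_count(top_n, "top_n")
  if (is.numeric(component)) component <- paste0("PC", as.integer(component))
  if (!component %in% colnames(pca$loadings)) {
    stop_deathcue(sprintf("component '%s' not in the decomposition.", component), "bad_param")
  }
  v <- pca$loadings[, component]
  p <- length(v)
  if (top_n > p) {
    rlang::warn(sprintf("top_n = %d exceeds %d metabolites; returning all.", top_n, p))
    top_n <- p
  }
  ord <- order(-abs(v), names(v))
  idx <- ord[seq_len(top_n)]
  tibble(
    rank = seq_len(top_n),
    metabolite = names(v)[idx],
    loading = as.numeric(v[idx]),
    abs_loading = abs(as.numeric(v[idx]))
  )
}

#' Two-criterion candidate-metabolite screen
#'
#' For each candidate metabolite, tests the exposure effect separately in
#' each genotype with a one-sided Student's t test (equal variances), the
#' direction being chosen from the sign of the control-genotype effect. A
#' candidate is flagged when the exposure effect is significant in the
#' control genotype (`p_control < alpha`) and not in the mutant genotype
#' (`p_mutant >= alpha`) — i.e. when the metabolite responds to exposure in
#' flies that can perceive it but not in the sensory mutant.
#'
#' @param m A [metab_matrix()] with complete values for the candidates
#'   (impute first).
#' @param candidates Character vector of metabolite names (e.g. from
#'   [rank_loadings()]).
#' @param alpha Significance level (default 0.05).
#' @param control_genotype,mutant_genotype Genotype level names.
#' @param exposed_level,unexposed_level Exposure level names.
#' @return A tibble with one row per candidate: `metabolite`, `direction`,
#'   `estimate_control`, `p_control`, `estimate_mutant`, `p_mutant`,
#'   `flagged`.
#' @export
screen_candidates <- function(m,
                              candidates,
                              alpha = 0.05,
                              control_genotype = "control",
                              mutant_genotype = "mutant",
                              exposed_level = "exposed",
                              unexposed_level = "unexposed") {
  check_metab(m)
  check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  missing_mets <- setdiff(candidates, colnames(m$abundance))
  if (length(missing_mets) > 0) {
    stop_deathcue(
      sprintf("candidate(s) not in matrix: %s.", paste(missing_mets, collapse = ", ")),
      "bad_param"
    )
  }
  genotypes <- as.character(m$samples$genotype)
  exposures <- as.character(m$samples$exposure)
  for (gl in c(control_genotype, mutant_genotype)) {
    for (el in c(exposed_level, unexposed_level)) {
      if (sum(genotypes == gl & exposures == el) < 2) {
        stop_deathcue(
          sprintf("fewer than 2 samples for genotype '%s', exposure '%s'.", gl, el),
          "insufficient_data"
        )
      }
    }
  }

  one_genotype <- function(met, genotype, alternative) {
    exp_vals <- metab_cell_values(m, met, genotype, exposed_level)
    unexp_vals <- metab_cell_values(m, met, genotype, unexposed_level)
    if (anyNA(exp_vals) || anyNA(unexp_vals)) {
      stop_deathcue(sprintf("missing values for metabolite '%s'; impute first.", met), "order_error")
    }
    ht <- t.test(exp_vals, unexp_vals, alternative = alternative, var.equal = TRUE)
    list(estimate = mean(exp_vals) - mean(unexp_vals), p = ht$p.value)
  }

  purrr::map_dfr(candidates, function(met) {
    exp_c <- metab_cell_values(m, met, control_genotype, exposed_level)
    unexp_c <- metab_cell_values(m, met, control_genotype, unexposed_level)
    direction <- if (mean(exp_c) >= mean(unexp_c)) "greater" else "less"
    ctrl <- one_genotype(met, control_genotype, direction)
    mut <- one_genotype(met, mutant_genotype, direction)
    tibble(
      metabolite = met,
      direction = direction,
      estimate_control = ctrl$estimate,
      p_control = ctrl$p,
      estimate_mutant = mut$estimate,
      p_mutant = mut$p,
      flagged = ctrl$p < alpha && mut$p >= alpha
    )
  })
}

#' Select the perception-dependent target component
#'
#' Identifies the principal component carrying a perception-dependent
#' exposure effect: one along which exposure significantly separates
#' samples *within the control genotype* but not *within the sensory
#' mutant*. This mirrors the defining observation of a perception effect —
#' present in flies that can see the stimulus, absent in blind mutants —
#' and, unlike the marginal rule of [select_target_pc()], is not defeated
#' by the fact that a shift confined to one design cell separates the
#' exposure and genotype factors equally.
#'
#' @param pca A `metab_pca` fitted on the full processed matrix.
#' @param alpha Significance level for both criteria.
#' @param n_permutations Label permutations per within-genotype test.
#' @param seed Optional integer seed.
#' @param control_genotype,mutant_genotype Genotype level names.
#' @return The selected component name, or `NA` with a warning if none
#'   qualifies; the per-component test table is attached as attribute
#'   `"tests"` (columns `component`, `z_control`, `p_control`, `z_mutant`,
#'   `p_mutant`, `qualifies`).
#' @export
select_perception_pc <- function(pca, alpha = 0.05, n_permutations = 10000,
                                 seed = NULL,
                                 control_genotype = "control",
                                 mutant_genotype = "mutant") {
  if (!inherits(pca, "metab_pca")) {
    stop_deathcue("expected a `metab_pca` object.", "bad_param")
  }
  check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  genotypes <- as.character(pca$samples$genotype)
  test_within <- function(gt, offset) {
    idx <- genotypes == gt
    if (sum(idx) < 4) {
      stop_deathcue(sprintf("genotype '%s' has too few samples.", gt), "label_error")
    }
    labels <- as.character(pca$samples$exposure[idx])
    if (length(unique(labels)) < 2) {
      stop_deathcue(sprintf("exposure is constant within genotype '%s'.", gt), "label_error")
    }
    perm_z_test(pca$scores[idx, , drop = FALSE], as.integer(factor(labels)),
                n_permutations, seed = if (is.null(seed)) NULL else seed + offset)
  }
  ctrl <- test_within(control_genotype, 0L)
  mut <- test_within(mutant_genotype, 1L)
  tests <- tibble(
    component = colnames(pca$scores),
    z_control = ctrl$z_observed,
    p_control = ctrl$p_value,
    z_mutant = mut$z_observed,
    p_mutant = mut$p_value,
    qualifies = ctrl$p_value < alpha & mut$p_value >= alpha
  )
  target <- if (any(tests$qualifies)) {
    hits <- tests[tests$qualifies, ]
    hits$component[order(hits$p_control)][1]
  } else {
    rlang::warn("no component separates exposure in the control genotype only.")
    NA_character_
  }
  structure(target, tests = tests)
}

#' Select the exposure-separating target component (marginal rule)
#'
#' Given per-component permutation tests for the exposure and the genotype
#' factors, returns the component that significantly separates exposure
#' groups but not genotype groups — the signature of a perception-driven
#' metabolome shift rather than a strain difference. Ties are resolved in
#' favour of the smallest exposure p-value, then the lowest component
#' index.
#'
#' @param exposure_test,genotype_test `pc_separation` tables from
#'   [permutation_pc_test()] with `grouping = "exposure"` and
#'   `"genotype"`.
#' @param alpha Significance level.
#' @return The selected component name (e.g. `"PC10"`), or `NA` with a
#'   warning when no component qualifies.
#' @export
select_target_pc <- function(exposure_test, genotype_test, alpha = 0.05) {
  stopifnot(inherits(exposure_test, "pc_separation"), inherits(genotype_test, "pc_separation"))
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(exposure_test), "component", p_exposure = "p_value"),
    dplyr::select(as_tibble(genotype_test), "component", p_genotype = "p_value"),
    by = "component"
  )
  hits <- joined |>
    dplyr::filter(.data$p_exposure < alpha, .data$p_genotype >= alpha) |>
    dplyr::arrange(.data$p_exposure)
  if (nrow(hits) == 0) {
    rlang::warn("no component separates exposure but not genotype at this alpha.")
    return(NA_character_)
  }
  hits$component[1]
}
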