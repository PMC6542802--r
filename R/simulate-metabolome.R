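#' Simulate a targeted head-metabolome matrix with a planted group effect
#'
#' Generates a 2 x 2 (genotype x exposure) targeted-metabolomics experiment
#' on the log scale, then exponentiates to raw abundances. The covariance of
#' the log abundances is built from a random orthonormal basis with a
#' strictly decreasing variance spectrum, so "the direction of variance rank
#' r" is well defined; an exposure effect of `effect_size` (in units of that
#' direction's standard deviation) is added along the basis vector of rank
#' `planted_rank`, for exposed samples of `affected_genotype` only. This
#' makes "which principal component carries the exposure effect" a
#' controllable ground truth for recovery and calibration studies.
#'
#' Missing entries are completely at random at rate `missing_fraction`, with
#' the per-metabolite missing count capped at `floor(missing_cap *
#' n_samples)` so that the default downstream missingness filter (drop when
#' missing in more than 5 of 32 samples) retains every metabolite.
#'
#' @param n_replicates Biological replicates per design cell (4 cells).
#' @param n_metabolites Number of metabolites on the targeted panel.
#' @param missing_fraction Per-cell missingness probability, in [0, 1).
#' @param planted_rank Variance rank of the direction carrying the exposure
#'   effect (1 = largest-variance direction).
#' @param effect_size Separation of exposed vs unexposed group means along
#'   the planted direction, in SD units of that direction's scores.
#' @param affected_genotype Genotype level carrying the effect (the other
#'   genotype, e.g. a blind mutant, is unaffected by construction).
#' @param base_log_mean,base_log_sd Location and approximate per-metabolite
#'   SD of log abundances.
#' @param n_signal Number of above-noise variance components in the
#'   spectrum.
#' @param variance_profile Optional full vector of `n_metabolites` strictly
#'   decreasing variances overriding the built-in spectrum (relative units;
#'   rescaled to unit mean).
#' @param missing_cap Per-metabolite cap on the missing fraction.
#' @param seed Optional integer seed.
#'
#' @return A [metab_matrix()] on the raw scale. The attribute `"planted"`
#'   records the planted direction (unit vector over metabolites), the true
#'   per-sample scores of the log-scale data on it, its variance rank, and
#'   the effect size.
#'
#' @examples
#' m <- simulate_metabolome(seed = 1)
#' dim(m)
#' @export
simulate_metabolome <- function(n_replicates = 8,
                                n_metabolites = 119,
                                missing_fraction = 0.05,
                                planted_rank = 10,
                                effect_size = 3,
                                affected_genotype = "control",
                                base_log_mean = 8,
                                base_log_sd = 0.6,
                                n_signal = 15,
                                variance_profile = NULL,
                                missing_cap = 5 / 32,
                                seed = NULL) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  p <- check_count(n_metabolites, "n_metabolites", min = 2L)
  check_prob(missing_fraction, "missing_fraction", open_right = TRUE)
  check_prob(missing_cap, "missing_cap", open_right = TRUE)
  n <- 4L * n_replicates
  planted_rank <- check_count(planted_rank, "planted_rank")
  if (planted_rank > min(n - 1L, p)) {
    stop_deathcue(
      sprintf("`planted_rank` must be <= min(n_samples - 1, n_metabolites) = %d.",
              min(n - 1L, p)),
      "bad_param"
    )
  }
  if (base_log_sd <= 0) stop_deathcue("`base_log_sd` must be positive.", "bad_param")
  local_seed(seed)

  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    genotype = factor(rep(c("control", "mutant"), each = 2L * n_replicates),
                      levels = c("control", "mutant")),
    exposure = factor(rep(rep(c("unexposed", "exposed"), each = n_replicates), 2L),
                      levels = c("unexposed", "exposed"))
  )
  affected_genotype <- as.character(affected_genotype)
  if (!affected_genotype %in% levels(samples$genotype)) {
    stop_deathcue("`affected_genotype` must be \"control\" or \"mutant\".", "bad_param")
  }

  # Strictly decreasing spectrum: n_signal strong components over a gently
  # sloped noise floor, normalized to unit mean so per-metabolite log-SD is
  # approximately base_log_sd.
  n_signal <- min(check_count(n_signal, "n_signal"), p)
  d <- if (is.null(variance_profile)) {
    c(
      seq(3, 2, length.out = n_signal),
      if (p > n_signal) seq(0.1, 0.05, length.out = p - n_signal)
    )
  } else {
    if (length(variance_profile) != p || any(diff(variance_profile) >= 0) ||
        any(variance_profile <= 0)) {
      stop_deathcue(
        "`variance_profile` must be a strictly decreasing positive vector of length n_metabolites.",
        "bad_param"
      )
    }
    variance_profile
  }
  d <- d / mean(d)

  basis <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  scores <- matrix(rnorm(n * p), n, p)
  # Make the realized signal scores exactly centered, orthogonal and of
  # variance d_j, so the basis vectors are exact empirical eigendirections
  # of the generated data and the planted variance rank is the realized
  # rank, not just the population one.
  k <- min(n - 1L, n_signal)
  q_sig <- qr.Q(qr(cbind(1, scores[, seq_len(k), drop = FALSE])))[, -1L, drop = FALSE]
  scores[, seq_len(k)] <- q_sig * sqrt(n - 1)
  scores <- scores %*% diag(sqrt(d), p)
  x_log <- base_log_mean + base_log_sd * (scores %*% t(basis))

  planted_dir <- basis[, planted_rank]
  shift_idx <- samples$genotype == affected_genotype & samples$exposure == "exposed"
  delta <- effect_size * sqrt(d[planted_rank]) * base_log_sd
  x_log[shift_idx, ] <- x_log[shift_idx, ] +
    matrix(delta * planted_dir, sum(shift_idx), p, byrow = TRUE)

  metabolites <- sprintf("met_%03d", seq_len(p))
  colnames(x_log) <- metabolites
  names(planted_dir) <- metabolites
  planted_score <- as.numeric(scale(x_log, center = TRUE, scale = FALSE) %*% planted_dir)

  abundance <- exp(x_log)
  if (missing_fraction > 0) {
    cap <- floor(missing_cap * n)
    for (j in seq_len(p)) {
      n_miss <- min(rbinom(1L, n, missing_fraction), cap)
      if (n_miss > 0) abundance[sample.int(n, n_miss), j] <- NA_real_
    }
  }

  out <- metab_matrix(abundance, samples, scale = "raw")
  attr(out, "planted") <- list(
    rank = planted_rank,
    direction = planted_dir,
    score = planted_score,
    effect_size = effect_size,
    affected_genotype = affected_genotype
  )
  out
}
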