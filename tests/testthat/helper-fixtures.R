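# Shared fixture builders and independent oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Trials tibble from explicit counts.
make_trials <- function(n_exposed, n_control, treatment, block = NA_character_,
                        flies_loaded = 20L) {
  tibble::tibble(
    trial_id = sprintf("t%02d", seq_along(n_exposed)),
    treatment = treatment,
    block = block,
    n_exposed_arm = n_exposed,
    n_control_arm = n_control,
    flies_loaded = flies_loaded
  )
}

# Small metab_matrix from an explicit matrix; default balanced 2x2 labels.
make_metab <- function(values, scale = "log", genotype = NULL, exposure = NULL) {
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  }
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    genotype = genotype %||% rep(c("control", "mutant"), length.out = n),
    exposure = exposure %||% rep(c("unexposed", "exposed"), each = ceiling(n / 2))[seq_len(n)]
  )
  metab_matrix(values, samples, scale = scale)
}

# Independent full-enumeration oracle for the two-group chooser-weighted
# Welch-style t randomization p-value (two-sided). Coded from the
# definition, not via package internals.
oracle_exact_p <- function(pi_a, w_a, pi_b, w_b) {
  x <- c(pi_a, pi_b)
  w <- c(w_a, w_b)
  n_a <- length(pi_a)
  n <- length(x)
  tstat <- function(idx_a) {
    xa <- x[idx_a]; wa <- w[idx_a]
    xb <- x[-idx_a]; wb <- w[-idx_a]
    ma <- sum(wa * xa) / sum(wa)
    mb <- sum(wb * xb) / sum(wb)
    va <- sum(wa^2 * (xa - ma)^2) / sum(wa)^2
    vb <- sum(wb^2 * (xb - mb)^2) / sum(wb)^2
    if (va + vb == 0) {
      if (ma == mb) 0 else sign(ma - mb) * Inf
    } else {
      (ma - mb) / sqrt(va + vb)
    }
  }
  obs <- tstat(seq_len(n_a))
  assignments <- utils::combn(n, n_a)
  vals <- apply(assignments, 2L, tstat)
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# Processed (filtered/logged/imputed/standardized) matrix from the
# generator, silencing the per-stage progress messages.
process_metab <- function(m, k = 10) {
  suppressMessages(
    m |> filter_missingness() |> log_transform() |> knn_impute(k) |> standardize()
  )
}
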