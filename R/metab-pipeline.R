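# Head-metabolome processing pipeline:
# filter_missingness() |> log_transform() |> knn_impute() |> standardize()
# |> run_pca(). Each stage checks the state flags set by the previous one,
# so calling out of order is an error rather than a silent misanalysis.

#' Drop metabolites with too many missing values
#'
#' Removes every metabolite whose missing-value count strictly exceeds
#' `floor(max_missing_fraction * n_samples)`. With the default threshold of
#' 5/32 and 32 samples, a metabolite missing in 6 samples is dropped while
#' one missing in 5 is retained. Column order of retained metabolites is
#' preserved; dropped names are recorded in the object and reported.
#'
#' @param m A [metab_matrix()].
#' @param max_missing_fraction Maximum tolerated missing fraction.
#' @return The filtered `metab_matrix` (flag `filtered` set).
#' @export
filter_missingness <- function(m, max_missing_fraction = 5 / 32) {
  check_metab(m)
  check_prob(max_missing_fraction, "max_missing_fraction", open_right = TRUE)
  n <- nrow(m$abundance)
  if (n == 0 || ncol(m$abundance) == 0) {
    stop_deathcue("empty abundance matrix.", "empty_matrix")
  }
  cap <- floor(max_missing_fraction * n)
  n_missing <- colSums(is.na(m$abundance))
  keep <- n_missing <= cap
  if (!any(keep)) {
    stop_deathcue("all metabolites exceed the missingness threshold.", "empty_matrix")
  }
  dropped <- colnames(m$abundance)[!keep]
  if (length(dropped) > 0) {
    rlang::inform(sprintf(
      "Dropped %d metabolite(s) missing in more than %d of %d samples: %s.",
      length(dropped), cap, n,
      paste(head(dropped, 10), collapse = ", ")
    ))
  }
  m$abundance <- m$abundance[, keep, drop = FALSE]
  if (!is.null(m$modes)) m$modes <- m$modes[keep]
  m$dropped <- c(m$dropped, dropped)
  m$filtered <- TRUE
  m$imputed <- !anyNA(m$abundance)
  m
}

#' Natural-log transform of raw abundances
#'
#' Replaces every observed abundance by its natural logarithm. The matrix
#' must be on the raw scale (re-logging a log-scale matrix is refused) and
#' all observed values must be strictly positive.
#'
#' @param m A [metab_matrix()] on the raw scale.
#' @return The `metab_matrix` on the log scale; missing entries unchanged.
#' @export
log_transform <- function(m) {
  check_metab(m)
  if (m$scale == "log") {
    stop_deathcue("matrix is already on the log scale.", "scale_error")
  }
  bad <- which(!is.na(m$abundance) & m$abundance <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_deathcue(
      sprintf(
        "non-positive abundance at sample %s, metabolite %s; cannot log-transform.",
        rownames(m$abundance)[bad[1, 1]], colnames(m$abundance)[bad[1, 2]]
      ),
      "domain_error"
    )
  }
  m$abundance <- log(m$abundance)
  m$scale <- "log"
  m
}

#' k-nearest-neighbour imputation of missing abundances
#'
#' Fills each missing entry with the mean of the same sample's values for
#' the `k` metabolites nearest to the incomplete one. Distance between two
#' metabolites is the root-mean-square difference of their log abundances
#' over the samples in which both are observed; only metabolites observed
#' in the target sample are eligible neighbours. When fewer than `k`
#' eligible neighbours exist, all available ones are used with a warning.
#' The procedure is deterministic: distance ties are broken by metabolite
#' name.
#'
#' @param m A [metab_matrix()] on the log scale.
#' @param k Number of neighbours (default 10).
#' @return The `metab_matrix` with no missing entries (flag `imputed` set).
#' @export
knn_impute <- function(m, k = 10) {
  check_metab(m)
  k <- check_count(k, "k")
  if (m$scale != "log") {
    stop_deathcue("impute on the log scale: call log_transform() first.", "order_error")
  }
  x <- m$abundance
  if (!anyNA(x)) {
    m$imputed <- TRUE
    return(m)
  }
  if (any(colSums(!is.na(x)) == 0)) {
    stop_deathcue("metabolite(s) with no observed values; filter first.", "empty_matrix")
  }

  obs <- !is.na(x)
  xz <- ifelse(obs, x, 0)
  # Pairwise mean squared difference over jointly observed samples.
  n_joint <- crossprod(obs)
  ss <- crossprod(xz^2, obs) + crossprod(obs, xz^2) - 2 * crossprod(xz)
  d2 <- ss / n_joint
  d2[n_joint == 0] <- Inf
  d <- sqrt(pmax(d2, 0))
  diag(d) <- Inf

  mets <- colnames(x)
  short <- FALSE
  miss_cells <- which(!obs, arr.ind = TRUE)
  for (r in seq_len(nrow(miss_cells))) {
    i <- miss_cells[r, 1]
    j <- miss_cells[r, 2]
    cand <- which(obs[i, ] & is.finite(d[j, ]))
    if (length(cand) == 0) {
      stop_deathcue(
        sprintf("no observed neighbours for sample %s, metabolite %s.",
                rownames(x)[i], mets[j]),
        "empty_matrix"
      )
    }
    if (length(cand) < k) short <- TRUE
    ord <- cand[order(d[j, cand], mets[cand])]
    nb <- ord[seq_len(min(k, length(ord)))]
    x[i, j] <- mean(x[i, nb])
  }
  if (short) {
    rlang::warn(sprintf("fewer than k = %d observed neighbours for some cells; used all available.", k))
  }
  m$abundance <- x
  m$imputed <- TRUE
  m
}

#' Standardize each metabolite to mean 0, variance 1
#'
#' Centers and scales every metabolite column to the standard normal scale
#' (sample variance, n - 1 denominator). Requires a complete (imputed)
#' matrix; a zero-variance metabolite is an error naming the offender.
#'
#' @param m A complete [metab_matrix()].
#' @return The standardized `metab_matrix` (flag `standardized` set).
#' @export
standardize <- function(m) {
  check_metab(m)
  if (anyNA(m$abundance)) {
    stop_deathcue("matrix has missing entries: call knn_impute() first.", "order_error")
  }
  sds <- apply(m$abundance, 2L, sd)
  if (any(sds == 0)) {
    stop_deathcue(
      sprintf("zero-variance metabolite(s): %s.",
              paste(colnames(m$abundance)[sds == 0], collapse = ", ")),
      "zero_variance"
    )
  }
  m$abundance <- scale(m$abundance, center = TRUE, scale = sds)
  attr(m$abundance, "scaled:center") <- NULL
  attr(m$abundance, "scaled:scale") <- NULL
  m$standardized <- TRUE
  m
}

#' Principal component analysis of a processed metabolite matrix
#'
#' Standard covariance PCA of the standardized matrix. Components are
#' ordered by non-increasing explained variance and at most
#' `min(n_samples - 1, n_metabolites)` components are returned. The sign of
#' each loading vector is fixed so that its largest-magnitude entry is
#' positive, making results reproducible across platforms.
#'
#' @param m A standardized [metab_matrix()].
#' @return An object of class `metab_pca` with elements `loadings`
#'   (metabolites x components, orthonormal), `scores` (samples x
#'   components), `explained_variance`, and the sample table.
#' @export
run_pca <- function(m) {
  check_metab(m)
  if (!m$standardized) {
    stop_deathcue("run PCA on a standardized matrix: call standardize() first.", "order_error")
  }
  n <- nrow(m$abundance)
  if (n < 3) {
    stop_deathcue("at least 3 samples are required for PCA.", "insufficient_data")
  }
  r <- min(n - 1L, ncol(m$abundance))
  pr <- prcomp(m$abundance, center = TRUE, scale. = FALSE)
  loadings <- pr$rotation[, seq_len(r), drop = FALSE]
  scores <- pr$x[, seq_len(r), drop = FALSE]
  flip <- apply(loadings, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  structure(
    list(
      loadings = loadings,
      scores = scores,
      explained_variance = pr$sdev[seq_len(r)]^2,
      samples = m$samples
    ),
    class = "metab_pca"
  )
}

#' @export
print.metab_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf(
    "<metab_pca> %d samples, %d components (%d metabolites)\n",
    nrow(x$scores), ncol(x$scores), nrow(x$loadings)
  ))
  cat(sprintf(
    "  variance explained by PC1-PC3: %s\n",
    paste(sprintf("%.1f%%", 100 * ev[seq_len(min(3, length(ev)))] / sum(ev)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a metabolome PCA
#'
#' @param x A `metab_pca` object.
#' @param matrix One of `"scores"` (per-sample projections with factor
#'   labels), `"loadings"`, or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.metab_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- rlang::arg_match(matrix)
  comp_names <- colnames(x$scores)
  switch(matrix,
    scores = dplyr::bind_cols(x$samples, as_tibble(x$scores)) |>
      tidyr::pivot_longer(dplyr::all_of(comp_names),
        names_to = "component", values_to = "score"
      ),
    loadings = as_tibble(x$loadings, rownames = "metabolite") |>
      tidyr::pivot_longer(dplyr::all_of(comp_names),
        names_to = "component", values_to = "loading"
      ),
    eigenvalues = tibble(
      component = comp_names,
      explained_variance = x$explained_variance,
      proportion = x$explained_variance / sum(x$explained_variance)
    )
  )
}

check_metab <- function(m) {
  if (!inherits(m, "metab_matrix")) {
    stop_deathcue("expected a `metab_matrix` object.", "bad_param")
  }
  invisible(m)
}
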