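#' Construct a metabolite abundance matrix
#'
#' Container for a targeted-metabolomics experiment: a samples x metabolites
#' abundance matrix (missing entries as `NA`), per-sample factor labels
#' (genotype and exposure), and processing-state flags that enforce the
#' pipeline order `filter_missingness() |> log_transform() |> knn_impute()
#' |> standardize() |> run_pca()`.
#'
#' @param abundance Numeric matrix, samples in rows, metabolites in columns.
#'   Column names (metabolite identifiers) must be unique; row names are
#'   taken from `samples$sample_id` if absent.
#' @param samples Data frame with one row per sample and columns
#'   `sample_id`, `genotype`, `exposure`.
#' @param scale Either `"raw"` (ion counts) or `"log"`.
#' @param modes Optional character vector (per metabolite) giving the MS
#'   acquisition mode, `"positive"` or `"negative"`.
#'
#' @return An object of class `metab_matrix`.
#' @export
metab_matrix <- function(abundance, samples, scale = c("raw", "log"), modes = NULL) {
  scale <- rlang::arg_match(scale)
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop_deathcue("`abundance` must be a numeric matrix (samples x metabolites).", "bad_param")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "genotype", "exposure")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop_deathcue(
      sprintf("`samples` is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "bad_param"
    )
  }
  if (nrow(samples) != nrow(abundance)) {
    stop_deathcue("`samples` must have one row per abundance-matrix row.", "bad_param")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_deathcue("duplicate sample_id in `samples`.", "bad_param")
  }
  if (is.null(colnames(abundance))) {
    stop_deathcue("`abundance` must have metabolite column names.", "bad_param")
  }
  if (anyDuplicated(colnames(abundance))) {
    stop_deathcue("metabolite names must be unique.", "bad_param")
  }
  if (!is.null(modes)) {
    modes <- as.character(rep_len(modes, ncol(abundance)))
    if (!all(modes %in% c("positive", "negative"))) {
      stop_deathcue("`modes` entries must be \"positive\" or \"negative\".", "bad_param")
    }
    names(modes) <- colnames(abundance)
  }
  rownames(abundance) <- samples$sample_id
  structure(
    list(
      abundance = abundance,
      samples = samples,
      scale = scale,
      filtered = FALSE,
      imputed = !anyNA(abundance),
      standardized = FALSE,
      modes = modes,
      dropped = character(0)
    ),
    class = "metab_matrix"
  )
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf(
    "<metab_matrix> %d samples x %d metabolites [%s scale]\n",
    nrow(x$abundance), ncol(x$abundance), x$scale
  ))
  cat(sprintf(
    "  missing entries: %d (%.1f%%)\n",
    sum(is.na(x$abundance)),
    100 * mean(is.na(x$abundance))
  ))
  stages <- c(
    if (x$filtered) "filtered",
    if (x$imputed) "imputed",
    if (x$standardized) "standardized"
  )
  cat("  stages done:", if (length(stages)) paste(stages, collapse = ", ") else "none", "\n")
  tab <- table(x$samples$genotype, x$samples$exposure)
  cat("  design:", paste(sprintf(
    "%s/%s n=%d", rep(rownames(tab), ncol(tab)),
    rep(colnames(tab), each = nrow(tab)), as.vector(tab)
  ), collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.metab_matrix <- function(x) dim(x$abundance)

#' Long tidy view of a metabolite matrix
#'
#' @param x A [metab_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per sample x metabolite cell (`sample_id`,
#'   `genotype`, `exposure`, `metabolite`, `abundance`, `missing`).
#' @export
as_tibble.metab_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(x$samples, as_tibble(x$abundance)),
    cols = dplyr::all_of(colnames(x$abundance)),
    names_to = "metabolite",
    values_to = "abundance"
  )
  dplyr::mutate(long, missing = is.na(.data$abundance))
}

# Values of one metabolite split by exposure within one genotype.
metab_cell_values <- function(m, metabolite, genotype, exposure) {
  idx <- m$samples$genotype == genotype & m$samples$exposure == exposure
  m$abundance[idx, metabolite]
}
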