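# CSV readers/writers for the three data kinds, the YAML-backed run
# configuration, and the end-to-end pipeline driver.

#' Read T-maze trials from CSV
#'
#' Expected columns: `trial_id`, `treatment`, `n_exposed_arm`,
#' `n_control_arm`; optional `block` and `flies_loaded` (default 20).
#' Malformed rows are reported with their file line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop_deathcue(sprintf("file not found: %s", path), "io_error")
  }
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("trial_id", "treatment", "n_exposed_arm", "n_control_arm")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop_deathcue(
      sprintf("trial CSV is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "io_error"
    )
  }
  if (!"flies_loaded" %in% names(trials)) trials$flies_loaded <- 20L
  if (!"block" %in% names(trials)) trials$block <- NA_character_
  trials$block <- as.character(trials$block)

  # data row i is file line i + 1 (header)
  line <- seq_len(nrow(trials)) + 1L
  bad_count <- function(x) is.na(x) | x < 0 | x != floor(x)
  problems <- c(
    if (any(b <- bad_count(trials$n_exposed_arm))) {
      sprintf("line %d: invalid n_exposed_arm", line[b])
    },
    if (any(b <- bad_count(trials$n_control_arm))) {
      sprintf("line %d: invalid n_control_arm", line[b])
    },
    if (any(b <- !bad_count(trials$n_exposed_arm) & !bad_count(trials$n_control_arm) &
              trials$n_exposed_arm + trials$n_control_arm > trials$flies_loaded)) {
      sprintf("line %d: arm counts exceed flies_loaded", line[b])
    }
  )
  if (length(problems) > 0) {
    stop_deathcue(
      paste0("invalid trial rows:\n", paste(" -", problems, collapse = "\n")),
      "io_error"
    )
  }
  dplyr::select(
    trials, "trial_id", "treatment", "block",
    "n_exposed_arm", "n_control_arm", "flies_loaded"
  )
}

#' Write T-maze trials to CSV
#'
#' @param trials Tibble of trials.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("trial_id", "treatment", "block", "n_exposed_arm", "n_control_arm", "flies_loaded")
  readr::write_csv(dplyr::select(as_tibble(trials), dplyr::any_of(cols)), path)
  invisible(path)
}

#' Read a metabolite abundance matrix from CSV
#'
#' Expected layout: first columns `sample_id`, `genotype`, `exposure`, then
#' one numeric column per metabolite. Empty cells or `NA` mark missing
#' abundances. Duplicate sample or metabolite names, and non-numeric
#' abundance cells, are errors.
#'
#' @param path Path to a CSV file.
#' @param scale `"raw"` (default) or `"log"`.
#' @return A [metab_matrix()].
#' @export
read_metabolite_matrix <- function(path, scale = "raw") {
  if (!file.exists(path)) {
    stop_deathcue(sprintf("file not found: %s", path), "io_error")
  }
  header <- strsplit(readr::read_lines(path, n_max = 1L), ",")[[1]]
  if (anyDuplicated(header)) {
    stop_deathcue(
      sprintf("duplicate column name(s): %s.",
              paste(unique(header[duplicated(header)]), collapse = ", ")),
      "io_error"
    )
  }
  # abundances are read as text and converted with strtod so that values
  # written at full precision round-trip bit-identically
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"),
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("sample_id", "genotype", "exposure")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_deathcue(
      sprintf("matrix CSV is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "io_error"
    )
  }
  if (anyDuplicated(df$sample_id)) {
    stop_deathcue("duplicate sample_id in matrix CSV.", "io_error")
  }
  met_cols <- setdiff(names(df), required)
  if (length(met_cols) == 0) {
    stop_deathcue("no metabolite columns found.", "io_error")
  }
  abundance <- matrix(NA_real_, nrow(df), length(met_cols),
                      dimnames = list(NULL, met_cols))
  for (mc in met_cols) {
    vals <- suppressWarnings(as.numeric(df[[mc]]))
    bad <- which(is.na(vals) & !is.na(df[[mc]]))
    if (length(bad) > 0) {
      stop_deathcue(
        sprintf("non-numeric abundance in column '%s', line %d.", mc, bad[1] + 1L),
        "io_error"
      )
    }
    abundance[, mc] <- vals
  }
  metab_matrix(abundance, df[required], scale = scale)
}

#' Write a metabolite matrix to CSV
#'
#' Inverse of [read_metabolite_matrix()]; missing entries are written as
#' `NA`. Round-trips losslessly (doubles are written with full precision).
#'
#' @param m A [metab_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_matrix <- function(m, path) {
  check_metab(m)
  df <- dplyr::bind_cols(
    dplyr::mutate(m$samples,
      genotype = as.character(.data$genotype),
      exposure = as.character(.data$exposure)
    ),
    as_tibble(m$abundance)
  )
  # 17 significant digits guarantee bit-exact double round-trips
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
  ))
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

#' Read a survival event list from CSV
#'
#' Accepts the per-fly event-list layout (`fly_id`, `exposure`,
#' optional `genotype`, `event_time`, `event_observed`) or the census
#' long format (`vial`, `census_time`, `n_dead`, `n_censored`, plus factor
#' columns), which is expanded to one row per fly via [expand_census()].
#'
#' @param path Path to a CSV file.
#' @return A tibble of per-fly events.
#' @export
read_cohorts <- function(path) {
  if (!file.exists(path)) {
    stop_deathcue(sprintf("file not found: %s", path), "io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("vial", "census_time", "n_dead", "n_censored") %in% names(df))) {
    return(expand_census(df))
  }
  required <- c("fly_id", "exposure", "event_time", "event_observed")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_deathcue(
      sprintf("event CSV is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "io_error"
    )
  }
  if (any(is.na(df$event_time) | df$event_time <= 0)) {
    bad <- which(is.na(df$event_time) | df$event_time <= 0)
    stop_deathcue(
      sprintf("non-positive event_time at line(s) %s.",
              paste(head(bad + 1L, 10), collapse = ", ")),
      "io_error"
    )
  }
  df$event_observed <- as.logical(df$event_observed)
  df
}

#' Expand census counts to per-fly event records
#'
#' Converts the long census format (deaths and censorings counted per vial
#' and census time) into one row per fly.
#'
#' @param census Tibble with columns `vial`, `census_time`, `n_dead`,
#'   `n_censored`, plus any factor columns (e.g. `exposure`, `genotype`)
#'   constant within vial.
#' @return A per-fly event tibble.
#' @export
expand_census <- function(census) {
  census <- as_tibble(census)
  keep <- setdiff(names(census), c("n_dead", "n_censored"))
  dead <- tidyr::uncount(dplyr::select(census, dplyr::all_of(keep), w = "n_dead"), .data$w)
  cens <- tidyr::uncount(dplyr::select(census, dplyr::all_of(keep), w = "n_censored"), .data$w)
  dead$event_observed <- TRUE
  cens$event_observed <- FALSE
  out <- dplyr::bind_rows(dead, cens) |>
    dplyr::rename(event_time = "census_time") |>
    dplyr::arrange(.data$vial, .data$event_time, dplyr::desc(.data$event_observed))
  out$fly_id <- sprintf("fly_%05d", seq_len(nrow(out)))
  dplyr::select(out, "fly_id", dplyr::everything())
}

#' Write a survival event list to CSV
#'
#' @param cohort Per-fly event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohorts <- function(cohort, path) {
  cohort <- dplyr::mutate(
    as_tibble(cohort),
    dplyr::across(dplyr::where(is.factor), as.character),
    dplyr::across(dplyr::where(is.double), ~ sprintf("%.17g", .x))
  )
  readr::write_csv(cohort, path)
  invisible(path)
}
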