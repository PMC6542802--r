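# Run configuration and the end-to-end driver tying the stages together.

#' Run configuration
#'
#' Bundles the tunable parameters of a full analysis run. Defaults follow
#' the study conventions: 100,000 permutations for preference tests,
#' 10,000 label permutations for the PC separation test, a missingness
#' threshold of 5/32, and 10 imputation neighbours. All randomness in
#' [run_full_pipeline()] flows from the single `seed` via deterministic
#' per-stage substreams.
#'
#' @param seed Master seed.
#' @param n_permutations_preference Permutations for the preference tests.
#' @param n_permutations_pca Label permutations for the PC test.
#' @param alpha Significance level used for PC selection and the candidate
#'   screen.
#' @param missingness_threshold Maximum tolerated missing fraction per
#'   metabolite.
#' @param knn_k Imputation neighbours.
#' @param top_n Number of top-loading candidate metabolites to screen.
#' @param paths Named list of optional input/output paths: `trials`,
#'   `matrix`, `events`, `out`. Stages with no input path use the
#'   synthetic-data generators.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       n_permutations_preference = 100000,
                       n_permutations_pca = 10000,
                       alpha = 0.05,
                       missingness_threshold = 5 / 32,
                       knn_k = 10,
                       top_n = 10,
                       paths = list()) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_permutations_preference = check_count(n_permutations_preference, "n_permutations_preference"),
    n_permutations_pca = check_count(n_permutations_pca, "n_permutations_pca"),
    alpha = check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE),
    missingness_threshold = check_prob(missingness_threshold, "missingness_threshold", open_right = TRUE),
    knn_k = check_count(knn_k, "knn_k"),
    top_n = check_count(top_n, "top_n"),
    paths = paths
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unset keys fall back to the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_deathcue(sprintf("config file not found: %s", path), "io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_deathcue(
      sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")),
      "io_error"
    )
  }
  do.call(run_config, raw)
}

#' Run the full death-perception analysis pipeline
#'
#' Executes the three analysis arms end to end — preference randomization
#' test, metabolome PC-separation analysis with candidate screen, and
#' survival comparisons — writes per-stage CSV outputs plus a JSON summary
#' to `out_dir`, and returns the results invisibly. Stages whose input
#' path is not set in `config$paths` run on synthetic data generated under
#' the study design (9 trials per treatment arm; 32 samples x 119
#' metabolites with an exposure effect planted at variance rank 10 in the
#' control genotype; 150 flies per lifespan cell with an
#' exposure x genotype hazard interaction). Identical config and seed give
#' byte-identical summaries.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; defaults to `config$paths$out`.
#' @return Invisibly, a list with elements `preference`, `metabolome`,
#'   `survival`, `summary` (the object written as `summary.json`).
#' @export
run_full_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) {
    stop_deathcue("`config` must be a run_config object.", "bad_param")
  }
  out_dir <- out_dir %||% config$paths$out
  if (is.null(out_dir)) {
    stop_deathcue("no output directory: set `out_dir` or config$paths$out.", "bad_param")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_deathcue(
        sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        "stage_error"
      )
    })
  }
  seed_for <- function(stage) substream_seed(config$seed, stage)

  # -- preference arm ------------------------------------------------------
  trials <- run_stage("trials", {
    if (!is.null(config$paths$trials)) {
      read_trials(config$paths$trials)
    } else {
      dplyr::bind_rows(
        simulate_choice_trials(9, p_exposed_arm = 0.32, treatment = "exposed",
                               seed = seed_for("trials_exposed")),
        simulate_choice_trials(9, p_exposed_arm = 0.5, treatment = "unexposed",
                               seed = seed_for("trials_unexposed"))
      )
    }
  })
  preference <- run_stage("preference", {
    summary_tbl <- summarize_preference(trials)
    test <- pi_randomization_test(
      trials,
      n_permutations = config$n_permutations_preference,
      seed = seed_for("preference_test")
    )
    list(summary = summary_tbl, test = test)
  })

  # -- metabolome arm ------------------------------------------------------
  metabolome <- run_stage("metabolome", {
    m <- if (!is.null(config$paths$matrix)) {
      read_metabolite_matrix(config$paths$matrix)
    } else {
      simulate_metabolome(seed = seed_for("metabolome"))
    }
    processed <- m |>
      filter_missingness(config$missingness_threshold) |>
      log_transform() |>
      knn_impute(config$knn_k) |>
      standardize()
    pca <- run_pca(processed)
    exposure_test <- permutation_pc_test(
      pca, "exposure",
      n_permutations = config$n_permutations_pca,
      seed = seed_for("pc_exposure")
    )
    genotype_test <- permutation_pc_test(
      pca, "genotype",
      n_permutations = config$n_permutations_pca,
      seed = seed_for("pc_genotype")
    )
    target <- select_perception_pc(
      pca, config$alpha,
      n_permutations = config$n_permutations_pca,
      seed = seed_for("pc_within_genotype")
    )
    top <- if (!is.na(target)) rank_loadings(pca, target, config$top_n) else NULL
    screen <- if (!is.null(top)) screen_candidates(processed, top$metabolite, config$alpha) else NULL
    list(
      matrix = processed, pca = pca,
      exposure_test = exposure_test, genotype_test = genotype_test,
      perception_tests = attr(target, "tests"),
      target_pc = as.character(target), top_loadings = top, screen = screen
    )
  })

  # -- survival arm --------------------------------------------------------
  surv <- run_stage("survival", {
    cohort <- if (!is.null(config$paths$events)) {
      read_cohorts(config$paths$events)
    } else {
      simulate_cohorts(
        n_per_arm = 150, beta_exposure = 0.35, beta_interaction = -0.3,
        seed = seed_for("cohorts")
      )
    }
    logrank <- lapply(split(cohort, cohort$genotype), function(d) {
      glance(logrank_test(d, "exposure"))
    })
    cox <- if (length(unique(cohort$genotype)) == 2) cox_interaction(cohort) else NULL
    list(cohort = cohort, logrank = logrank, cox = cox)
  })

  # -- outputs -------------------------------------------------------------
  run_stage("outputs", {
    readr::write_csv(preference$summary |> dplyr::select(!dplyr::where(is.list)),
                     file.path(out_dir, "preference_summary.csv"))
    readr::write_csv(tidy(preference$test), file.path(out_dir, "preference_test.csv"))
    readr::write_csv(as_tibble(metabolome$exposure_test),
                     file.path(out_dir, "pc_separation_exposure.csv"))
    readr::write_csv(as_tibble(metabolome$genotype_test),
                     file.path(out_dir, "pc_separation_genotype.csv"))
    readr::write_csv(metabolome$perception_tests,
                     file.path(out_dir, "pc_perception_tests.csv"))
    if (!is.null(metabolome$top_loadings)) {
      readr::write_csv(metabolome$top_loadings, file.path(out_dir, "top_loadings.csv"))
    }
    if (!is.null(metabolome$screen)) {
      readr::write_csv(metabolome$screen, file.path(out_dir, "candidate_screen.csv"))
    }
    readr::write_csv(
      dplyr::bind_rows(surv$logrank, .id = "genotype"),
      file.path(out_dir, "survival_logrank.csv")
    )
    if (!is.null(surv$cox)) {
      readr::write_csv(as_tibble(surv$cox), file.path(out_dir, "survival_interaction.csv"))
    }
  })

  summary <- list(
    seed = config$seed,
    parameters = list(
      n_permutations_preference = config$n_permutations_preference,
      n_permutations_pca = config$n_permutations_pca,
      alpha = config$alpha,
      missingness_threshold = config$missingness_threshold,
      knn_k = config$knn_k,
      top_n = config$top_n
    ),
    preference = as.list(tidy(preference$test)),
    metabolome = list(
      n_metabolites_retained = ncol(metabolome$matrix$abundance),
      n_perception_pcs = sum(metabolome$perception_tests$qualifies),
      target_pc = metabolome$target_pc,
      top_loadings = if (!is.null(metabolome$top_loadings)) {
        metabolome$top_loadings$metabolite
      },
      flagged_candidates = if (!is.null(metabolome$screen)) {
        metabolome$screen$metabolite[metabolome$screen$flagged]
      }
    ),
    survival = list(
      logrank = lapply(surv$logrank, as.list),
      cox_interaction = if (!is.null(surv$cox)) as.list(surv$cox)
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  invisible(list(
    preference = preference, metabolome = metabolome,
    survival = surv, summary = summary
  ))
}
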