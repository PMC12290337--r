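#' Default end-to-end experiment configurations
#'
#' `exp1_config()` describes a paired-comparison study: a 4 gloss x 4 filter
#' stimulus grid, 4 repetitions per unordered pair (480 trials per observer),
#' 8 simulated observers sharing an additive ground truth in which lighter
#' layers subtract from perceived gloss, and Metelli layers with reflectance
#' `t` in {0, 0.33, 0.66, 1} at transmittance 0.5. `exp2_config()` describes
#' an asymmetric matching study on the 7 x 7 albedo x gloss lattice: 2 albedo
#' x 2 gloss target materials, 2 shapes, 4 layers (`t = 0.5`, `alpha` in
#' {0.2, 0.4, 0.6, 0.8}), three conditions, with per-filter matching biases
#' that are largest for the most contrast-compressing layer.
#'
#' @param n_observers Number of simulated observers.
#' @param repetitions Repetitions per unordered pair (exp 1) or per design
#'   cell and observer (exp 2).
#' @param seed Master seed; every stage derives its own child seed from it.
#' @return A named list understood by [run_experiment1()] /
#'   [run_experiment2()].
#' @export
exp1_config <- function(n_observers = 8, repetitions = 4, seed = 1) {
  list(
    n_gloss = 4, n_filter = 4, repetitions = repetitions,
    n_observers = n_observers,
    truth = list(psi_g = c(0, 1, 2, 3), psi_r = c(0, -0.2, -0.4, -0.6),
                 sigma = 1),
    filters = list(t = c(0, 0.33, 0.66, 1), alpha = rep(0.5, 4)),
    models = c("independent", "additive", "full"),
    family_alpha = 0.05,
    seed = seed
  )
}

#' @rdname exp1_config
#' @export
exp2_config <- function(n_observers = 8, repetitions = 2, seed = 1) {
  list(
    lattice = 7,
    albedo_levels = c(3, 5), gloss_levels = c(3, 5), shapes = 1:2,
    n_observers = n_observers, repetitions = repetitions,
    filters = list(t = rep(0.5, 4), alpha = c(0.2, 0.4, 0.6, 0.8)),
    bias_albedo = c(0.6, 0.3, 0.15, 0.1),
    bias_gloss = c(1.0, 0.7, 0.4, 0.2),
    noise_sd = 0.5,
    image = list(size = 128, albedo = 0.5, gloss = 0.7, n_highlights = 4),
    seed = seed
  )
}

write_manifest <- function(path, config, extra) {
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("glosstrans")),
    config = config,
    config_hash = rlang::hash(config)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the paired-comparison experiment end to end
#'
#' Simulates every observer's trials, fits the three nested observer models,
#' runs both likelihood-ratio tests per observer against the
#' Bonferroni-corrected level, and writes the artifact bundle: per-observer
#' trial CSVs, the pooled proportion matrix, a fit summary, the LR-test
#' table, the aggregated normalized scales, and a manifest recording the
#' configuration hash and seeds. Reruns with the same config are
#' byte-identical.
#'
#' @param config List from [exp1_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`fits`, `lr_table`,
#'   `scales`, `proportions`, `manifest`).
#' @export
run_experiment1 <- function(config = exp1_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- observer_model(config$truth$psi_g, config$truth$psi_r,
                          sigma = config$truth$sigma)
  bonf <- bonferroni_level(config$family_alpha, config$n_observers)

  all_trials <- list(); fits <- list(); lr_rows <- list()
  for (obs in seq_len(config$n_observers)) {
    design <- conjoint_design(config$n_gloss, config$n_filter,
                              config$repetitions,
                              seed = derive_seed(config$seed, obs))
    trials <- simulate_conjoint(design, truth,
                                seed = derive_seed(config$seed, 1000 + obs))
    readr::write_csv(trials, file.path(out_dir, sprintf("trials_observer%02d.csv", obs)))
    all_trials[[obs]] <- trials
    fits[[obs]] <- purrr::map(setNames(config$models, config$models),
                              function(m) mlcm_fit(trials, m))
    tests <- dplyr::bind_rows(
      lr_test(fits[[obs]]$independent, fits[[obs]]$additive),
      lr_test(fits[[obs]]$additive, fits[[obs]]$full)
    )
    lr_rows[[obs]] <- dplyr::mutate(tests, observer = obs, .before = 1)
  }

  pooled <- dplyr::bind_rows(all_trials)
  prop <- proportion_matrix(pooled)
  readr::write_csv(tidy(prop), file.path(out_dir, "proportion_matrix.csv"))

  fit_summary <- purrr::imap(fits, function(fl, obs) {
    dplyr::bind_rows(purrr::map(fl, glance)) |>
      dplyr::mutate(observer = obs, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_csv(fit_summary, file.path(out_dir, "model_fits.csv"))

  lr_table <- dplyr::bind_rows(lr_rows) |>
    dplyr::mutate(bonferroni_level = bonf,
                  significant = .data$p_value < bonf)
  readr::write_csv(lr_table, file.path(out_dir, "lr_tests.csv"))

  scales <- aggregate_scales(purrr::map(fits, "additive"))
  readr::write_csv(scales, file.path(out_dir, "normalized_scales.csv"))

  manifest <- write_manifest(file.path(out_dir, "manifest.json"), config, list(
    n_trials_per_observer = nrow(all_trials[[1]]),
    n_pairs = nrow(all_trials[[1]]) / config$repetitions,
    bonferroni_level = bonf
  ))
  invisible(list(fits = fits, lr_table = lr_table, scales = scales,
                 proportions = prop, manifest = manifest))
}

#' Run the matching experiment end to end
#'
#' Simulates lattice-quantized matches for every observer under the
#' configured per-filter biases, summarizes matching errors, relates the
#' gloss error to the Michelson contrast of a procedurally generated object
#' behind each layer, fits the condition-3 prediction regression, and writes
#' the bundle: matching CSV, error summary, contrast-error table, regression
#' JSON and manifest.
#'
#' @param config List from [exp2_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `trials`, `errors`, `contrast_table`,
#'   `prediction`, `manifest`.
#' @export
run_experiment2 <- function(config = exp2_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_filters <- length(config$filters$t)
  targets <- matching_targets(config$albedo_levels, config$gloss_levels,
                              n_filters = n_filters, shapes = config$shapes,
                              repetitions = config$repetitions)
  trials <- purrr::map(seq_len(config$n_observers), function(obs) {
    simulate_matching(targets, config$bias_albedo, config$bias_gloss,
                      config$noise_sd, seed = derive_seed(config$seed, obs)) |>
      dplyr::mutate(observer = obs, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_csv(trials, file.path(out_dir, "matching_trials.csv"))

  errors <- matching_errors(trials)
  readr::write_csv(errors, file.path(out_dir, "matching_errors.csv"))

  base_img <- glossy_image(config$image$size, config$image$albedo,
                           config$image$gloss, config$image$n_highlights,
                           seed = derive_seed(config$seed, 9001))
  images <- setNames(
    purrr::map(seq_len(n_filters), function(f) {
      apply_filter(base_img, metelli_filter(config$filters$t[f],
                                            config$filters$alpha[f]))
    }),
    as.character(seq_len(n_filters))
  )
  contrast_table <- contrast_error_table(errors, images)
  readr::write_csv(contrast_table, file.path(out_dir, "contrast_errors.csv"))

  prediction <- predict_condition3(errors)
  jsonlite::write_json(
    list(records = prediction$records, regression = prediction$regression),
    file.path(out_dir, "condition3_regression.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  manifest <- write_manifest(file.path(out_dir, "manifest.json"), config, list(
    n_selectable_materials = config$lattice^2,
    n_trials = nrow(trials),
    n_observers = config$n_observers
  ))
  invisible(list(trials = trials, errors = errors,
                 contrast_table = contrast_table, prediction = prediction,
                 manifest = manifest))
}
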