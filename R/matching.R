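#' Matching errors on the 7-step lattice
#'
#' Computes the signed matching error — matched level minus target level, so
#' positive values are overestimations — for every attribute the observer
#' actually adjusted, and summarizes per design cell. In the `albedo_only`
#' condition only the albedo error is reported (gloss was held at its true
#' value), symmetrically for `gloss_only`; `both` yields both attributes.
#'
#' @param trials Matching tibble with matched values filled in (see
#'   [simulate_matching()]).
#' @param by Character vector of grouping columns for the summary; defaults to
#'   the full design cell
#'   `c("condition", "filter_id", "target_albedo", "target_gloss", "target_shape")`.
#' @return A tibble with the grouping columns plus `attribute`, `mean_error`,
#'   `sem`, `n`.
#' @export
matching_errors <- function(trials,
                            by = c("condition", "filter_id", "target_albedo",
                                   "target_gloss", "target_shape")) {
  need <- c("condition", "filter_id", "target_albedo", "target_gloss",
            "matched_albedo", "matched_gloss")
  if (!all(need %in% names(trials)) || anyNA(trials$matched_albedo) ||
      anyNA(trials$matched_gloss))
    abort("`trials` must carry complete matched values.",
          class = "glosstrans_data_validation")
  bad <- (trials$condition == "albedo_only" & trials$matched_gloss != trials$target_gloss) |
    (trials$condition == "gloss_only" & trials$matched_albedo != trials$target_albedo)
  if (any(bad))
    abort("Fixed attribute altered in a single-attribute condition.",
          class = "glosstrans_data_validation")
  by <- intersect(by, names(trials))

  long <- trials |>
    dplyr::mutate(albedo = .data$matched_albedo - .data$target_albedo,
                  gloss = .data$matched_gloss - .data$target_gloss) |>
    tidyr::pivot_longer(c("albedo", "gloss"), names_to = "attribute",
                        values_to = "error") |>
    dplyr::filter(
      (.data$condition == "both") |
        (.data$condition == "albedo_only" & .data$attribute == "albedo") |
        (.data$condition == "gloss_only" & .data$attribute == "gloss")
    )
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "attribute")))) |>
    dplyr::summarise(
      mean_error = mean(.data$error),
      sem = if (dplyr::n() > 1) sd(.data$error) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop"
    )
}

#' Gloss-matching error versus image contrast
#'
#' Joins the per-filter mean gloss-matching error (from the gloss-only
#' condition) with the Michelson contrast of the object seen behind each
#' filter, the diagnostic relating matching overshoot to the contrast
#' compression a layer induces.
#'
#' @param summary Output of [matching_errors()] (any grouping that retains
#'   `filter_id`).
#' @param images Named list mapping filter id (`"1"`, `"2"`, ...) to the
#'   luminance image of the object behind that filter.
#' @param region_mask Optional mask passed to [michelson_contrast()].
#' @return A tibble `filter_id`, `contrast`, `mean_error`, `sem`, sorted by
#'   contrast.
#' @export
contrast_error_table <- function(summary, images, region_mask = NULL) {
  err <- summary |>
    dplyr::filter(.data$condition == "gloss_only", .data$attribute == "gloss") |>
    dplyr::group_by(.data$filter_id) |>
    dplyr::summarise(mean_error = stats::weighted.mean(.data$mean_error, .data$n),
                     sem = sqrt(sum(.data$sem^2 * .data$n^2)) / sum(.data$n),
                     .groups = "drop")
  missing <- setdiff(as.character(err$filter_id), names(images))
  if (length(missing))
    abort(paste0("No image supplied for filter level(s): ",
                 paste(missing, collapse = ", ")),
          class = "glosstrans_join_error")
  err |>
    dplyr::mutate(contrast = purrr::map_dbl(
      as.character(.data$filter_id),
      function(id) michelson_contrast(images[[id]], region_mask)
    )) |>
    dplyr::select("filter_id", "contrast", "mean_error", "sem") |>
    dplyr::arrange(.data$contrast)
}

#' Predict joint matching errors from single-attribute errors
#'
#' Tests whether the error made when matching albedo and gloss simultaneously
#' is predicted by the errors made when matching each attribute alone. Per
#' (target material, filter) cell the predicted deviation is the Euclidean
#' norm of the albedo-only and gloss-only mean errors, and the observed
#' deviation is the Euclidean distance (in lattice steps) from the true
#' material to the mean joint match. Observed deviations are regressed on
#' predicted ones by ordinary least squares; the slope is tested against 1
#' with a one-sample t-test on its standard error (df = n - 2). Exactly
#' additive errors give slope 1 and r = 1.
#'
#' @param summary Output of [matching_errors()]; all three conditions must be
#'   present. Cells are formed by
#'   (`target_albedo`, `target_gloss`, `filter_id`), averaging over any finer
#'   grouping (shapes) weighted by trial counts.
#' @return A list of class `condition3_prediction` with `records` (one row per
#'   cell: predicted and observed distance) and `regression` (slope,
#'   intercept, r, t_vs_1, df, p_value, degenerate flag).
#' @export
predict_condition3 <- function(summary) {
  cell_mean <- function(cond, attr) {
    summary |>
      dplyr::filter(.data$condition == cond, .data$attribute == attr) |>
      dplyr::group_by(.data$target_albedo, .data$target_gloss, .data$filter_id) |>
      dplyr::summarise(err = stats::weighted.mean(.data$mean_error, .data$n),
                       .groups = "drop")
  }
  e1 <- cell_mean("albedo_only", "albedo") |> dplyr::rename(e_albedo1 = "err")
  e2 <- cell_mean("gloss_only", "gloss") |> dplyr::rename(e_gloss2 = "err")
  e3a <- cell_mean("both", "albedo") |> dplyr::rename(e_albedo3 = "err")
  e3g <- cell_mean("both", "gloss") |> dplyr::rename(e_gloss3 = "err")
  records <- purrr::reduce(list(e1, e2, e3a, e3g), dplyr::inner_join,
                           by = c("target_albedo", "target_gloss", "filter_id"))
  if (nrow(records) < 3)
    abort("Fewer than 3 complete (material, filter) cells across the three conditions.",
          class = "glosstrans_insufficient_data")
  records <- records |>
    dplyr::mutate(
      predicted = sqrt(.data$e_albedo1^2 + .data$e_gloss2^2),
      observed = sqrt(.data$e_albedo3^2 + .data$e_gloss3^2)
    )

  degenerate <- sd(records$observed) == 0 || sd(records$predicted) == 0
  if (degenerate) {
    reg <- tibble::tibble(slope = 0, intercept = mean(records$observed), r = 0,
                          t_vs_1 = NA_real_, df = nrow(records) - 2,
                          p_value = NA_real_, degenerate = TRUE)
  } else {
    fit <- lm(observed ~ predicted, data = records)
    slope <- coef(fit)[["predicted"]]
    # perfect fits trip summary.lm's warning; that case is handled explicitly
    s <- suppressWarnings(summary(fit))
    se <- s$coefficients["predicted", "Std. Error"]
    df <- nrow(records) - 2
    # an exact linear relation leaves only floating-point noise in the
    # residuals; the t-statistic is then determined by the slope alone
    perfect <- s$sigma < 1e-10 * sd(records$observed)
    t1 <- if (perfect) {
      if (abs(slope - 1) < 1e-8) 0 else sign(slope - 1) * Inf
    } else {
      (slope - 1) / se
    }
    reg <- tibble::tibble(
      slope = slope, intercept = coef(fit)[["(Intercept)"]],
      r = cor(records$observed, records$predicted),
      t_vs_1 = t1, df = df,
      p_value = 2 * stats::pt(abs(t1), df, lower.tail = FALSE),
      degenerate = FALSE
    )
  }
  structure(list(records = records, regression = reg),
            class = "condition3_prediction")
}

#' @export
print.condition3_prediction <- function(x, ...) {
  r <- x$regression
  cat(sprintf("<condition3_prediction> %d cells\n", nrow(x$records)))
  if (r$degenerate) {
    cat("Degenerate regression (no variance in observed or predicted distances).\n")
  } else {
    cat(sprintf("observed ~ predicted: slope %.3f, r = %.3f, t(%d) vs 1 = %.3f, p = %.3f\n",
                r$slope, r$r, r$df, r$t_vs_1, r$p_value))
  }
  invisible(x)
}

#' @export
tidy.condition3_prediction <- function(x, ...) x$records

#' @export
glance.condition3_prediction <- function(x, ...) x$regression

#' Paired t-test with degenerate-data guard
#'
#' Classic paired t-test on the differences `x - y` (df = n - 1, two-sided).
#' Differences with zero variance make the statistic undefined; such calls
#' return a flagged degenerate result instead of an error or an infinite
#' statistic.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    abort("`x` and `y` must have equal lengths.", class = "glosstrans_data_error")
  if (length(x) < 2)
    abort("Need at least 2 pairs.", class = "glosstrans_data_error")
  d <- x - y
  if (sd(d) == 0) {
    return(tibble::tibble(t = if (mean(d) == 0) 0 else NA_real_,
                          df = length(d) - 1,
                          p_value = if (mean(d) == 0) 1 else NA_real_,
                          mean_difference = mean(d), degenerate = mean(d) != 0))
  }
  ht <- t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_difference = mean(d),
                 degenerate = FALSE)
}
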