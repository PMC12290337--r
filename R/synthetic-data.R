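#' Ground-truth observer for conjoint simulations
#'
#' Bundles the perceptual scales that drive a simulated paired-comparison
#' observer: a gloss scale `psi_g` (one value per specularity level), a filter
#' contribution `psi_r` (one value per transparent layer), an optional
#' interaction matrix `psi_gr`, and the decision-noise standard deviation
#' `sigma`. The first level of each dimension is anchored at 0 (and, when an
#' interaction is present, its first row and column), the identifiability
#' convention under which the fitting routines report their estimates.
#'
#' @param psi_g Numeric vector, `psi_g[1] == 0`.
#' @param psi_r Numeric vector, `psi_r[1] == 0`.
#' @param psi_gr Optional interaction matrix `length(psi_g) x length(psi_r)`
#'   with zero first row and column.
#' @param sigma Positive decision-noise SD.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(psi_g, psi_r, psi_gr = NULL, sigma = 1) {
  if (sigma <= 0) abort("`sigma` must be positive.", class = "glosstrans_invalid_parameter")
  if (psi_g[1] != 0 || psi_r[1] != 0)
    abort("First levels of `psi_g` and `psi_r` must be anchored at 0.",
          class = "glosstrans_invalid_parameter")
  if (!is.null(psi_gr)) {
    if (!is.matrix(psi_gr) || nrow(psi_gr) != length(psi_g) || ncol(psi_gr) != length(psi_r))
      abort("`psi_gr` must be a length(psi_g) x length(psi_r) matrix.",
            class = "glosstrans_invalid_parameter")
    if (any(psi_gr[1, ] != 0) || any(psi_gr[, 1] != 0))
      abort("First row and column of `psi_gr` must be 0.",
            class = "glosstrans_invalid_parameter")
  }
  structure(list(psi_g = psi_g, psi_r = psi_r, psi_gr = psi_gr, sigma = sigma),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> %d gloss x %d filter levels, sigma = %g%s\n",
              length(x$psi_g), length(x$psi_r), x$sigma,
              if (is.null(x$psi_gr)) "" else ", with interaction"))
  invisible(x)
}

# latent value of stimulus (g, f) under an observer's scales
observer_psi <- function(observer, g, f) {
  observer$psi_g[g] + observer$psi_r[f] +
    if (is.null(observer$psi_gr)) 0 else observer$psi_gr[cbind(g, f)]
}

#' Paired-comparison trial design
#'
#' Enumerates every unordered pair of distinct (gloss level, filter level)
#' stimuli on an `n_gloss x n_filter` grid — `choose(n_gloss * n_filter, 2)`
#' pairs, e.g. 120 on a 4 x 4 grid — and replicates each pair `repetitions`
#' times. Left/right position is randomized per trial under the seed; no
#' position-bias term is modelled.
#'
#' @param n_gloss,n_filter Grid dimensions; the grid needs at least 2 stimuli.
#' @param repetitions Replicates per unordered pair (>= 1).
#' @param seed Integer seed for the left/right shuffle.
#' @return A tibble with columns `trial_id`, `gloss_left`, `filter_left`,
#'   `gloss_right`, `filter_right` (responses absent until simulated).
#' @examples
#' nrow(conjoint_design(4, 4, repetitions = 4, seed = 1)) # 480
#' @export
conjoint_design <- function(n_gloss, n_filter, repetitions = 1, seed = 1) {
  if (repetitions < 1) abort("`repetitions` must be >= 1.", class = "glosstrans_invalid_parameter")
  if (n_gloss < 1 || n_filter < 1 || n_gloss * n_filter < 2)
    abort("The grid must contain at least 2 stimuli.", class = "glosstrans_invalid_design")
  stim <- tidyr::expand_grid(gloss = seq_len(n_gloss), filter = seq_len(n_filter))
  s <- nrow(stim)
  pairs <- t(utils::combn(s, 2))
  design <- tibble::tibble(
    a = rep(pairs[, 1], repetitions),
    b = rep(pairs[, 2], repetitions)
  )
  withr::with_seed(as.integer(seed), {
    flip <- runif(nrow(design)) < 0.5
    left <- ifelse(flip, design$b, design$a)
    right <- ifelse(flip, design$a, design$b)
    tibble::tibble(
      trial_id = seq_len(nrow(design)),
      gloss_left = stim$gloss[left], filter_left = stim$filter[left],
      gloss_right = stim$gloss[right], filter_right = stim$filter[right]
    )[sample(nrow(design)), ] |>
      dplyr::mutate(trial_id = dplyr::row_number())
  })
}

#' Simulate binary glossiness judgments
#'
#' For each trial the observer compares the latent values of the two stimuli;
#' the decision variable is their difference plus one draw of Gaussian noise,
#' so "left glossier" occurs with probability `pnorm(delta / sigma)` where
#' `delta` is the deterministic scale difference.
#'
#' @param trials Design tibble from [conjoint_design()].
#' @param observer An [observer_model()] whose scales cover the trial indices.
#' @param seed Integer seed; identical inputs give identical responses.
#' @return `trials` with a `response` column (1 = left judged glossier).
#' @export
simulate_conjoint <- function(trials, observer, seed) {
  stopifnot(inherits(observer, "observer_model"))
  gmax <- max(trials$gloss_left, trials$gloss_right)
  fmax <- max(trials$filter_left, trials$filter_right)
  if (gmax > length(observer$psi_g) || fmax > length(observer$psi_r))
    abort("Trial indices exceed the observer's scale lengths.",
          class = "glosstrans_dimension_mismatch")
  delta <- observer_psi(observer, trials$gloss_left, trials$filter_left) -
    observer_psi(observer, trials$gloss_right, trials$filter_right)
  withr::with_seed(as.integer(seed), {
    dplyr::mutate(trials,
                  response = as.integer(rbinom(length(delta), 1,
                                               pnorm(delta / observer$sigma))))
  })
}

#' Matching-task target lattice
#'
#' Builds the target tibble for an asymmetric matching experiment on a 7-step
#' albedo x gloss lattice: every combination of condition, target material,
#' filter and shape, replicated `repetitions` times. Conditions follow the
#' three-block design: `albedo_only` (gloss held at its true value),
#' `gloss_only` (albedo held), and `both`.
#'
#' @param albedo_levels,gloss_levels Target lattice levels (default 1..7 is
#'   subsampled to the tested materials when supplied).
#' @param n_filters Number of transparent layers.
#' @param shapes Shape ids (default 1:2).
#' @param conditions Character subset of `c("albedo_only","gloss_only","both")`.
#' @param repetitions Replicates per cell.
#' @return A tibble with columns `trial_id`, `condition`, `target_albedo`,
#'   `target_gloss`, `filter_id`, `target_shape`.
#' @export
matching_targets <- function(albedo_levels = c(3, 5), gloss_levels = c(3, 5),
                             n_filters = 4, shapes = 1:2,
                             conditions = c("albedo_only", "gloss_only", "both"),
                             repetitions = 1) {
  stopifnot(all(albedo_levels %in% 1:7), all(gloss_levels %in% 1:7))
  conditions <- match.arg(conditions, several.ok = TRUE)
  tidyr::expand_grid(
    condition = conditions,
    target_albedo = albedo_levels, target_gloss = gloss_levels,
    filter_id = seq_len(n_filters), target_shape = shapes,
    rep = seq_len(repetitions)
  ) |>
    dplyr::select(-"rep") |>
    dplyr::mutate(trial_id = dplyr::row_number(), .before = 1)
}

#' Simulate lattice-quantized matching responses
#'
#' Fills in matched levels for a matching-target tibble: the matched value is
#' the target plus a per-filter bias plus Gaussian noise, rounded
#' half-away-from-zero to the 7-step lattice and clipped to 1..7. In the
#' single-attribute conditions the fixed attribute is copied unchanged, as in
#' the task where it is held at its true value.
#'
#' @param targets Tibble from [matching_targets()].
#' @param bias_albedo,bias_gloss Numeric bias per filter level, in lattice
#'   steps.
#' @param noise_sd Non-negative SD of the matching noise, in lattice steps.
#' @param seed Integer seed.
#' @return `targets` with `matched_albedo` and `matched_gloss` columns.
#' @export
simulate_matching <- function(targets, bias_albedo, bias_gloss,
                              noise_sd = 0.5, seed = 1) {
  n_filters <- max(targets$filter_id)
  if (length(bias_albedo) != n_filters || length(bias_gloss) != n_filters)
    abort("Bias vectors need one entry per filter level.",
          class = "glosstrans_invalid_parameter")
  if (noise_sd < 0)
    abort("`noise_sd` must be non-negative.", class = "glosstrans_invalid_parameter")
  quantize <- function(x) pmin(pmax(round_half_away(x), 1), 7)
  withr::with_seed(as.integer(seed), {
    n <- nrow(targets)
    ma <- quantize(targets$target_albedo + bias_albedo[targets$filter_id] +
                     rnorm(n, 0, noise_sd))
    mg <- quantize(targets$target_gloss + bias_gloss[targets$filter_id] +
                     rnorm(n, 0, noise_sd))
    dplyr::mutate(targets,
      matched_albedo = dplyr::if_else(.data$condition == "gloss_only",
                                      as.numeric(.data$target_albedo), ma),
      matched_gloss = dplyr::if_else(.data$condition == "albedo_only",
                                     as.numeric(.data$target_gloss), mg)
    )
  })
}

#' Simulated difference-scaling trials
#'
#' Draws quadruples `a < b <= c < d` of stimulus indices and simulates the
#' judgment of which pair, (a, b) or (c, d), differs more on the perceptual
#' scale: "(a, b) more different" with probability
#' `pnorm(((psi[b] - psi[a]) - (psi[d] - psi[c])) / sigma)`.
#'
#' @param scale True perceptual values, one per stimulus level.
#' @param n_trials Number of quadruples.
#' @param sigma Judgment-noise SD.
#' @param seed Integer seed.
#' @return A tibble with columns `a`, `b`, `c`, `d`, `response`.
#' @export
simulate_mlds <- function(scale, n_trials, sigma = 0.2, seed = 1) {
  n <- length(scale)
  if (n < 4) abort("Need at least 4 stimulus levels.", class = "glosstrans_invalid_design")
  withr::with_seed(as.integer(seed), {
    quads <- t(replicate(n_trials, sort(sample.int(n, 4))))
    delta <- (scale[quads[, 2]] - scale[quads[, 1]]) -
      (scale[quads[, 4]] - scale[quads[, 3]])
    tibble::tibble(
      a = quads[, 1], b = quads[, 2], c = quads[, 3], d = quads[, 4],
      response = as.integer(rbinom(n_trials, 1, pnorm(delta / sigma)))
    )
  })
}
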