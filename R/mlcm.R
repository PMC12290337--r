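#' Conjoint proportion matrix
#'
#' Tabulates, for every unordered stimulus pair that was presented, the
#' proportion of trials in which the first-indexed stimulus was judged
#' glossier, pooling left and right presentations. Stimuli are indexed
#' gloss-major: stimulus `s = (gloss - 1) * n_filter + filter`.
#'
#' @param trials Responded trial tibble (see [simulate_conjoint()]).
#' @return An object of class `proportion_matrix`: a list with `prop` and
#'   `count` S x S matrices (cells without observations are `NA`) and the grid
#'   dimensions. `tidy()` returns it in long form.
#' @export
proportion_matrix <- function(trials) {
  if (!"response" %in% names(trials) || all(is.na(trials$response)))
    abort("`trials` carries no responses.", class = "glosstrans_empty_data")
  n_gloss <- max(trials$gloss_left, trials$gloss_right)
  n_filter <- max(trials$filter_left, trials$filter_right)
  s_left <- (trials$gloss_left - 1) * n_filter + trials$filter_left
  s_right <- (trials$gloss_right - 1) * n_filter + trials$filter_right
  s <- n_gloss * n_filter
  wins <- matrix(0, s, s); count <- matrix(0, s, s)
  for (i in seq_len(nrow(trials))) {
    a <- s_left[i]; b <- s_right[i]; y <- trials$response[i]
    wins[a, b] <- wins[a, b] + y
    wins[b, a] <- wins[b, a] + (1 - y)
    count[a, b] <- count[a, b] + 1
    count[b, a] <- count[b, a] + 1
  }
  prop <- ifelse(count > 0, wins / count, NA_real_)
  labels <- paste0("g", rep(seq_len(n_gloss), each = n_filter),
                   "f", rep(seq_len(n_filter), n_gloss))
  dimnames(prop) <- dimnames(count) <- list(labels, labels)
  structure(list(prop = prop, count = count,
                 n_gloss = n_gloss, n_filter = n_filter),
            class = "proportion_matrix")
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("<proportion_matrix> %d x %d stimuli (%d gloss x %d filter)\n",
              nrow(x$prop), ncol(x$prop), x$n_gloss, x$n_filter))
  print(round(x$prop, 2))
  invisible(x)
}

#' @export
tidy.proportion_matrix <- function(x, ...) {
  s <- nrow(x$prop)
  grid <- tidyr::expand_grid(row = seq_len(s), col = seq_len(s))
  tibble::tibble(
    row_gloss = (grid$row - 1) %/% x$n_filter + 1,
    row_filter = (grid$row - 1) %% x$n_filter + 1,
    col_gloss = (grid$col - 1) %/% x$n_filter + 1,
    col_filter = (grid$col - 1) %% x$n_filter + 1,
    proportion = x$prop[cbind(grid$row, grid$col)],
    n = x$count[cbind(grid$row, grid$col)]
  ) |> dplyr::filter(.data$n > 0)
}

# ---- design matrices -------------------------------------------------------
# Free parameters (sigma == 1, first level of each dimension anchored at 0):
#   independent: psi_g[2..n_g]
#   additive:    + psi_r[2..n_f]
#   full:        + psi_gr[i, j] for i >= 2, j >= 2
mlcm_param_info <- function(model, n_gloss, n_filter) {
  names <- paste0("g", seq_len(n_gloss)[-1])
  if (model %in% c("additive", "full"))
    names <- c(names, paste0("r", seq_len(n_filter)[-1]))
  if (model == "full")
    names <- c(names, as.vector(outer(seq_len(n_gloss)[-1], seq_len(n_filter)[-1],
                                      function(i, j) paste0("gr", i, ".", j))))
  names
}

mlcm_design_matrix <- function(trials, model, n_gloss, n_filter) {
  par_names <- mlcm_param_info(model, n_gloss, n_filter)
  n <- nrow(trials)
  X <- matrix(0, n, length(par_names), dimnames = list(NULL, par_names))
  add_stim <- function(X, g, f, sgn) {
    keep <- g > 1
    X[cbind(which(keep), match(paste0("g", g[keep]), par_names))] <-
      X[cbind(which(keep), match(paste0("g", g[keep]), par_names))] + sgn
    if (model %in% c("additive", "full")) {
      keep <- f > 1
      X[cbind(which(keep), match(paste0("r", f[keep]), par_names))] <-
        X[cbind(which(keep), match(paste0("r", f[keep]), par_names))] + sgn
    }
    if (model == "full") {
      keep <- g > 1 & f > 1
      X[cbind(which(keep), match(paste0("gr", g[keep], ".", f[keep]), par_names))] <-
        X[cbind(which(keep), match(paste0("gr", g[keep], ".", f[keep]), par_names))] + sgn
    }
    X
  }
  X <- add_stim(X, trials$gloss_left, trials$filter_left, +1)
  add_stim(X, trials$gloss_right, trials$filter_right, -1)
}

# penalized negative log-likelihood of the probit paired-comparison model
mlcm_nll <- function(beta, X, y, ridge = 1e-6) {
  eta <- drop(X %*% beta)
  -sum(y * pnorm(eta, log.p = TRUE) + (1 - y) * pnorm(-eta, log.p = TRUE)) +
    ridge * sum(beta^2)
}

mlcm_nll_grad <- function(beta, X, y, ridge = 1e-6) {
  eta <- drop(X %*% beta)
  # d/d eta of log-likelihood, in log space for tail stability
  w <- y * exp(dnorm(eta, log = TRUE) - pnorm(eta, log.p = TRUE)) -
    (1 - y) * exp(dnorm(eta, log = TRUE) - pnorm(-eta, log.p = TRUE))
  -drop(crossprod(X, w)) + 2 * ridge * beta
}

#' Fit a conjoint-measurement observer model
#'
#' Maximum-likelihood fit of the Thurstonian paired-comparison model for two
#' stimulus dimensions. The probability that the left stimulus is chosen is
#' `pnorm(delta)` where `delta` is the difference of the two stimuli's latent
#' values under one of three nested parameterizations:
#' \describe{
#'   \item{independent}{only the gloss dimension carries scale values;}
#'   \item{additive}{the filter dimension contributes an additive term;}
#'   \item{full}{an interaction term per (gloss, filter) cell is added.}
#' }
#' Identifiability follows the standard conjoint-measurement convention:
#' decision noise is fixed at 1 (scales are in d'-like units) and the first
#' level of each dimension — and the first row and column of the interaction —
#' is anchored at 0, giving `n_g - 1`, `(n_g - 1) + (n_f - 1)` and
#' `n_g * n_f - 1` free parameters respectively.
#'
#' Estimation is penalized maximum likelihood with a tiny ridge
#' (`1e-6 * sum(psi^2)`) so that complete separation (empirical proportions of
#' 0 or 1, common in small designs) yields large-but-finite estimates rather
#' than divergence; such fits are flagged via `separation`. BFGS with an
#' analytic gradient, relative tolerance 1e-8, at most 500 iterations, started
#' from zeros and from one random perturbation (best of the two kept).
#'
#' @param trials Responded trial tibble.
#' @param model `"independent"`, `"additive"` or `"full"`.
#' @param n_gloss,n_filter Grid dimensions; inferred from the trials when
#'   missing. Every level must occur in the data.
#' @return An object of class `mlcm_fit` with the anchored estimates
#'   (`psi_g`, `psi_r`, `psi_gr`), the unpenalized `log_likelihood`,
#'   `n_free_params`, `n_trials` and convergence flags. `tidy()` returns the
#'   scale estimates, `glance()` the fit summary.
#' @examples
#' obs <- observer_model(psi_g = c(0, 1, 2, 3), psi_r = c(0, -0.2, -0.4, -0.6))
#' trials <- simulate_conjoint(conjoint_design(4, 4, 4, seed = 1), obs, seed = 2)
#' fit <- mlcm_fit(trials, "additive")
#' glance(fit)
#' @export
mlcm_fit <- function(trials, model = c("additive", "independent", "full"),
                     n_gloss = NULL, n_filter = NULL) {
  model <- match.arg(model)
  if (!"response" %in% names(trials) || anyNA(trials$response))
    abort("`trials` must carry complete responses.", class = "glosstrans_empty_data")
  n_gloss <- n_gloss %||% max(trials$gloss_left, trials$gloss_right)
  n_filter <- n_filter %||% max(trials$filter_left, trials$filter_right)
  seen_g <- sort(unique(c(trials$gloss_left, trials$gloss_right)))
  seen_f <- sort(unique(c(trials$filter_left, trials$filter_right)))
  if (!identical(seen_g, seq_len(n_gloss)) || !identical(seen_f, seq_len(n_filter)))
    abort("Every gloss and filter level must be observed at least once.",
          class = "glosstrans_under_identified")
  if (n_gloss < 2)
    abort("Trials must span at least two gloss levels.",
          class = "glosstrans_under_identified")

  X <- mlcm_design_matrix(trials, model, n_gloss, n_filter)
  y <- trials$response
  p <- ncol(X)

  run <- function(start) {
    optim(start, mlcm_nll, mlcm_nll_grad, X = X, y = y, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-8))
  }
  fits <- list(run(rep(0, p)))
  fits[[2]] <- withr::with_seed(20240601L, run(rnorm(p, 0, 0.5)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  beta <- setNames(best$par, colnames(X))

  est <- list(psi_g = c(0, beta[paste0("g", seq_len(n_gloss)[-1])]),
              psi_r = rep(0, n_filter), psi_gr = NULL)
  names(est$psi_g) <- NULL
  if (model %in% c("additive", "full")) {
    est$psi_r <- c(0, unname(beta[paste0("r", seq_len(n_filter)[-1])]))
  }
  if (model == "full") {
    gr <- matrix(0, n_gloss, n_filter)
    for (i in seq_len(n_gloss)[-1]) for (j in seq_len(n_filter)[-1])
      gr[i, j] <- beta[paste0("gr", i, ".", j)]
    est$psi_gr <- gr
  }
  ll <- -mlcm_nll(best$par, X, y, ridge = 0)
  structure(list(
    model = model, estimates = est, log_likelihood = ll,
    n_free_params = p, n_trials = nrow(trials),
    n_gloss = n_gloss, n_filter = n_filter,
    converged = best$convergence == 0,
    separation = any(abs(beta) > 8)
  ), class = "mlcm_fit")
}

#' @export
print.mlcm_fit <- function(x, ...) {
  cat(sprintf("<mlcm_fit> %s model, %d trials, logLik %.2f (%d free params)%s\n",
              x$model, x$n_trials, x$log_likelihood, x$n_free_params,
              if (x$separation) " [separation flagged]" else ""))
  cat("psi_g:", format(round(x$estimates$psi_g, 3)), "\n")
  if (x$model != "independent")
    cat("psi_r:", format(round(x$estimates$psi_r, 3)), "\n")
  invisible(x)
}

#' @export
tidy.mlcm_fit <- function(x, ...) {
  out <- dplyr::bind_rows(
    tibble::tibble(dimension = "gloss", level = seq_along(x$estimates$psi_g),
                   estimate = x$estimates$psi_g),
    tibble::tibble(dimension = "filter", level = seq_along(x$estimates$psi_r),
                   estimate = x$estimates$psi_r)
  )
  if (!is.null(x$estimates$psi_gr)) {
    gr <- x$estimates$psi_gr
    out <- dplyr::bind_rows(out, tibble::tibble(
      dimension = "interaction",
      level = seq_along(gr),
      gloss_level = as.vector(row(gr)), filter_level = as.vector(col(gr)),
      estimate = as.vector(gr)
    ))
  }
  out
}

#' @export
glance.mlcm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, log_likelihood = x$log_likelihood,
                 n_free_params = x$n_free_params, n_trials = x$n_trials,
                 converged = x$converged, separation = x$separation)
}

#' Likelihood-ratio test of nested conjoint models
#'
#' The statistic is twice the log-likelihood gain of the richer model; its
#' null distribution is chi-square with as many degrees of freedom as the
#' difference in free parameters (independent < additive < full).
#'
#' @param reduced,full `mlcm_fit` objects on the same trials, `reduced` nested
#'   in `full`.
#' @return A one-row tibble: `reduced_model`, `full_model`, `statistic`, `df`,
#'   `p_value`.
#' @export
lr_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "mlcm_fit"), inherits(full, "mlcm_fit"))
  order <- c(independent = 1, additive = 2, full = 3)
  if (order[reduced$model] >= order[full$model] ||
      reduced$n_trials != full$n_trials)
    abort("Models must be nested fits of the same trials (independent < additive < full).",
          class = "glosstrans_invalid_comparison")
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  df <- full$n_free_params - reduced$n_free_params
  tibble::tibble(
    reduced_model = reduced$model, full_model = full$model,
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Bonferroni-corrected significance level
#'
#' @param family_alpha Familywise error rate in (0, 1].
#' @param m Number of comparisons (>= 1).
#' @return `family_alpha / m`, e.g. 0.00625 for 8 observers at 0.05.
#' @export
bonferroni_level <- function(family_alpha, m) {
  if (m < 1) abort("`m` must be at least 1.", class = "glosstrans_invalid_parameter")
  if (family_alpha <= 0 || family_alpha > 1)
    abort("`family_alpha` must lie in (0, 1].", class = "glosstrans_invalid_parameter")
  family_alpha / m
}

#' Normalize and aggregate scale estimates across observers
#'
#' Each observer's scale estimates are divided by that observer's maximum
#' estimate over both dimensions (so the relative contribution of the
#' unattended dimension is comparable across observers), then averaged per
#' level; the spread is the standard error of the mean across observers.
#' Observers whose maximum estimate is not positive cannot be normalized and
#' are excluded with a warning.
#'
#' @param fits List of `mlcm_fit` objects sharing grid dimensions and model.
#' @return A tibble with columns `dimension`, `level`, `mean`, `sem`,
#'   `n_observers`.
#' @export
aggregate_scales <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "mlcm_fit")))
  dims <- unique(lapply(fits, function(f) c(f$n_gloss, f$n_filter, f$model)))
  if (length(dims) != 1)
    abort("All fits must share grid dimensions and model.",
          class = "glosstrans_invalid_comparison")
  per_obs <- purrr::imap(fits, function(f, i) {
    mx <- max(f$estimates$psi_g, f$estimates$psi_r)
    if (mx <= 0) {
      warn(sprintf("Observer %d has no positive estimate; excluded from aggregation.", i))
      return(NULL)
    }
    tidy(f) |>
      dplyr::filter(.data$dimension %in% c("gloss", "filter")) |>
      dplyr::mutate(observer = i, normalized = .data$estimate / mx)
  }) |> purrr::compact()
  if (length(per_obs) == 0)
    abort("No observer could be normalized.", class = "glosstrans_empty_data")
  dplyr::bind_rows(per_obs) |>
    dplyr::group_by(.data$dimension, .data$level) |>
    dplyr::summarise(
      mean = mean(.data$normalized),
      sem = if (dplyr::n() > 1) sd(.data$normalized) / sqrt(dplyr::n()) else 0,
      n_observers = dplyr::n(), .groups = "drop"
    )
}
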