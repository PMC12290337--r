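#' Maximum-likelihood difference scaling
#'
#' Estimates a perceptual scale from quadruple judgments: on each trial the
#' observer saw stimuli `a < b <= c < d` and reported whether pair (a, b) or
#' pair (c, d) differed more. Under the Thurstonian model the probability of
#' choosing (a, b) is
#' `pnorm(((psi[b] - psi[a]) - (psi[d] - psi[c])) / sigma)`.
#' The scale is anchored at `psi[1] = 0` and `psi[n] = 1` and the judgment
#' noise `sigma` is estimated (log-parameterized), so interior scale values
#' are expressed as fractions of the full perceptual range. Monotonicity is
#' not enforced; the estimate is reported as fitted.
#'
#' When responses carry no information (choice rates at 0.5 for every
#' quadruple) the likelihood is flat in the interior scale values and the
#' maximum is not unique. A vanishing quadratic tie-break (weight 1e-6)
#' toward the equally spaced scale selects the linear solution in that
#' degenerate case; with informative data its influence is far below the
#' likelihood curvature and the estimate is the MLE.
#'
#' @param trials Tibble with columns `a`, `b`, `c`, `d`, `response`
#'   (1 = pair (a, b) judged more different).
#' @param n_levels Number of stimulus levels; every level must occur in some
#'   trial.
#' @return A list of class `mlds_fit` with `scale` (length `n_levels`),
#'   `sigma`, `log_likelihood`, `converged`, `n_trials`.
#' @examples
#' trials <- simulate_mlds(scale = (0:6 / 6)^2, n_trials = 500, seed = 1)
#' fit_mlds(trials, n_levels = 7)$scale
#' @export
fit_mlds <- function(trials, n_levels) {
  need <- c("a", "b", "c", "d", "response")
  stopifnot(all(need %in% names(trials)))
  if (!all(trials$a < trials$b, trials$b <= trials$c, trials$c < trials$d))
    abort("Quadruples must satisfy a < b <= c < d.", class = "glosstrans_invalid_design")
  seen <- sort(unique(unlist(trials[c("a", "b", "c", "d")])))
  if (!identical(seen, seq_len(n_levels)))
    abort("Every stimulus level must appear in some trial.",
          class = "glosstrans_under_identified")

  y <- trials$response
  idx <- as.matrix(trials[c("a", "b", "c", "d")])
  # free params: psi[2..n-1] plus log(sigma); psi[1] = 0, psi[n] = 1
  unpack <- function(par) {
    psi <- c(0, par[seq_len(n_levels - 2)], 1)
    list(psi = psi, sigma = exp(par[n_levels - 1]))
  }
  linear <- seq_len(n_levels - 2) / (n_levels - 1)
  nll <- function(par) {
    p <- unpack(par)
    delta <- (p$psi[idx[, 2]] - p$psi[idx[, 1]]) -
      (p$psi[idx[, 4]] - p$psi[idx[, 3]])
    eta <- delta / p$sigma
    -sum(y * pnorm(eta, log.p = TRUE) + (1 - y) * pnorm(-eta, log.p = TRUE)) +
      1e-6 * sum((par[seq_len(n_levels - 2)] - linear)^2)
  }
  start <- c(seq_len(n_levels - 2) / (n_levels - 1), log(0.2))
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  p <- unpack(fit$par)
  structure(list(scale = p$psi, sigma = p$sigma,
                 log_likelihood = -fit$value,
                 converged = fit$convergence == 0,
                 n_trials = nrow(trials)),
            class = "mlds_fit")
}

#' @export
print.mlds_fit <- function(x, ...) {
  cat(sprintf("<mlds_fit> %d levels, %d trials, sigma = %.3f, logLik %.2f\n",
              length(x$scale), x$n_trials, x$sigma, x$log_likelihood))
  cat("scale:", format(round(x$scale, 3)), "\n")
  invisible(x)
}

#' @export
tidy.mlds_fit <- function(x, ...) {
  tibble::tibble(level = seq_along(x$scale), estimate = x$scale)
}

#' @export
glance.mlds_fit <- function(x, ...) {
  tibble::tibble(n_levels = length(x$scale), sigma = x$sigma,
                 log_likelihood = x$log_likelihood,
                 converged = x$converged, n_trials = x$n_trials)
}

#' Perceptually equal stimulus steps
#'
#' Given a fitted perceptual scale sampled on a fine physical grid, returns
#' `n_steps` physical values whose perceptual values are equally spaced — the
#' pre-scaling step that turns a nonlinear physical-to-perceptual mapping into
#' a lattice of perceptually equal increments. The scale is first projected
#' onto monotone nondecreasing values (isotonic regression, to absorb sampling
#' noise), then inverted by linear interpolation.
#'
#' @param physical Increasing physical stimulus values.
#' @param perceptual Fitted perceptual values at `physical`.
#' @param n_steps Number of steps to return (>= 2).
#' @return Numeric vector of `n_steps` physical values, spanning the full
#'   range.
#' @examples
#' x <- seq(0, 1, length.out = 201)
#' equal_step_levels(x, x^2, 7) # close to sqrt((0:6)/6)
#' @export
equal_step_levels <- function(physical, perceptual, n_steps) {
  stopifnot(length(physical) == length(perceptual), n_steps >= 2)
  if (is.unsorted(physical, strictly = TRUE))
    abort("`physical` must be strictly increasing.", class = "glosstrans_invalid_parameter")
  iso <- isoreg(physical, perceptual)$yf
  if (max(iso) - min(iso) <= 0)
    abort("Perceptual scale is flat; no inverse exists.",
          class = "glosstrans_degenerate_scale")
  targets <- seq(min(iso), max(iso), length.out = n_steps)
  # invert the monotone scale; ties from flat stretches resolved to the
  # first physical value attaining each perceptual level
  approx(iso, physical, xout = targets, ties = min)$y
}
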