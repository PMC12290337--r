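# Independent oracles used to validate the fitted likelihoods. These compute
# the log-likelihood directly from the latent-scale definition of the models,
# sharing no code with the package's design-matrix / optimizer path.

# log-likelihood of a responded conjoint trial set under explicit scales
oracle_conjoint_ll <- function(trials, psi_g, psi_r, psi_gr = NULL) {
  val <- function(g, f) {
    psi_g[g] + psi_r[f] + if (is.null(psi_gr)) 0 else psi_gr[cbind(g, f)]
  }
  delta <- val(trials$gloss_left, trials$filter_left) -
    val(trials$gloss_right, trials$filter_right)
  sum(ifelse(trials$response == 1,
             pnorm(delta, log.p = TRUE), pnorm(-delta, log.p = TRUE)))
}

# exhaustive lattice search (coarse pass + local fine pass) for the best
# log-likelihood of a 2 x 2 additive model: free parameters g2, r2
lattice_ll_additive_2x2 <- function(trials, lo = -3, hi = 3,
                                    step = 0.05, fine = 0.005) {
  best <- -Inf; best_par <- c(0, 0)
  for (pass in 1:2) {
    if (pass == 1) {
      g2s <- seq(lo, hi, by = step); r2s <- seq(lo, hi, by = step)
    } else {
      g2s <- seq(best_par[1] - step, best_par[1] + step, by = fine)
      r2s <- seq(best_par[2] - step, best_par[2] + step, by = fine)
    }
    for (g2 in g2s) for (r2 in r2s) {
      ll <- oracle_conjoint_ll(trials, c(0, g2), c(0, r2))
      if (ll > best) { best <- ll; best_par <- c(g2, r2) }
    }
  }
  best
}

# same for the full 2 x 2 model: free parameters g2, r2, gr22
lattice_ll_full_2x2 <- function(trials, lo = -3, hi = 3,
                                step = 0.1, fine = 0.005) {
  best <- -Inf; best_par <- c(0, 0, 0)
  grids <- function(center, width, by) seq(center - width, center + width, by = by)
  for (pass in 1:2) {
    if (pass == 1) {
      g2s <- seq(lo, hi, by = step); r2s <- g2s; grs <- g2s
    } else {
      g2s <- grids(best_par[1], step, fine)
      r2s <- grids(best_par[2], step, fine)
      grs <- grids(best_par[3], step, fine)
    }
    for (g2 in g2s) for (r2 in r2s) for (gr in grs) {
      gr_mat <- matrix(c(0, 0, 0, gr), 2, 2)
      ll <- oracle_conjoint_ll(trials, c(0, g2), c(0, r2), gr_mat)
      if (ll > best) { best <- ll; best_par <- c(g2, r2, gr) }
    }
  }
  best
}

# exhaustive lattice search for a 3-level difference-scaling problem:
# free parameters psi_2 (psi_1 = 0, psi_3 = 1) and sigma
lattice_ll_mlds_3 <- function(trials, step = 0.02, fine = 0.002) {
  ll_at <- function(psi2, sigma) {
    psi <- c(0, psi2, 1)
    delta <- (psi[trials$b] - psi[trials$a]) - (psi[trials$d] - psi[trials$c])
    eta <- delta / sigma
    sum(ifelse(trials$response == 1,
               pnorm(eta, log.p = TRUE), pnorm(-eta, log.p = TRUE)))
  }
  best <- -Inf; best_par <- c(0.5, 0.2)
  for (pass in 1:2) {
    if (pass == 1) {
      p2s <- seq(-0.5, 1.5, by = step); sgs <- seq(0.02, 2, by = step)
    } else {
      p2s <- seq(best_par[1] - step, best_par[1] + step, by = fine)
      sgs <- seq(max(best_par[2] - step, 0.005), best_par[2] + step, by = fine)
    }
    for (p2 in p2s) for (sg in sgs) {
      ll <- ll_at(p2, sg)
      if (ll > best) { best <- ll; best_par <- c(p2, sg) }
    }
  }
  best
}

# default additive ground truth used across recovery tests
default_truth <- function() {
  observer_model(psi_g = c(0, 1, 2, 3), psi_r = c(0, -0.2, -0.4, -0.6), sigma = 1)
}
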