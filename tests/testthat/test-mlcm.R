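test_that("proportion matrices pool presentations and stay complementary", {
  one <- tibble::tibble(trial_id = 1, gloss_left = 2L, filter_left = 1L,
                        gloss_right = 1L, filter_right = 1L, response = 1L)
  pm <- proportion_matrix(one)
  expect_equal(pm$prop["g2f1", "g1f1"], 1)
  expect_equal(pm$prop["g1f1", "g2f1"], 0)

  obs <- default_truth()
  tr <- simulate_conjoint(conjoint_design(3, 2, 10, seed = 1), obs, seed = 2)
  pm <- proportion_matrix(tr)
  pairs <- which(pm$count > 0 & upper.tri(pm$count), arr.ind = TRUE)
  expect_equal(pm$prop[pairs] + pm$prop[pairs[, 2:1]], rep(1, nrow(pairs)))
  expect_equal(tidy(pm)$n |> sum(), 2 * nrow(tr))

  # a noiseless observer with equal filters yields a deterministic pattern
  sharp <- observer_model(c(0, 1, 2), c(0, 0), sigma = 1e-9)
  tr <- simulate_conjoint(conjoint_design(3, 2, 4, seed = 3), sharp, seed = 4)
  td <- tidy(proportion_matrix(tr))
  differ <- td$row_gloss != td$col_gloss
  expect_equal(td$proportion[differ],
               as.numeric(td$row_gloss[differ] > td$col_gloss[differ]))

  expect_error(proportion_matrix(dplyr::select(tr, -response)),
               class = "glosstrans_empty_data")
})

test_that("null data drive every scale estimate to zero", {
  null_obs <- observer_model(c(0, 0, 0), c(0, 0, 0), sigma = 1)
  tr <- simulate_conjoint(conjoint_design(3, 3, 30, seed = 5), null_obs, seed = 6)
  fit <- mlcm_fit(tr, "additive")
  expect_lt(max(abs(c(fit$estimates$psi_g, fit$estimates$psi_r))), 0.15)
  expect_lt(abs(fit$log_likelihood - nrow(tr) * log(0.5)),
            0.02 * abs(nrow(tr) * log(0.5)))
})

test_that("the optimizer attains the exhaustively searched likelihood on toy problems", {
  obs <- observer_model(c(0, 1), c(0, -0.5), sigma = 1)
  for (seed in 1:3) {
    tr <- simulate_conjoint(conjoint_design(2, 2, 4, seed = seed),
                            obs, seed = 100 + seed)
    fit_add <- mlcm_fit(tr, "additive")
    expect_lt(abs(fit_add$log_likelihood - lattice_ll_additive_2x2(tr)), 1e-3)
    fit_full <- mlcm_fit(tr, "full")
    expect_lt(abs(fit_full$log_likelihood - lattice_ll_full_2x2(tr)), 1e-3)
  }
})

test_that("additive scales are recovered from simulated observers", {
  obs <- default_truth()
  tr <- simulate_conjoint(conjoint_design(4, 4, 40, seed = 7), obs, seed = 8)
  fit <- mlcm_fit(tr, "additive")
  est <- c(fit$estimates$psi_g, fit$estimates$psi_r)
  truth <- c(obs$psi_g, obs$psi_r)
  expect_gte(cor(est, truth), 0.98)
  # consistency: error shrinks as repetitions grow
  rmse <- vapply(c(4, 16, 64), function(reps) {
    tr <- simulate_conjoint(conjoint_design(4, 4, reps, seed = reps),
                            obs, seed = 1000 + reps)
    f <- mlcm_fit(tr, "additive")
    sqrt(mean((c(f$estimates$psi_g, f$estimates$psi_r) - truth)^2))
  }, 0)
  expect_lt(rmse[3], rmse[1])
})

test_that("fits agree with an independent probit-regression route", {
  obs <- default_truth()
  tr <- simulate_conjoint(conjoint_design(4, 4, 8, seed = 9), obs, seed = 10)
  fit <- mlcm_fit(tr, "additive")
  X <- glosstrans:::mlcm_design_matrix(tr, "additive", 4, 4)
  g <- glm(tr$response ~ X - 1, family = binomial("probit"))
  expect_lt(max(abs(unname(coef(g)) -
                      c(fit$estimates$psi_g[-1], fit$estimates$psi_r[-1]))),
            1e-3)
  expect_lt(abs(as.numeric(logLik(g)) - fit$log_likelihood), 1e-4)
})

test_that("likelihoods are monotone over the nested model family", {
  obs <- default_truth()
  for (seed in 1:4) {
    tr <- simulate_conjoint(conjoint_design(4, 4, 4, seed = seed),
                            obs, seed = 200 + seed)
    lls <- vapply(c("independent", "additive", "full"),
                  function(m) mlcm_fit(tr, m)$log_likelihood, 0)
    expect_lte(lls["independent"], lls["additive"] + 1e-6)
    expect_lte(lls["additive"], lls["full"] + 1e-6)
  }
})

test_that("shifting one dimension's scales before anchoring changes nothing", {
  base <- observer_model(c(0, 1, 2), c(0, -0.3, -0.6), sigma = 1)
  shifted <- base
  shifted$psi_g <- base$psi_g + 5 # same differences, different origin
  shifted$psi_r <- base$psi_r
  d <- conjoint_design(3, 3, 6, seed = 11)
  expect_identical(simulate_conjoint(d, base, seed = 12)$response,
                   simulate_conjoint(d, shifted, seed = 12)$response)
})

test_that("fitting demands complete responses and full level coverage", {
  obs <- default_truth()
  tr <- simulate_conjoint(conjoint_design(4, 4, 2, seed = 13), obs, seed = 14)
  expect_error(mlcm_fit(dplyr::select(tr, -response), "additive"),
               class = "glosstrans_empty_data")
  expect_error(mlcm_fit(tr[tr$gloss_left != 3 & tr$gloss_right != 3, ], "additive"),
               class = "glosstrans_under_identified")
})

test_that("separation from a deterministic observer is flagged, not fatal", {
  sharp <- observer_model(c(0, 3, 6), c(0, 0), sigma = 1e-9)
  tr <- simulate_conjoint(conjoint_design(3, 2, 4, seed = 15), sharp, seed = 16)
  fit <- mlcm_fit(tr, "independent")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$estimates$psi_g)))
})

test_that("likelihood-ratio tests count parameters and degrees of freedom correctly", {
  obs <- default_truth()
  tr <- simulate_conjoint(conjoint_design(4, 4, 4, seed = 17), obs, seed = 18)
  fi <- mlcm_fit(tr, "independent")
  fa <- mlcm_fit(tr, "additive")
  ff <- mlcm_fit(tr, "full")
  expect_equal(fi$n_free_params, 3)
  expect_equal(fa$n_free_params, 6)
  expect_equal(ff$n_free_params, 15) # n_g * n_f - 1
  expect_equal(lr_test(fi, fa)$df, 3)
  expect_equal(lr_test(fa, ff)$df, 9)

  same <- lr_test(fa, fa |> (\(x) { x$model <- "full"; x })())
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lr_test(fa, fi), class = "glosstrans_invalid_comparison")
})

test_that("Bonferroni correction divides the family level", {
  expect_equal(bonferroni_level(0.05, 8), 0.00625)
  expect_equal(bonferroni_level(0.05, 1), 0.05)
  expect_equal(bonferroni_level(0.01, 4), 0.0025)
  expect_error(bonferroni_level(0.05, 0), class = "glosstrans_invalid_parameter")
})

test_that("normalization and aggregation behave per observer", {
  obs <- default_truth()
  tr <- simulate_conjoint(conjoint_design(4, 4, 8, seed = 19), obs, seed = 20)
  fit <- mlcm_fit(tr, "additive")
  single <- aggregate_scales(list(fit))
  expect_equal(max(single$mean), 1)
  expect_true(all(single$sem == 0))

  # proportional scales normalize to identical curves with zero SEM
  fit2 <- fit
  fit2$estimates$psi_g <- fit$estimates$psi_g * 3
  fit2$estimates$psi_r <- fit$estimates$psi_r * 3
  both <- aggregate_scales(list(fit, fit2))
  expect_true(all(abs(both$sem) < 1e-12))
  expect_equal(both$mean, single$mean)

  # an observer with no positive estimate is excluded with a warning
  neg <- fit
  neg$estimates$psi_g <- -abs(fit$estimates$psi_g)
  neg$estimates$psi_r <- -abs(fit$estimates$psi_r)
  expect_warning(agg <- aggregate_scales(list(fit, neg)), "excluded")
  expect_equal(unique(agg$n_observers), 1)
})

test_that("a cohort of additive observers reproduces the normalized truth", {
  truth <- default_truth()
  fits <- lapply(1:8, function(i) {
    tr <- simulate_conjoint(conjoint_design(4, 4, 4, seed = 300 + i),
                            truth, seed = 400 + i)
    mlcm_fit(tr, "additive")
  })
  agg <- aggregate_scales(fits)
  norm_truth <- c(truth$psi_g, truth$psi_r) / max(truth$psi_g, truth$psi_r)
  ref <- tibble::tibble(
    dimension = rep(c("gloss", "filter"), c(4, 4)),
    level = rep(1:4, 2), truth = norm_truth
  )
  cmp <- dplyr::inner_join(agg, ref, by = c("dimension", "level"))
  expect_true(all(abs(cmp$mean - cmp$truth) <= pmax(2 * cmp$sem, 0.05)))
})
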