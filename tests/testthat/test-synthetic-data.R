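test_that("conjoint designs enumerate every unordered pair the right number of times", {
  for (ng in 2:5) for (nf in 1:5) for (reps in c(1L, 3L)) {
    d <- conjoint_design(ng, nf, reps, seed = ng * 100 + nf * 10 + reps)
    expect_equal(nrow(d), reps * choose(ng * nf, 2))
    key <- function(g, f) (g - 1) * nf + f
    a <- pmin(key(d$gloss_left, d$filter_left), key(d$gloss_right, d$filter_right))
    b <- pmax(key(d$gloss_left, d$filter_left), key(d$gloss_right, d$filter_right))
    expect_true(all(a < b)) # no self-comparisons
    expect_true(all(table(paste(a, b)) == reps))
  }
  expect_equal(nrow(conjoint_design(4, 4, 1, seed = 1)), 120)
  expect_equal(nrow(conjoint_design(4, 4, 4, seed = 1)), 480)
  expect_equal(nrow(conjoint_design(2, 1, 1, seed = 1)), 1)
  expect_error(conjoint_design(1, 1, 1, seed = 1), class = "glosstrans_invalid_design")
})

test_that("response simulation follows the probit closed form", {
  # zero-signal observer: choice rate converges to one half
  null_obs <- observer_model(c(0, 0), c(0), sigma = 1)
  d <- conjoint_design(2, 1, 5000, seed = 1)
  tr <- simulate_conjoint(d, null_obs, seed = 2)
  expect_lt(abs(mean(tr$response) - 0.5), 3 * sqrt(0.25 / nrow(tr)))

  # unit scale difference: rate of choosing the glossier stimulus ~ pnorm(1)
  n <- 1e5
  trials <- tibble::tibble(trial_id = seq_len(n), gloss_left = 2L,
                           filter_left = 1L, gloss_right = 1L, filter_right = 1L)
  obs <- observer_model(c(0, 1), c(0), sigma = 1)
  r <- simulate_conjoint(trials, obs, seed = 3)
  p_hat <- mean(r$response)
  expect_lt(abs(p_hat - pnorm(1)), 3 * sqrt(pnorm(1) * (1 - pnorm(1)) / n))

  # closed-form agreement over a grid of scale differences
  for (delta in c(-2, -0.5, 0.5, 2)) {
    obs_d <- observer_model(c(0, delta), c(0), sigma = 1)
    r <- simulate_conjoint(trials[1:20000, ], obs_d, seed = 40 + delta)
    p <- pnorm(delta)
    expect_lt(abs(mean(r$response) - p), 3 * sqrt(p * (1 - p) / 20000))
  }

  # noiseless limit: strictly increasing gloss always wins
  sharp <- observer_model(c(0, 1, 2, 3), c(0, 0, 0, 0), sigma = 1e-9)
  d4 <- conjoint_design(4, 4, 1, seed = 5)
  r4 <- simulate_conjoint(d4, sharp, seed = 6)
  differ <- r4$gloss_left != r4$gloss_right
  expect_true(all(((r4$response == 1) == (r4$gloss_left > r4$gloss_right))[differ]))
})

test_that("simulation validates observer dimensions and is seed-reproducible", {
  d <- conjoint_design(3, 3, 2, seed = 1)
  small <- observer_model(c(0, 1), c(0), sigma = 1)
  expect_error(simulate_conjoint(d, small, seed = 1),
               class = "glosstrans_dimension_mismatch")
  obs <- default_truth()
  d <- conjoint_design(4, 4, 2, seed = 9)
  expect_identical(simulate_conjoint(d, obs, seed = 7),
                   simulate_conjoint(d, obs, seed = 7))
  expect_identical(conjoint_design(4, 4, 2, seed = 9), d)
})

test_that("matching simulation injects, quantizes and clips as specified", {
  tg <- matching_targets(albedo_levels = c(2, 4, 6), gloss_levels = c(2, 4, 6),
                         n_filters = 2, repetitions = 3)
  # zero bias, zero noise: identity on targets
  m0 <- simulate_matching(tg, c(0, 0), c(0, 0), noise_sd = 0, seed = 1)
  expect_equal(m0$matched_albedo, as.numeric(m0$target_albedo))
  expect_equal(m0$matched_gloss, as.numeric(m0$target_gloss))

  # +1.4 bias at target 7 clips to the lattice ceiling
  tg7 <- matching_targets(albedo_levels = 7, gloss_levels = 7, n_filters = 1,
                          conditions = "both")
  m7 <- simulate_matching(tg7, 1.4, 1.4, noise_sd = 0, seed = 1)
  expect_true(all(m7$matched_albedo == 7) && all(m7$matched_gloss == 7))

  # condition rules: fixed attribute copied unchanged
  mb <- simulate_matching(tg, c(1, 1), c(1, 1), noise_sd = 0.8, seed = 2)
  a_only <- mb[mb$condition == "albedo_only", ]
  expect_equal(a_only$matched_gloss, as.numeric(a_only$target_gloss))
  g_only <- mb[mb$condition == "gloss_only", ]
  expect_equal(g_only$matched_albedo, as.numeric(g_only$target_albedo))

  expect_error(simulate_matching(tg, c(0, 0), c(0, 0), noise_sd = -1, seed = 1),
               class = "glosstrans_invalid_parameter")
  expect_error(simulate_matching(tg, 0, c(0, 0), noise_sd = 0, seed = 1),
               class = "glosstrans_invalid_parameter")
})

test_that("mean simulated matching error reproduces the injected bias", {
  # oracle: exact expectation of the rounded, clipped match at target 4
  bias <- 0.5; noise <- 0.5
  ks <- 1:7
  probs <- vapply(ks, function(k) {
    lo <- if (k == 1) -Inf else k - 0.5
    hi <- if (k == 7) Inf else k + 0.5
    pnorm(hi, 4 + bias, noise) - pnorm(lo, 4 + bias, noise)
  }, 0)
  expected_error <- sum(ks * probs) - 4

  tg <- matching_targets(albedo_levels = 4, gloss_levels = 4, n_filters = 1,
                         shapes = 1, conditions = "both", repetitions = 1e4)
  m <- simulate_matching(tg, bias, bias, noise_sd = noise, seed = 3)
  err <- m$matched_gloss - m$target_gloss
  expect_lt(abs(mean(err) - expected_error), 3 * sd(err) / sqrt(length(err)))
})

test_that("procedural glossy images are deterministic and monotone in gloss", {
  img <- glossy_image(64, albedo = 0.5, gloss = 0.6, seed = 10)
  expect_identical(img, glossy_image(64, albedo = 0.5, gloss = 0.6, seed = 10))
  expect_true(all(img >= 0 & img <= 1))

  # zero gloss leaves only the diffuse shading: identical with or without
  # highlight slots, and adding gloss can only raise the maximum
  base <- glossy_image(64, albedo = 0.9, gloss = 0, n_highlights = 4, seed = 11)
  expect_identical(base, glossy_image(64, albedo = 0.9, gloss = 0,
                                      n_highlights = 0, seed = 11))
  prev <- max(base)
  for (g in c(0.2, 0.5, 0.9)) {
    cur <- max(glossy_image(64, albedo = 0.9, gloss = g, seed = 11))
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_error(glossy_image(8, seed = 1), class = "glosstrans_invalid_parameter")
  expect_error(glossy_image(64, albedo = 2, seed = 1),
               class = "glosstrans_invalid_parameter")
})

test_that("simulated difference-scaling trials satisfy the quadruple protocol", {
  tr <- simulate_mlds((0:6) / 6, 500, sigma = 0.2, seed = 12)
  expect_true(all(tr$a < tr$b, tr$b <= tr$c, tr$c < tr$d))
  expect_identical(tr, simulate_mlds((0:6) / 6, 500, sigma = 0.2, seed = 12))
  # widely separated pair is almost always judged more different
  wide <- tr[tr$b - tr$a >= 4 & tr$d - tr$c == 1, ]
  if (nrow(wide) > 10) expect_gt(mean(wide$response), 0.9)
})
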