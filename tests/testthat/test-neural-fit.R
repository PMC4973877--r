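test_that("exact linear responses are recovered with r2 = 1", {
  rep4 <- suffstat_rep(4)
  tones <- generate_block(0.5, 400, mode = "bernoulli", seed = 42)
  tr <- trace_sequence(rep4, tones, burn_in = 50)
  sel <- tr$trials$tone == "high"
  trials <- data.frame(block_id = "b1",
                       trial_index = tr$trials$trial_index[sel],
                       tone = "high",
                       spike_count = 2.5 * tr$trials$expected_error[sel] + 3)
  fit <- weighted_regression(trials, tr)
  expect_equal(fit$weighted_r2, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 2.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 3, tolerance = 1e-9)
})

test_that("weighted fit with a deterministic representation equals OLS on expected errors", {
  rep6 <- suffstat_rep(6)
  tones <- generate_block(0.3, 400, seed = 7)
  tr <- trace_sequence(rep6, tones, burn_in = 50)
  sel <- which(tr$trials$tone == "low")
  set.seed(99)
  y <- 1.7 * tr$trials$expected_error[sel] + 4 + rnorm(length(sel))
  trials <- data.frame(block_id = "b1",
                       trial_index = tr$trials$trial_index[sel],
                       tone = "low", spike_count = y)
  fit <- weighted_regression(trials, tr)
  ols <- lm(y ~ tr$trials$expected_error[sel])
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-9)
  expect_equal(fit$weighted_r2, summary(ols)$r.squared, tolerance = 1e-9)
})

test_that("weighted fit with a soft representation matches lm on the expanded set", {
  soft <- curve_at_complexity(cached_curve(10), 1.2)
  tones <- generate_block(0.5, 300, seed = 5)
  tr <- trace_sequence(soft, tones, burn_in = 50)
  sel <- which(tr$trials$tone == "high")
  set.seed(1)
  y <- 2 * tr$trials$expected_error[sel] + 3 + rnorm(length(sel), sd = 0.5)
  trials <- data.frame(block_id = "b1",
                       trial_index = tr$trials$trial_index[sel],
                       tone = "high", spike_count = y)
  fit <- weighted_regression(trials, tr)
  ## independent oracle: explicit expansion into (state, trial) rows + lm
  W <- tr$weights[sel, ]
  E <- tr$errors[sel, ]
  df <- data.frame(y = rep(y, ncol(W)), x = as.vector(E), w = as.vector(W))
  df <- df[df$w > 0, ]
  ol <- lm(y ~ x, data = df, weights = w)
  expect_equal(fit$slope, unname(coef(ol)[2]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(coef(ol)[1]), tolerance = 1e-9)
  ybar <- sum(df$w * df$y) / sum(df$w)
  r2_oracle <- 1 - sum(df$w * resid(ol)^2) / sum(df$w * (df$y - ybar)^2)
  expect_equal(fit$weighted_r2, r2_oracle, tolerance = 1e-9)
})

test_that("degenerate fits are handled: constant counts and constant predictor", {
  rep1 <- suffstat_rep(1)
  tones <- generate_block(0.5, 200, seed = 3)
  tr <- trace_sequence(rep1, tones, burn_in = 50)
  sel <- which(tr$trials$tone == "high")
  trials <- data.frame(block_id = "b1",
                       trial_index = tr$trials$trial_index[sel],
                       tone = "high", spike_count = 5)
  expect_warning(fit <- weighted_regression(trials, tr), "zero spike-count")
  expect_equal(fit$weighted_r2, 0)
  ## complexity-0 representation: constant prediction error
  flat <- ib_fixed_point(joint_suffstat(oddball_world(4)), beta = 0)
  trf <- trace_sequence(flat, tones, burn_in = 50)
  trials$spike_count <- rnorm(nrow(trials), 5)
  fitf <- weighted_regression(trials, trf)
  expect_equal(fitf$weighted_r2, 0)
  expect_true(is.na(fitf$slope))
  expect_error(weighted_regression(trials[1:2, ], tr), "at least 3")
})

test_that("grid search agrees with the single-representation fit and finds the generator", {
  bank <- test_bank()
  exp1 <- experiment_suite(bank, "main", 1, seed = 21)[[1]]
  g <- grid_search(exp1$trials, bank, "high")
  expect_equal(dim(g$r2), c(20, 50))
  expect_equal(g$rmax2, max(g$r2))
  expect_true(any(g$good_set))
  expect_equal(g$n_trials, sum(exp1$trials$tone == "high" &
                                 exp1$trials$trial_index >= 50))
  ## cross-check one grid cell against the explicit weighted regression
  N <- 10; j <- 30
  r <- bank$curves[[N]]$points[[j]]
  tr <- trace_sequence(r, exp1$trials$tone, exp1$trials$block_id)
  sel <- exp1$trials$tone == "high" & exp1$trials$trial_index >= 50
  fit <- weighted_regression(exp1$trials[sel, ], tr)
  expect_equal(g$r2[N, j], fit$weighted_r2, tolerance = 1e-9)
  ## the generating member (N* = 10, C* = 2) is in the good set
  gen_idx <- which.min(abs(bank$curves[[10]]$complexity - 2))
  expect_true(g$good_set[10, gen_idx])
  expect_gte(g$argmax$N, 8)
})

test_that("shuffled responses yield near-zero fits", {
  bank <- small_bank()
  exp1 <- experiment_suite(bank, "main", 1, seed = 31,
                           neuron = synthetic_neuron(a = 0, b = 5,
                                                     noise = "poisson",
                                                     N_star = 6,
                                                     complexity_star = 1))[[1]]
  g <- grid_search(exp1$trials, bank, "high")
  expect_gt(g$rmax2, 0)      # max over many fits is positive
  expect_lt(g$rmax2, 0.08)   # but small for sequence-independent counts
})

test_that("permutation test separates linear neurons from null neurons", {
  bank <- small_bank()
  lin <- experiment_suite(bank, "main", 1, seed = 41,
                          neuron = synthetic_neuron(a = 3, b = 4, sigma = 0.5,
                                                    N_star = 6,
                                                    complexity_star = 1.5))[[1]]
  p <- permutation_test(lin$trials, bank, "high", n_perm = 20, seed = 8)
  expect_true(p$significant)
  expect_length(p$permuted, 20)
  expect_true(all(p$permuted < p$observed))
  ## determinism under the same seed
  p2 <- permutation_test(lin$trials, bank, "high", n_perm = 20, seed = 8)
  expect_identical(p$permuted, p2$permuted)
  expect_error(permutation_test(lin$trials, bank, "high", n_perm = 0),
               "n_perm")
})

test_that("response significance is one-sided and rank-based", {
  set.seed(2)
  evoked <- rpois(100, 10)
  spont <- rpois(100, 1)
  expect_true(response_significance(evoked, spont))
  expect_false(response_significance(spont, evoked))
  expect_false(response_significance(rep(3, 50), rep(3, 50)))
  expect_error(response_significance(numeric(0), spont), "nonempty")
})

test_that("population maps aggregate good sets and respect the rmax2 filter", {
  bank <- small_bank()
  exps <- experiment_suite(bank, "main", 3, seed = 51,
                           neuron = synthetic_neuron(a = 2, b = 3, sigma = 1,
                                                     N_star = 6,
                                                     complexity_star = 2))
  grids <- lapply(exps, function(e) grid_search(e$trials, bank, "high"))
  maps <- population_maps(grids, min_rmax2 = 0.1)
  expect_equal(maps$n_cases, 3)
  expect_true(all(maps$fraction >= 0 & maps$fraction <= 1))
  expect_true(all(maps$N_cx >= 0 & maps$N_cx <= 1))
  ## single case: the map is its good set as 0/1
  m1 <- population_maps(grids[1], min_rmax2 = 0.1)
  expect_equal(m1$fraction, grids[[1]]$good_set * 1, ignore_attr = TRUE)
  ## contour extraction
  ct <- map_contour(maps$N_cx, 0.5)
  expect_type(ct, "logical")
  expect_error(population_maps(grids, min_rmax2 = 2), "no case")
})
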