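compatible_only <- function(seed = 3, eggs_mean = 150,
                            replicates = 40) {
  design <- enumerate_diallel("A") |>
    dplyr::filter(cross_class == "compatible_control")
  simulate_diallel(
    diallel_params(
      genotypes = "A", fert = 0.7, base_mort = 0, day_sd = 0,
      replicates_per_cross = replicates, eggs_mean = eggs_mean, seed = seed
    ),
    design = design
  )
}

test_that("an intercept-only fit matches the conjugate beta-binomial oracle", {
  rec <- compatible_only()
  fit <- fit_ci_model(
    rec, ci_model_spec("F", "1", day_intercepts = FALSE),
    chains = quick$chains, iter = quick$iter, warmup = quick$warmup, seed = 1
  )
  resp <- derive_responses(rec)
  s <- sum(resp$f_num)
  f <- sum(resp$f_den) - s
  oracle_mean <- (s + 1) / (s + f + 2) # Beta(1, 1) prior, pooled counts
  p_draws <- plogis(fit$draws[, "(Intercept)"])
  expect_equal(mean(p_draws), oracle_mean, tolerance = 0.01)
  expect_equal(mean(p_draws), 0.7, tolerance = 0.02)
})

test_that("a single 5/10 observation gives a symmetric posterior near 0.5", {
  rec <- toy_records()[2, ]
  rec$adult_females <- 5L
  rec$adult_males <- 0L
  rec$eggs <- 10L
  fit <- fit_ci_model(
    rec, ci_model_spec("F", "1", day_intercepts = FALSE),
    chains = quick$chains, iter = 3000, warmup = 500, seed = 2
  )
  p <- plogis(fit$draws[, "(Intercept)"])
  expect_equal(mean(p), 0.5, tolerance = 0.03)
  expect_equal(unname(quantile(p, 0.5)), 0.5, tolerance = 0.03)
  expect_equal(
    unname(quantile(p, 0.9) - 0.5), unname(0.5 - quantile(p, 0.1)),
    tolerance = 0.03
  )
})

test_that("predictions are the inverse-logit of the linear predictor", {
  rec <- simulate_diallel(diallel_params(genotypes = "A", seed = 6))
  fit <- fit_ci_model(
    rec, ci_model_spec("F", "inf", day_intercepts = FALSE),
    chains = quick$chains, iter = quick$iter, warmup = quick$warmup, seed = 3
  )
  crosses <- tibble::tibble(
    female_genotype = "A", male_genotype = "A",
    male_infected = c(FALSE, TRUE)
  )
  p <- predict_proportion(fit, crosses)
  # reference level: intercept draws only
  expect_equal(unname(p[, 1]), unname(plogis(fit$draws[, "(Intercept)"])))
  # per-draw logit difference equals the infection coefficient
  expect_equal(
    unname(qlogis(p[, 2]) - qlogis(p[, 1])),
    unname(fit$draws[, "infinfected"])
  )
  expect_error(
    predict_proportion(fit, tibble::tibble(
      female_genotype = "Z", male_genotype = "A", male_infected = TRUE
    )),
    "Unknown"
  )
  tidy_p <- predict_proportion(fit, crosses, format = "tidy")
  expect_equal(nrow(tidy_p), 2 * nrow(p))
})

test_that("pointwise log-likelihood equals the binomial log-mass at each draw", {
  rec <- simulate_diallel(diallel_params(genotypes = "A", seed = 6))
  fit <- fit_ci_model(
    rec, ci_model_spec("F", "inf", day_intercepts = TRUE),
    chains = quick$chains, iter = quick$iter, warmup = quick$warmup, seed = 3
  )
  mf <- fit$data$mf
  X <- stats::model.matrix(~inf, mf)
  eta <- fit$draws[, fit$beta_names] %*% t(X) +
    fit$draws[, paste0("day:", levels(fit$data$day))][, as.integer(fit$data$day)]
  i <- c(1L, nrow(X))
  for (obs in i) {
    expect_equal(
      fit$pointwise_loglik[, obs],
      dbinom(fit$data$y[obs], fit$data$n[obs], plogis(eta[, obs]), log = TRUE)
    )
  }
  expect_equal(ncol(fit$pointwise_loglik), length(fit$data$y))
})

test_that("zero-denominator rows are dropped per response only", {
  rec <- toy_records()
  rec$adult_males[1] <- 100L # FM denominator 0 for row 1
  rec$adult_females[1] <- 0L
  fit_fm <- fit_ci_model(
    rec, ci_model_spec("FM", "1", day_intercepts = FALSE),
    chains = 2, iter = 600, warmup = 200, seed = 1
  )
  fit_f <- fit_ci_model(
    rec, ci_model_spec("F", "1", day_intercepts = FALSE),
    chains = 2, iter = 600, warmup = 200, seed = 1
  )
  expect_equal(length(fit_fm$data$y), 1)
  expect_equal(length(fit_f$data$y), 2)
  empty <- rec[1, ]
  empty$eggs <- 0L
  empty$adult_males <- 0L
  expect_error(
    fit_ci_model(empty, ci_model_spec("F", "1", day_intercepts = FALSE)),
    "positive denominator"
  )
})

test_that("the fitted model ranks male CI penetrance correctly", {
  g <- c("A", "B", "C")
  theta <- matrix(rep(c(0.85, 0.45, 0.05), 3), 3, 3,
    dimnames = list(g, g))
  rec <- simulate_diallel(diallel_params(
    genotypes = g, theta = theta, phi = 0.1, day_sd = 0,
    replicates_per_cross = 10, eggs_mean = 80, seed = 19
  ))
  fit <- fit_ci_model(
    rec, ci_model_spec("F", "inf*mgeno*fgeno", day_intercepts = FALSE),
    chains = quick$chains, iter = quick$iter, warmup = quick$warmup, seed = 4
  )
  crosses <- tibble::tibble(
    female_genotype = "A", male_genotype = g, male_infected = TRUE
  )
  f_means <- colMeans(predict_proportion(fit, crosses))
  # stronger CI (higher theta) = fewer females
  expect_equal(order(f_means), order(-theta[, 1]))
})

test_that("day-effect scale estimates track the simulated day variance", {
  fits <- purrr::map(c(0, 1), function(sd_day) {
    rec <- simulate_diallel(diallel_params(
      genotypes = c("A", "B"), day_sd = sd_day, n_days = 12,
      replicates_per_cross = 10, seed = 23
    ))
    fit_ci_model(
      rec, ci_model_spec("F", "inf", day_intercepts = TRUE),
      chains = quick$chains, iter = quick$iter, warmup = quick$warmup,
      seed = 5
    )
  })
  sd_hat <- purrr::map_dbl(fits, ~ median(.x$draws[, "sd_day"]))
  expect_lt(sd_hat[1], sd_hat[2])
  expect_lt(sd_hat[1], 0.3)
  expect_gt(sd_hat[2], 0.4)
})

test_that("posterior intervals cover the generating proportion", {
  covered <- 0L
  for (rep in 1:20) {
    rec <- simulate_diallel(diallel_params(
      genotypes = "A", theta = 0.6, phi = 0.2, fert = 0.7, base_mort = 0,
      day_sd = 0, replicates_per_cross = 6, eggs_mean = 60, seed = 100 + rep
    ))
    fit <- fit_ci_model(
      rec, ci_model_spec("F", "inf", day_intercepts = FALSE),
      chains = 2, iter = 800, warmup = 300, seed = rep
    )
    p_inc <- predict_proportion(fit, tibble::tibble(
      female_genotype = "A", male_genotype = "A", male_infected = TRUE
    ))[, 1]
    truth <- 0.7 * (1 - 0.6)
    q <- quantile(p_inc, c(0.025, 0.975))
    if (q[1] <= truth && truth <= q[2]) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("rank-normalized diagnostics behave on constructed chains", {
  set.seed(99)
  iid <- cbind(x = rnorm(2000))
  d <- diagnose(iid, chain = rep(1:2, each = 1000))
  expect_equal(d$rhat, 1, tolerance = 0.01)
  expect_gt(d$ess_bulk, 1000)
  expect_false(d$flagged)

  apart <- cbind(x = c(rnorm(1000, -5), rnorm(1000, 5)))
  d2 <- diagnose(apart, chain = rep(1:2, each = 1000))
  expect_gt(d2$rhat, 1.5)
  expect_true(d2$flagged)

  flat <- cbind(x = rep(1, 2000))
  d3 <- diagnose(flat, chain = rep(1:2, each = 1000))
  expect_true(is.na(d3$rhat))
  expect_true(d3$flagged)

  one_chain <- diagnose(iid, chain = rep(1L, 2000))
  expect_match(attr(one_chain, "note"), "single chain")
})
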