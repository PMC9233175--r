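test_that("WAIC matches hand-computed values on a 2x2 log-likelihood matrix", {
  # draws in rows: obs1 has logliks log .5 / log .25, obs2 log .5 / log .5
  ll <- cbind(log(c(0.5, 0.25)), log(c(0.5, 0.5)))
  w <- waic(ll)
  lppd <- log(0.375) + log(0.5)
  p_waic <- var(log(c(0.5, 0.25)))
  expect_equal(w$lppd, lppd, tolerance = 1e-12)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-12)
  pw <- c(
    -2 * (log(0.375) - p_waic),
    -2 * (log(0.5) - 0)
  )
  expect_equal(w$se, sqrt(2 * var(pw)), tolerance = 1e-12)
})

test_that("constant log-likelihoods give zero effective parameters", {
  ll <- matrix(rep(c(-1.3, -0.4), each = 3), nrow = 3)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * (-1.3 - 0.4))
  expect_error(waic(ll[1, , drop = FALSE]), "2 posterior draws")
})

test_that("WAIC is invariant to draw and observation permutations", {
  set.seed(5)
  ll <- matrix(log(runif(200, 0.05, 0.9)), nrow = 20)
  w <- waic(ll)
  w_perm <- waic(ll[sample(20), sample(10)])
  expect_equal(w$waic, w_perm$waic)
  expect_equal(w$se, w_perm$se)
})

test_that("finite-population SDs equal hand values on toy coefficient draws", {
  # two-level term with effects {0, c}: centered SD = |c| / sqrt(2)
  draws <- cbind("(Intercept)" = c(0.3, -0.2), "infinfected" = c(1.2, -0.8))
  fit <- fake_ci_fit(draws, ~inf)
  out <- finite_population_sd(fit)
  inf_sd <- dplyr::filter(out$draws, group == "inf")$sd
  expect_equal(inf_sd, abs(c(1.2, -0.8)) / sqrt(2), tolerance = 1e-12)
  # a draw with zero coefficient: all level effects equal, SD = 0
  fit0 <- fake_ci_fit(
    cbind("(Intercept)" = c(0, 0), "infinfected" = c(0, 2)), ~inf
  )
  expect_equal(
    dplyr::filter(finite_population_sd(fit0)$draws, group == "inf")$sd,
    c(0, sqrt(2))
  )
})

test_that("interaction groups span the full level grid with reference zeros", {
  # inf (2 levels) x mgeno (2 levels): interaction grid has 4 cells, one
  # free coefficient; SD over {0, 0, 0, c} with denominator 3
  f <- ~ inf * mgeno
  nm <- colnames(stats::model.matrix(
    f,
    data.frame(
      inf = factor(c("cured", "infected")), mgeno = factor(c("A", "B"))
    )
  ))
  draws <- matrix(c(0, 0, 0, 2), nrow = 1, dimnames = list(NULL, nm))
  out <- finite_population_sd(fake_ci_fit(draws, f))
  expect_equal(
    dplyr::filter(out$draws, group == "inf:mgeno")$sd,
    sd(c(0, 0, 0, 2))
  )
  # day intercepts form their own group
  draws2 <- cbind(draws, "day:d1" = 1, "day:d2" = -1)
  out2 <- finite_population_sd(
    fake_ci_fit(draws2, f, day_levels = c("d1", "d2"))
  )
  expect_equal(dplyr::filter(out2$draws, group == "day")$sd, sqrt(2))
})

test_that("group SDs are invariant to the reference genotype", {
  g <- c("A", "B")
  theta <- matrix(c(0.8, 0.8, 0.2, 0.2), 2, 2, dimnames = list(g, g))
  rec <- simulate_diallel(diallel_params(
    genotypes = g, theta = theta, day_sd = 0, replicates_per_cross = 12,
    eggs_mean = 80, seed = 41
  ))
  relabelled <- rec |>
    dplyr::mutate(
      female_genotype = ifelse(female_genotype == "A", "Z", "B"),
      male_genotype = ifelse(male_genotype == "A", "Z", "B")
    )
  sds <- purrr::map(list(rec, relabelled), function(r) {
    fit <- fit_ci_model(
      r, ci_model_spec("F", "inf*mgeno", day_intercepts = FALSE),
      chains = quick$chains, iter = quick$iter, warmup = quick$warmup,
      seed = 11
    )
    finite_population_sd(fit)$summary
  })
  merged <- dplyr::left_join(sds[[1]], sds[[2]], by = "group")
  expect_lt(max(abs(merged$q50.x - merged$q50.y)), 0.15)
})

test_that("model comparison requires a shared response and sorts by WAIC", {
  rec <- simulate_diallel(diallel_params(genotypes = c("A", "B"), seed = 2))
  specs <- list(
    a = ci_model_spec("F", "inf", day_intercepts = FALSE),
    b = ci_model_spec("MD", "inf", day_intercepts = FALSE)
  )
  expect_error(
    compare_ci_models(rec, specs, chains = 2, iter = 600, warmup = 200),
    "same response"
  )
  dup <- list(
    m1 = ci_model_spec("F", "inf", day_intercepts = FALSE),
    m2 = ci_model_spec("F", "inf", day_intercepts = FALSE)
  )
  cmp <- compare_ci_models(rec, dup,
    chains = 2, iter = 800, warmup = 300, seed = 3
  )
  # identical specs under the same seed give identical fits
  expect_equal(unname(cmp$d_waic), c(0, 0))
  expect_true(all(diff(cmp$waic) >= 0))
})
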