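test_that("simulated broods conserve counts and respect the seed", {
  params <- diallel_params(genotypes = c("A", "B", "C"), seed = 9)
  rec <- simulate_diallel(params)
  expect_true(all(rec$adult_females + rec$adult_males <= rec$eggs))
  expect_identical(rec, simulate_diallel(params))
  other <- simulate_diallel(diallel_params(genotypes = c("A", "B", "C"),
    seed = 10))
  expect_false(identical(rec, other))
  # the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_diallel(params)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("without CI, incompatible and compatible crosses are exchangeable", {
  params <- diallel_params(
    genotypes = c("A", "B"), theta = 0, day_sd = 0,
    replicates_per_cross = 40, eggs_mean = 100, seed = 21
  )
  rec <- derive_responses(simulate_diallel(params))
  by_class <- rec |>
    dplyr::group_by(cross_class) |>
    dplyr::summarise(f = sum(f_num) / sum(f_den))
  expect_equal(diff(by_class$f), 0, tolerance = 0.02)
})

test_that("complete female-mortality CI kills all fertilized eggs", {
  params <- diallel_params(
    genotypes = c("A", "B"), theta = 1, phi = 0, fert = 0.7, base_mort = 0,
    day_sd = 0, replicates_per_cross = 30, eggs_mean = 100, seed = 5
  )
  rec <- derive_responses(simulate_diallel(params))
  inc <- dplyr::filter(rec, cross_class == "incompatible")
  expect_true(all(inc$adult_females == 0))
  # every fertilized egg fails: expected failed fraction = fert
  expect_equal(sum(inc$fm_num) / sum(inc$eggs), 0.7, tolerance = 0.02)
})

test_that("closed-form indexes match the generative expectations", {
  expect_equal(
    unlist(closed_form_indexes(0, 0.5)[, c("ci_corr", "md_corr", "fm_corr")]),
    c(ci_corr = 0, md_corr = 0, fm_corr = 0)
  )
  expect_equal(
    unlist(closed_form_indexes(1, 1)[, c("ci_corr", "md_corr", "fm_corr")]),
    c(ci_corr = 1, md_corr = 1, fm_corr = 0)
  )
  out <- closed_form_indexes(0.8, 0.25)
  expect_equal(out$ci_corr, 0.8)
  expect_equal(out$md_corr, 0.2)
  expect_equal(out$fm_corr, 0.6)
})

test_that("the fertilization rate cancels from all three indexes", {
  grid <- tidyr::expand_grid(theta = c(0.2, 0.8), phi = c(0.1, 0.9))
  for (f in c(0.3, 0.6, 0.9)) {
    out <- closed_form_indexes(grid$theta, grid$phi, fert = f)
    expect_equal(out$ci_corr, grid$theta)
    expect_equal(out$md_corr, grid$theta * grid$phi)
    expect_equal(out$fm_corr, grid$theta * (1 - grid$phi))
  }
})

test_that("plug-in indexes on large simulations converge to the closed form", {
  params <- diallel_params(
    genotypes = c("A", "B"), theta = 0.8, phi = 0.25, base_mort = 0,
    day_sd = 0, replicates_per_cross = 60, eggs_mean = 400, seed = 13
  )
  plug <- plugin_indexes(simulate_diallel(params))
  expect_equal(mean(plug$ci_corr), 0.8, tolerance = 0.02)
  expect_equal(mean(plug$md_corr), 0.2, tolerance = 0.02)
  expect_equal(mean(plug$fm_corr), 0.6, tolerance = 0.02)
  # additivity CI_corr = MD_corr + FM_corr in the zero-mortality limit
  expect_equal(plug$ci_corr, plug$md_corr + plug$fm_corr, tolerance = 0.03)
})

test_that("rescue crosses behave like compatible crosses", {
  design <- enumerate_diallel(c("A", "B")) |>
    dplyr::mutate(
      female_infected = TRUE,
      cross_class = cross_class(male_infected, female_infected)
    )
  params <- diallel_params(
    genotypes = c("A", "B"), theta = 1, phi = 0, day_sd = 0,
    replicates_per_cross = 30, eggs_mean = 100, base_mort = 0, seed = 2
  )
  rec <- derive_responses(simulate_diallel(params, design = design))
  by_class <- rec |>
    dplyr::group_by(cross_class) |>
    dplyr::summarise(f = sum(f_num) / sum(f_den))
  expect_setequal(by_class$cross_class, c("rescue", "rescue_control"))
  expect_equal(diff(by_class$f), 0, tolerance = 0.02)
})

test_that("F2 females segregate the modifier at 0.5 per locus", {
  for (k in c(1L, 3L)) {
    params <- inheritance_params(
      k_loci = k, n_f2_incompatible = 400L, n_f2_compatible = 0L,
      n_parental = 0L, n_f1 = 0L, seed = 31 + k
    )
    f2 <- simulate_inheritance(params) |>
      dplyr::filter(generation == "F2", maternal_origin == "LonX")
    frac <- mean(f2$modifier_genotype == "homozygous")
    expect_lt(abs(frac - 0.5^k), 0.05)
  }
})

test_that("modifier homozygosity drives the MD phenotype of F2 broods", {
  params <- inheritance_params(
    phi_high = 0.7, phi_low = 0.05, theta = 0.7, base_mort = 0,
    n_f2_incompatible = 150L, eggs_mean = 200, seed = 8
  )
  f2 <- simulate_inheritance(params) |>
    dplyr::filter(generation == "F2", cross_class == "incompatible") |>
    derive_responses() |>
    dplyr::group_by(modifier_genotype) |>
    dplyr::summarise(md = sum(md_num) / sum(md_den))
  md_hom <- f2$md[f2$modifier_genotype == "homozygous"]
  md_het <- f2$md[f2$modifier_genotype == "heterozygous"]
  # expected MD: (1 - f) + f * theta * phi
  expect_equal(md_hom, 0.3 + 0.7 * 0.7 * 0.7, tolerance = 0.02)
  expect_equal(md_het, 0.3 + 0.7 * 0.7 * 0.05, tolerance = 0.02)
})

test_that("degenerate inheritance (phi_high = phi_low) removes the contrast", {
  params <- inheritance_params(
    phi_high = 0.3, phi_low = 0.3, n_f2_incompatible = 200L, seed = 4
  )
  f2 <- simulate_inheritance(params) |>
    dplyr::filter(generation == "F2", cross_class == "incompatible") |>
    derive_responses() |>
    dplyr::group_by(modifier_genotype) |>
    dplyr::summarise(md = sum(md_num) / sum(md_den))
  expect_lt(abs(diff(f2$md)), 0.03)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(diallel_params(theta = 1.2), "theta")
  expect_error(diallel_params(fert = 0), "fert")
  expect_error(diallel_params(base_mort = 1), "base_mort")
  expect_error(diallel_params(genotypes = c("A", "A")), "Duplicate")
  expect_error(inheritance_params(phi_high = 0.2, phi_low = 0.5), "phi_low")
  expect_error(inheritance_params(k_loci = 0), "k_loci")
  theta_m <- matrix(0.5, 2, 2)
  expect_error(
    diallel_params(genotypes = c("A", "B"), theta = theta_m), "rownames"
  )
})

test_that("per-pair parameter matrices are honoured", {
  g <- c("A", "B")
  theta <- matrix(c(0.9, 0.9, 0.05, 0.05), 2, 2, byrow = TRUE,
    dimnames = list(g, g)) # rows = male genotype
  params <- diallel_params(
    genotypes = g, theta = theta, phi = 0, base_mort = 0, day_sd = 0,
    replicates_per_cross = 30, eggs_mean = 150, seed = 17
  )
  plug <- plugin_indexes(simulate_diallel(params))
  ci_male_a <- plug$ci_corr[plug$male_genotype == "A"]
  ci_male_b <- plug$ci_corr[plug$male_genotype == "B"]
  expect_true(all(ci_male_a > 0.8))
  expect_true(all(ci_male_b < 0.2))
})
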