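#' Simulation parameters for the diallel CI experiment
#'
#' Bundles the ground-truth parameters of the generative model of haplodiploid
#' CI brood counts. Eggs are laid per replicate with an overdispersed
#' (negative-binomial) count; each egg is fertilized with probability `fert`
#' (unfertilized eggs develop into haploid males); in an incompatible cross a
#' fertilized egg is CI-affected with probability `theta` and an affected egg
#' either develops into a male (probability `phi`, the MD route) or dies (the
#' FM route); every surviving candidate reaches adulthood with probability
#' `1 - base_mort`. Day cohorts shift fertilization and survival on the logit
#' scale by a shared normal effect with standard deviation `day_sd`.
#'
#' `theta`, `phi` and `fert` may be scalars or matrices indexed
#' `[male_genotype, female_genotype]` (dimnames required for matrices).
#'
#' @param genotypes Character vector of genotype labels.
#' @param theta CI penetrance in `[0, 1]`: probability that a fertilized egg
#'   of an incompatible cross is CI-affected.
#' @param phi MD fraction in `[0, 1]`: probability that a CI-affected egg
#'   develops into an adult male rather than dying.
#' @param fert Fertilization probability in `(0, 1]`.
#' @param base_mort Baseline egg-to-adult mortality in `[0, 1)`, applied to
#'   every candidate adult regardless of sex.
#' @param day_sd Standard deviation of day-cohort effects on the logit scale.
#' @param n_days Number of day cohorts.
#' @param replicates_per_cross Integer count, or a length-2 range from which
#'   each cross type's replicate count is drawn uniformly.
#' @param eggs_mean,eggs_dispersion Negative-binomial mean and size of the
#'   per-replicate egg count (a replicate is a leaf disc with ~5 females over
#'   5 days); `eggs_dispersion = Inf` gives Poisson counts.
#' @param seed Integer seed; simulation is fully reproducible from it.
#' @return An object of class `"diallel_params"`.
#' @export
diallel_params <- function(genotypes = c("Beis", "LonX", "Scp", "Stt", "Temp"),
                           theta = 0.7, phi = 0.1, fert = 0.7,
                           base_mort = 0.05, day_sd = 0.3, n_days = 10,
                           replicates_per_cross = c(8L, 11L),
                           eggs_mean = 80, eggs_dispersion = 10,
                           seed = 1L) {
  genotypes <- as.character(genotypes)
  if (length(genotypes) < 1 || anyDuplicated(genotypes)) {
    abort("Duplicate or empty genotype labels.")
  }
  params <- list(
    genotypes = genotypes,
    theta = check_pair_param(theta, genotypes, "theta", 0, 1),
    phi = check_pair_param(phi, genotypes, "phi", 0, 1),
    fert = check_pair_param(fert, genotypes, "fert", 0, 1, lower_open = TRUE),
    base_mort = check_prob(base_mort, "base_mort", upper = 1 - 1e-12),
    day_sd = check_nonneg(day_sd, "day_sd"),
    n_days = check_count(n_days, "n_days", min = 1),
    replicates_per_cross = check_rep_range(replicates_per_cross),
    eggs_mean = check_nonneg(eggs_mean, "eggs_mean", strict = TRUE),
    eggs_dispersion = check_nonneg(eggs_dispersion, "eggs_dispersion",
      strict = TRUE, allow_inf = TRUE
    ),
    seed = as.integer(seed)
  )
  structure(params, class = "diallel_params")
}

#' Simulation parameters for the F1/F2 inheritance experiment
#'
#' Parameters of the backcross design used to probe the Mendelian
#' architecture of a recessive maternal modifier of the CI phenotype:
#' heterozygous F1 females (reciprocal crosses between the modifier line and
#' a non-modifier line) are backcrossed to modifier-line males, and single F2
#' females are each crossed to one infected (incompatible) or cured
#' (compatible) male. An F2 female is modifier-homozygous at each of `k_loci`
#' unlinked loci independently with probability 1/2 and expresses the high MD
#' fraction `phi_high` only when homozygous at all of them (recessive loci,
#' jointly required); otherwise she expresses `phi_low`.
#'
#' @param k_loci Number of unlinked recessive modifier loci (>= 1).
#' @param phi_high,phi_low MD fractions of modifier-homozygous vs other
#'   females; `0 <= phi_low < phi_high <= 1`.
#' @param theta CI penetrance of the infected male line.
#' @param modifier_line,other_line Labels of the maternal modifier line and
#'   of the line supplying the (infected or cured) males.
#' @param n_parental,n_f1 Replicates per parental / F1 cross type.
#' @param n_f2_incompatible,n_f2_compatible Number of single-female F2 broods
#'   per maternal origin in incompatible / compatible crosses.
#' @param eggs_mean,eggs_dispersion Negative-binomial egg-count parameters
#'   for a single-female brood (~7 days of oviposition).
#' @inheritParams diallel_params
#' @return An object of class `"inheritance_params"`.
#' @export
inheritance_params <- function(k_loci = 1L, phi_high = 0.7, phi_low = 0.05,
                               theta = 0.7, fert = 0.7, base_mort = 0.05,
                               modifier_line = "LonX", other_line = "Scp",
                               n_parental = 8L, n_f1 = 8L,
                               n_f2_incompatible = 28L, n_f2_compatible = 13L,
                               eggs_mean = 40, eggs_dispersion = 10,
                               seed = 1L) {
  phi_high <- check_prob(phi_high, "phi_high")
  phi_low <- check_prob(phi_low, "phi_low")
  if (phi_low > phi_high) {
    abort("`phi_low` must not exceed `phi_high`.")
  }
  structure(list(
    k_loci = check_count(k_loci, "k_loci", min = 1),
    phi_high = phi_high, phi_low = phi_low,
    theta = check_prob(theta, "theta"),
    fert = check_prob(fert, "fert", lower_open = TRUE),
    base_mort = check_prob(base_mort, "base_mort", upper = 1 - 1e-12),
    modifier_line = as.character(modifier_line),
    other_line = as.character(other_line),
    n_parental = check_count(n_parental, "n_parental", min = 0),
    n_f1 = check_count(n_f1, "n_f1", min = 0),
    n_f2_incompatible = check_count(n_f2_incompatible, "n_f2_incompatible",
      min = 1
    ),
    n_f2_compatible = check_count(n_f2_compatible, "n_f2_compatible", min = 0),
    eggs_mean = check_nonneg(eggs_mean, "eggs_mean", strict = TRUE),
    eggs_dispersion = check_nonneg(eggs_dispersion, "eggs_dispersion",
      strict = TRUE, allow_inf = TRUE
    ),
    seed = as.integer(seed)
  ), class = "inheritance_params")
}

check_prob <- function(x, name, lower_open = FALSE, upper = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > upper ||
    (lower_open && x == 0)) {
    abort(paste0("`", name, "` must be a probability in ",
      if (lower_open) "(0, " else "[0, ", format(upper), "]."))
  }
  as.numeric(x)
}

check_nonneg <- function(x, name, strict = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (allow_inf || is.finite(x)) && (if (strict) x > 0 else x >= 0)
  if (!ok) abort(paste0("`", name, "` must be a ",
    if (strict) "positive" else "non-negative", " number."))
  as.numeric(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) ||
    x < min) {
    abort(paste0("`", name, "` must be an integer >= ", min, "."))
  }
  as.integer(x)
}

check_rep_range <- function(x) {
  if (!is.numeric(x) || !length(x) %in% 1:2 || anyNA(x) ||
    any(x != floor(x)) || any(x < 1) || (length(x) == 2 && x[2] < x[1])) {
    abort("`replicates_per_cross` must be a positive count or a length-2 range.")
  }
  as.integer(x)
}

# Expand a scalar per-pair parameter to a [male, female] matrix and validate
# its range.
check_pair_param <- function(x, genotypes, name, lower, upper,
                             lower_open = FALSE) {
  genotypes <- as.character(genotypes)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)) ||
      !setequal(rownames(x), genotypes) || !setequal(colnames(x), genotypes)) {
      abort(paste0("`", name,
        "` matrix needs male-genotype rownames and female-genotype colnames ",
        "covering all genotypes."))
    }
    x <- x[genotypes, genotypes, drop = FALSE]
  } else if (is.numeric(x) && length(x) == 1) {
    x <- matrix(x, length(genotypes), length(genotypes),
      dimnames = list(genotypes, genotypes)
    )
  } else {
    abort(paste0("`", name, "` must be a scalar or a genotype-pair matrix."))
  }
  if (anyNA(x) || any(x < lower) || any(x > upper) ||
    (lower_open && any(x == lower))) {
    abort(paste0("`", name, "` values must lie in ",
      if (lower_open) "(" else "[", lower, ", ", upper, "]."))
  }
  x
}

# Evaluate an expression with a local RNG state seeded by `seed`, restoring
# the caller's state afterwards.
with_sim_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Vectorized generative chain for one set of broods. `day_shift` moves
# fertilization and survival on the logit scale.
sim_brood_counts <- function(n, eggs_mean, eggs_dispersion, fert, theta, phi,
                             base_mort, day_shift = 0) {
  eggs <- as.integer(if (is.infinite(eggs_dispersion)) {
    stats::rpois(n, eggs_mean)
  } else {
    rnbinom(n, size = eggs_dispersion, mu = eggs_mean)
  })
  fert_p <- plogis(qlogis(fert) + day_shift)
  surv_p <- plogis(qlogis(1 - base_mort) + day_shift)
  unfert <- rbinom(n, eggs, 1 - fert_p)
  fertilized <- eggs - unfert
  affected <- rbinom(n, fertilized, theta)
  ci_males <- rbinom(n, affected, phi)
  adult_females <- rbinom(n, fertilized - affected, surv_p)
  adult_males <- rbinom(n, unfert + ci_males, surv_p)
  tibble(eggs = eggs, adult_females = adult_females, adult_males = adult_males)
}

#' Simulate brood counts for a full diallel CI experiment
#'
#' Draws replicated brood records from the generative model described in
#' [diallel_params()]. Incompatible crosses express the pair-specific CI
#' penetrance `theta`; compatible controls and rescue(-control) crosses have
#' CI ablated (`theta = 0`). Output records satisfy
#' `adult_females + adult_males <= eggs` and are reproducible from the seed.
#'
#' @param params A [diallel_params()] object.
#' @param design Optional cross-type tibble (as from [enumerate_diallel()]);
#'   defaults to the full diallel over `params$genotypes`.
#' @return A tibble of brood records in the package schema, with a
#'   `cross_class` column.
#' @examples
#' records <- simulate_diallel(diallel_params(genotypes = c("A", "B"), seed = 7))
#' dplyr::count(records, cross_class)
#' @export
simulate_diallel <- function(params, design = NULL) {
  stopifnot(inherits(params, "diallel_params"))
  design <- design %||% enumerate_diallel(params$genotypes)
  with_sim_seed(params$seed, {
    day_effects <- rnorm(params$n_days, 0, params$day_sd)
    rep_counts <- if (length(params$replicates_per_cross) == 2) {
      sample(
        params$replicates_per_cross[1]:params$replicates_per_cross[2],
        nrow(design),
        replace = TRUE
      )
    } else {
      rep(params$replicates_per_cross, nrow(design))
    }
    purrr::pmap(
      list(seq_len(nrow(design)), rep_counts),
      function(i, n_rep) {
        cross <- design[i, ]
        day_idx <- sample.int(params$n_days, n_rep, replace = TRUE)
        theta_eff <- if (cross$cross_class == "incompatible") {
          params$theta[cross$male_genotype, cross$female_genotype]
        } else {
          0
        }
        counts <- sim_brood_counts(
          n_rep,
          eggs_mean = params$eggs_mean,
          eggs_dispersion = params$eggs_dispersion,
          fert = params$fert[cross$male_genotype, cross$female_genotype],
          theta = theta_eff,
          phi = params$phi[cross$male_genotype, cross$female_genotype],
          base_mort = params$base_mort,
          day_shift = day_effects[day_idx]
        )
        tibble(
          day = paste0("d", day_idx),
          female_genotype = cross$female_genotype,
          male_genotype = cross$male_genotype,
          male_infected = cross$male_infected,
          female_infected = cross$female_infected,
          replicate = paste0("r", seq_len(n_rep)),
          counts,
          cross_class = cross$cross_class
        )
      }
    ) |>
      purrr::list_rbind()
  })
}

#' Closed-form corrected indexes implied by the generative model
#'
#' In the zero-baseline-mortality, infinite-sample limit of the brood
#' simulator the expected responses are `F_obs = f(1 - theta)`, `F_c = f`,
#' `MD_obs = (1 - f) + f * theta * phi`, `MD_c = 1 - f` and
#' `FM_obs = theta (1 - phi) / (1 - theta phi)`, `FM_c = 0`, where `f` is the
#' fertilization probability. Substituting these into the corrected-index
#' formulas makes `f` cancel and yields `CI_corr = theta`,
#' `MD_corr = theta * phi`, `FM_corr = theta * (1 - phi)`. The function
#' performs that substitution numerically through [ci_corr()], [md_corr()]
#' and [fm_corr()], so the cancellation of `fert` is a computed fact rather
#' than an assumption.
#'
#' @param theta,phi CI penetrance and MD fraction, in `[0, 1]` (vectorized).
#' @param fert Fertilization probability used in the substitution; the result
#'   is independent of it.
#' @return A tibble with columns `theta`, `phi`, `ci_corr`, `md_corr`,
#'   `fm_corr`.
#' @examples
#' closed_form_indexes(0.8, 0.25)
#' @export
closed_form_indexes <- function(theta, phi, fert = 0.7) {
  stopifnot(
    all(theta >= 0 & theta <= 1), all(phi >= 0 & phi <= 1),
    fert > 0, fert <= 1
  )
  pair <- tibble(theta = theta, phi = phi)
  f_obs <- fert * (1 - pair$theta)
  f_c <- rep(fert, nrow(pair))
  md_obs <- (1 - fert) + fert * pair$theta * pair$phi
  md_c <- rep(1 - fert, nrow(pair))
  fm_den_obs <- fert - fert * pair$theta * pair$phi
  fm_obs <- ifelse(fm_den_obs > 0,
    fert * pair$theta * (1 - pair$phi) / fm_den_obs, 0
  )
  fm_c <- rep(0, nrow(pair))
  md <- md_corr(md_obs, md_c)
  pair |>
    mutate(
      ci_corr = ci_corr(f_obs, f_c),
      md_corr = md,
      fm_corr = fm_corr(fm_obs, fm_c, md)
    )
}

#' Simulate the F1/F2 inheritance experiment
#'
#' Generates parental-line, heterozygous-F1 and backcross-F2 brood records
#' under the recessive maternal-modifier model of [inheritance_params()].
#' Every brood is a single-female cross to an infected (incompatible) or
#' cured (compatible) male of the non-modifier line; day effects are absent
#' by design. Pedigree columns `generation`, `maternal_origin` and
#' `modifier_genotype` annotate each record and are ignored by downstream
#' model fitting.
#'
#' @param params An [inheritance_params()] object.
#' @return A tibble of brood records with pedigree annotations.
#' @examples
#' broods <- simulate_inheritance(inheritance_params(seed = 3))
#' dplyr::count(broods, generation, cross_class)
#' @export
simulate_inheritance <- function(params) {
  stopifnot(inherits(params, "inheritance_params"))
  mod <- params$modifier_line
  oth <- params$other_line
  with_sim_seed(params$seed, {
    plan <- bind_rows(
      tibble(
        generation = "parental", maternal_origin = c(mod, oth),
        female_genotype = c(mod, oth),
        phi = c(params$phi_high, params$phi_low),
        modifier_genotype = c("homozygous", "wildtype"),
        n_inc = params$n_parental, n_comp = params$n_parental
      ),
      tibble(
        generation = "F1", maternal_origin = c(mod, oth),
        female_genotype = paste0("F1.", c(mod, oth)),
        phi = params$phi_low, modifier_genotype = "heterozygous",
        n_inc = params$n_f1, n_comp = params$n_f1
      )
    )
    fixed <- purrr::pmap(plan, function(generation, maternal_origin,
                                        female_genotype, phi,
                                        modifier_genotype, n_inc, n_comp) {
      purrr::map2(
        c(TRUE, FALSE), c(n_inc, n_comp),
        function(infected, n_rep) {
          if (n_rep == 0) return(NULL)
          counts <- sim_brood_counts(
            n_rep,
            eggs_mean = params$eggs_mean,
            eggs_dispersion = params$eggs_dispersion,
            fert = params$fert,
            theta = if (infected) params$theta else 0,
            phi = phi, base_mort = params$base_mort
          )
          tibble(
            day = "d1", female_genotype = female_genotype,
            male_genotype = oth, male_infected = infected,
            female_infected = FALSE,
            replicate = paste0(if (infected) "inc" else "comp", seq_len(n_rep)),
            counts,
            generation = generation, maternal_origin = maternal_origin,
            modifier_genotype = modifier_genotype
          )
        }
      ) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

    f2 <- purrr::map(c(mod, oth), function(origin) {
      purrr::map2(
        c(TRUE, FALSE), c(params$n_f2_incompatible, params$n_f2_compatible),
        function(infected, n_rep) {
          if (n_rep == 0) return(NULL)
          # Each F2 female is modifier-homozygous at each locus with
          # probability 1/2; phi_high requires homozygosity at all k loci.
          hom_all <- stats::rbinom(n_rep, params$k_loci, 0.5) == params$k_loci
          counts <- purrr::map(seq_len(n_rep), function(i) {
            sim_brood_counts(
              1,
              eggs_mean = params$eggs_mean,
              eggs_dispersion = params$eggs_dispersion,
              fert = params$fert,
              theta = if (infected) params$theta else 0,
              phi = if (hom_all[i]) params$phi_high else params$phi_low,
              base_mort = params$base_mort
            )
          }) |> purrr::list_rbind()
          tibble(
            day = "d1", female_genotype = paste0("F2.", origin),
            male_genotype = oth, male_infected = infected,
            female_infected = FALSE,
            replicate = paste0(if (infected) "inc" else "comp", seq_len(n_rep)),
            counts,
            generation = "F2", maternal_origin = origin,
            modifier_genotype = ifelse(hom_all, "homozygous", "heterozygous")
          )
        }
      ) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

    bind_rows(fixed, f2) |>
      mutate(cross_class = cross_class(.data$male_infected, .data$female_infected))
  })
}
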