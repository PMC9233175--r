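.onLoad <- function(libname, pkgname) {
  # The JAGS glm module provides efficient block samplers for binomial-logit
  # GLMs; fall back silently to the base samplers if it cannot be loaded.
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
}

#' Specify a Bayesian binomial CI model
#'
#' Defines one of the binomial-logit regressions used for CI analysis:
#' `numerator ~ Binomial(denominator, p)` with
#' `logit(p) = fixed effects (+ day random intercepts)`. The modelled
#' response is `F` (adult females / eggs), `MD` (adult males / eggs) or `FM`
#' (failed eggs / eggs not becoming adult males). Fixed-effect structures are
#' formula strings over `inf` (male Wolbachia infection state), `mgeno`
#' (male genotype) and `fgeno` (female genotype); the full model is
#' `"inf*mgeno*fgeno"` and the canonical comparison set is `"inf"`,
#' `"inf*mgeno"`, `"inf*fgeno"`, `"inf*mgeno*fgeno"`.
#'
#' Priors are weakly informative on the logit scale: Normal(0, 1.5) for
#' coefficients, Normal(0, 3) for the intercept, half-Normal(0, 1) for the
#' day-intercept scale.
#'
#' @param response One of `"F"`, `"MD"`, `"FM"`.
#' @param fixed Fixed-effect formula string (also accepts `"1"` for an
#'   intercept-only model).
#' @param day_intercepts Include zero-mean day random intercepts with an
#'   estimated scale?
#' @param priors Named list overriding `intercept_sd`, `coef_sd`,
#'   `day_sd_scale`.
#' @return An object of class `"ci_model_spec"`.
#' @examples
#' ci_model_spec("F", "inf*mgeno")
#' @export
ci_model_spec <- function(response = c("F", "MD", "FM"),
                          fixed = "inf*mgeno*fgeno",
                          day_intercepts = TRUE,
                          priors = list()) {
  response <- match.arg(response)
  fml <- stats::as.formula(paste("~", fixed))
  vars <- all.vars(fml)
  bad <- setdiff(vars, c("inf", "mgeno", "fgeno"))
  if (length(bad)) {
    abort(paste0("Unknown model variable(s): ", paste(bad, collapse = ", ")))
  }
  priors <- modifyList(
    list(intercept_sd = 3, coef_sd = 1.5, day_sd_scale = 1), priors
  )
  structure(
    list(
      response = response, fixed = fixed, formula = fml,
      day_intercepts = isTRUE(day_intercepts), priors = priors
    ),
    class = "ci_model_spec"
  )
}

#' The four canonical fixed-effect variants
#'
#' All retain the male infection state and day intercepts and differ in the
#' genotype terms, forming the nested comparison set used to attribute CI
#' variation to male and female genotypes.
#'
#' @inheritParams ci_model_spec
#' @return A named list of [ci_model_spec()] objects.
#' @export
ci_model_variants <- function(response = c("F", "MD", "FM"),
                              day_intercepts = TRUE) {
  response <- match.arg(response)
  fixed <- c("inf", "inf*mgeno", "inf*fgeno", "inf*mgeno*fgeno")
  setNames(
    purrr::map(fixed, ~ ci_model_spec(response, .x, day_intercepts)),
    fixed
  )
}

response_pair <- function(responses, response) {
  switch(response,
    F = list(y = responses$f_num, n = responses$f_den),
    MD = list(y = responses$md_num, n = responses$md_den),
    FM = list(y = responses$fm_num, n = responses$fm_den)
  )
}

# Build the model frame with fixed factor codings. `inf` always carries both
# levels (cured = reference) even if the data hold only one, so that
# predictions at unobserved infection states remain defined.
model_frame_ci <- function(records, genotype_levels = NULL) {
  glev <- genotype_levels %||%
    sort(unique(c(records$female_genotype, records$male_genotype)))
  tibble(
    inf = factor(ifelse(records$male_infected, "infected", "cured"),
      levels = c("cured", "infected")
    ),
    mgeno = factor(records$male_genotype, levels = glev),
    fgeno = factor(records$female_genotype, levels = glev)
  )
}

prepare_model_data <- function(records, spec) {
  responses <- derive_responses(records)
  yn <- response_pair(responses, spec$response)
  keep <- which(yn$n > 0)
  if (!length(keep)) {
    abort("No rows with a positive denominator for this response.")
  }
  mf <- model_frame_ci(records)[keep, , drop = FALSE]
  list(
    y = yn$y[keep], n = yn$n[keep], mf = mf, keep = keep,
    day = factor(records$day[keep])
  )
}

jags_model_string <- function(K, day_intercepts) {
  coef_prior <- if (K > 1) {
    "  for (k in 2:K) { beta[k] ~ dnorm(0, prec_coef) }\n"
  } else {
    ""
  }
  if (day_intercepts) {
    paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    y[i] ~ dbin(p[i], n[i])\n",
      "    logit(p[i]) <- inprod(X[i,], beta[]) + u[day[i]]\n",
      "  }\n",
      "  beta[1] ~ dnorm(0, prec_intercept)\n",
      coef_prior,
      "  for (j in 1:J) { u[j] ~ dnorm(0, tau_day) }\n",
      "  sd_day ~ dnorm(0, prec_day) T(0,)\n",
      "  tau_day <- pow(sd_day, -2)\n",
      "}\n"
    )
  } else {
    paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    y[i] ~ dbin(p[i], n[i])\n",
      "    logit(p[i]) <- inprod(X[i,], beta[])\n",
      "  }\n",
      "  beta[1] ~ dnorm(0, prec_intercept)\n",
      coef_prior,
      "}\n"
    )
  }
}

run_jags <- function(model_string, data, monitor, chains, iter, warmup,
                     seed) {
  if (iter <= warmup) abort("`iter` must exceed `warmup`.")
  inits <- lapply(seq_len(chains), function(ch) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = as.integer(seed + ch)
    )
  })
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = data, inits = inits, n.chains = chains,
    n.adapt = warmup, quiet = TRUE
  )
  samples <- rjags::coda.samples(
    jm, monitor, n.iter = iter - warmup, progress.bar = "none"
  )
  draws <- do.call(rbind, lapply(samples, function(ch) {
    m <- unclass(ch)
    attr(m, "mcpar") <- NULL
    m
  }))
  chain <- rep(seq_len(chains), each = iter - warmup)
  list(draws = draws, chain = chain)
}

#' Fit a Bayesian binomial CI model with MCMC
#'
#' Fits the binomial-logit regression defined by a [ci_model_spec()] to brood
#' records via JAGS. Rows with a zero denominator for the chosen response are
#' dropped from the likelihood (an `FM` row where every egg became an adult
#' male is dropped from `FM` fits only). The returned object carries the
#' post-warmup draws, the pointwise log-likelihood matrix needed for WAIC,
#' and rank-normalized convergence diagnostics; `flagged` is `TRUE` when any
#' parameter fails \eqn{\widehat{R} \le} 1.01 or ESS \eqn{\ge} 400.
#'
#' @param records A tibble of brood records.
#' @param spec A [ci_model_spec()].
#' @param chains,iter,warmup MCMC settings; defaults are 2 chains of 5000
#'   iterations with 1000 warmup.
#' @param seed Integer seed (chains use derived streams).
#' @return An object of class `"ci_fit"`.
#' @examples
#' \donttest{
#' rec <- simulate_diallel(diallel_params(genotypes = c("A", "B"), seed = 1))
#' fit <- fit_ci_model(rec, ci_model_spec("F", "inf"),
#'   iter = 600, warmup = 200, seed = 1
#' )
#' glance(fit)
#' }
#' @export
fit_ci_model <- function(records, spec, chains = 2L, iter = 5000L,
                         warmup = 1000L, seed = 1L) {
  stopifnot(inherits(spec, "ci_model_spec"))
  prep <- prepare_model_data(records, spec)
  X <- model.matrix(spec$formula, prep$mf)
  pr <- spec$priors
  data <- list(
    y = prep$y, n = prep$n, X = X, N = nrow(X),
    prec_intercept = pr$intercept_sd^-2
  )
  if (ncol(X) > 1) {
    data$K <- ncol(X)
    data$prec_coef <- pr$coef_sd^-2
  }
  monitor <- "beta"
  if (spec$day_intercepts) {
    data$day <- as.integer(prep$day)
    data$J <- nlevels(prep$day)
    data$prec_day <- pr$day_sd_scale^-2
    monitor <- c("beta", "u", "sd_day")
  }
  res <- run_jags(
    jags_model_string(ncol(X), spec$day_intercepts),
    data, monitor, chains, iter, warmup, seed
  )
  draws <- res$draws
  beta_idx <- grep("^beta\\[", colnames(draws))
  if (ncol(X) == 1) beta_idx <- which(colnames(draws) == "beta")
  colnames(draws)[beta_idx] <- colnames(X)
  if (spec$day_intercepts) {
    u_idx <- grep("^u\\[", colnames(draws))
    colnames(draws)[u_idx] <- paste0("day:", levels(prep$day))
  }
  if (any(!is.finite(draws))) abort("Sampler produced non-finite draws.")
  eta <- draws[, colnames(X), drop = FALSE] %*% t(X)
  if (spec$day_intercepts) {
    u <- draws[, paste0("day:", levels(prep$day)), drop = FALSE]
    eta <- eta + u[, as.integer(prep$day), drop = FALSE]
  }
  p <- plogis(eta)
  pointwise <- vapply(
    seq_len(ncol(p)),
    function(i) dbinom(prep$y[i], prep$n[i], p[, i], log = TRUE),
    numeric(nrow(p))
  )
  colnames(pointwise) <- rownames(X)
  diagnostics <- diagnose(draws, chain = res$chain)
  structure(
    list(
      draws = draws, chain = res$chain, pointwise_loglik = pointwise,
      spec = spec, terms = terms(spec$formula),
      xlevels = lapply(prep$mf, levels), beta_names = colnames(X),
      assign = attr(X, "assign"),
      day_levels = if (spec$day_intercepts) levels(prep$day) else NULL,
      data = c(prep["y"], prep["n"], list(mf = prep$mf, day = prep$day,
        keep = prep$keep)),
      diagnostics = diagnostics,
      flagged = any(diagnostics$flagged),
      mcmc = list(chains = chains, iter = iter, warmup = warmup, seed = seed)
    ),
    class = "ci_fit"
  )
}

#' @export
print.ci_fit <- function(x, ...) {
  cat(
    "<ci_fit> response ", x$spec$response, ", logit(p) ~ ", x$spec$fixed,
    if (x$spec$day_intercepts) " + (1|day)", "\n",
    "  ", nrow(x$draws), " draws (", x$mcmc$chains, " chains), ",
    length(x$data$y), " observations\n",
    "  max R-hat ", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
    ", min bulk ESS ", round(min(x$diagnostics$ess_bulk, na.rm = TRUE)),
    if (x$flagged) "  [FLAGGED]", "\n",
    sep = ""
  )
  invisible(x)
}

#' Posterior predicted proportions for cross types
#'
#' Evaluates the inverse-logit of the linear predictor at the covariates of
#' each requested cross type, draw by draw. Day intercepts are excluded: the
#' prediction is the population-level proportion, and draws stay aligned by
#' sample index across cross types so that downstream index ratios are
#' computed within draws.
#'
#' @param fit A [fit_ci_model()] result.
#' @param newdata Data frame with columns `female_genotype`, `male_genotype`,
#'   `male_infected` (one row per cross type).
#' @param format `"matrix"` (draws x cross types) or `"tidy"` (one row per
#'   draw x cross type).
#' @return A matrix or tibble of predicted proportions.
#' @export
predict_proportion <- function(fit, newdata, format = c("matrix", "tidy")) {
  stopifnot(inherits(fit, "ci_fit"))
  format <- match.arg(format)
  glev <- fit$xlevels$mgeno
  check_level <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) {
      abort(paste0(
        "Unknown ", what, " level(s): ", paste(bad, collapse = ", ")
      ))
    }
  }
  check_level(newdata$male_genotype, glev, "male genotype")
  check_level(newdata$female_genotype, fit$xlevels$fgeno, "female genotype")
  mf <- model_frame_ci(newdata, genotype_levels = glev)
  X <- model.matrix(stats::formula(fit$terms), mf)
  p <- plogis(fit$draws[, fit$beta_names, drop = FALSE] %*% t(X))
  if (format == "matrix") {
    colnames(p) <- NULL
    return(p)
  }
  newdata |>
    as_tibble() |>
    mutate(.row = row_number()) |>
    tidyr::expand_grid(.draw = seq_len(nrow(p))) |>
    mutate(p = as.vector(p[cbind(.data$.draw, .data$.row)])) |>
    select(-".row")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a CI model fit
#'
#' One row per sampled parameter with posterior mean, standard deviation,
#' the 9/50/91 posterior percentiles used throughout the CI analyses, and
#' convergence diagnostics.
#'
#' @param x A `ci_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ci_fit
#' @export
tidy.ci_fit <- function(x, ...) {
  qs <- apply(x$draws, 2, quantile, probs = c(0.09, 0.5, 0.91))
  tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, sd),
    q09 = qs[1, ], q50 = qs[2, ], q91 = qs[3, ]
  ) |>
    left_join(
      x$diagnostics |> rename(term = "parameter"),
      by = "term"
    )
}

#' One-line model summary
#'
#' @param x A `ci_fit`.
#' @param ... Unused.
#' @return A tibble with observation/draw counts, WAIC and diagnostic
#'   extremes.
#' @method glance ci_fit
#' @export
glance.ci_fit <- function(x, ...) {
  w <- waic(x)
  tibble(
    response = x$spec$response, fixed = x$spec$fixed,
    nobs = length(x$data$y), n_draws = nrow(x$draws),
    waic = w$waic, p_waic = w$p_waic,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess_bulk, na.rm = TRUE),
    flagged = x$flagged
  )
}
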