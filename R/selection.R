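#' Widely Applicable Information Criterion
#'
#' Computes WAIC from a pointwise log-likelihood matrix (posterior draws in
#' rows, observations in columns):
#' `lppd = sum_i log mean_s exp(loglik[s, i])` (evaluated by log-sum-exp),
#' `p_waic = sum_i var_s(loglik[s, i])` and `waic = -2 (lppd - p_waic)`, with
#' the standard error `sqrt(n * var_i(pointwise))` of the pointwise WAIC
#' contributions.
#'
#' @param x A `ci_fit` or a draws x observations log-likelihood matrix.
#' @param ... Unused.
#' @return A list of class `"waic_result"` with elements `lppd`, `p_waic`,
#'   `waic`, `se`, `n_obs` and the `pointwise` tibble.
#' @examples
#' ll <- matrix(log(c(0.5, 0.25, 0.5, 0.5)), nrow = 2)
#' waic(ll)
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @export
waic.ci_fit <- function(x, ...) waic(x$pointwise_loglik)

#' @export
waic.matrix <- function(x, ...) {
  if (nrow(x) < 2) abort("WAIC needs at least 2 posterior draws.")
  s <- nrow(x)
  lppd_i <- apply(x, 2, function(ll) {
    m <- max(ll)
    m + log(mean(exp(ll - m)))
  })
  p_i <- apply(x, 2, var)
  pointwise <- tibble(
    lppd = lppd_i, p_waic = p_i, waic = -2 * (lppd_i - p_i)
  )
  n <- ncol(x)
  structure(
    list(
      lppd = sum(lppd_i), p_waic = sum(p_i),
      waic = -2 * (sum(lppd_i) - sum(p_i)),
      se = sqrt(n * var(pointwise$waic)),
      n_obs = n, pointwise = pointwise
    ),
    class = "waic_result"
  )
}

#' @export
print.waic_result <- function(x, ...) {
  cat(
    "WAIC ", round(x$waic, 2), " (se ", round(x$se, 2), "), lppd ",
    round(x$lppd, 2), ", p_waic ", round(x$p_waic, 2), ", n ", x$n_obs, "\n",
    sep = ""
  )
  invisible(x)
}

#' Compare binomial CI models by WAIC
#'
#' Fits every supplied model specification to the same records — all specs
#' must share the response, so each model sees the identical retained rows —
#' and tabulates WAIC ascending with differences to the best model. The
#' difference standard error `d_se` is computed from the pointwise WAIC
#' contrasts against the best model.
#'
#' @param records Brood records.
#' @param specs Named list of [ci_model_spec()] objects (e.g.
#'   [ci_model_variants()]).
#' @inheritParams fit_ci_model
#' @return An object of class `"ci_model_comparison"`: a tibble with columns
#'   `model`, `waic`, `se`, `p_waic`, `d_waic`, `d_se`, `flagged`, carrying
#'   the fitted models in the `"fits"` attribute.
#' @export
compare_ci_models <- function(records, specs, chains = 2L, iter = 5000L,
                              warmup = 1000L, seed = 1L) {
  stopifnot(length(specs) >= 2)
  responses <- unique(purrr::map_chr(specs, "response"))
  if (length(responses) != 1) {
    abort("All model specs must target the same response.")
  }
  if (is.null(names(specs))) {
    names(specs) <- purrr::map_chr(specs, "fixed")
  }
  fits <- purrr::imap(specs, function(spec, nm) {
    fit_ci_model(records, spec,
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
  })
  waics <- purrr::map(fits, waic)
  tab <- tibble(
    model = names(specs),
    waic = unname(purrr::map_dbl(waics, "waic")),
    se = unname(purrr::map_dbl(waics, "se")),
    p_waic = unname(purrr::map_dbl(waics, "p_waic")),
    flagged = unname(purrr::map_lgl(fits, "flagged"))
  ) |>
    arrange(.data$waic)
  best <- tab$model[1]
  best_pw <- waics[[best]]$pointwise$waic
  tab <- tab |>
    mutate(
      d_waic = .data$waic - .data$waic[1],
      d_se = purrr::map_dbl(.data$model, function(m) {
        if (m == best) return(0)
        d <- waics[[m]]$pointwise$waic - best_pw
        sqrt(length(d) * var(d))
      })
    ) |>
    relocate("d_waic", "d_se", .after = "se")
  structure(tab, fits = fits, class = c("ci_model_comparison", class(tab)))
}

#' Finite-population standard deviation of model-term effects
#'
#' For each model term (e.g. `inf`, `mgeno`, `inf:mgeno`, and the day
#' intercepts) and each posterior draw, reconstructs the complete vector of
#' per-level effects — under treatment coding every cell involving a
#' reference level contributes an effect of 0 — centers it, and takes the
#' standard deviation with denominator `J - 1`, `J` being the number of
#' level combinations of the term. Comparing these finite-population SDs
#' across terms quantifies how much each explanatory variable and
#' interaction contributes to the fitted variation.
#'
#' @param fit A `ci_fit`.
#' @return An object of class `"group_sd_draws"`: a list with `draws`
#'   (tibble of per-draw SD per term) and `summary` (posterior mean and
#'   9/50/91 percentiles per term).
#' @export
finite_population_sd <- function(fit) {
  stopifnot(inherits(fit, "ci_fit"))
  term_labels <- attr(fit$terms, "term.labels")
  if (!length(term_labels) && is.null(fit$day_levels)) {
    abort("The model has no non-intercept terms to decompose.")
  }
  factor_levels <- purrr::map_int(fit$xlevels, length)
  term_vars <- attr(fit$terms, "factors")
  group_draws <- purrr::imap(setNames(seq_along(term_labels), term_labels),
    function(t_idx, label) {
      cols <- which(fit$assign == t_idx)
      if (!length(cols)) {
        abort(paste0("No coefficients mapped to term ", label, "."))
      }
      vars <- rownames(term_vars)[term_vars[, label] > 0]
      j <- prod(factor_levels[vars])
      eff <- fit$draws[, fit$beta_names[cols], drop = FALSE]
      n_zero <- j - length(cols)
      # sd over the J cell effects: the reference cells are exact zeros.
      apply(eff, 1, function(b) sd(c(rep(0, n_zero), b)))
    }
  )
  if (!is.null(fit$day_levels)) {
    u <- fit$draws[, paste0("day:", fit$day_levels), drop = FALSE]
    group_draws$day <- apply(u, 1, sd)
  }
  draws <- purrr::imap(group_draws, function(v, g) {
    tibble(group = g, .draw = seq_along(v), sd = v)
  }) |>
    purrr::list_rbind()
  summary <- draws |>
    group_by(.data$group) |>
    summarise(
      mean = mean(.data$sd),
      q09 = unname(quantile(.data$sd, 0.09)),
      q50 = unname(quantile(.data$sd, 0.50)),
      q91 = unname(quantile(.data$sd, 0.91)),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$q50))
  structure(
    list(draws = draws, summary = summary),
    class = "group_sd_draws"
  )
}

#' @export
print.group_sd_draws <- function(x, ...) {
  cat("<group_sd_draws> finite-population SD per model term\n")
  print(x$summary, ...)
  invisible(x)
}

#' @rdname tidy.ci_fit
#' @method tidy group_sd_draws
#' @export
tidy.group_sd_draws <- function(x, ...) x$summary
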