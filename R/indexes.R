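#' Corrected CI indexes
#'
#' The three corrected indexes compare an incompatible cross with the
#' compatible control of the same female x male genotype pair, removing
#' variation due to nuclear background and day effects:
#' \deqn{CI_{corr} = 1 - F_{obs} / F_c}
#' \deqn{MD_{corr} = (MD_{obs} - MD_c) / (1 - MD_c)}
#' \deqn{FM_{corr} = (FM_{obs} (1 - MD_{corr}) - FM_c) / (1 - FM_c)}
#' where the `obs` quantities are estimated proportions in the incompatible
#' cross and the `c` quantities in its compatible control. All three operate
#' per posterior draw on sample-aligned vectors; values outside `[0, 1]` are
#' legal and reported unclipped (a negative `CI_corr` means the incompatible
#' cross outperformed its control).
#'
#' @param f_obs,f_c Draws of the `F` proportion in the incompatible and
#'   compatible cross; `f_c` must be strictly positive.
#' @param md_obs,md_c Draws of the `MD` proportion; `md_c` must be `< 1`.
#' @param fm_obs,fm_c Draws of the `FM` proportion; `fm_c` must be `< 1`.
#' @param md_corr_draws Draws of `MD_corr` (from the MD model fit),
#'   sample-aligned with the FM draws.
#' @param cross Optional label used in error messages.
#' @return A numeric vector of per-draw index values.
#' @examples
#' ci_corr(0.15, 0.6)   # 0.75
#' md_corr(0.7, 0.4)    # 0.5
#' fm_corr(0.5, 0.1, 0.2)
#' @name ci_indexes
NULL

check_aligned <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens[lens != 1])) > 1) {
    abort("Draw vectors must be sample-aligned (equal length).")
  }
}

#' @rdname ci_indexes
#' @export
ci_corr <- function(f_obs, f_c, cross = NULL) {
  check_aligned(f_obs, f_c)
  if (any(f_c == 0)) {
    abort(paste0(
      "F_c contains zero draws",
      if (!is.null(cross)) paste0(" for cross ", cross),
      ": the compatible cross is degenerate and CI_corr is undefined."
    ))
  }
  1 - f_obs / f_c
}

#' @rdname ci_indexes
#' @export
md_corr <- function(md_obs, md_c, cross = NULL) {
  check_aligned(md_obs, md_c)
  if (any(md_c == 1)) {
    abort(paste0(
      "MD_c contains draws equal to 1",
      if (!is.null(cross)) paste0(" for cross ", cross),
      ": an all-male compatible brood leaves MD_corr undefined."
    ))
  }
  (md_obs - md_c) / (1 - md_c)
}

#' @rdname ci_indexes
#' @export
fm_corr <- function(fm_obs, fm_c, md_corr_draws, cross = NULL) {
  check_aligned(fm_obs, fm_c, md_corr_draws)
  if (any(fm_c == 1)) {
    abort(paste0(
      "FM_c contains draws equal to 1",
      if (!is.null(cross)) paste0(" for cross ", cross),
      ": FM_corr is undefined."
    ))
  }
  (fm_obs * (1 - md_corr_draws) - fm_c) / (1 - fm_c)
}

# Pair every male-infected cross with the male-uninfected control of the
# same female x male genotype (and female infection state): incompatible
# with compatible_control, rescue with rescue_control.
pair_crosses <- function(records) {
  crosses <- records |>
    distinct(
      .data$female_genotype, .data$male_genotype, .data$female_infected,
      .data$male_infected
    )
  pairs <- crosses |>
    filter(.data$male_infected) |>
    select(-"male_infected") |>
    dplyr::inner_join(
      crosses |> filter(!.data$male_infected) |> select(-"male_infected"),
      by = c("female_genotype", "male_genotype", "female_infected")
    )
  if (!nrow(pairs)) {
    abort("No incompatible/control cross pairs found in the records.")
  }
  pairs
}

#' Posterior draws of the corrected indexes for every cross pair
#'
#' Combines three fitted models (responses `F`, `MD`, `FM`) into per-draw
#' corrected indexes for every incompatible cross and its same-genotype
#' compatible control. Indexes are computed draw by draw and only then
#' summarized; the `MD_corr` draws feed the `FM_corr` formula by sample
#' position. Predictions exclude day intercepts.
#'
#' @param fit_f,fit_md,fit_fm `ci_fit` objects for the three responses,
#'   fitted to the same records with the same MCMC settings.
#' @param records The brood records (used to enumerate the cross pairs).
#' @return An object of class `"ci_index_draws"`: a list with `draws` (tibble
#'   of per-draw `ci_corr`, `md_corr`, `fm_corr` per cross pair) and
#'   `summary` (mean and 9/50/91 percentiles per cross pair and index).
#' @export
ci_index_draws <- function(fit_f, fit_md, fit_fm, records) {
  for (f in list(fit_f, fit_md, fit_fm)) stopifnot(inherits(f, "ci_fit"))
  stopifnot(
    fit_f$spec$response == "F", fit_md$spec$response == "MD",
    fit_fm$spec$response == "FM"
  )
  if (length(unique(c(nrow(fit_f$draws), nrow(fit_md$draws),
    nrow(fit_fm$draws)))) != 1) {
    abort("The three fits must have the same number of posterior draws.")
  }
  pairs <- pair_crosses(records)
  obs_covariates <- pairs |> mutate(male_infected = TRUE)
  ctl_covariates <- pairs |> mutate(male_infected = FALSE)
  draws <- purrr::map(seq_len(nrow(pairs)), function(i) {
    label <- paste0(
      pairs$female_genotype[i], " x ", pairs$male_genotype[i]
    )
    f_obs <- predict_proportion(fit_f, obs_covariates[i, ])[, 1]
    f_c <- predict_proportion(fit_f, ctl_covariates[i, ])[, 1]
    md_obs <- predict_proportion(fit_md, obs_covariates[i, ])[, 1]
    md_c <- predict_proportion(fit_md, ctl_covariates[i, ])[, 1]
    fm_obs <- predict_proportion(fit_fm, obs_covariates[i, ])[, 1]
    fm_c <- predict_proportion(fit_fm, ctl_covariates[i, ])[, 1]
    md <- md_corr(md_obs, md_c, cross = label)
    tibble(
      female_genotype = pairs$female_genotype[i],
      male_genotype = pairs$male_genotype[i],
      female_infected = pairs$female_infected[i],
      .draw = seq_along(f_obs),
      ci_corr = ci_corr(f_obs, f_c, cross = label),
      md_corr = md,
      fm_corr = fm_corr(fm_obs, fm_c, md, cross = label)
    )
  }) |>
    purrr::list_rbind()
  structure(
    list(draws = draws, summary = summarize_index_draws(draws)),
    class = "ci_index_draws"
  )
}

summarize_index_draws <- function(draws) {
  draws |>
    tidyr::pivot_longer(
      c("ci_corr", "md_corr", "fm_corr"),
      names_to = "index", values_to = "value"
    ) |>
    group_by(
      .data$female_genotype, .data$male_genotype, .data$female_infected,
      .data$index
    ) |>
    summarise(
      mean = mean(.data$value),
      q09 = unname(quantile(.data$value, 0.09)),
      q50 = unname(quantile(.data$value, 0.50)),
      q91 = unname(quantile(.data$value, 0.91)),
      .groups = "drop"
    )
}

#' Estimate corrected CI indexes from brood records
#'
#' One-shot pipeline: fits the three full binomial models (`F`, `MD`, `FM`)
#' to the records and returns the corrected-index posterior for every cross
#' pair.
#'
#' @param records Brood records.
#' @param fixed Fixed-effect structure shared by the three fits.
#' @param day_intercepts Include day random intercepts.
#' @inheritParams fit_ci_model
#' @return A `ci_index_draws` object (see [ci_index_draws()]).
#' @export
estimate_ci_indexes <- function(records, fixed = "inf*mgeno*fgeno",
                                day_intercepts = TRUE, chains = 2L,
                                iter = 5000L, warmup = 1000L, seed = 1L) {
  fits <- purrr::map(c("F", "MD", "FM"), function(resp) {
    fit_ci_model(
      records, ci_model_spec(resp, fixed, day_intercepts),
      chains = chains, iter = iter, warmup = warmup, seed = seed
    )
  })
  ci_index_draws(fits[[1]], fits[[2]], fits[[3]], records)
}

#' @export
print.ci_index_draws <- function(x, ...) {
  cat("<ci_index_draws> ", dplyr::n_distinct(paste(
    x$summary$female_genotype, x$summary$male_genotype
  )), " cross pairs, ", max(x$draws$.draw), " draws\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' @rdname tidy.ci_fit
#' @method tidy ci_index_draws
#' @export
tidy.ci_index_draws <- function(x, ...) x$summary

#' Plug-in corrected indexes from pooled counts
#'
#' A non-Bayesian oracle for the corrected indexes: counts are pooled over
#' replicates within each cross type, the raw proportions are substituted
#' into the same three formulas, and one point estimate per cross pair is
#' returned. Used to cross-check the posterior pipeline on large simulated
#' data.
#'
#' @param records Brood records.
#' @return A tibble with one row per cross pair and columns `ci_corr`,
#'   `md_corr`, `fm_corr`.
#' @export
plugin_indexes <- function(records) {
  responses <- derive_responses(records)
  pooled <- responses |>
    group_by(
      .data$female_genotype, .data$male_genotype, .data$female_infected,
      .data$male_infected
    ) |>
    summarise(
      across(c("f_num", "f_den", "md_num", "md_den", "fm_num", "fm_den"), sum),
      .groups = "drop"
    )
  pairs <- pair_crosses(records)
  obs <- pairs |>
    left_join(
      pooled |> filter(.data$male_infected),
      by = c("female_genotype", "male_genotype", "female_infected")
    )
  ctl <- pairs |>
    left_join(
      pooled |> filter(!.data$male_infected),
      by = c("female_genotype", "male_genotype", "female_infected")
    )
  bad <- which(
    is.na(obs$f_den) | is.na(ctl$f_den) | obs$f_den == 0 | ctl$f_den == 0
  )
  if (length(bad)) {
    abort(paste0(
      "Empty cross cell for pair(s): ",
      paste(paste0(pairs$female_genotype[bad], " x ",
        pairs$male_genotype[bad]), collapse = ", ")
    ))
  }
  md <- md_corr(obs$md_num / obs$md_den, ctl$md_num / ctl$md_den)
  pairs |>
    mutate(
      ci_corr = ci_corr(obs$f_num / obs$f_den, ctl$f_num / ctl$f_den),
      md_corr = md,
      fm_corr = fm_corr(
        obs$fm_num / obs$fm_den, ctl$fm_num / ctl$fm_den, md
      )
    )
}
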