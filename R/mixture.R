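#' Fit an ordered two-component binomial mixture to brood MD counts
#'
#' Models the per-brood adult-male counts of single-female F2 crosses as a
#' mixture of two binomial distributions with success probabilities
#' `p_lo < p_hi`, the ordering enforced by construction (the high component's
#' logit is the low component's logit plus a positive increment), so the
#' mixture weight `w` always refers to the high-MD component and label
#' switching is impossible. Under a recessive maternal modifier segregating
#' in a backcross, `w` estimates the fraction of F2 females with the extreme
#' MD phenotype — expected `0.5^k` for `k` jointly required recessive loci.
#'
#' Likelihood per brood `i`:
#' `w * Bin(md_num_i | md_den_i, p_hi) + (1 - w) * Bin(md_num_i | md_den_i, p_lo)`.
#' Priors: `w ~ Uniform(0, 1)`; the base logit and the log of the increment
#' are Normal(0, 1.5).
#'
#' @param broods A data frame of brood records, or any data frame with
#'   `md_num` / `md_den` columns; needs at least 5 broods with positive
#'   denominators.
#' @inheritParams fit_ci_model
#' @return An object of class `"mixture_fit"` with draws of `w`, `p_lo`,
#'   `p_hi`, posterior summaries, diagnostics, a pointwise log-likelihood
#'   matrix (marginalized over component membership), and a
#'   `non_identifiable` flag set when every brood has the same MD proportion.
#' @examples
#' \donttest{
#' broods <- simulate_inheritance(inheritance_params(seed = 2)) |>
#'   dplyr::filter(generation == "F2", cross_class == "incompatible")
#' fit <- fit_binomial_mixture(broods, iter = 1000, warmup = 300, seed = 2)
#' glance(fit)
#' }
#' @export
fit_binomial_mixture <- function(broods, chains = 2L, iter = 5000L,
                                 warmup = 1000L, seed = 1L) {
  if (!all(c("md_num", "md_den") %in% names(broods))) {
    broods <- derive_responses(broods)
  }
  broods <- broods |> filter(.data$md_den > 0)
  if (nrow(broods) < 5) {
    abort("Need at least 5 broods with a positive MD denominator.")
  }
  y <- broods$md_num
  n <- broods$md_den
  if (any(y > n)) abort("md_num may not exceed md_den.")
  non_identifiable <- length(unique(y / n)) == 1
  model_string <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    z[i] ~ dcat(wv[])\n",
    "    y[i] ~ dbin(p[z[i]], n[i])\n",
    "  }\n",
    "  wv[1] <- 1 - w\n",
    "  wv[2] <- w\n",
    "  w ~ dunif(0, 1)\n",
    "  base ~ dnorm(0, ", format(1 / 1.5^2), ")\n",
    "  log_inc ~ dnorm(0, ", format(1 / 1.5^2), ")\n",
    "  p[1] <- ilogit(base)\n",
    "  p[2] <- ilogit(base + exp(log_inc))\n",
    "}\n"
  )
  res <- run_jags(
    model_string, list(y = y, n = n, N = length(y)),
    monitor = c("w", "p"), chains = chains, iter = iter, warmup = warmup,
    seed = seed
  )
  draws <- res$draws
  colnames(draws) <- sub("^p\\[1\\]$", "p_lo", colnames(draws))
  colnames(draws) <- sub("^p\\[2\\]$", "p_hi", colnames(draws))
  draws <- draws[, c("w", "p_lo", "p_hi"), drop = FALSE]
  if (any(!is.finite(draws))) abort("Sampler produced non-finite draws.")
  pointwise <- vapply(
    seq_along(y),
    function(i) {
      log(draws[, "w"] * dbinom(y[i], n[i], draws[, "p_hi"]) +
        (1 - draws[, "w"]) * dbinom(y[i], n[i], draws[, "p_lo"]))
    },
    numeric(nrow(draws))
  )
  diagnostics <- diagnose(draws, chain = res$chain)
  structure(
    list(
      draws = draws, chain = res$chain, pointwise_loglik = pointwise,
      data = tibble(md_num = y, md_den = n),
      diagnostics = diagnostics,
      flagged = any(diagnostics$flagged),
      non_identifiable = non_identifiable,
      mcmc = list(chains = chains, iter = iter, warmup = warmup, seed = seed)
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  s <- quantile(x$draws[, "w"], c(0.09, 0.5, 0.91))
  cat(
    "<mixture_fit> ordered two-binomial mixture, ", nrow(x$data),
    " broods, ", nrow(x$draws), " draws\n",
    "  high-MD weight w: median ", round(s[2], 3), " (q09 ",
    round(s[1], 3), ", q91 ", round(s[3], 3), ")",
    if (x$non_identifiable) "  [NON-IDENTIFIABLE]",
    if (x$flagged) "  [FLAGGED]", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname tidy.ci_fit
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  qs <- apply(x$draws, 2, quantile, probs = c(0.09, 0.5, 0.91))
  tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, sd),
    q09 = qs[1, ], q50 = qs[2, ], q91 = qs[3, ]
  )
}

#' @rdname glance.ci_fit
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    n_broods = nrow(x$data), n_draws = nrow(x$draws),
    w_median = median(x$draws[, "w"]),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess_bulk, na.rm = TRUE),
    flagged = x$flagged, non_identifiable = x$non_identifiable
  )
}

#' Expected extreme-phenotype fraction in a backcross
#'
#' For `k` unlinked recessive modifier loci that are all required for the
#' extreme phenotype, an F2 backcross female is homozygous at each locus
#' independently with probability 1/2, so the expected extreme fraction is
#' `0.5^k` — 0.5 for a monogenic recessive trait.
#'
#' @param k_loci Non-negative integer (vectorized).
#' @return `0.5^k_loci`.
#' @examples
#' expected_extreme_fraction(1:3)
#' @export
expected_extreme_fraction <- function(k_loci) {
  if (!is.numeric(k_loci) || anyNA(k_loci) || any(k_loci < 0) ||
    any(k_loci != floor(k_loci))) {
    abort("`k_loci` must contain non-negative integers.")
  }
  0.5^k_loci
}

#' Rank Mendelian hypotheses for the mixture weight
#'
#' Summarizes the posterior of the high-MD component weight `w` and compares
#' it against the candidate Mendelian expectations `0.5^k` for
#' `k = 1..k_max`: the posterior mass within `tolerance` of each candidate,
#' whether 0.5 (the monogenic recessive expectation) lies inside the
#' 9–91 posterior percentile interval, and the candidate closest to the
#' posterior median. A non-identifiable fit yields a report that declines to
#' rank hypotheses.
#'
#' @param fit A [fit_binomial_mixture()] result.
#' @param k_max Largest locus number considered.
#' @param tolerance Half-width of the posterior-mass band per candidate.
#' @return A list of class `"monogenic_test"` with `w_summary`, `candidates`
#'   (tibble over `k`), `monogenic_supported` (is 0.5 inside q09–q91?) and
#'   `closest_k` (NA when non-identifiable).
#' @export
test_monogenic <- function(fit, k_max = 4L, tolerance = 0.05) {
  stopifnot(inherits(fit, "mixture_fit"))
  w <- fit$draws[, "w"]
  qs <- quantile(w, c(0.09, 0.5, 0.91))
  w_summary <- tibble(
    mean = mean(w), q09 = qs[1], q50 = qs[2], q91 = qs[3]
  )
  candidates <- tibble(
    k = seq_len(k_max),
    expected_w = expected_extreme_fraction(seq_len(k_max))
  ) |>
    mutate(
      posterior_mass = purrr::map_dbl(
        .data$expected_w,
        ~ mean(abs(w - .x) <= tolerance)
      ),
      abs_median_diff = abs(w_summary$q50 - .data$expected_w)
    )
  structure(
    list(
      w_summary = w_summary,
      candidates = candidates,
      monogenic_supported = !fit$non_identifiable &&
        qs[1] <= 0.5 && 0.5 <= qs[3],
      closest_k = if (fit$non_identifiable) NA_integer_ else
        candidates$k[which.min(candidates$abs_median_diff)],
      non_identifiable = fit$non_identifiable
    ),
    class = "monogenic_test"
  )
}

#' @export
print.monogenic_test <- function(x, ...) {
  cat("Ordered binomial mixture: high-MD component weight w\n")
  cat(
    "  median ", round(x$w_summary$q50, 3), " (q09 ",
    round(x$w_summary$q09, 3), ", q91 ", round(x$w_summary$q91, 3), ")\n",
    sep = ""
  )
  if (x$non_identifiable) {
    cat("  Fit is non-identifiable; declining to rank Mendelian hypotheses.\n")
  } else {
    cat(
      "  Monogenic recessive (w = 0.5) ",
      if (x$monogenic_supported) "inside" else "outside",
      " the q09-q91 interval; closest candidate: k = ", x$closest_k, "\n",
      sep = ""
    )
    print(x$candidates, ...)
  }
  invisible(x)
}
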