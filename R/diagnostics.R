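# Rank-normalized split-Rhat and bulk effective sample size, following the
# now-standard definitions (split each chain in half, rank-normalize pooled
# draws through the normal quantile function, then apply the classical
# between/within variance ratio and Geyer's initial-monotone-sequence
# truncation for the autocorrelation time).

split_chain_matrix <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) abort("Need at least 4 draws per chain for split diagnostics.")
  do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[(n - half + 1):n, j])
  }))
}

rank_normalize <- function(m) {
  s <- length(m)
  z <- qnorm((rank(m, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

# FFT autocovariance (biased, divided by n), as used in ESS estimation.
autocovariance <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m
  ac / n
}

rhat_one <- function(draws) {
  z <- rank_normalize(split_chain_matrix(draws))
  n <- nrow(z)
  w <- mean(apply(z, 2, var))
  b <- n * var(colMeans(z))
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_bulk_one <- function(draws) {
  z <- rank_normalize(split_chain_matrix(draws))
  n <- nrow(z)
  m <- ncol(z)
  chain_var <- apply(z, 2, var)
  w <- mean(chain_var)
  if (!is.finite(w) || w == 0) return(NA_real_)
  var_plus <- (n - 1) / n * w + if (m > 1) var(colMeans(z)) else 0
  acov <- rowMeans(sapply(seq_len(m), function(j) autocovariance(z[, j])))
  # rho[k + 1] is the combined-chain autocorrelation at lag k.
  rho <- 1 - (w - acov * n / (n - 1)) / var_plus
  # Geyer: sum successive lag pairs (2k, 2k+1) while the pair sum stays
  # positive, forcing the sequence to be non-increasing.
  pair_sums <- numeric(0)
  k <- 0
  while (2 * k + 2 <= n) {
    p <- rho[2 * k + 1] + rho[2 * k + 2]
    if (is.na(p) || p <= 0) break
    if (length(pair_sums) && p > pair_sums[length(pair_sums)]) {
      p <- pair_sums[length(pair_sums)]
    }
    pair_sums <- c(pair_sums, p)
    k <- k + 1
  }
  tau <- max(-1 + 2 * sum(pair_sums), 1e-8)
  min(n * m / tau, n * m)
}

#' Convergence diagnostics for posterior draws
#'
#' Computes rank-normalized split-\eqn{\widehat{R}} and bulk effective sample
#' size for every parameter of a fitted model (or for a plain draws matrix
#' with a chain index). A parameter is flagged when \eqn{\widehat{R}} exceeds
#' `rhat_max` or the effective sample size falls below `ess_min`. With a
#' single chain \eqn{\widehat{R}} is still defined through the split halves,
#' but between-chain mixing cannot be assessed and a note is attached.
#'
#' @param fit A `ci_fit` or `mixture_fit` object, or a numeric draws matrix.
#' @param chain Integer chain index per draw (rows of the matrix); required
#'   for the matrix method.
#' @param rhat_max,ess_min Flagging thresholds (defaults 1.01 and 400).
#' @return A tibble with columns `parameter`, `rhat`, `ess_bulk`, `flagged`.
#' @examples
#' draws <- cbind(theta = rnorm(2000))
#' diagnose(draws, chain = rep(1:2, each = 1000))
#' @export
diagnose <- function(fit, chain = NULL, rhat_max = 1.01, ess_min = 400) {
  if (inherits(fit, c("ci_fit", "mixture_fit"))) {
    draws <- fit$draws
    chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) abort("`chain` is required for a plain draws matrix.")
  }
  stopifnot(nrow(draws) == length(chain))
  chains <- sort(unique(chain))
  single_chain <- length(chains) < 2
  per_param <- purrr::map(colnames(draws) %||% seq_len(ncol(draws)),
    function(p) {
      m <- sapply(chains, function(ch) draws[chain == ch, p])
      m <- matrix(m, ncol = length(chains))
      tibble(
        parameter = as.character(p),
        # between-chain R-hat needs at least two chains
        rhat = if (single_chain) NA_real_ else rhat_one(m),
        ess_bulk = ess_bulk_one(m)
      )
    }
  ) |>
    purrr::list_rbind() |>
    mutate(flagged = is.na(.data$rhat) | is.na(.data$ess_bulk) |
      .data$rhat > rhat_max | .data$ess_bulk < ess_min)
  if (single_chain) {
    attr(per_param, "note") <-
      "single chain: between-chain R-hat is not assessable"
  }
  per_param
}
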