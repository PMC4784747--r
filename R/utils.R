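# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The five contaminated food categories
#'
#' Canonical category identifiers used throughout the package: sport drinks,
#' tea drinks, juice beverages, fruit jam/nectar/jelly, and health or
#' nutrition supplements.
#'
#' @return Character vector of length 5.
#' @export
food_categories <- function() {
  c("sport_drinks", "tea_drinks", "juice_beverages", "fruit_jam",
    "supplements")
}

#' The two surveying agencies
#'
#' @return Character vector `c("KBOH", "TFDA")` (Kaohsiung Bureau of Health
#'   and Taiwan FDA).
#' @export
agencies <- function() c("KBOH", "TFDA")

## One Dirichlet draw (alpha > 0). Gamma representation.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) return(rep(1 / length(alpha), length(alpha)))
  g / sum(g)
}

## n draws from Normal(mean, sd) truncated below at `lower` (inverse CDF).
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(pmax(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

## Vectorised draws from lognormal(mu, sigma) truncated to [a, b).
## Degenerate sigma collapses to the clamped point mass exp(mu).
rtlnorm <- function(n, mu, sigma, a, b) {
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  deg <- sigma < 1e-8
  if (any(deg)) out[deg] <- pmin(pmax(exp(mu[deg]), a[deg]), b[deg])
  if (any(!deg)) {
    i <- !deg
    plo <- stats::plnorm(a[i], mu[i], sigma[i])
    phi <- stats::plnorm(b[i], mu[i], sigma[i])
    out[i] <- stats::qlnorm(stats::runif(sum(i), plo, phi), mu[i], sigma[i])
  }
  out
}

## Mean of lognormal(mu, sigma) truncated to [a, b); b may be Inf.
## E[Y | a <= Y < b] = exp(mu + s^2/2) *
##   (Phi((log b - mu)/s - s) - Phi((log a - mu)/s - s)) / Z
trunc_lnorm_mean <- function(mu, sigma, a, b) {
  n <- max(length(mu), length(sigma), length(a), length(b))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  deg <- sigma < 1e-8
  if (any(deg)) out[deg] <- pmin(pmax(exp(mu[deg]), a[deg]), b[deg])
  if (any(!deg)) {
    i <- !deg
    s <- sigma[i]; m <- mu[i]
    za <- (log(a[i]) - m) / s
    zb <- ifelse(is.finite(b[i]), (log(b[i]) - m) / s, Inf)
    Z <- stats::pnorm(zb) - stats::pnorm(za)
    num <- stats::pnorm(zb - s) - stats::pnorm(za - s)
    ey <- exp(m + s^2 / 2) * num / Z
    ## numerical guard: Z underflows when the bin is far in a tail
    bad <- !is.finite(ey) | Z < 1e-12
    if (any(bad)) {
      mid <- ifelse(is.finite(b[i]), sqrt(a[i] * b[i]), a[i] * 2)
      ey[bad] <- mid[bad]
    }
    out[i] <- ey
  }
  out
}

## Weighted sample of bin indices, one per row of weight matrix w (n x K).
sample_bins <- function(w) {
  cw <- t(apply(w, 1, cumsum))
  cw <- cw / cw[, ncol(cw)]
  u <- stats::runif(nrow(w))
  rowSums(u > cw) + 1L
}

## set.seed only when a seed is supplied
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

check_probs <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("invalid probability in %s: values must lie in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}
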