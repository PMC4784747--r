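#' Concentration bin scheme
#'
#' Disjoint ppm intervals used for the binned lognormal mixture of detected
#' (tainted) food concentrations. The first edge is the 1-ppm screening
#' level; the last bin is nominally open-ended but truncated at a physical
#' cap so expected concentrations remain bounded even when a bin holds no
#' data and falls back to its prior.
#'
#' @param edges strictly increasing lower bin edges (ppm), first edge 1.
#' @param cap upper truncation of the last bin (ppm); may be `Inf` for
#'   degenerate (point-mass) mixtures.
#' @return An object of class `bin_scheme` with `lower` and `upper` edges.
#' @export
bin_scheme <- function(edges = c(1, 10, 100), cap = 5000) {
  if (length(edges) < 1 || edges[1] != 1 ||
      (length(edges) > 1 && any(diff(edges) <= 0))) {
    stop("edges must be strictly increasing and start at 1 ppm",
         call. = FALSE)
  }
  if (cap <= edges[length(edges)]) stop("cap must exceed the last edge",
                                        call. = FALSE)
  structure(list(lower = edges, upper = c(edges[-1], cap),
                 n_bins = length(edges)),
            class = "bin_scheme")
}

#' MCMC settings
#'
#' @param chains number of independent chains.
#' @param burnin burn-in iterations per chain (with proposal adaptation).
#' @param keep total posterior draws kept across chains after burn-in.
#' @param seed optional RNG seed for the sampler.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, burnin = 5000, keep = 10000,
                        seed = NULL) {
  stopifnot(chains >= 1, burnin >= 0, keep >= chains)
  structure(list(chains = chains, burnin = burnin, keep = keep, seed = seed),
            class = "mcmc_config")
}

## ---- internal likelihoods -------------------------------------------------

## Binomial non-detection log-likelihood; exp(beta) is the TFDA/KBOH
## non-detection odds ratio, alpha the KBOH non-detection logit.
det_loglik <- function(alpha, beta, det, tot, tfda) {
  eta <- alpha + beta * tfda
  ## (tot - det) * log(p_nd) + det * log(1 - p_nd), 0 * log(0) treated as 0
  sum((tot - det) * stats::plogis(eta, log.p = TRUE) +
        det * stats::plogis(-eta, log.p = TRUE))
}

det_logpost <- function(alpha, beta, det, tot, tfda, prior_sd = 10) {
  det_loglik(alpha, beta, det, tot, tfda) +
    stats::dnorm(alpha, 0, prior_sd, log = TRUE) +
    stats::dnorm(beta, 0, prior_sd, log = TRUE)
}

## Truncated-lognormal log-posterior for one bin, parameterised by
## (mu, log sigma); sufficient statistics n, S1 = sum(log y), S2 = sum(log y)^2.
bin_logpost <- function(mu, ls, n, S1, S2, a, b) {
  ## each component describes its own interval: constrain the log-mean to
  ## the bin, which removes the unidentified low-mu/large-sigma ridge that
  ## a flat location prior would otherwise leave under truncation
  if (mu < log(a) || (is.finite(b) && mu > log(b))) return(-Inf)
  s <- exp(ls)
  lp <- stats::dnorm(mu, 0, 10, log = TRUE) +
    stats::dnorm(s, 0, 5, log = TRUE) + log(2) + ls  # half-normal + Jacobian
  if (n > 0) {
    za <- (log(a) - mu) / s
    zb <- if (is.finite(b)) (log(b) - mu) / s else Inf
    Z <- stats::pnorm(zb) - stats::pnorm(za)
    if (Z <= 0) return(-Inf)
    lp <- lp - n * ls - (S2 - 2 * mu * S1 + n * mu^2) / (2 * s^2) -
      n * log(Z)
  }
  lp
}

## Split-chain potential scale reduction (R-hat) from a chains x draws matrix.
split_rhat <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  half <- floor(ncol(mat) / 2)
  if (half < 2) return(NA_real_)
  seqs <- rbind(mat[, seq_len(half), drop = FALSE],
                mat[, half + seq_len(half), drop = FALSE])
  m <- nrow(seqs); n <- ncol(seqs)
  means <- rowMeans(seqs)
  W <- mean(apply(seqs, 1, stats::var))
  B <- n * stats::var(means)
  if (!is.finite(W) || W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## ---- fitting --------------------------------------------------------------

#' Fit the Bayesian DEHP concentration model
#'
#' Fits, independently per food category, the three-part concentration
#' model: (i) a Bernoulli detection submodel on the 1-ppm screen with a
#' logistic agency effect, `logit P(not detected) = alpha + beta I(TFDA)`,
#' so `exp(beta)` is the TFDA/KBOH non-detection odds ratio and the reported
#' detection probability `p_D = 1 - plogis(alpha)` refers to the baseline
#' (KBOH) stratum; (ii) a binned lognormal mixture for detected
#' concentrations, with per-bin lognormal parameters truncated to the bin
#' and Dirichlet(1, ..., 1) weights updated by the quantified bin counts
#' (censored "> 1 ppm" records span all bins and are uninformative about the
#' weights); and (iii) a Beta(1, 1)-prior split of the non-detected mass
#' into a point mass at 0 (`p_0`) and a sub-threshold component on (0, 1)
#' ppm (`p_1`), enforcing `p_D + p_0 + p_1 = 1` in every draw. Priors are
#' weakly informative: Normal(0, 10^2) on logits and log-means,
#' Half-Normal(0, 5) on log-SDs.
#'
#' Sampling is random-walk Metropolis within Gibbs with proposal adaptation
#' during burn-in; convergence is monitored by the split-chain potential
#' scale reduction factor (flagged, not fatal, above 1.1). Values of
#' concentrated juice are divided by `juice_divisor` before fitting.
#' Categories without quantified detections fall back to the mixture priors
#' with a warning.
#'
#' @param records concentration-record data frame (see
#'   [generate_concentration_survey()] for the columns); typically passed
#'   through [merge_product_records()] first.
#' @param bins a [bin_scheme()].
#' @param mcmc an [mcmc_config()].
#' @param juice_divisor dilution ratio applied to concentrated-juice values.
#' @param sub_mean mean of the sub-threshold component on (0, 1) ppm
#'   (uniform, so 0.5).
#' @param split_prior Beta prior parameters of the p_1 share of the
#'   non-detected mass.
#' @return An object of class `conc_fit`: a list with one
#'   `category_posterior` per category plus the scheme and settings.
#'   Methods: [print.conc_fit()], [summary.conc_fit()], [coef.conc_fit()],
#'   [plot.conc_fit()], [simulate.conc_fit()].
#' @seealso [expected_concentrations()], [sample_concentration()]
#' @export
#' @examples
#' cfg <- synth_config()
#' sv <- generate_concentration_survey(cfg, seed = 1)
#' fit <- fit_concentration_model(sv[sv$category == "supplements", ],
#'                                mcmc = mcmc_config(2, 200, 400, seed = 1))
#' summary(fit)
fit_concentration_model <- function(records, bins = bin_scheme(),
                                    mcmc = mcmc_config(),
                                    juice_divisor = 7, sub_mean = 0.5,
                                    split_prior = c(1, 1)) {
  stopifnot(inherits(bins, "bin_scheme"), inherits(mcmc, "mcmc_config"))
  if (nrow(records) == 0) stop("no records to fit", call. = FALSE)
  set_seed_if(mcmc$seed)
  cats <- intersect(food_categories(), unique(records$category))
  if (length(cats) == 0) cats <- unique(records$category)
  posts <- lapply(cats, function(cat) {
    sub <- records[records$category == cat, , drop = FALSE]
    fit_category(sub, cat, bins, mcmc, juice_divisor, sub_mean, split_prior)
  })
  names(posts) <- cats
  structure(list(categories = posts, bins = bins, mcmc = mcmc,
                 juice_divisor = juice_divisor, sub_mean = sub_mean),
            class = "conc_fit")
}

fit_category <- function(records, category, bins, mcmc, juice_divisor,
                         sub_mean, split_prior) {
  K <- bins$n_bins
  tfda <- c(0, 1)
  det <- tot <- numeric(2)
  for (j in 1:2) {
    ag <- agencies()[j]
    sub <- records[records$agency == ag, , drop = FALSE]
    tot[j] <- nrow(sub)
    det[j] <- sum(sub$status %in% c("detected_quantified",
                                    "detected_censored"))
  }
  present <- tot > 0
  y <- records$value_ppm[records$status == "detected_quantified"]
  cc <- records$concentrated_flag[records$status == "detected_quantified"]
  if (category == "juice_beverages" && any(cc)) {
    y[cc] <- y[cc] / juice_divisor
  }
  y <- y[is.finite(y)]
  if (any(y < bins$lower[1])) {
    warning("quantified values below 1 ppm clamped to the first bin")
    y <- pmax(y, bins$lower[1])
  }
  prior_only <- length(y) == 0
  if (prior_only) {
    warning(sprintf("category %s has no quantified detections; %s",
                    category, "mixture parameters fall back to priors"))
  }
  bin_id <- findInterval(pmin(y, bins$upper[K] * 0.999999), bins$lower)
  n_k <- tabulate(bin_id, nbins = K)
  S1 <- vapply(1:K, function(k) sum(log(y[bin_id == k])), numeric(1))
  S2 <- vapply(1:K, function(k) sum(log(y[bin_id == k])^2), numeric(1))

  chains <- mcmc$chains
  keep_pc <- ceiling(mcmc$keep / chains)
  bin_ctr <- log(sqrt(bins$lower * pmin(bins$upper, bins$lower * 100)))
  alpha_c <- beta_c <- array(NA_real_, c(chains, keep_pc))
  mu_c <- sigma_c <- array(NA_real_, c(chains, keep_pc, K))

  for (ch in seq_len(chains)) {
    p_nd0 <- (sum(tot) - sum(det) + 0.5) / (sum(tot) + 1)
    alpha <- stats::qlogis(min(max(p_nd0, 0.02), 0.98)) +
      stats::rnorm(1, 0, 0.5)
    beta <- stats::rnorm(1, 0, 0.5)
    mid <- log(sqrt(bins$lower * pmin(bins$upper,
                                      bins$lower * 10)))
    mu <- mid + stats::rnorm(K, 0, 0.3)
    ls <- log(0.5) + stats::rnorm(K, 0, 0.2)
    lp_det <- det_logpost(alpha, beta, det[present], tot[present],
                          tfda[present])
    lp_bin <- vapply(1:K, function(k)
      bin_logpost(mu[k], ls[k], n_k[k], S1[k], S2[k],
                  bins$lower[k], bins$upper[k]), numeric(1))
    step_a <- 0.4; step_b <- 0.4
    step_bin <- rep(0.3, K); step_mu <- rep(1, K)
    acc_a <- 0; acc_b <- 0; acc_bin <- rep(0, K); acc_mu <- rep(0, K)
    batch <- 0

    n_iter <- mcmc$burnin + keep_pc
    for (it in seq_len(n_iter)) {
      ## detection block: univariate updates, separately tuned (alpha is
      ## data-informed while beta can be prior-dominated and much wider)
      pa <- alpha + stats::rnorm(1, 0, step_a)
      lp2 <- det_logpost(pa, beta, det[present], tot[present],
                         tfda[present])
      if (log(stats::runif(1)) < lp2 - lp_det) {
        alpha <- pa; lp_det <- lp2; acc_a <- acc_a + 1
      }
      pb <- beta + stats::rnorm(1, 0, step_b)
      lp2 <- det_logpost(alpha, pb, det[present], tot[present],
                         tfda[present])
      if (log(stats::runif(1)) < lp2 - lp_det) {
        beta <- pb; lp_det <- lp2; acc_b <- acc_b + 1
      }
      ## mixture bins: mu proposals scale with the current sigma (the
      ## conditional posterior of mu widens with sigma -- funnel geometry);
      ## sigma is unchanged within the mu update, so the proposal stays
      ## symmetric
      for (k in 1:K) {
        pm <- mu[k] + stats::rnorm(1, 0, step_mu[k] * max(exp(ls[k]), 0.05))
        lp2 <- bin_logpost(pm, ls[k], n_k[k], S1[k], S2[k],
                           bins$lower[k], bins$upper[k])
        if (log(stats::runif(1)) < lp2 - lp_bin[k]) {
          mu[k] <- pm; lp_bin[k] <- lp2
          acc_mu[k] <- acc_mu[k] + 1
        }
        pl <- ls[k] + stats::rnorm(1, 0, step_bin[k])
        lp2 <- bin_logpost(mu[k], pl, n_k[k], S1[k], S2[k],
                           bins$lower[k], bins$upper[k])
        if (log(stats::runif(1)) < lp2 - lp_bin[k]) {
          ls[k] <- pl; lp_bin[k] <- lp2
          acc_bin[k] <- acc_bin[k] + 1
        }
        ## ridge move: within a bounded bin (mu, sigma) are identified only
        ## through the density shape inside the bin, leaving a scaling ridge;
        ## stretch both about the bin centre (Jacobian e^eps from the mu map)
        eps <- stats::rnorm(1, 0, 0.3)
        ctr <- bin_ctr[k]
        pm <- ctr + (mu[k] - ctr) * exp(eps)
        pl <- ls[k] + eps
        lp2 <- bin_logpost(pm, pl, n_k[k], S1[k], S2[k],
                           bins$lower[k], bins$upper[k])
        if (log(stats::runif(1)) < lp2 - lp_bin[k] + eps) {
          mu[k] <- pm; ls[k] <- pl; lp_bin[k] <- lp2
        }
      }
      batch <- batch + 1
      if (it <= mcmc$burnin && batch == 50) {
        step_a <- min(max(step_a * exp(acc_a / 50 - 0.4), 0.02), 20)
        step_b <- min(max(step_b * exp(acc_b / 50 - 0.4), 0.02), 20)
        step_bin <- pmin(pmax(step_bin * exp(acc_bin / 50 - 0.4), 0.02), 20)
        step_mu <- pmin(pmax(step_mu * exp(acc_mu / 50 - 0.4), 0.02), 20)
        acc_a <- 0; acc_b <- 0; acc_bin[] <- 0; acc_mu[] <- 0; batch <- 0
      }
      if (it > mcmc$burnin) {
        j <- it - mcmc$burnin
        alpha_c[ch, j] <- alpha; beta_c[ch, j] <- beta
        mu_c[ch, j, ] <- mu; sigma_c[ch, j, ] <- exp(ls)
      }
    }
  }

  rhat <- c(alpha = split_rhat(alpha_c), beta = split_rhat(beta_c),
    stats::setNames(vapply(1:K, function(k) split_rhat(mu_c[, , k]),
                           numeric(1)), paste0("mu", 1:K)),
    stats::setNames(vapply(1:K, function(k) split_rhat(sigma_c[, , k]),
                           numeric(1)), paste0("sigma", 1:K)))
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning(sprintf("category %s: split R-hat above 1.1 (max %.2f)%s",
                    category, max(rhat, na.rm = TRUE),
                    "; inspect convergence"))
  }

  n <- chains * keep_pc
  alpha_d <- as.vector(t(alpha_c)); beta_d <- as.vector(t(beta_c))
  mu_d <- matrix(NA_real_, n, K); sigma_d <- matrix(NA_real_, n, K)
  for (k in 1:K) {
    mu_d[, k] <- as.vector(t(mu_c[, , k]))
    sigma_d[, k] <- as.vector(t(sigma_c[, , k]))
  }
  w_d <- t(vapply(seq_len(n), function(i) rdirichlet1(1 + n_k),
                  numeric(K)))
  u_d <- stats::rbeta(n, split_prior[1], split_prior[2])

  draws <- derive_draws(alpha_d, beta_d, u_d, w_d, mu_d, sigma_d, bins,
                        sub_mean)
  structure(list(
    category = category, draws = draws, rhat = rhat, bins = bins,
    sub_mean = sub_mean, prior_only = prior_only,
    counts = list(detected = stats::setNames(det, agencies()),
                  total = stats::setNames(tot, agencies()),
                  quantified_per_bin = n_k,
                  censored = sum(records$status == "detected_censored"))
  ), class = "category_posterior")
}

## Assemble the draws data frame with all derived quantities.
derive_draws <- function(alpha, beta, u, w, mu, sigma, bins, sub_mean) {
  n <- length(alpha); K <- bins$n_bins
  p_nd <- stats::plogis(alpha)
  p_d <- 1 - p_nd
  p_1 <- p_nd * u
  p_0 <- p_nd * (1 - u)
  m <- matrix(NA_real_, n, K)
  for (k in 1:K) {
    m[, k] <- trunc_lnorm_mean(mu[, k], sigma[, k], bins$lower[k],
                               bins$upper[k])
  }
  e_y <- rowSums(w * m)
  e_c <- p_d * e_y + p_1 * sub_mean
  draws <- data.frame(alpha = alpha, beta = beta, p_d = p_d, p_0 = p_0,
                      p_1 = p_1, u = u, e_y = e_y, e_c = e_c)
  for (k in 1:K) {
    draws[[paste0("w", k)]] <- w[, k]
    draws[[paste0("mu", k)]] <- mu[, k]
    draws[[paste0("sigma", k)]] <- sigma[, k]
  }
  draws
}

#' Construct a category posterior from explicit draws
#'
#' Builds a `category_posterior` directly from supplied (possibly
#' degenerate) parameter values, bypassing MCMC. Useful for point-mass
#' posteriors in deterministic checks and for sampling from published
#' summary estimates.
#'
#' @param p_d detection probability draw(s).
#' @param beta agency log-odds draw(s) (default 0).
#' @param w mixture weights: vector of length K (constant over draws).
#' @param mu,sigma per-bin lognormal parameters (length K).
#' @param p_1 sub-threshold mass draw(s); must satisfy `p_d + p_1 <= 1`.
#' @param bins a [bin_scheme()]; defaults to a single unbounded bin when
#'   K = 1.
#' @param sub_mean sub-threshold component mean (ppm).
#' @param n_draws number of draws (values recycled).
#' @return A `category_posterior` object.
#' @export
#' @examples
#' post <- category_posterior(p_d = 0.5, w = 1, mu = log(10), sigma = 0)
#' expected_concentrations(post)  # E(Y) = 10, E(C) = 5
category_posterior <- function(p_d, beta = 0, w = 1, mu = log(10),
                               sigma = 0, p_1 = 0, bins = NULL,
                               sub_mean = 0.5, n_draws = NULL) {
  K <- length(mu)
  stopifnot(length(sigma) == K, length(w) == K)
  if (is.null(bins)) {
    if (K != 1) stop("bins required for multi-bin posteriors", call. = FALSE)
    bins <- bin_scheme(edges = 1, cap = Inf)
  }
  if (any(p_d + p_1 > 1 + 1e-12) || any(p_d < 0) || any(p_1 < 0)) {
    stop("p_d + p_1 must lie in [0, 1]", call. = FALSE)
  }
  n <- n_draws %||% max(length(p_d), length(p_1), length(beta))
  p_d <- rep_len(p_d, n); p_1 <- rep_len(p_1, n); beta <- rep_len(beta, n)
  p_nd <- 1 - p_d
  u <- ifelse(p_nd > 0, p_1 / p_nd, 0)
  alpha <- stats::qlogis(pmin(pmax(p_nd, 1e-12), 1 - 1e-12))
  w_m <- matrix(w / sum(w), n, K, byrow = TRUE)
  mu_m <- matrix(mu, n, K, byrow = TRUE)
  sigma_m <- matrix(sigma, n, K, byrow = TRUE)
  draws <- derive_draws(alpha, beta, u, w_m, mu_m, sigma_m, bins, sub_mean)
  structure(list(category = "manual", draws = draws, rhat = NULL,
                 bins = bins, sub_mean = sub_mean, prior_only = FALSE,
                 counts = NULL),
            class = "category_posterior")
}

## Resolve a category_posterior from a conc_fit or pass one through.
resolve_posterior <- function(post, category = NULL) {
  if (inherits(post, "conc_fit")) {
    if (is.null(category) || !category %in% names(post$categories)) {
      stop("specify a fitted category", call. = FALSE)
    }
    post <- post$categories[[category]]
  }
  if (!inherits(post, "category_posterior")) {
    stop("not a category posterior", call. = FALSE)
  }
  post
}

#' Expected concentration composition
#'
#' The expected overall-category concentration given the model components:
#' `E(C) = p_D * E(Y) + p_1 * sub_mean`, where `E(Y)` is the expected
#' tainted-food concentration and the sub-threshold component on (0, 1) ppm
#' has mean `sub_mean` (uniform: 0.5).
#'
#' @param p_d detection probability.
#' @param e_y expected tainted-food concentration (ppm).
#' @param p_1 sub-threshold probability mass.
#' @param sub_mean sub-threshold component mean (ppm).
#' @return E(C) in ppm (vectorised).
#' @export
#' @examples
#' ec_composition(0.042, 19.1, 0.013)  # tea drinks: ~0.81 ppm
ec_composition <- function(p_d, e_y, p_1, sub_mean = 0.5) {
  p_d * e_y + p_1 * sub_mean
}

#' Expected tainted-food and overall concentrations
#'
#' Posterior mean and central 95% interval of `E(Y)` (expected DEHP
#' concentration of tainted foods, ppm) and `E(C)` (expected concentration
#' over all foods of the category, including non-detected mass), computed
#' from the per-draw mixture means.
#'
#' @param post a `category_posterior`, or a `conc_fit` with `category`.
#' @param category category name when `post` is a `conc_fit`.
#' @return List with numeric vectors `e_y` and `e_c`, each
#'   `c(mean, lo95, hi95)`.
#' @export
expected_concentrations <- function(post, category = NULL) {
  post <- resolve_posterior(post, category)
  d <- post$draws
  if (is.null(d) || nrow(d) == 0) stop("empty posterior", call. = FALSE)
  s <- function(x) c(mean = mean(x),
                     lo95 = unname(stats::quantile(x, 0.025)),
                     hi95 = unname(stats::quantile(x, 0.975)))
  list(e_y = s(d$e_y), e_c = s(d$e_c))
}

#' Sample exposure concentrations given an exposure belief
#'
#' Draws DEHP concentrations (ppm) for a participant-category scenario.
#' With belief `"yes"` (certain exposure, including self-reports) values
#' come from the tainted-food mixture, whose mean is `E(Y)`. With `"unsure"`
#' values come from the overall category distribution: zero with
#' probability `p_0`, uniform on (0, 1) ppm with probability `p_1`, and the
#' tainted mixture with probability `p_D` -- mean `E(C)`. With `"no"` all
#' draws are zero. Posterior uncertainty is propagated by resampling
#' posterior draws with replacement.
#'
#' @param post a `category_posterior`, or a `conc_fit` with `category`.
#' @param belief `"yes"`, `"unsure"` or `"no"`.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @param category category name when `post` is a `conc_fit`.
#' @return Numeric vector of `n` concentration draws (ppm).
#' @export
sample_concentration <- function(post, belief, n, seed = NULL,
                                 category = NULL) {
  post <- resolve_posterior(post, category)
  if (!belief %in% c("yes", "unsure", "no")) {
    stop("unknown belief level", call. = FALSE)
  }
  set_seed_if(seed)
  if (belief == "no") return(numeric(n))
  d <- post$draws
  K <- post$bins$n_bins
  idx <- sample.int(nrow(d), n, replace = TRUE)
  w <- as.matrix(d[idx, paste0("w", 1:K), drop = FALSE])
  mu <- as.matrix(d[idx, paste0("mu", 1:K), drop = FALSE])
  sigma <- as.matrix(d[idx, paste0("sigma", 1:K), drop = FALSE])
  bin <- sample_bins(w)
  sel <- cbind(seq_len(n), bin)
  tainted <- rtlnorm(n, mu[sel], sigma[sel], post$bins$lower[bin],
                     post$bins$upper[bin])
  if (belief == "yes") return(tainted)
  r <- stats::runif(n)
  out <- numeric(n)
  sub <- r < d$p_1[idx]
  taint <- r >= d$p_1[idx] & r < d$p_1[idx] + d$p_d[idx]
  out[sub] <- stats::runif(sum(sub), 0, 1)
  out[taint] <- tainted[taint]
  out
}
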