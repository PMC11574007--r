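# Internal MCMC machinery for the Gaussian hierarchical trajectory model.
#
# Model: y = X beta + Z u + e,  u_f ~ N(0, sigma_f^2),  e ~ N(0, sigma_e^2)
# Priors: beta_j ~ N(0, 10^2) on the standardized predictor scale,
#         sigma_f, sigma_e ~ half-Normal(0, 5).
# beta and u have conjugate Gaussian full conditionals; the two SDs are
# updated by univariate slice sampling on the log scale (half-Normal priors
# are not conjugate).

# univariate slice sampler with stepping out (Neal 2003)
slice_sample1 <- function(x0, logf, w = 0.5, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# one chain of the Gibbs sampler; returns post-warmup draws (raw scale)
run_chain <- function(y, Xs, fam_idx, n_fam, warmup, iter_keep,
                      prior_sd_beta, prior_sd_scale, center, scale_) {
  n <- length(y); p <- ncol(Xs)
  XtX <- crossprod(Xs)
  prior_prec <- diag(1 / prior_sd_beta^2, p)
  fam_n <- tabulate(fam_idx, n_fam)

  # initialization: ridge LS + dispersed jitter
  beta <- drop(solve(XtX + diag(1e-6, p), crossprod(Xs, y)))
  beta <- beta + rnorm(p, 0, 0.1 * (1 + abs(beta)))
  u <- rnorm(n_fam, 0, 0.05)
  sigma_e <- sd(y - Xs %*% beta) * exp(rnorm(1, 0, 0.2))
  if (!is.finite(sigma_e) || sigma_e <= 0) sigma_e <- 1
  sigma_f <- 0.5 * sigma_e

  keep <- matrix(NA_real_, iter_keep, p + 2)
  total <- warmup + iter_keep
  for (it in seq_len(total)) {
    ## beta | .
    r_u <- y - u[fam_idx]
    prec <- XtX / sigma_e^2 + prior_prec
    ch <- chol(prec)
    m <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, r_u) / sigma_e^2))
    beta <- drop(m + backsolve(ch, rnorm(p)))

    ## u | .
    r_b <- y - drop(Xs %*% beta)
    s_fam <- rowsum(r_b, fam_idx, reorder = TRUE)
    prec_u <- fam_n / sigma_e^2 + 1 / sigma_f^2
    u <- rnorm(n_fam, drop(s_fam) / sigma_e^2 / prec_u, sqrt(1 / prec_u))

    ## scale parameters | .
    ssr <- sum((r_b - u[fam_idx])^2)
    ls_e <- slice_sample1(log(sigma_e), function(ls) {
      -(n - 1) * ls - ssr / (2 * exp(2 * ls)) -
        exp(2 * ls) / (2 * prior_sd_scale^2)
    })
    sigma_e <- exp(ls_e)
    ssu <- sum(u^2)
    ls_f <- slice_sample1(log(sigma_f), function(ls) {
      -(n_fam - 1) * ls - ssu / (2 * exp(2 * ls)) -
        exp(2 * ls) / (2 * prior_sd_scale^2)
    })
    sigma_f <- exp(ls_f)

    ## interweaving (ASIS) step for sigma_f: in the non-centered
    ## parameterization u = sigma_f * z, the conditional for sigma_f is a
    ## Gaussian regression coefficient, which decorrelates the scale from
    ## the family effects and fixes its otherwise slow mixing
    z <- u / sigma_f
    wz <- z[fam_idx]
    prec_s <- sum(wz^2) / sigma_e^2 + 1 / prior_sd_scale^2
    mean_s <- sum(wz * r_b) / sigma_e^2 / prec_s
    a <- rnorm(1, mean_s, sqrt(1 / prec_s))
    sigma_f <- max(abs(a), 1e-8)
    u <- a * z

    if (it > warmup) {
      # back-transform standardized coefficients to the raw predictor scale
      braw <- beta
      if (p > 1) {
        braw[-1] <- beta[-1] / scale_[-1]
        braw[1] <- beta[1] - sum(beta[-1] * center[-1] / scale_[-1])
      }
      keep[it - warmup, ] <- c(braw, sigma_f, sigma_e)
    }
  }
  keep
}

# split-Rhat (Gelman et al. 2013): split each chain in half, compute the
# classic potential scale reduction over the 2C half-chains
split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (ch in draws_by_chain) {
    m <- length(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

fit_bayes_lmm <- function(y, X, family, chains = 4L, warmup = 500L,
                          draws = 1000L, seed = 1L,
                          prior_sd_beta = 10, prior_sd_scale = 5) {
  stopifnot(length(y) == nrow(X), length(family) == length(y))
  fam_f <- factor(family)
  fam_idx <- as.integer(fam_f)
  n_fam <- nlevels(fam_f)

  # standardize non-intercept columns (prior scale is standardized scale)
  center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  Xs <- X
  for (j in seq_len(ncol(X))[-1]) {
    center[j] <- mean(X[, j])
    s <- sd(X[, j])
    scale_[j] <- if (is.finite(s) && s > 0) s else 1
    Xs[, j] <- (X[, j] - center[j]) / scale_[j]
  }

  par_names <- c(colnames(X), "sd_family", "sd_residual")
  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed * 1000L + ch)
    chain_draws[[ch]] <- run_chain(y, Xs, fam_idx, n_fam, warmup, draws,
                                   prior_sd_beta, prior_sd_scale,
                                   center, scale_)
    colnames(chain_draws[[ch]]) <- par_names
  }

  all_draws <- do.call(rbind, chain_draws)
  rhat <- vapply(par_names, function(pn) {
    split_rhat(lapply(chain_draws, function(m) m[, pn]))
  }, numeric(1))
  ess <- vapply(par_names, function(pn) {
    sum(vapply(chain_draws, function(m) {
      unname(coda::effectiveSize(coda::mcmc(m[, pn])))
    }, numeric(1)))
  }, numeric(1))

  list(draws = all_draws, chain_draws = chain_draws,
       rhat = rhat, ess = ess,
       chains = chains, warmup = warmup, draws_per_chain = draws,
       n_obs = length(y), n_family = n_fam, seed = seed)
}
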