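# Independent oracle implementations used to cross-check the package.
# These are written directly from the published formulas and share no code
# with the implementation paths they verify.

# --- brute-force moderated t-statistic oracle -------------------------------
# Per-gene weighted least squares on a design matrix, residual variances
# shrunk toward a common prior estimated by the method of moments on
# log-variances (scaled-F model), moderated t and two-sided p-values.

oracle_trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  repeat {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

# method-of-moments fit of the scaled F model to sample variances s2 with
# df residual degrees of freedom; returns prior df and prior variance
oracle_fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * oracle_trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion beyond chi-square: infinitely strong prior at
    # the pooled average variance
    df_prior <- Inf
    s2_prior <- mean(s2)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# y: genes x samples; w: weights (same shape); x: group indicator (0/1)
# coef of interest: the indicator's slope
oracle_moderated_t <- function(y, w, x, df_prior = NULL) {
  n <- ncol(y)
  X <- cbind(1, x)
  p <- ncol(X)
  beta <- sigma2 <- su <- numeric(nrow(y))
  for (g in seq_len(nrow(y))) {
    W <- diag(w[g, ])
    XtWX <- t(X) %*% W %*% X
    XtWXi <- solve(XtWX)
    b <- XtWXi %*% t(X) %*% W %*% y[g, ]
    res <- y[g, ] - X %*% b
    sigma2[g] <- sum(w[g, ] * res^2) / (n - p)
    beta[g] <- b[2]
    su[g] <- sqrt(XtWXi[2, 2])
  }
  df_resid <- n - p
  if (is.null(df_prior)) {
    fit <- oracle_fit_f_dist(sigma2, df_resid)
    df_prior <- fit$df_prior
    s2_prior <- fit$s2_prior
  } else {
    s2_prior <- mean(sigma2)
  }
  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(sigma2)) else
    (df_prior * s2_prior + df_resid * sigma2) / (df_prior + df_resid)
  t_mod <- beta / (su * sqrt(s2_post))
  df_total <- min(df_resid + df_prior, nrow(y) * df_resid)
  p_mod <- 2 * stats::pt(-abs(t_mod), df = df_total)
  t_classic <- beta / (su * sqrt(sigma2))
  list(log2_fc = beta, t_mod = t_mod, p_value = p_mod,
       adj_p_value = oracle_bh(p_mod), t_classic = t_classic,
       df_prior = df_prior, s2_post = s2_post)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- dense simplex grid search oracle for constrained least squares --------
# Enumerates the simplex at the given step and returns the grid point
# minimizing ||S f - m||^2.

simplex_grid <- function(k, step) {
  ticks <- seq(0, 1, by = step)
  if (k == 2) {
    cbind(ticks, 1 - ticks)
  } else if (k == 3) {
    g <- expand.grid(f1 = ticks, f2 = ticks)
    g <- g[g$f1 + g$f2 <= 1 + 1e-12, ]
    cbind(g$f1, g$f2, pmax(1 - g$f1 - g$f2, 0))
  } else {
    stop("grid oracle supports k = 2 or 3")
  }
}

oracle_qp_grid <- function(S, m, step = 1e-3, grid = NULL) {
  k <- ncol(S)
  if (is.null(grid)) grid <- simplex_grid(k, step)
  D <- crossprod(S)
  d <- drop(crossprod(S, m))
  obj <- rowSums((grid %*% D) * grid) - 2 * drop(grid %*% d)
  grid[which.min(obj), ]
}

# --- tiny simulation configs shared across tests ---------------------------

tiny_sim_config <- function(seed = 11L) {
  sim_config(n_cell_types = 4L, n_genes = 120L, markers_per_type = 5L,
             replicates_per_type = 3L, n_mixtures = 5L,
             tumor_fractions = c(0, 0.5), noise_sd_log2 = 0.05, seed = seed)
}

# small full-rank signature + simplex fractions for solver tests
toy_system <- function(n_genes = 60, k = 4, seed = 5) {
  withr::with_seed(seed, {
    S <- matrix(stats::rlnorm(n_genes * k, log(50), 1), n_genes, k,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                paste0("ct", seq_len(k))))
    f <- stats::rgamma(k, 1)
  })
  list(S = S, f = f / sum(f))
}
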