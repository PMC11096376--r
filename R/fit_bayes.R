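# Bayesian backend: blocked Gibbs sampler for the same mixed model as
# the REML backend.
#
# Priors: Normal(0, prior_beta_sd^2) on (standardized) coefficients;
# half-Student-t(prior_sd_df, 0, prior_sd_scale) on every standard
# deviation, implemented by the Huang-Wand (2013) inverse-gamma mixture
#   s2 | a ~ IG(nu/2, nu/a),  a ~ IG(1/2, 1/A^2)
# which keeps every full conditional conjugate. Defaults: four chains,
# 10,000 iterations, first 1000 discarded per chain, equal-tailed 95%
# credible intervals, split-Rhat convergence checks (< 1.1).

fit_bayes <- function(mm, phylo, control) {
  y <- mm$y
  X <- mm$X
  n <- length(y)
  p <- ncol(X)
  comps <- re_design(mm, phylo, control$re)
  k <- length(comps)
  nu <- control$prior_sd_df
  A2 <- control$prior_sd_scale^2
  sb2 <- control$prior_beta_sd^2
  seed <- control$seed %||% 1L

  XtX <- crossprod(X)
  Sx <- stats::cov(X) * (n - 1) / n        # population cov of X columns
  fidx <- lapply(comps, function(cm) as.integer(cm$factor))
  counts <- lapply(comps, function(cm) as.numeric(table(cm$factor)))
  qs <- vapply(counts, length, 0L)
  Cinv <- lapply(comps, function(cm) {
    if (is.null(cm$corr)) NULL
    else chol2inv(chol(cm$corr + diag(1e-8, nrow(cm$corr))))
  })

  n_iter <- control$iter
  n_burn <- control$burnin
  n_keep <- n_iter - n_burn
  n_chains <- control$chains
  if (n_keep < 2) stop("iter must exceed burnin")

  beta_draws <- array(NA_real_, c(n_keep, n_chains, p))
  s2_draws <- array(NA_real_, c(n_keep, n_chains, k + 1))
  r2_draws <- array(NA_real_, c(n_keep, n_chains, 2))

  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch)
    beta <- rep(0, p)
    u <- lapply(qs, function(qk) rep(0, qk))
    s2 <- rep(0.5, k)
    s2e <- 0.5
    a <- rep(1, k)
    ae <- 1
    fit_u <- function() {
      out <- rep(0, n)
      for (i in seq_len(k)) out <- out + u[[i]][fidx[[i]]]
      out
    }
    uf <- fit_u()

    for (it in seq_len(n_iter)) {
      # beta
      Qb <- XtX / s2e
      diag(Qb) <- diag(Qb) + 1 / sb2
      Rb <- chol(Qb)
      bb <- crossprod(X, y - uf) / s2e
      mu <- backsolve(Rb, backsolve(Rb, bb, transpose = TRUE))
      beta <- drop(mu + backsolve(Rb, stats::rnorm(p)))
      xb <- drop(X %*% beta)

      # random-effect blocks
      for (i in seq_len(k)) {
        r <- y - xb - (uf - u[[i]][fidx[[i]]])
        sums <- drop(rowsum(r, fidx[[i]], reorder = TRUE))
        if (is.null(Cinv[[i]])) {
          prec <- counts[[i]] / s2e + 1 / s2[i]
          mu_u <- (sums / s2e) / prec
          u[[i]] <- stats::rnorm(qs[i], mu_u, sqrt(1 / prec))
        } else {
          Q <- Cinv[[i]] / s2[i]
          diag(Q) <- diag(Q) + counts[[i]] / s2e
          Rq <- chol(Q)
          mu_u <- backsolve(Rq, backsolve(Rq, sums / s2e, transpose = TRUE))
          u[[i]] <- drop(mu_u + backsolve(Rq, stats::rnorm(qs[i])))
        }
        uf <- fit_u()
      }

      # residual variance
      resid <- y - xb - uf
      s2e <- 1 / stats::rgamma(1, nu / 2 + n / 2,
                               nu / ae + sum(resid^2) / 2)
      ae <- 1 / stats::rgamma(1, (nu + 1) / 2, nu / s2e + 1 / A2)

      # component variances
      for (i in seq_len(k)) {
        quad <- if (is.null(Cinv[[i]])) sum(u[[i]]^2)
                else drop(crossprod(u[[i]], Cinv[[i]] %*% u[[i]]))
        s2[i] <- 1 / stats::rgamma(1, nu / 2 + qs[i] / 2,
                                   nu / a[i] + quad / 2)
        a[i] <- 1 / stats::rgamma(1, (nu + 1) / 2, nu / s2[i] + 1 / A2)
      }

      if (it > n_burn) {
        j <- it - n_burn
        beta_draws[j, ch, ] <- beta
        s2_draws[j, ch, ] <- c(s2, s2e)
        vf <- drop(crossprod(beta, Sx %*% beta))
        tot <- vf + sum(s2) + s2e
        r2_draws[j, ch, ] <- c(vf / tot, (vf + sum(s2)) / tot)
      }
    }
  }

  flat <- function(arr, j) as.vector(arr[, , j])
  beta_hat <- vapply(seq_len(p), function(j) mean(flat(beta_draws, j)), 0)
  ci <- vapply(seq_len(p), function(j) {
    stats::quantile(flat(beta_draws, j), c(0.025, 0.975), names = FALSE)
  }, numeric(2))
  rhat_beta <- vapply(seq_len(p), function(j) {
    gelman_rubin(beta_draws[, , j, drop = TRUE])
  }, 0)
  rhat_s2 <- vapply(seq_len(k + 1), function(j) {
    gelman_rubin(s2_draws[, , j, drop = TRUE])
  }, 0)

  sigma2 <- stats::setNames(rep(0, length(RE_NAMES)), RE_NAMES)
  if (k) sigma2[names(comps)] <-
    vapply(seq_len(k), function(j) mean(flat(s2_draws, j)), 0)
  nm <- colnames(X)
  rhat_all <- c(stats::setNames(rhat_beta, nm),
                stats::setNames(rhat_s2, c(names(comps), "resid")))

  lp <- drop(X %*% beta_hat)
  list(
    backend = "bayes",
    beta = stats::setNames(beta_hat, nm),
    se = stats::setNames(vapply(seq_len(p), function(j) {
      stats::sd(flat(beta_draws, j))
    }, 0), nm),
    lower = stats::setNames(ci[1, ], nm),
    upper = stats::setNames(ci[2, ], nm),
    p_value = stats::setNames(rep(NA_real_, p), nm),
    sigma2 = c(sigma2, resid = mean(flat(s2_draws, k + 1))),
    var_fixed = mean((lp - mean(lp))^2),
    R2_draws = c(marginal = mean(flat(r2_draws, 1)),
                 conditional = mean(flat(r2_draws, 2))),
    rhat = rhat_all,
    converged = all(rhat_all < 1.1, na.rm = TRUE),
    n_obs = n, df = NA_real_
  )
}

#' Gelman-Rubin split-Rhat convergence diagnostic
#'
#' Each chain is split in half, then Rhat is the usual
#' between/within-chain variance ratio over the split chains. Values
#' near 1 indicate convergence; the pipeline's threshold is 1.1.
#' Chains that are all equal to the same constant return 1 by the limit
#' convention.
#'
#' @param draws matrix of posterior draws, iterations x chains (>= 2
#'   chains, equal lengths).
#' @return scalar Rhat.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("need at least 2 chains")
  half <- floor(nrow(draws) / 2)
  if (half < 2) stop("chains too short to split")
  split_chains <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])
  }))
  m <- ncol(split_chains)
  n <- nrow(split_chains)
  means <- colMeans(split_chains)
  vars <- apply(split_chains, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}
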