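# Likelihood backend: REML for the Gaussian mixed model
#
#   y = X beta + u_phylo + u_species + u_paper(species) + u_year + eps
#
# with u_phylo ~ N(0, s2_phylo * C_corr) across species (Brownian
# correlation, lambda fixed at 1) and the other random intercepts
# i.i.d. The marginal covariance is V = s2_e (I + sum_k gamma_k Z_k G_k
# Z_k'), gamma_k = s2_k / s2_e. The REML criterion is evaluated through
# the Woodbury identity on the q x q inner matrix (q = total random
# levels), which is much smaller than n, so each evaluation costs one
# q x q Cholesky. Variance ratios are optimized on the log scale.

# Shared random-effect design for both backends. Components with fewer
# than two levels cannot carry a variance and are dropped with a note.
re_design <- function(mm, phylo, re = c("phylo", "species", "paper", "year")) {
  comps <- list()
  need_phylo <- "phylo" %in% re || "species" %in% re
  f_sp <- mm$groups$species
  if (need_phylo && nlevels(f_sp) < 2) {
    stop("need at least 2 species for species-level random effects")
  }
  Cc <- NULL
  if ("phylo" %in% re) {
    if (is.null(phylo)) stop("phylo covariance required for phylo effect")
    missing <- setdiff(levels(f_sp), phylo$species)
    if (length(missing)) {
      stop("species missing from phylogeny: ",
           paste(missing, collapse = ", "))
    }
    Cc <- phylo$C_corr[levels(f_sp), levels(f_sp)]
    comps$phylo <- list(name = "phylo", factor = f_sp, corr = Cc)
  }
  if ("species" %in% re) {
    comps$species <- list(name = "species", factor = f_sp, corr = NULL)
  }
  for (nm in intersect(c("paper", "year"), re)) {
    f <- droplevels(mm$groups[[nm]])
    if (nlevels(f) < 2) {
      msg("random effect '", nm, "' has a single level; dropped")
      next
    }
    comps[[nm]] <- list(name = nm, factor = f, corr = NULL)
  }
  comps
}

indicator_matrix <- function(f) {
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  colnames(Z) <- levels(f)
  Z
}

RE_NAMES <- c("phylo", "species", "paper", "year")

fit_reml <- function(mm, phylo, control) {
  y <- mm$y
  X <- mm$X
  n <- length(y)
  p <- ncol(X)
  comps <- re_design(mm, phylo, control$re)
  k <- length(comps)

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)

  if (k == 0) {
    # no random structure: ordinary least squares
    cX <- chol(XtX)
    beta <- backsolve(cX, backsolve(cX, Xty, transpose = TRUE))
    rss <- yty - sum(beta * Xty)
    s2 <- rss / (n - p)
    vcov_beta <- s2 * chol2inv(cX)
    return(finish_reml(mm, beta, vcov_beta, s2, numeric(0), comps,
                       converged = TRUE, X = X))
  }

  Zs <- lapply(comps, function(cm) indicator_matrix(cm$factor))
  q_each <- vapply(Zs, ncol, 0L)
  Z <- do.call(cbind, Zs)
  q <- ncol(Z)
  comp_rows <- split(seq_len(q), rep(seq_len(k), q_each))
  Ls <- lapply(comps, function(cm) {
    if (is.null(cm$corr)) NULL
    else t(chol(cm$corr + diag(1e-8, nrow(cm$corr))))
  })

  ZtZ <- crossprod(Z)
  ZtX <- crossprod(Z, X)
  Zty <- crossprod(Z, y)

  # With K = blockdiag(sqrt(gamma_k) L_k) and L_k = I except for the
  # correlated (phylo) block, Kt A K = D (Lt A L) D where D scales each
  # row by sqrt(gamma) of its component. Pre-apply the L factors once
  # so each objective evaluation is elementwise scaling plus one
  # Cholesky of the q x q inner matrix.
  for (i in seq_len(k)) {
    if (!is.null(Ls[[i]])) {
      r <- comp_rows[[i]]
      ZtZ[r, ] <- crossprod(Ls[[i]], ZtZ[r, , drop = FALSE])
      ZtZ[, r] <- ZtZ[, r, drop = FALSE] %*% Ls[[i]]
      ZtX[r, ] <- crossprod(Ls[[i]], ZtX[r, , drop = FALSE])
      Zty[r, ] <- crossprod(Ls[[i]], Zty[r, , drop = FALSE])
    }
  }
  comp_of <- rep(seq_len(k), q_each)

  eval_pieces <- function(eta) {
    g <- exp(pmin(pmax(eta, -12), 8))
    sg <- sqrt(g)[comp_of]
    M <- ZtZ * tcrossprod(sg)
    diag(M) <- diag(M) + 1
    cholM <- chol(M)
    PX <- ZtX * sg
    Py <- Zty * sg
    minv <- function(P) backsolve(cholM,
                                  backsolve(cholM, P, transpose = TRUE))
    MiPX <- minv(PX)
    MiPy <- minv(Py)
    XtViX <- XtX - crossprod(PX, MiPX)
    XtViy <- Xty - crossprod(PX, MiPy)
    ytViy <- yty - sum(Py * MiPy)
    cXV <- chol((XtViX + t(XtViX)) / 2)
    beta <- backsolve(cXV, backsolve(cXV, XtViy, transpose = TRUE))
    rss <- max(ytViy - sum(beta * XtViy), 1e-12)
    crit <- 2 * sum(log(diag(cholM))) + 2 * sum(log(diag(cXV))) +
      (n - p) * log(rss)
    list(crit = crit, beta = beta, rss = rss, cXV = cXV, g = g)
  }

  obj <- function(eta) {
    tryCatch(eval_pieces(eta)$crit, error = function(e) 1e10)
  }
  start <- rep(log(0.1), k)
  opt <- if (k == 1) {
    stats::optim(start, function(e) obj(e), method = "Brent",
                 lower = -12, upper = 8)
  } else {
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = control$reml_maxit,
                                reltol = control$reml_reltol))
  }
  pieces <- eval_pieces(opt$par)
  s2_resid <- pieces$rss / (n - p)
  vcov_beta <- s2_resid * chol2inv(pieces$cXV)
  finish_reml(mm, pieces$beta, vcov_beta, s2_resid, pieces$g, comps,
              converged = opt$convergence == 0, X = X)
}

finish_reml <- function(mm, beta, vcov_beta, s2_resid, gamma, comps,
                        converged, X) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- drop(beta)
  names(beta) <- colnames(X)
  se <- stats::setNames(sqrt(pmax(diag(vcov_beta), 0)), colnames(X))
  df <- wald_df(X, mm$groups$species)
  tc <- stats::qt(0.975, df = df)
  tval <- stats::setNames(ifelse(se > 0, beta / se, 0), colnames(X))
  sigma2 <- stats::setNames(rep(0, length(RE_NAMES)), RE_NAMES)
  if (length(comps)) sigma2[names(comps)] <- gamma * s2_resid
  lp <- drop(X %*% beta)
  list(
    backend = "reml",
    beta = beta, se = se,
    lower = beta - tc * se, upper = beta + tc * se,
    p_value = 2 * stats::pt(-abs(tval), df = df),
    sigma2 = c(sigma2, resid = s2_resid),
    var_fixed = mean((lp - mean(lp))^2),
    rhat = stats::setNames(rep(NA_real_, length(beta)), names(beta)),
    converged = converged,
    n_obs = n, df = df
  )
}

# Containment (between-within) degrees of freedom: a predictor that is
# constant within species is replicated only at the species level, so
# its Wald test uses between-species df; record-level predictors use
# residual df. Without this, species-level effects (body mass, flight
# mode) are tested against n - p and are badly anti-conservative.
wald_df <- function(X, species) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(species)) return(rep(n - p, p))
  sp_level <- vapply(seq_len(p), function(j) {
    x <- X[, j]
    all(abs(x - stats::ave(x, species)) < 1e-8 * (1 + max(abs(x))))
  }, NA)
  n_between <- max(sum(sp_level), 1L)
  df_between <- max(nlevels(factor(species)) - n_between, 3L)
  stats::setNames(ifelse(sp_level, df_between, n - p), colnames(X))
}
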