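# User-facing fitting layer: one structural equation, or the whole
# piecewise SEM (one mixed model per endogenous node of the DAG).

#' Fitting settings
#'
#' @param backend `"bayes"` (Gibbs sampler; the default matches the
#'   published analysis: 4 chains x 10,000 iterations, first 1000
#'   discarded per chain) or `"reml"` (fast likelihood fit with Wald
#'   intervals; used for simulation testing).
#' @param chains,iter,burnin MCMC settings (bayes backend).
#' @param seed integer seed threaded through all stochastic steps.
#' @param prior_beta_sd Normal prior SD on standardized coefficients.
#' @param prior_sd_scale,prior_sd_df half-Student-t prior scale and df
#'   on all SD parameters.
#' @param re random-effect components to include, a subset of
#'   `c("phylo", "species", "paper", "year")`.
#' @param scale_response z-score the response so coefficients are fully
#'   standardized (default TRUE).
#' @param reml_maxit,reml_reltol optimizer settings (reml backend).
#' @return list of settings, class `sem_control`.
#' @export
sem_control <- function(backend = c("bayes", "reml"),
                        chains = 4, iter = 10000, burnin = 1000,
                        seed = 1L,
                        prior_beta_sd = 2.5, prior_sd_scale = 2.5,
                        prior_sd_df = 3,
                        re = c("phylo", "species", "paper", "year"),
                        scale_response = TRUE,
                        reml_maxit = 500, reml_reltol = 1e-8) {
  backend <- match.arg(backend)
  re <- match.arg(re, several.ok = TRUE)
  structure(list(backend = backend, chains = chains, iter = iter,
                 burnin = burnin, seed = as.integer(seed),
                 prior_beta_sd = prior_beta_sd,
                 prior_sd_scale = prior_sd_scale,
                 prior_sd_df = prior_sd_df, re = re,
                 scale_response = scale_response,
                 reml_maxit = reml_maxit, reml_reltol = reml_reltol),
            class = "sem_control")
}

#' Marginal and conditional R-squared (Nakagawa-Schielzeth, Gaussian)
#'
#' `R2_marginal = var_fixed / (var_fixed + sum(var_random) + var_resid)`
#' (fixed effects only); `R2_conditional` adds the random-effect
#' variances to the numerator.
#'
#' @param var_fixed variance of the fixed-effect linear predictor.
#' @param var_random numeric vector (or sum) of random-effect variances.
#' @param var_resid residual variance.
#' @return named vector `c(marginal, conditional)`.
#' @export
r_squared <- function(var_fixed, var_random, var_resid) {
  vr <- sum(var_random)
  if (any(c(var_fixed, vr, var_resid) < 0)) {
    stop("variance components must be non-negative")
  }
  tot <- var_fixed + vr + var_resid
  if (tot == 0) stop("all variance components are zero")
  c(marginal = var_fixed / tot, conditional = (var_fixed + vr) / tot)
}

#' Fit one structural equation
#'
#' Fits the mixed model for `response`'s equation with the selected
#' backend and packages standardized coefficients, 95% intervals (an
#' interval excluding zero flags the effect significant), variance
#' components, marginal/conditional R-squared, VIFs and convergence
#' diagnostics.
#'
#' @param mm a `model_matrix` from [assemble_matrix()].
#' @param phylo a `phylo_cov` covering the species in `mm` (may be
#'   `NULL` if `"phylo"` is not in `control$re`).
#' @param control a [sem_control()].
#' @return object of class `equation_fit`.
#' @export
fit_equation <- function(mm, phylo, control = sem_control()) {
  fit <- switch(control$backend,
                reml = fit_reml(mm, phylo, control),
                bayes = fit_bayes(mm, phylo, control))
  keep <- setdiff(names(fit$beta), "(Intercept)")
  vifs <- vif(mm)
  coefs <- data.frame(
    term = keep,
    estimate = fit$beta[keep],
    lower = fit$lower[keep],
    upper = fit$upper[keep],
    significant = fit$lower[keep] > 0 | fit$upper[keep] < 0,
    p_value = fit$p_value[keep],
    rhat = fit$rhat[keep],
    vif = vifs[match(keep, names(vifs))],
    row.names = NULL, stringsAsFactors = FALSE
  )
  r2 <- if (!is.null(fit$R2_draws)) fit$R2_draws else {
    r_squared(fit$var_fixed, fit$sigma2[RE_NAMES], fit$sigma2[["resid"]])
  }
  if (!fit$converged) {
    warning("equation for ", mm$response, " did not converge; ",
            "downstream use is blocked unless forced")
  }
  structure(list(
    response = mm$response,
    coefficients = coefs,
    sigma2 = fit$sigma2,
    R2 = r2,
    diagnostics = list(backend = fit$backend, converged = fit$converged,
                       rhat = fit$rhat, n_obs = mm$n_obs,
                       n_species = mm$n_species,
                       n_dropped = mm$n_dropped),
    intercept = unname(fit$beta["(Intercept)"])
  ), class = "equation_fit")
}

#' Build an equation fit from known coefficients
#'
#' Constructs a minimal `equation_fit` from externally supplied
#' standardized coefficients and intervals -- e.g. published table
#' values -- so that [decompose_effects()] can be applied without
#' refitting.
#'
#' @param response node name.
#' @param terms named numeric vector of coefficient estimates.
#' @param lower,upper interval bounds (default: tight intervals of the
#'   same sign as the estimate, i.e. every effect significant).
#' @return an `equation_fit`.
#' @export
manual_fit <- function(response, terms, lower = NULL, upper = NULL) {
  est <- unlist(terms)
  lower <- lower %||% (est - 1e-6)
  upper <- upper %||% (est + 1e-6)
  structure(list(
    response = response,
    coefficients = data.frame(
      term = names(est), estimate = unname(est),
      lower = unname(lower), upper = unname(upper),
      significant = unname(lower) > 0 | unname(upper) < 0,
      p_value = NA_real_, rhat = NA_real_, vif = NA_real_,
      stringsAsFactors = FALSE),
    sigma2 = NULL, R2 = NULL,
    diagnostics = list(backend = "manual", converged = TRUE),
    intercept = 0
  ), class = "equation_fit")
}

#' @export
print.equation_fit <- function(x, ...) {
  cat("Equation:", x$response, "~",
      paste(x$coefficients$term, collapse = " + "), "\n")
  cat("  backend:", x$diagnostics$backend,
      if (isTRUE(x$diagnostics$converged)) "(converged)"
      else "(NOT converged)", "\n")
  df <- x$coefficients
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %7.3f  [%7.3f, %7.3f]%s\n", df$term[i],
                df$estimate[i], df$lower[i], df$upper[i],
                if (isTRUE(df$significant[i])) " *" else ""))
  }
  if (!is.null(x$R2)) {
    cat(sprintf("  R2m = %.3f, R2c = %.3f\n", x$R2[["marginal"]],
                x$R2[["conditional"]]))
  }
  invisible(x)
}

#' Fit the full piecewise SEM
#'
#' Fits one mixed model per endogenous node of the DAG, in topological
#' order, sharing the random-effect structure and settings.
#'
#' @param derived a `cycle_derived` table.
#' @param dag a `dag_model` (default [build_default_dag()]).
#' @param phylo a `phylo_cov` covering the species.
#' @param control a [sem_control()].
#' @return object of class `sem_fit`: list of `equation_fit`s keyed by
#'   response, with the DAG attached.
#' @export
fit_sem <- function(derived, dag = build_default_dag(), phylo,
                    control = sem_control()) {
  fits <- list()
  for (node in endogenous_nodes(dag)) {
    mm <- assemble_matrix(derived, node, dag,
                          scale_response = control$scale_response)
    fits[[node]] <- fit_equation(mm, phylo, control)
  }
  structure(list(fits = fits, dag = dag, control = control),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Piecewise SEM:", length(x$fits), "equations\n")
  for (f in x$fits) print(f)
  invisible(x)
}
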