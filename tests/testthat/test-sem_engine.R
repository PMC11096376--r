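test_that("r_squared closed forms", {
  expect_equal(r_squared(1, 1, 2),
               c(marginal = 0.25, conditional = 0.50))
  r <- r_squared(0.4, 0, 0.6)
  expect_equal(unname(r["marginal"]), unname(r["conditional"]))
  expect_equal(unname(r_squared(0, c(0.3, 0.2), 0.5)["marginal"]), 0)
  expect_error(r_squared(-1, 0, 1), "non-negative")
})

test_that("gelman_rubin behaves at its limits", {
  # identical constant chains: Rhat = 1 by convention
  expect_equal(gelman_rubin(matrix(5, 100, 3)), 1)
  # two chains centred 10 SDs apart: far from converged
  set.seed(1)
  bad <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  expect_gt(gelman_rubin(bad), 1.1)
  # well-mixed chains from one distribution
  set.seed(2)
  good <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(gelman_rubin(good), 1.01)
  expect_error(gelman_rubin(matrix(1, 100, 1)), "2 chains")
})

test_that("degenerate and no-random-structure fits match OLS facts", {
  # response an exact copy of a predictor: beta -> 1, residual -> 0
  set.seed(3)
  z <- zscore(rnorm(120))
  f <- factor(rep(1:12, each = 10))
  mm <- structure(list(
    y = z, X = cbind(`(Intercept)` = 1, x = z), predictors = "x",
    groups = list(species = f, paper = f, year = f),
    n_obs = 120L, n_species = 12L, response = "y", n_dropped = 0L),
    class = "model_matrix")
  ctrl <- sem_control(backend = "reml", re = c("species", "year"))
  fit <- migsem:::fit_reml(mm, NULL, ctrl)
  expect_equal(unname(fit$beta["x"]), 1, tolerance = 1e-6)
  expect_lt(fit$sigma2[["resid"]], 1e-6)

  # i.i.d. data with no group structure: REML agrees with OLS
  set.seed(4)
  x1 <- rnorm(300)
  x2 <- rnorm(300)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(300)
  g <- factor(sample(1:30, 300, TRUE))
  mm2 <- structure(list(
    y = y, X = cbind(`(Intercept)` = 1, x1 = x1, x2 = x2),
    predictors = c("x1", "x2"),
    groups = list(species = g, paper = g, year = g),
    n_obs = 300L, n_species = 30L, response = "y", n_dropped = 0L),
    class = "model_matrix")
  fit2 <- migsem:::fit_reml(mm2, NULL,
                            sem_control(backend = "reml",
                                        re = c("species", "year")))
  ols <- coef(lm(y ~ x1 + x2))
  expect_equal(unname(fit2$beta[c("x1", "x2")]),
               unname(ols[c("x1", "x2")]), tolerance = 0.02)
  expect_true(all(ols[c("x1", "x2")] > fit2$lower[c("x1", "x2")] &
                    ols[c("x1", "x2")] < fit2$upper[c("x1", "x2")]))
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  s <- small_derived()
  d <- s$derived
  dag <- build_default_dag()
  mm1 <- assemble_matrix(d, "arr_b", dag)
  d2 <- d
  d2$mig_dist <- d2$mig_dist * 1000     # metres instead of km
  mm2 <- assemble_matrix(d2, "arr_b", dag)
  expect_equal(mm1$X, mm2$X, tolerance = 1e-12)
  ctrl <- sem_control(backend = "reml")
  f1 <- fit_equation(mm1, s$phylo, ctrl)
  f2 <- fit_equation(mm2, s$phylo, ctrl)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("an equation fit reports the full contract", {
  s <- small_derived()
  fit <- fit_equation(assemble_matrix(s$derived, "dep_nb",
                                      build_default_dag()),
                      s$phylo, sem_control(backend = "reml"))
  cf <- fit$coefficients
  expect_setequal(cf$term, c("body_mass", "breed_lat", "nb_lat_abs",
                             "mig_dist", "flight_mode"))
  expect_true(all(cf$lower <= cf$estimate & cf$estimate <= cf$upper))
  expect_true(all(fit$sigma2 >= 0))
  r2 <- fit$R2
  expect_true(r2[["marginal"]] >= 0 && r2[["marginal"]] <=
                r2[["conditional"]] && r2[["conditional"]] <= 1)
  expect_true(all(is.finite(cf$vif)))
  expect_true(all(cf$vif >= 1))
  expect_equal(fit$diagnostics$n_species, 20L)
})

test_that("species-intercept-only data gives R2m ~ 0 and R2c ~ 1", {
  set.seed(6)
  S <- 40
  f <- factor(rep(seq_len(S), each = 12))
  y <- rnorm(S, 0, 2)[as.integer(f)] + rnorm(length(f), 0, 0.05)
  x <- rnorm(length(f))
  mm <- structure(list(
    y = zscore(y), X = cbind(`(Intercept)` = 1, x = zscore(x)),
    predictors = "x",
    groups = list(species = f, paper = f, year = f),
    n_obs = length(y), n_species = S, response = "y", n_dropped = 0L),
    class = "model_matrix")
  fit <- migsem:::fit_reml(mm, NULL,
                           sem_control(backend = "reml", re = "species"))
  r2 <- r_squared(fit$var_fixed, fit$sigma2[migsem:::RE_NAMES],
                  fit$sigma2[["resid"]])
  expect_lt(r2[["marginal"]], 0.05)
  expect_gt(r2[["conditional"]], 0.95)
})

test_that("likelihood and Bayesian backends agree at n >= 1000", {
  b <- simulate_bundle(n_species = 100, mean_records = 10, seed = 21)
  d <- derive_cycle(b$tracking, b$traits)
  expect_gte(nrow(d), 1000)
  pv <- vcv_from_tree(b$tree)
  mm <- assemble_matrix(d, "arr_b", build_default_dag())
  fr <- fit_equation(mm, pv, sem_control(backend = "reml"))
  # short chains may flag the weakly identified phylo/species variance
  # split; that warning is expected here
  fb <- suppressWarnings(
    fit_equation(mm, pv, sem_control(backend = "bayes", chains = 2,
                                     iter = 1500, burnin = 300,
                                     seed = 8)))
  expect_lt(max(abs(fr$coefficients$estimate - fb$coefficients$estimate)),
            0.05)
  # the coefficients mix quickly even in short test chains; the
  # phylo/species variance split needs the full-length default run
  expect_true(all(fb$coefficients$rhat < 1.1))
})

test_that("the Bayesian sampler is reproducible given a seed", {
  s <- small_derived()
  mm <- assemble_matrix(s$derived, "dep_b", build_default_dag())
  ctrl <- sem_control(backend = "bayes", chains = 2, iter = 400,
                      burnin = 100, seed = 77)
  f1 <- suppressWarnings(fit_equation(mm, s$phylo, ctrl))
  f2 <- suppressWarnings(fit_equation(mm, s$phylo, ctrl))
  expect_identical(f1$coefficients$estimate, f2$coefficients$estimate)
})

test_that("interval coverage of a known coefficient (scaled-down recovery)", {
  # dep_nb -> arr_b generated at 0.35; 25 replicates at 60 species
  hits <- 0L
  for (seed in 1:25) {
    b <- simulate_bundle(n_species = 60, mean_records = 8, seed = 100 + seed)
    d <- derive_cycle(b$tracking, b$traits)
    pv <- vcv_from_tree(b$tree)
    fit <- fit_equation(assemble_matrix(d, "arr_b", build_default_dag()),
                        pv, sem_control(backend = "reml"))
    cf <- fit$coefficients
    i <- match("dep_nb", cf$term)
    if (cf$lower[i] <= 0.35 && 0.35 <= cf$upper[i]) hits <- hits + 1L
  }
  # binomial(25, .95): >= 21 hits with probability ~0.993
  expect_gte(hits, 21L)
})
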