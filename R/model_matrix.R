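# Assembly of the per-equation response/predictor matrices.

# Map a DAG node to its column in the derived table, on the scale the
# model uses: body mass is log10-transformed (masses span three orders
# of magnitude), flight mode is coded flapping = 0 / soaring = 1, sex
# male = 0 / female = 1, timings are continuous day indices, and the
# non-breeding latitude is the absolute value (already in the derived
# table) so southern winterers do not induce collinearity with
# distance.
node_column <- function(derived, node) {
  switch(node,
    body_mass = log10(derived$body_mass),
    flight_mode = as.numeric(derived$flight_mode == "soaring"),
    sex = as.numeric(derived$sex == "female"),
    dep_nb = derived$dep_nb_doy,
    arr_b = derived$arr_b_doy,
    dep_b = derived$dep_b_doy,
    arr_nb = derived$arr_nb_doy,
    {
      if (!node %in% names(derived)) stop("unknown model variable: ", node)
      derived[[node]]
    }
  )
}

BINARY_NODES <- c("flight_mode", "sex")

#' Assemble the model matrix for one structural equation
#'
#' Builds the z-scored response and predictor matrix for `response`'s
#' equation in `dag`, plus the grouping factors for the random effects.
#' Continuous columns are z-scored (population SD); binary covariates
#' (flight mode, sex) stay 0/1. Rows with any missing value in the
#' equation's variables are dropped listwise with a logged count; when
#' `sex` is in the equation, unknown-sex records are dropped too.
#'
#' @param derived a `cycle_derived` table.
#' @param response an endogenous node of `dag`.
#' @param dag a `dag_model`.
#' @param scale_response z-score the response as well (default TRUE, so
#'   coefficients are fully standardized and multiply along paths).
#' @return object of class `model_matrix`: list with `y`, `X`
#'   (intercept + predictors), `predictors`, `groups` (species, paper
#'   nested in species, year factors), `n_obs`, `n_species`,
#'   `response`.
#' @export
assemble_matrix <- function(derived, response, dag, scale_response = TRUE) {
  pa <- dag$parents[[response]]
  if (!length(pa)) stop("node ", response, " has no parents in the DAG")
  vars <- c(response, pa)

  cols <- lapply(vars, function(v) node_column(derived, v))
  names(cols) <- vars
  if ("sex" %in% pa) cols$sex[derived$sex == "unknown"] <- NA

  keep <- Reduce(`&`, lapply(cols, function(x) !is.na(x)))
  dropped <- sum(!keep)
  if (dropped > 0) {
    msg("assemble_matrix(", response, "): listwise deletion of ",
        dropped, " incomplete rows")
  }
  if (sum(keep) < 3) stop("fewer than 3 complete rows for ", response)
  cols <- lapply(cols, function(x) x[keep])

  for (v in vars) {
    if (length(unique(cols[[v]])) < 2) {
      stop("zero-variance variable in equation for ", response, ": ", v)
    }
  }
  scale_col <- function(v) {
    if (v %in% BINARY_NODES) cols[[v]] else zscore(cols[[v]])
  }
  y <- if (scale_response) zscore(cols[[response]]) else cols[[response]]
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, stats::setNames(lapply(pa, scale_col), pa)))

  d <- derived[keep, ]
  groups <- list(
    species = factor(d$species),
    paper = factor(paste(d$species, d$paper_id, sep = ":")),
    year = factor(d$year)
  )
  structure(list(y = y, X = X, predictors = pa, groups = groups,
                 species = as.character(d$species),
                 n_obs = length(y), n_species = nlevels(groups$species),
                 response = response, n_dropped = dropped),
            class = "model_matrix")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the other
#' predictors (fixed effects only, intercept excluded from the set).
#' Perfect collinearity yields `Inf`.
#'
#' @param x a `model_matrix` or a numeric predictor matrix.
#' @return named numeric vector of VIFs (NA with a single predictor).
#' @export
vif <- function(x) {
  X <- if (inherits(x, "model_matrix")) {
    x$X[, setdiff(colnames(x$X), "(Intercept)"), drop = FALSE]
  } else {
    as.matrix(x)
  }
  p <- ncol(X)
  if (p < 2) return(stats::setNames(rep(NA_real_, p), colnames(X)))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(X))
}
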