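# Path tracing over the fitted DAG: standardized direct, indirect and
# total effects, plus d-separation tests of the causal structure.
#
# Edge weights are the standardized coefficients of the per-equation
# fits, gated by significance: an edge whose 95% interval covers zero
# contributes 0 to every path. On z-scored variables coefficients
# multiply along a path, indirect effects sum over all directed paths
# of length >= 2, and total = direct + indirect.

edge_weights <- function(dag, fits, gate = TRUE) {
  W <- matrix(0, length(dag$nodes), length(dag$nodes),
              dimnames = list(dag$nodes, dag$nodes))
  has_edge <- W > 1  # all FALSE
  for (v in endogenous_nodes(dag)) {
    f <- fits[[v]]
    if (is.null(f)) stop("missing fit for node ", v)
    cf <- f$coefficients
    for (pa in dag$parents[[v]]) {
      i <- match(pa, cf$term)
      if (is.na(i)) stop("fit for ", v, " lacks coefficient for ", pa)
      has_edge[pa, v] <- TRUE
      W[pa, v] <- if (!gate || isTRUE(cf$significant[i])) cf$estimate[i]
                  else 0
    }
  }
  list(W = W, has_edge = has_edge)
}

# All directed paths from `from` to `to`; DAG, so all paths are simple.
enumerate_paths <- function(dag, from, to) {
  out <- list()
  walk <- function(v, path) {
    if (v == to) {
      out[[length(out) + 1]] <<- path
      return(invisible(NULL))
    }
    for (w in dag$nodes) {
      if (v %in% dag$parents[[w]]) walk(w, c(path, w))
    }
  }
  walk(from, from)
  out
}

#' Decompose standardized effects over the fitted DAG
#'
#' For every ordered (predictor, outcome) pair connected by at least
#' one directed path: the direct effect is the (significance-gated)
#' weight of the direct edge, the indirect effect the sum over all
#' directed paths of length >= 2 of the product of edge weights, and
#' the total their sum. Path enumeration is exact.
#'
#' @param dag a `dag_model`.
#' @param fits named list of `equation_fit`s (or a `sem_fit`), one per
#'   endogenous node.
#' @param gate gate non-significant edges to zero (default TRUE).
#' @param force proceed even if some equation did not converge.
#' @return object of class `effect_table`: data frame with columns
#'   `predictor`, `outcome`, `direct` (NA when there is no direct edge
#'   or it is gated out), `indirect`, `total`; per-path contributions in
#'   `attr(, "paths")`.
#' @export
decompose_effects <- function(dag, fits, gate = TRUE, force = FALSE) {
  if (inherits(fits, "sem_fit")) fits <- fits$fits
  for (v in endogenous_nodes(dag)) {
    f <- fits[[v]]
    if (is.null(f)) stop("missing fit for node ", v)
    if (!isTRUE(f$diagnostics$converged) && !force) {
      stop("fit for ", v, " did not converge (use force = TRUE to override)")
    }
  }
  ew <- edge_weights(dag, fits, gate)
  rows <- list()
  paths_out <- list()
  for (from in dag$order) {
    for (to in dag$order) {
      if (from == to) next
      paths <- enumerate_paths(dag, from, to)
      if (!length(paths)) next
      direct <- if (ew$has_edge[from, to] && ew$W[from, to] != 0) {
        ew$W[from, to]
      } else {
        NA_real_
      }
      indirect <- 0
      contrib <- list()
      for (pth in paths) {
        if (length(pth) == 2) next
        prod_w <- prod(ew$W[cbind(pth[-length(pth)], pth[-1])])
        indirect <- indirect + prod_w
        contrib[[paste(pth, collapse = " -> ")]] <- prod_w
      }
      total <- (if (is.na(direct)) 0 else direct) + indirect
      rows[[length(rows) + 1]] <- data.frame(
        predictor = from, outcome = to, direct = direct,
        indirect = indirect, total = total, stringsAsFactors = FALSE)
      paths_out[[paste(from, to, sep = " -> ")]] <- contrib
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "paths") <- paths_out
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Render an effect table in the conventional report layout
#'
#' Rows are the four migration timings; columns the seven explanatory
#' variables (body mass, breeding latitude, absolute non-breeding
#' latitude, migration distance, and the three earlier timings). Three
#' sub-rows per timing give direct, indirect and total effects, rounded
#' half-away-from-zero to `digits` decimals; a missing direct effect
#' (no edge, or gated out as non-significant) renders as `"-"`, an
#' indirect effect with no contributing path likewise. A negative value
#' rounding to zero keeps its sign (`"-0.00"`).
#'
#' @param effects an `effect_table` from [decompose_effects()].
#' @param digits decimal places (default 2).
#' @param outcomes,predictors row/column variables (defaults: the four
#'   timings and seven explanatory variables).
#' @return character matrix, one row per (timing, effect-type).
#' @export
render_effect_table <- function(effects, digits = 2,
                                outcomes = TIMING_NODES,
                                predictors = EXPLANATORY_NODES) {
  rows <- list()
  for (oc in outcomes) {
    for (kind in c("direct", "indirect", "total")) {
      cells <- vapply(predictors, function(pr) {
        if (pr == oc) return("")
        i <- which(effects$predictor == pr & effects$outcome == oc)
        if (!length(i)) return("-")
        v <- effects[[kind]][i]
        if (kind == "direct" && is.na(v)) return("-")
        if (kind == "indirect" && v == 0) return("-")
        if (kind == "total" && is.na(effects$direct[i]) &&
            effects$indirect[i] == 0) return("-")
        format_signed(v, digits)
      }, "")
      rows[[paste(oc, kind)]] <- cells
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- predictors
  out
}

#' Total effects by the matrix identity
#'
#' With W the (gated) edge-weight matrix, the total effect of i on j is
#' the (i, j) entry of `sum_{k>=1} W^k` (a finite sum: W is nilpotent
#' on a DAG). Used as an internal cross-check of the path enumeration.
#'
#' @param dag a `dag_model`.
#' @param fits fits as in [decompose_effects()].
#' @param gate gate non-significant edges.
#' @return node x node matrix of total effects.
#' @export
total_effects_matrix <- function(dag, fits, gate = TRUE) {
  if (inherits(fits, "sem_fit")) fits <- fits$fits
  W <- edge_weights(dag, fits, gate)$W
  total <- W
  Wk <- W
  for (i in seq_len(length(dag$nodes) - 1)) {
    Wk <- Wk %*% W
    if (all(Wk == 0)) break
    total <- total + Wk
  }
  total
}

#' d-separation basis set of a DAG
#'
#' The conditional-independence claims implied by the DAG among
#' non-adjacent variable pairs: for each ordered pair (i, j) with i
#' before j in topological order and no edge either way, the claim
#' "i independent of j given parents(j) union parents(i)". Pairs where
#' both variables are exogenous are excluded (no structural equation
#' constrains their association). Ordering is deterministic.
#'
#' @param dag a `dag_model`.
#' @return list of claims, each `list(x, y, cond)`; empty for a
#'   saturated DAG.
#' @export
basis_set <- function(dag) {
  ord <- dag$order
  exo <- setdiff(dag$nodes, endogenous_nodes(dag))
  claims <- list()
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i >= j) next
      x <- ord[i]
      y <- ord[j]
      if (x %in% dag$parents[[y]] || y %in% dag$parents[[x]]) next
      if (x %in% exo && y %in% exo) next
      cond <- setdiff(union(dag$parents[[y]], dag$parents[[x]]), c(x, y))
      claims[[length(claims) + 1]] <- list(x = x, y = y, cond = cond)
    }
  }
  claims
}

#' Fisher's C over a set of independence-claim p-values
#'
#' `C = -2 * sum(log(p_i))`, compared to chi-square with `2k` degrees
#' of freedom. A non-significant global p means the data are consistent
#' with the DAG.
#'
#' @param p_values numeric vector of claim-level p-values in (0, 1].
#' @return list with `C`, `df`, `p_value`, `k`.
#' @export
fishers_c <- function(p_values) {
  if (!length(p_values)) stop("need at least one claim p-value")
  if (any(is.na(p_values)) || any(p_values > 1)) {
    stop("p-values must be in (0, 1]")
  }
  if (any(p_values <= 0)) {
    stop("claim p-value of 0: decisive violation of an independence claim")
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p_value = stats::pchisq(C, df, lower.tail = FALSE),
       k = length(p_values))
}

#' d-separation test of the DAG against data
#'
#' Tests every basis-set claim by refitting the same mixed-model
#' machinery: for the claim "x independent of y given cond", y is
#' regressed on cond plus x with the shared random-effect structure.
#' Claim fits use the Gibbs sampler (short chains), because the
#' posterior SD of x's coefficient marginalizes over the
#' variance-component uncertainty that a plug-in Wald SE ignores --
#' with a few dozen species, plug-in claim tests for species-level
#' predictors reject a true null well above nominal rate. The claim
#' p-value is the two-sided tail of the posterior z-score under a t
#' reference with containment (between-within) degrees of freedom, and
#' claim p-values combine into Fisher's C.
#'
#' @param derived a `cycle_derived` table.
#' @param dag a `dag_model`.
#' @param phylo a `phylo_cov`.
#' @param control a [sem_control()]; only `seed`, `re` and
#'   `scale_response` are consulted (claim chains are fixed at 2 x 1000
#'   with 250 burn-in for determinism and speed).
#' @return object of class `dsep_result`: list with `claims` (data
#'   frame of x, y, conditioning set, p), `C`, `df`, `p_value`.
#' @export
dsep_test <- function(derived, dag = build_default_dag(), phylo,
                      control = sem_control(backend = "reml")) {
  claims <- basis_set(dag)
  if (!length(claims)) {
    return(structure(list(
      claims = data.frame(x = character(), y = character(),
                          cond = character(), p_value = numeric()),
      C = 0, df = 0L, p_value = 1), class = "dsep_result"))
  }
  ps <- vapply(seq_along(claims), function(i) {
    cl <- claims[[i]]
    test_dag <- dag_model(stats::setNames(
      list(unique(c(cl$cond, cl$x))), cl$y))
    mm <- assemble_matrix(derived, cl$y, test_dag,
                          scale_response = control$scale_response)
    ctrl <- control
    ctrl$chains <- 2L
    ctrl$iter <- 1000L
    ctrl$burnin <- 250L
    ctrl$seed <- control$seed + i
    fit <- fit_bayes(mm, phylo, ctrl)
    z <- fit$beta[cl$x] / fit$se[cl$x]
    df <- wald_df(mm$X, mm$groups$species)[cl$x]
    unname(2 * stats::pt(-abs(z), df = df))
  }, 0)
  fc <- fishers_c(ps)
  structure(list(
    claims = data.frame(
      x = vapply(claims, `[[`, "", "x"),
      y = vapply(claims, `[[`, "", "y"),
      cond = vapply(claims, function(cl) paste(cl$cond, collapse = "+"), ""),
      p_value = ps, stringsAsFactors = FALSE),
    C = fc$C, df = fc$df, p_value = fc$p_value
  ), class = "dsep_result")
}

#' @export
print.dsep_result <- function(x, ...) {
  cat("d-separation test:", nrow(x$claims), "claims\n")
  for (i in seq_len(nrow(x$claims))) {
    cat(sprintf("  %s _||_ %s | %s : p = %.4f\n", x$claims$x[i],
                x$claims$y[i], x$claims$cond[i], x$claims$p_value[i]))
  }
  cat(sprintf("  Fisher's C = %.3f, df = %d, p = %.4f\n",
              x$C, x$df, x$p_value))
  invisible(x)
}
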