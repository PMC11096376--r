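# The hypothesized causal DAG and its structural-equation layout.
#
# Nodes are the model variables; each endogenous node carries one
# structural equation whose fixed effects are its parents. Every
# equation shares the same random-effect structure (phylogeny, species,
# paper within species, year), which is supplied at fit time.

#' Construct a causal DAG model
#'
#' @param parents named list: for each endogenous node, the character
#'   vector of its parents. Nodes that appear only as parents are
#'   exogenous.
#' @return object of class `dag_model` with elements `nodes`, `parents`
#'   (all nodes, exogenous ones mapped to `character(0)`), `edges`
#'   (two-column matrix from/to) and `order` (a topological order).
#' @export
dag_model <- function(parents) {
  if (is.null(names(parents)) || any(names(parents) == "")) {
    stop("parents must be a fully named list")
  }
  nodes <- unique(c(unlist(parents, use.names = FALSE), names(parents)))
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) full[[v]] <- character(0)
  for (v in names(parents)) {
    pa <- unique(parents[[v]])
    if (v %in% pa) stop("self-loop at node ", v)
    full[[v]] <- pa
  }
  ord <- topo_order(full)
  edges <- do.call(rbind, lapply(names(full), function(v) {
    if (length(full[[v]])) cbind(from = full[[v]], to = v)
  }))
  structure(list(nodes = nodes, parents = full,
                 edges = edges, order = ord),
            class = "dag_model")
}

# Kahn's algorithm; errors on a cycle.
topo_order <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, 0L)
  ord <- character(0)
  avail <- nodes[indeg == 0]
  remaining <- parents
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    ord <- c(ord, v)
    for (w in names(remaining)) {
      if (v %in% remaining[[w]]) {
        remaining[[w]] <- setdiff(remaining[[w]], v)
        if (!length(remaining[[w]]) && !(w %in% ord) && !(w %in% avail)) {
          avail <- c(avail, w)
        }
      }
    }
  }
  if (length(ord) != length(nodes)) {
    stop("graph contains a cycle involving: ",
         paste(setdiff(nodes, ord), collapse = ", "))
  }
  ord
}

#' Endogenous nodes of a DAG (nodes with at least one parent)
#' @param dag a `dag_model`.
#' @return character vector in topological order.
#' @export
endogenous_nodes <- function(dag) {
  dag$order[vapply(dag$parents[dag$order], length, 0L) > 0]
}

#' Add or remove edges of a DAG
#'
#' @param dag a `dag_model`.
#' @param add,remove lists of `c(from, to)` pairs.
#' @return a new `dag_model`; adding an edge that creates a cycle is an
#'   error.
#' @export
edit_dag <- function(dag, add = list(), remove = list()) {
  parents <- dag$parents
  for (e in remove) parents[[e[2]]] <- setdiff(parents[[e[2]]], e[1])
  for (e in add) parents[[e[2]]] <- unique(c(parents[[e[2]]], e[1]))
  dag_model(parents[vapply(parents, length, 0L) > 0])
}

# Canonical node names used throughout the package.
TIMING_NODES <- c("dep_nb", "arr_b", "dep_b", "arr_nb")
EXPLANATORY_NODES <- c("body_mass", "breed_lat", "nb_lat_abs", "mig_dist",
                       "dep_nb", "arr_b", "dep_b")

#' The default annual-cycle causal graph
#'
#' Nodes: `body_mass` and `flight_mode` (exogenous), `breed_lat`,
#' `nb_lat_abs` (absolute non-breeding latitude), `mig_dist`, and the
#' four timings `dep_nb`, `arr_b`, `dep_b`, `arr_nb`. Structure:
#' body mass drives the latitudes (Bergmann's rule for the non-breeding
#' latitude); distance is set by mass, both latitudes and flight mode;
#' each timing depends on mass, latitudes, distance, flight mode and
#' all earlier timings of the same cycle (carry-over). There are no
#' edges between annual cycles: timing is reset during the non-breeding
#' period.
#'
#' @param include_sex add `sex` as an exogenous covariate of the four
#'   timing equations (records with unknown sex are then dropped at
#'   matrix assembly).
#' @return a `dag_model`.
#' @export
build_default_dag <- function(include_sex = FALSE) {
  covars <- c("body_mass", "breed_lat", "nb_lat_abs", "mig_dist",
              "flight_mode")
  sx <- if (include_sex) "sex" else character(0)
  dag_model(list(
    breed_lat = "body_mass",
    nb_lat_abs = "body_mass",
    mig_dist = c("body_mass", "breed_lat", "nb_lat_abs", "flight_mode"),
    dep_nb = c(covars, sx),
    arr_b = c(covars, "dep_nb", sx),
    dep_b = c(covars, "dep_nb", "arr_b", sx),
    arr_nb = c(covars, "dep_nb", "arr_b", "dep_b", sx)
  ))
}

#' @export
print.dag_model <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  for (v in endogenous_nodes(x)) {
    cat(" ", v, "~", paste(x$parents[[v]], collapse = " + "), "\n")
  }
  invisible(x)
}
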