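# Shared fixtures and independent oracles used across test files.

options(migsem.verbose = FALSE)

# A minimal, hand-checkable 3-row tracking table (all rows valid).
tiny_tracking <- function() {
  data.frame(
    record_id = c("r1", "r2", "r3"),
    species = c("spA", "spA", "spB"),
    level = c("individual", "population", "individual"),
    paper_id = c("p1", "p1", "p2"),
    year = c(2010L, 2011L, 2010L),
    sex = c("female", "unknown", "male"),
    capture_site_class = c("breeding", "nonbreeding", "stopover"),
    breed_lat = c(55.5, 54.0, 62.25),
    breed_lon = c(10.0, 11.5, -20.0),
    nb_first_lat = c(5.0, 4.5, -30.0),
    nb_first_lon = c(0.0, 1.0, -45.0),
    nb_last_lat = c(6.0, 4.5, -30.0),
    nb_last_lon = c(-1.0, 1.0, -45.0),
    dep_nb = c("2010-03-27", "2011-04-02", "2010-04-15"),
    arr_b = c("2010-05-02", "2011-05-10", "2010-05-20"),
    dep_b = c("2010-08-26", "2011-08-15", "2010-09-01"),
    arr_nb = c("2010-10-16", "2011-10-05", "2010-11-10"),
    flight_mode = c("flapping", "flapping", "soaring"),
    stringsAsFactors = FALSE
  )
}

tiny_traits <- function() {
  data.frame(
    species = c("spA", "spB"),
    order = c("Passeriformes", "Accipitriformes"),
    family = c("FamA", "FamB"),
    min_mass_female = c(100, 900),
    min_mass_male = c(120, 800),
    stringsAsFactors = FALSE
  )
}

write_tiny_tables <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("migsem_fix")
    dir.create(dir)
  }
  tp <- file.path(dir, "tracking.csv")
  rp <- file.path(dir, "traits.csv")
  utils::write.csv(tiny_tracking(), tp, row.names = FALSE, quote = FALSE)
  utils::write.csv(tiny_traits(), rp, row.names = FALSE, quote = FALSE)
  list(tracking = tp, traits = rp)
}

# Brute-force phylogenetic covariance: for every tip pair, intersect
# the root-to-tip edge paths and sum the lengths of shared edges.
# Independent of vcv_from_tree's MRCA-depth computation.
bf_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  paths <- lapply(seq_len(n), function(tip) ape::nodepath(tree, root, tip))
  elen <- function(a, b) {
    tree$edge.length[tree$edge[, 1] == a & tree$edge[, 2] == b]
  }
  base <- if (!is.null(tree$root.edge) && is.finite(tree$root.edge)) {
    tree$root.edge
  } else {
    0
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pi <- paths[[i]]
      pj <- paths[[j]]
      m <- min(length(pi), length(pj))
      shared <- 0
      for (s in seq_len(m - 1)) {
        if (pi[s] != pj[s] || pi[s + 1] != pj[s + 1]) break
        shared <- shared + elen(pi[s], pi[s + 1])
      }
      C[i, j] <- shared + base
    }
  }
  for (i in seq_len(n)) {
    pth <- paths[[i]]
    C[i, i] <- base +
      sum(vapply(seq_len(length(pth) - 1),
                 function(s) elen(pth[s], pth[s + 1]), 0))
  }
  C
}

# Random tree with random (non-ultrametric) branch lengths.
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

# Random weighted DAG over nodes in a fixed topological order.
random_weighted_dag <- function(n_nodes, seed, p_edge = 0.45) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  W <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (stats::runif(1) < p_edge) W[i, j] <- stats::runif(1, -1, 1)
    }
  }
  # ensure at least one edge so dag_model has an endogenous node
  if (all(W == 0)) W[1, 2] <- 0.5
  W
}

dag_from_weights <- function(W) {
  nodes <- colnames(W)
  parents <- list()
  for (j in nodes) {
    pa <- nodes[W[, j] != 0]
    if (length(pa)) parents[[j]] <- pa
  }
  dag_model(parents)
}

fits_from_weights <- function(W) {
  nodes <- colnames(W)
  fits <- list()
  for (j in nodes) {
    pa <- nodes[W[, j] != 0]
    if (length(pa)) fits[[j]] <- manual_fit(j, stats::setNames(W[pa, j], pa))
  }
  fits
}

# Brute-force path sums: all simple directed paths from -> to, product
# of weights, separated into direct (single edge) and indirect.
bf_indirect <- function(W, from, to) {
  nodes <- colnames(W)
  total_indirect <- 0
  recurse <- function(v, prod, len) {
    if (v == to) {
      if (len >= 2) total_indirect <<- total_indirect + prod
      return(invisible(NULL))
    }
    for (w in nodes) {
      if (W[v, w] != 0) recurse(w, prod * W[v, w], len + 1)
    }
  }
  recurse(from, 1, 0)
  total_indirect
}

# One small derived dataset shared by several fitting tests.
small_derived <- function(seed = 11, n_species = 20, mean_records = 6) {
  b <- simulate_bundle(n_species = n_species, mean_records = mean_records,
                       seed = seed)
  list(bundle = b, derived = derive_cycle(b$tracking, b$traits),
       phylo = vcv_from_tree(b$tree))
}
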