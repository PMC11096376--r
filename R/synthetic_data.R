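# Synthetic-data generator: tree, traits and tracking records drawn
# from the structural model with known ground truth.
#
# The generated world mirrors the compiled-study structure: by default
# 186 species with ~9 records each (zero-truncated negative binomial,
# so 1700-odd records with heavy skew), records nested in papers nested
# in species, phylogenetic signal in body mass, and DAG-structured
# timings with carry-over effects plus phylogenetic / species / paper /
# year variance components. All structural equations are generated on
# the standardized scale (so the truth coefficients are directly the
# standardized effects the pipeline estimates), then rescaled to
# natural units: grams, degrees, kilometres and calendar dates around
# the observed anchors (27 Mar, 2 May, 26 Aug, 16 Oct).

#' Ground truth for the synthetic generator
#'
#' @param n_species number of species (>= 3; default the study scale,
#'   186).
#' @param mean_records mean records per species (zero-truncated
#'   negative binomial; default 9, giving ~1700 records at 186
#'   species).
#' @param null set every path coefficient to zero (for calibration
#'   studies) while keeping the variance components.
#' @param coefficients optional named list overriding the default path
#'   coefficients per endogenous node.
#' @param varcomp optional named list overriding the per-equation
#'   variance components `c(phylo, species, paper, year)` on the
#'   standardized scale (residual variance is set at generation time so
#'   each node has unit variance).
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(n_species = 186, mean_records = 9, null = FALSE,
                      coefficients = NULL, varcomp = NULL) {
  if (n_species < 3) stop("n_species must be >= 3")
  coef_default <- list(
    breed_lat = c(body_mass = 0.10),
    nb_lat_abs = c(body_mass = 0.55),
    mig_dist = c(body_mass = -0.20, breed_lat = 0.45, nb_lat_abs = -0.40,
                 flight_mode = 0.05),
    dep_nb = c(body_mass = -0.33, breed_lat = 0.29, nb_lat_abs = 0,
               mig_dist = 0, flight_mode = 0),
    arr_b = c(body_mass = 0, breed_lat = 0.21, nb_lat_abs = 0,
              mig_dist = 0.24, flight_mode = 0, dep_nb = 0.35),
    dep_b = c(body_mass = 0.42, breed_lat = 0, nb_lat_abs = 0,
              mig_dist = 0, flight_mode = 0, dep_nb = 0, arr_b = 0.10),
    arr_nb = c(body_mass = 0.23, breed_lat = 0, nb_lat_abs = 0,
               mig_dist = 0.14, flight_mode = 0, dep_nb = 0,
               arr_b = 0.17, dep_b = 0.38)
  )
  if (null) coef_default <- lapply(coef_default, function(v) v * 0)
  if (!is.null(coefficients)) {
    coef_default[names(coefficients)] <- coefficients
  }
  vc_lat <- c(phylo = 0.06, species = 0.40, paper = 0.10, year = 0.01)
  vc_dist <- c(phylo = 0.04, species = 0.18, paper = 0.08, year = 0.01)
  vc_time <- c(phylo = 0.03, species = 0.12, paper = 0.10, year = 0.02)
  vc_default <- list(breed_lat = vc_lat, nb_lat_abs = vc_lat,
                     mig_dist = vc_dist, dep_nb = vc_time,
                     arr_b = vc_time, dep_b = vc_time, arr_nb = vc_time)
  if (!is.null(varcomp)) vc_default[names(varcomp)] <- varcomp

  structure(list(
    n_species = n_species,
    mean_records = mean_records,
    coefficients = coef_default,
    varcomp = vc_default,
    mass_h2 = 0.5,              # phylogenetic signal in log mass
    p_soaring = 0.25,
    sex_unknown_frac = 0.37,
    mean_papers = 1.6,
    year_range = c(1995L, 2021L),
    scales = list(
      log10_mass = c(mean = 2.2, sd = 0.65),   # 8.7 g .. 7600 g envelope
      breed_lat = c(mean = 55, sd = 8),
      nb_lat_abs = c(mean = 20, sd = 10),
      mig_dist = c(mean = 6500, sd = 1800),
      anchors = c(dep_nb = 86, arr_b = 122, dep_b = 238, arr_nb = 289),
      date_sd = c(dep_nb = 14, arr_b = 14, dep_b = 18, arr_nb = 18)
    )
  ), class = "sim_truth")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree on `n_species` tips, rescaled to unit root-to-tip
#' depth; stands in for a dated supertree.
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer seed; the same seed yields an identical Newick
#'   string.
#' @return a `phylo` with tips `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 3) stop("need at least 3 species")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180

#' Simulate a complete data bundle from the truth
#'
#' Draws species traits (log body mass with Brownian phylogenetic
#' signal, flight mode), a nested design (papers in species, records in
#' papers, tracking years), then generates the endogenous variables in
#' topological order on the standardized scale -- each node is the sum
#' of coefficient x parent, phylogenetic, species, paper and year
#' random effects, and a residual sized so the node has unit variance
#' -- and finally rescales to natural units and back-computes
#' non-breeding coordinates so that the great-circle distance between
#' the written coordinates reproduces the generated migration distance.
#'
#' Two feasibility guards distort the truth for a small fraction of
#' records and are recorded in the returned truth: distances are
#' clamped into the geometrically feasible band for the record's
#' latitudes, and records violating the event-order invariant redraw
#' their timing residuals (falling back to minimal 1-day separation).
#'
#' @param truth a [sim_truth()].
#' @param tree a `phylo` whose tips are the species (e.g.
#'   [simulate_tree()]); tip count must equal `truth$n_species`.
#' @param seed integer seed; identical seed + truth gives an identical
#'   bundle.
#' @return object of class `sim_bundle`: list with `tracking` (a
#'   validated `track_table`), `traits`, `tree`, `truth` (including
#'   achieved residual variances and guard counts).
#' @export
simulate_dataset <- function(truth, tree, seed = 1L) {
  if (length(tree$tip.label) != truth$n_species) {
    stop("tree has ", length(tree$tip.label), " tips but truth expects ",
         truth$n_species, " species")
  }
  set.seed(seed)
  species <- tree$tip.label
  S <- length(species)
  sc <- truth$scales
  pv <- vcv_from_tree(tree)
  Lc <- t(chol(pv$C_corr + diag(1e-8, S)))
  phylo_draw <- function() drop(Lc %*% stats::rnorm(S))

  # --- species-level traits ------------------------------------------
  zlm <- sqrt(truth$mass_h2) * phylo_draw() +
    sqrt(1 - truth$mass_h2) * stats::rnorm(S)
  zlm <- (zlm - mean(zlm)) / stats::sd(zlm)
  log10_mass <- sc$log10_mass["mean"] + sc$log10_mass["sd"] * zlm
  mass <- 10^log10_mass
  traits <- data.frame(
    species = species,
    order = ifelse(stats::runif(S) < 0.28, "Passeriformes",
                   paste0("Order", 1 + (seq_len(S) - 1) %/% 25)),
    family = paste0("Fam", 1 + (seq_len(S) - 1) %/% 6),
    min_mass_female = round(mass * 0.95, 1),
    min_mass_male = round(mass * 1.05, 1),
    stringsAsFactors = FALSE
  )
  soaring <- stats::runif(S) < truth$p_soaring
  breed_lon_base <- stats::runif(S, -175, 175)

  # --- nested design -------------------------------------------------
  n_papers <- 1L + stats::rpois(S, truth$mean_papers - 1)
  n_rec <- 1L + stats::rnbinom(S, size = 1, mu = truth$mean_records - 1)
  sp_idx <- rep(seq_len(S), n_rec)
  n <- length(sp_idx)
  paper_of <- integer(n)
  paper_labels <- character(0)
  paper_year <- integer(0)
  offset <- 0L
  yr_lo <- truth$year_range[1]
  yr_hi <- truth$year_range[2]
  for (s in seq_len(S)) {
    labs <- sprintf("%s_p%d", species[s], seq_len(n_papers[s]))
    paper_labels <- c(paper_labels, labs)
    paper_year <- c(paper_year,
                    sample(seq(yr_lo, yr_hi - 2), n_papers[s],
                           replace = TRUE))
    rows <- which(sp_idx == s)
    paper_of[rows] <- offset + sample.int(n_papers[s], length(rows),
                                          replace = TRUE)
    offset <- offset + n_papers[s]
  }
  year <- paper_year[paper_of] + sample(0:2, n, replace = TRUE)
  year_f <- factor(year)

  sex <- ifelse(stats::runif(n) < truth$sex_unknown_frac, "unknown",
                ifelse(stats::runif(n) < 0.5, "male", "female"))
  capture <- sample(LEVELS_CAPTURE, n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  level <- ifelse(stats::runif(n) < 0.1, "population", "individual")

  # --- record-level exogenous columns --------------------------------
  mass_rec <- ifelse(sex == "female", traits$min_mass_female[sp_idx],
                     ifelse(sex == "male", traits$min_mass_male[sp_idx],
                            (traits$min_mass_female[sp_idx] +
                             traits$min_mass_male[sp_idx]) / 2))
  cols <- list(
    body_mass = zscore(log10(mass_rec)),
    flight_mode = as.numeric(soaring[sp_idx])
  )

  # --- endogenous nodes on the standardized scale --------------------
  # Each node's raw value is lin + random effects + residual with
  # implied variance 1; the column is then standardized empirically so
  # downstream equations (and the fitted models, which z-score) see
  # exactly unit-SD parents.
  dag <- build_default_dag()
  resid_sd <- list()
  re_parts <- list()
  raw <- list()
  for (node in endogenous_nodes(dag)) {
    beta <- truth$coefficients[[node]]
    lin <- rep(0, n)
    for (pa in names(beta)) lin <- lin + beta[[pa]] * cols[[pa]]
    vc <- truth$varcomp[[node]]
    v_lin <- mean((lin - mean(lin))^2)
    v_res <- 1 - v_lin - sum(vc)
    if (v_res < 0.02) {
      stop("truth implies near-zero residual variance for ", node)
    }
    re <- sqrt(vc[["phylo"]]) * phylo_draw()[sp_idx] +
      stats::rnorm(S, 0, sqrt(vc[["species"]]))[sp_idx] +
      stats::rnorm(length(paper_labels), 0, sqrt(vc[["paper"]]))[paper_of] +
      stats::rnorm(nlevels(year_f), 0,
                   sqrt(vc[["year"]]))[as.integer(year_f)]
    raw[[node]] <- lin + re + stats::rnorm(n, 0, sqrt(v_res))
    cols[[node]] <- zscore(raw[[node]])
    resid_sd[[node]] <- sqrt(v_res)
    re_parts[[node]] <- re
  }
  resid_var <- lapply(resid_sd, function(s) s^2)

  # --- event-order guard: redraw timing residuals per bad record -----
  timing_doy <- function() {
    lapply(TIMING_NODES, function(nd) {
      sc$anchors[[nd]] + sc$date_sd[[nd]] * cols[[nd]]
    })
  }
  order_ok <- function(d) {
    d[[1]] < d[[2]] & d[[2]] < d[[3]] & d[[3]] < d[[4]] &
      d[[4]] < d[[1]] + 360
  }
  redraws <- 0L
  for (attempt in seq_len(50)) {
    bad <- which(!order_ok(timing_doy()))
    if (!length(bad)) break
    redraws <- redraws + length(bad)
    for (nd in TIMING_NODES) {
      beta <- truth$coefficients[[nd]]
      lin <- rep(0, length(bad))
      for (pa in names(beta)) lin <- lin + beta[[pa]] * cols[[pa]][bad]
      raw[[nd]][bad] <- lin + re_parts[[nd]][bad] +
        stats::rnorm(length(bad), 0, resid_sd[[nd]])
      cols[[nd]] <- zscore(raw[[nd]])
    }
  }
  doys <- timing_doy()
  names(doys) <- TIMING_NODES
  doys <- lapply(doys, round)
  # integer rounding can collapse a 0-1 day gap: force 1-day separation
  forced <- 0L
  for (j in 2:4) {
    bump <- doys[[j]] <= doys[[j - 1]]
    forced <- forced + sum(bump)
    doys[[j]][bump] <- doys[[j - 1]][bump] + 1
  }
  doys$arr_nb <- pmin(doys$arr_nb, doys$dep_nb + 360)

  # --- natural units and geometry ------------------------------------
  breed_lat <- pmin(pmax(sc$breed_lat["mean"] +
                           sc$breed_lat["sd"] * cols$breed_lat, 1), 80)
  nb_abs <- pmin(pmax(sc$nb_lat_abs["mean"] +
                        sc$nb_lat_abs["sd"] * cols$nb_lat_abs, 0.5), 65)
  km <- sc$mig_dist["mean"] + sc$mig_dist["sd"] * cols$mig_dist

  deg <- km / KM_PER_DEG
  south <- deg > (breed_lat + nb_abs + 0.5)
  nb_lat <- ifelse(south, -nb_abs, nb_abs)
  deg_min <- ifelse(south, breed_lat + nb_abs, abs(breed_lat - nb_abs)) + 0.3
  deg_max <- 180 - abs(breed_lat + nb_lat) - 0.3
  clamped <- sum(deg < deg_min | deg > deg_max)
  deg <- pmin(pmax(deg, deg_min), deg_max)
  km <- deg * KM_PER_DEG

  breed_lon <- wrap_lon(breed_lon_base[sp_idx] + stats::rnorm(n, 0, 3))
  dlon <- delta_lon_for_distance(breed_lat, nb_lat, km)
  nb_lon <- wrap_lon(breed_lon + sample(c(-1, 1), n, TRUE) * dlon)

  jan1 <- as.Date(paste0(year, "-01-01"))
  tracking <- data.frame(
    record_id = sprintf("r%05d", seq_len(n)),
    species = species[sp_idx],
    level = level,
    paper_id = paper_labels[paper_of],
    year = year,
    sex = sex,
    capture_site_class = capture,
    breed_lat = breed_lat, breed_lon = breed_lon,
    nb_first_lat = nb_lat, nb_first_lon = nb_lon,
    nb_last_lat = nb_lat, nb_last_lon = nb_lon,
    dep_nb = jan1 + (doys$dep_nb - 1),
    arr_b = jan1 + (doys$arr_b - 1),
    dep_b = jan1 + (doys$dep_b - 1),
    arr_nb = jan1 + (doys$arr_nb - 1),
    flight_mode = ifelse(soaring[sp_idx], "soaring", "flapping"),
    stringsAsFactors = FALSE
  )
  tracking <- validate_tracking(tracking)
  if (nrow(attr(tracking, "rejected"))) {
    stop("internal error: generated records failed validation")
  }

  truth$resid_var <- resid_var
  truth$seed <- as.integer(seed)
  truth$n_records <- n
  truth$guards <- list(distance_clamped = clamped,
                       timing_redraws = redraws,
                       gap_forced = forced)
  structure(list(tracking = tracking, traits = traits, tree = tree,
                 truth = truth), class = "sim_bundle")
}

#' Convenience wrapper: tree + dataset in one call
#'
#' @param n_species,mean_records,null passed to [sim_truth()].
#' @param seed single seed for tree and data.
#' @param ... further arguments to [sim_truth()].
#' @return a `sim_bundle`.
#' @export
simulate_bundle <- function(n_species = 186, mean_records = 9,
                            seed = 1L, null = FALSE, ...) {
  truth <- sim_truth(n_species = n_species, mean_records = mean_records,
                     null = null, ...)
  tree <- simulate_tree(n_species, seed = seed)
  simulate_dataset(truth, tree, seed = seed + 1L)
}

#' Write a bundle to disk
#'
#' Emits `tracking.csv`, `traits.csv`, `tree.nwk` and `truth.json` in
#' exactly the dialects the readers consume; a write/read round trip
#' reproduces the records.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracking = file.path(dir, "tracking.csv"),
             traits = file.path(dir, "traits.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_tracking_table(bundle$tracking, paths["tracking"])
  utils::write.csv(bundle$traits, paths["traits"], row.names = FALSE,
                   quote = FALSE)
  ape::write.tree(bundle$tree, paths["tree"])
  # named atomic vectors serialize as unnamed JSON arrays; convert them
  # to lists so names (parent/component labels) survive the round trip
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(listify(unclass(bundle$truth)), paths["truth"],
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(paths)
}
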