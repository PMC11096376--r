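# Pipeline orchestration: validate -> derive -> fit -> decompose ->
# report, behind one configurable entry point.

#' Assemble a run configuration
#'
#' @param tracking,traits,tree input file paths.
#' @param out_dir output directory for artifacts.
#' @param backend,chains,iter,burnin,seed fitting settings (see
#'   [sem_control()]).
#' @param include_sex add sex to the timing equations.
#' @param subset optional named list of filters applied to the derived
#'   table before fitting; names are columns (`order`, `sex`,
#'   `capture_site_class`, `flight_mode`, `species`), values the levels
#'   to keep.
#' @param add_edges,remove_edges lists of `c(from, to)` DAG edits.
#' @param dsep run the d-separation test (default TRUE).
#' @return a validated `run_config`.
#' @export
run_config <- function(tracking, traits, tree, out_dir = "migsem_out",
                       backend = "reml", chains = 4, iter = 10000,
                       burnin = 1000, seed = 1L, include_sex = FALSE,
                       subset = NULL, add_edges = list(),
                       remove_edges = list(), dsep = TRUE) {
  cfg <- list(tracking = tracking, traits = traits, tree = tree,
              out_dir = out_dir, backend = backend, chains = chains,
              iter = iter, burnin = burnin, seed = as.integer(seed),
              include_sex = isTRUE(include_sex), subset = subset,
              add_edges = add_edges, remove_edges = remove_edges,
              dsep = isTRUE(dsep))
  for (f in c("tracking", "traits", "tree")) {
    if (!file.exists(cfg[[f]])) stop(f, " not found: ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  do.call(run_config, raw)
}

write_coef_csv <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    cbind(response = f$response, f$coefficients,
          R2_marginal = f$R2[["marginal"]],
          R2_conditional = f$R2[["conditional"]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

write_varcomp_csv <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    data.frame(response = f$response, component = names(f$sigma2),
               variance = unname(f$sigma2), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Duration mixed models
#'
#' One mixed model per annual-cycle period (spring, breeding, autumn,
#' non-breeding duration) with fixed effects body mass, breeding
#' latitude, absolute non-breeding latitude and migration distance, and
#' the shared random-effect structure.
#'
#' @param derived a `cycle_derived` table.
#' @param phylo a `phylo_cov`.
#' @param control a [sem_control()].
#' @return named list of `equation_fit`s.
#' @export
run_duration_models <- function(derived, phylo, control = sem_control()) {
  fits <- list()
  for (dur in DURATION_VARS) {
    dg <- dag_model(stats::setNames(list(
      c("body_mass", "breed_lat", "nb_lat_abs", "mig_dist")), dur))
    mm <- assemble_matrix(derived, dur, dg,
                          scale_response = control$scale_response)
    fits[[dur]] <- fit_equation(mm, phylo, control)
  }
  fits
}

apply_subset <- function(derived, subset) {
  if (is.null(subset)) return(derived)
  keep <- rep(TRUE, nrow(derived))
  for (nm in names(subset)) {
    if (!nm %in% names(derived)) stop("unknown subset column: ", nm)
    keep <- keep & derived[[nm]] %in% unlist(subset[[nm]])
  }
  msg("subset filters keep ", sum(keep), " of ", length(keep), " records")
  derived[keep, ]
}

#' Run the full analysis pipeline
#'
#' Stages: read and validate the tracking/trait tables and tree; derive
#' cycle quantities; summarize timing (including the paired autumn vs
#' spring duration t test); fit the piecewise SEM and the four duration
#' models; decompose direct/indirect/total effects; d-separation test;
#' write per-stage artifacts and a machine-readable manifest.
#'
#' @param cfg a `run_config`, or a path to a YAML/JSON config file.
#' @return list with the in-memory results (`summary`, `paired_t`,
#'   `sem`, `durations`, `effects`, `dsep`, `manifest`), invisibly;
#'   artifacts under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  t0 <- Sys.time()
  stage <- function(name) {
    stages <<- c(stages, name)
    msg("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", name)
  }

  stage("read")
  records <- read_tracking_table(cfg$tracking)
  traits <- read_trait_table(cfg$traits)
  tree <- read_newick(cfg$tree)
  rejected <- attr(records, "rejected")
  utils::write.csv(rejected, file.path(out, "rejected.csv"),
                   row.names = FALSE)

  stage("derive")
  derived <- derive_cycle(records, traits)
  derived <- apply_subset(derived, cfg$subset)
  if (nrow(derived) == 0) stop("no records left after filtering")
  utils::write.csv(derived, file.path(out, "derived.csv"),
                   row.names = FALSE)

  stage("phylogeny")
  tree_used <- prune_to_species(tree, unique(derived$species))
  phylo <- vcv_from_tree(tree_used)

  stage("summarize")
  summ <- summarize_timing(derived)
  utils::write.csv(summ$species, file.path(out, "timing_species.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$overall, file.path(out, "timing_overall.csv"),
                   row.names = FALSE)
  pt <- paired_t_autumn_vs_spring(derived)
  jsonlite::write_json(pt, file.path(out, "paired_t.json"),
                       auto_unbox = TRUE, digits = NA)

  stage("fit")
  control <- sem_control(backend = cfg$backend, chains = cfg$chains,
                         iter = cfg$iter, burnin = cfg$burnin,
                         seed = cfg$seed)
  dag <- edit_dag(build_default_dag(include_sex = cfg$include_sex),
                  add = cfg$add_edges, remove = cfg$remove_edges)
  sem <- fit_sem(derived, dag, phylo, control)
  write_coef_csv(sem$fits, file.path(out, "sem_coefficients.csv"))
  write_varcomp_csv(sem$fits, file.path(out, "sem_varcomp.csv"))

  stage("durations")
  durations <- run_duration_models(derived, phylo, control)
  write_coef_csv(durations, file.path(out, "duration_coefficients.csv"))

  stage("decompose")
  effects <- decompose_effects(dag, sem, force = TRUE)
  utils::write.csv(as.data.frame(effects),
                   file.path(out, "effects.csv"), row.names = FALSE)
  rendered <- render_effect_table(effects)
  utils::write.table(rendered, file.path(out, "effects_table.txt"),
                     quote = FALSE, sep = "\t", col.names = NA)
  jsonlite::write_json(attr(effects, "paths"),
                       file.path(out, "effect_paths.json"),
                       auto_unbox = TRUE, digits = NA)

  dsep <- NULL
  if (cfg$dsep) {
    stage("dsep")
    dsep <- dsep_test(derived, dag, phylo, control)
    utils::write.csv(dsep$claims, file.path(out, "dsep_claims.csv"),
                     row.names = FALSE)
    jsonlite::write_json(dsep[c("C", "df", "p_value")],
                         file.path(out, "dsep.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  stage("manifest")
  manifest <- list(
    package = "migsem",
    version = as.character(utils::packageVersion("migsem")),
    seed = cfg$seed,
    backend = cfg$backend,
    config = unclass(cfg),
    config_hash = unname(tools::md5sum(cfg$tracking)),
    n_records = nrow(derived),
    n_rejected = nrow(rejected),
    n_species = length(unique(derived$species)),
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(summary = summ, paired_t = pt, sem = sem,
                 durations = durations, effects = effects, dsep = dsep,
                 manifest = manifest))
}
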