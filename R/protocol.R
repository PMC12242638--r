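# End-to-end protocol runner
# --------------------------
# Wires the stages together: curate an activity table, diversity-select
# representatives, screen a feature library against a pharmacophore model
# (with and without the required hinge constraint), and evaluate the two
# protocols by ROC/AUC. Every output lands in one run directory together
# with a manifest (parameters, seed, file checksums).

default_config <- function() {
  list(
    seed = 1L,
    model = "ROCK1",
    active_nM = 100,
    inactive_nM = 5000,
    max_mw = 550,
    diversity_threshold = 0.5,
    max_conformers = 200,
    synthetic = list(
      n_active = 15, n_inactive = 25, n_intermediate = 5, n_ic50 = 5,
      library_actives = 20, library_decoys = 180, jitter_sigma = 0.3
    ),
    activities_csv = NULL
  )
}

#' Run the complete screening protocol
#'
#' Stages: (1) obtain an activity table (from `config$activities_csv` or the
#' synthetic generator), (2) curate it (activity classes, structural filters,
#' diversity selection), (3) screen a pharmacophore feature library against
#' the configured model with the hinge acceptor required, and once more with
#' no required point, (4) evaluate both protocols (ROC/AUC, enrichment).
#'
#' @param config named list overriding the defaults (see
#'   `phorescreen:::default_config()`); unknown model names abort with the
#'   list of valid choices.
#' @param out_dir run directory (created).
#' @return the manifest (invisibly); all stage outputs are files in
#'   `out_dir`.
#' @export
run_protocol <- function(config = list(), out_dir = tempfile("psrun")) {
  cfg <- utils::modifyList(default_config(), config)
  if (!(cfg$model %in% c("ROCK1", "ROCK2"))) {
    stop("unknown model '", cfg$model, "'; valid choices: ROCK1, ROCK2")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- builtin_model(cfg$model)
  stages <- character()

  message("[curate] activity table")
  if (!is.null(cfg$activities_csv)) {
    parsed <- parse_activity_table(cfg$activities_csv)
  } else {
    syn <- make_activity_table(cfg$synthetic$n_active, cfg$synthetic$n_inactive,
                               cfg$synthetic$n_intermediate,
                               cfg$synthetic$n_ic50, seed = cfg$seed,
                               dir = out_dir)
    parsed <- list(records = syn$table,
                   rejects = data.frame(row = integer(), smiles = character(),
                                        reason = character()))
  }
  labeled <- classify_activity(parsed$records, cfg$active_nM, cfg$inactive_nM)
  filt <- apply_structural_filters(labeled$actives, max_mw = cfg$max_mw)
  curated <- rbind(
    data.frame(compound_id = filt$kept$compound_id,
               canonical_smiles = filt$kept$canonical_smiles,
               label = "active", stringsAsFactors = FALSE),
    if (nrow(labeled$inactives)) data.frame(
      compound_id = labeled$inactives$compound_id,
      canonical_smiles = labeled$inactives$smiles, label = "inactive",
      stringsAsFactors = FALSE)
  )
  write.csv(curated, file.path(out_dir, "curated.csv"), row.names = FALSE)
  stages <- c(stages, "curate")

  message("[diversity] representative selection")
  if (nrow(filt$kept) >= 2) {
    div <- diversity_select(
      data.frame(compound_id = filt$kept$compound_id,
                 smiles = filt$kept$canonical_smiles,
                 stringsAsFactors = FALSE),
      distance_threshold = cfg$diversity_threshold)
    write.csv(data.frame(compound_id = filt$kept$compound_id,
                         cluster = div$cluster_labels),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
  }
  stages <- c(stages, "diversity")

  message("[screen] pharmacophore screening")
  lib <- make_planted_feature_library(
    model, n_actives = cfg$synthetic$library_actives,
    n_decoys = cfg$synthetic$library_decoys,
    jitter_sigma = cfg$synthetic$jitter_sigma, seed = cfg$seed)
  ranked <- screen_library(lib$library, model,
                           max_conformers = cfg$max_conformers)
  ranked_free <- screen_library(lib$library, model,
                                max_conformers = cfg$max_conformers,
                                require = character())
  write.csv(ranked, file.path(out_dir, "ranked_constrained.csv"),
            row.names = FALSE)
  write.csv(ranked_free, file.path(out_dir, "ranked_unconstrained.csv"),
            row.names = FALSE)
  stages <- c(stages, "screen")

  message("[evaluate] ROC/AUC")
  runs <- lapply(list(constrained = ranked, unconstrained = ranked_free),
                 function(r) {
    s <- setNames(r$score, r$compound_id)
    list(scores = s, labels = lib$labels[names(s)])
  })
  cmp <- compare_protocols(runs)
  jsonlite::write_json(
    list(metrics = cmp$metrics,
         auc_difference = cmp$auc_differences["constrained", "unconstrained"]),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  stages <- c(stages, "evaluate")

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phorescreen")),
    seed = cfg$seed,
    model = cfg$model,
    parameters = cfg[c("active_nM", "inactive_nM", "max_mw",
                       "diversity_threshold", "max_conformers")],
    stages = stages,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
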