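#' Run the full assessment and apportionment pipeline
#'
#' Chains every stage on a paired survey: descriptive statistics,
#' pollution indices, BCF summary and exceedance folds, per-species
#' soil-plant correlations, group-difference tests, the APCS-MLR
#' receptor model, and (when a source table is given) random-forest
#' apportionment. One CSV per stage plus a JSON run manifest is
#' written under `out_dir` when it is non-NULL.
#'
#' @param soil,plants paired `concentration_table`s (see
#'   [read_survey()]).
#' @param refs a [reference_set()].
#' @param sources optional [source_table()] for the RF stage.
#' @param out_dir optional output directory.
#' @param seed seed for the RF split (default 42).
#' @param lambda proximity decay length in km for RF features.
#' @return List of stage results (invisible when writing to disk):
#'   `soil_stats`, `plant_stats`, `indices`, `bcf`, `exceedance`,
#'   `correlations`, `tests`, `apcs`, `rf` (NULL without sources).
#' @export
run_pipeline <- function(soil, plants, refs = default_references(),
                         sources = NULL, out_dir = NULL, seed = 42,
                         lambda = 10) {
  res <- list(
    soil_stats = describe(soil),
    plant_stats = describe(plants),
    indices = pollution_indices(soil, refs),
    bcf = species_bcf_summary(plants, soil),
    exceedance = exceedance_table(plants, refs),
    correlations = soil_plant_correlations(plants, soil),
    tests = group_difference_tests(plants),
    apcs = apcs_mlr(plants))
  res$rf <- if (!is.null(sources) && all(c("x", "y") %in% names(plants)))
    rf_apportion(plants, sources = sources, seed = seed,
                 lambda = lambda) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    w(res$soil_stats, "soil_stats.csv")
    w(res$plant_stats, "plant_stats.csv")
    w(res$indices$summary, "indices.csv")
    w(res$bcf$species, "bcf.csv")
    w(res$exceedance, "exceedance.csv")
    cors <- do.call(rbind, lapply(names(res$correlations), function(s) {
      r <- unclass(res$correlations)[[s]]
      data.frame(species = s,
                 plant_metal = rep(rownames(r), ncol(r)),
                 soil_metal = rep(colnames(r), each = nrow(r)),
                 r = as.vector(r))
    }))
    w(cors, "correlations.csv")
    w(res$tests$omnibus, "tests_omnibus.csv")
    w(res$tests$pairwise, "tests_pairwise.csv")
    w(source_contributions(res$apcs), "apcs_contributions.csv")
    load_long <- data.frame(
      metal = rep(rownames(res$apcs$pca$loadings), res$apcs$pca$q),
      component = rep(colnames(res$apcs$pca$loadings)[seq_len(res$apcs$pca$q)],
                      each = length(res$apcs$metals)),
      loading = as.vector(
        res$apcs$pca$loadings[, seq_len(res$apcs$pca$q), drop = FALSE]))
    w(load_long, "apcs_loadings.csv")
    if (!is.null(res$rf)) {
      w(res$rf$metrics, "rf_report.csv")
      imp <- res$rf$importance
      w(data.frame(metal = rep(rownames(imp), ncol(imp)),
                   source = rep(colnames(imp), each = nrow(imp)),
                   percent = as.vector(imp)), "rf_importance.csv")
    }
    manifest <- list(
      package = "metalsource",
      version = as.character(utils::packageVersion("metalsource")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = seed, lambda = lambda,
      n_soil = nrow(soil), n_plants = nrow(plants),
      metals = attr(soil, "metals"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res
}
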