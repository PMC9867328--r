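#' Run the full analysis pipeline
#'
#' Orchestrates synthesis (or loading), preprocessing, feature extraction,
#' subject-dependent nested cross-validation, feature-set comparison, and
#' topography export, writing plain-text results to `outputDir`:
#' `results_<dimension>.csv` (per-subject fold accuracies),
#' `comparison_<dimension>.csv` (paired statistics vs the reference set),
#' `topography_<dimension>.json`, and `manifest.json` (configuration echo,
#' seeds, per-stage row counts, wall time). Deterministic for a fixed seed.
#'
#' @param synth a [synthConfig()] describing the synthetic dataset, or
#'   `NULL` to supply `recordings` + `ratings`.
#' @param recordings,ratings pre-loaded data (used when `synth` is NULL).
#' @param dimension rating dimension to classify.
#' @param sets feature sets to evaluate (plus `"combined"`).
#' @param classifiers classifiers to evaluate.
#' @param cv a [cvConfig()].
#' @param topoFeature feature whose scalp topography is exported.
#' @param outputDir output directory, or `NULL` to skip writing.
#' @param seed master seed; overrides the seeds inside `synth` and `cv`.
#' @return Invisibly, a list with `epochs`, `features`, `results`,
#'   `comparison`, `topography` and `manifest`.
#' @export
runPipeline <- function(synth = synthConfig(),
                        recordings = NULL, ratings = NULL,
                        dimension = c("valence", "arousal"),
                        sets = c("statistical", "fractal"),
                        classifiers = "cart",
                        cv = cvConfig(classifier = "cart"),
                        topoFeature = "fd_higuchi",
                        outputDir = NULL, seed = 1L) {
  dimension <- match.arg(dimension)
  t0 <- Sys.time()
  if (!is.null(synth)) {
    synth$seed <- as.integer(seed)
    ds <- genDataset(synth)
    recordings <- ds$recordings
    ratings <- ds$ratings
  }
  if (is.null(recordings) || is.null(ratings))
    stop("stage preprocess: recordings and ratings are required")
  epochs <- buildEpochSet(recordings, ratings, dimension = dimension)
  features <- assembleFeatureTable(epochs, sets = setdiff(sets, "combined"))
  cv$seed <- as.integer(seed)
  results <- subjectCV(features, sets = sets, classifiers = classifiers,
                       config = cv)
  comparison <- if (length(setdiff(unique(results$featureSet), "fractal")) &&
                    "fractal" %in% results$featureSet)
    compareFeatureSets(results, classifier = classifiers[1])
  topography <- topographyExport(features, topoFeature,
                                 channels = channelNames(epochs))
  manifest <- list(
    dimension = dimension, sets = sets, classifiers = classifiers,
    seed = seed, cv = unclass(cv),
    synth = if (!is.null(synth)) unclass(synth),
    n_recordings = length(recordings),
    n_epochs = dim(eegData(epochs))[1],
    n_rejected = nRejected(epochs),
    n_features = nrow(features),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(results,
                       file.path(outputDir,
                                 paste0("results_", dimension, ".csv")))
    if (!is.null(comparison))
      data.table::fwrite(comparison,
                         file.path(outputDir,
                                   paste0("comparison_", dimension, ".csv")))
    jsonlite::write_json(topography,
                         file.path(outputDir,
                                   paste0("topography_", dimension, ".json")),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(epochs = epochs, features = features, results = results,
                 comparison = comparison, topography = topography,
                 manifest = manifest))
}
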