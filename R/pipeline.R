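#' Run configuration
#'
#' Collects all tunable settings of the pipeline in one serializable list:
#' labeling thresholds, feature-extraction settings, ML settings (seed,
#' model families, ranking tolerance) and the float precision of written
#' reports. `runConfig()` fills in the defaults; `readRunConfig()` loads a
#' YAML file, with unspecified keys falling back to the defaults.
#' `configHash()` is an MD5 over a canonicalized (recursively key-sorted)
#' JSON serialization, so it is stable under key reordering.
#'
#' @param labeling a [LabelingConfig-class].
#' @param features a [FeatureConfig-class].
#' @param seed integer seed for all stochastic stages.
#' @param models model family names to evaluate.
#' @param tolerance ranking tie tolerance.
#' @param digits report float precision.
#' @return `runConfig()`: a list of class `"runConfig"`.
#' @export
runConfig <- function(labeling = labelingConfig(),
                      features = featureConfig(), seed = 1L,
                      models = MODEL_FAMILIES, tolerance = 0.001,
                      digits = 3) {
  structure(list(labeling = labeling, features = features,
                 seed = as.integer(seed), models = models,
                 tolerance = tolerance, digits = digits),
            class = "runConfig")
}

#' @rdname runConfig
#' @param path YAML file; recognized top-level keys: `labeling`,
#'   `features` (each a map of the respective config slots), `seed`,
#'   `models`, `tolerance`, `digits`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  lab <- do.call(labelingConfig, as.list(y$labeling %||% list()))
  fc <- y$features %||% list()
  if (!is.null(fc$vdwRadii)) fc$vdwRadii <- unlist(fc$vdwRadii)
  feat <- do.call(featureConfig, as.list(fc))
  runConfig(labeling = lab, features = feat,
            seed = y$seed %||% 1L,
            models = y$models %||% MODEL_FAMILIES,
            tolerance = y$tolerance %||% 0.001,
            digits = y$digits %||% 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configAsList <- function(config) {
  s4list <- function(obj) {
    out <- lapply(methods::slotNames(obj), function(s) slot(obj, s))
    names(out) <- methods::slotNames(obj)
    out
  }
  list(labeling = s4list(config$labeling),
       features = s4list(config$features),
       seed = config$seed, models = config$models,
       tolerance = config$tolerance, digits = config$digits)
}

.sortKeys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    x <- lapply(x, .sortKeys)
  }
  x
}

#' @rdname runConfig
#' @param config a `"runConfig"` list.
#' @return `configHash()`: a single MD5 hex string.
#' @export
configHash <- function(config) {
  canon <- jsonlite::toJSON(.sortKeys(.configAsList(config)),
                            auto_unbox = TRUE, digits = 12)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the labeling-to-evaluation pipeline
#'
#' Wires the stages end to end on one homolog pair: label the reference's
#' pocket waters against the homolog, extract the six features, evaluate
#' feature combinations under the configured models (when both classes have
#' enough rows for cross-validation), and write all reports plus a run
#' manifest to `outDir`. No stage mutates its inputs; every written table
#' is deterministic given config and seed, so reruns are byte-identical.
#'
#' @param reference,homolog [StructureModel-class]s or PDB file paths.
#' @param ligand ligand selector (required when paths are given; see
#'   [parsePdb()]).
#' @param outDir output directory (created if needed).
#' @param config a [runConfig()].
#' @param combinations evaluate all combinations (`"all"`), or only the
#'   full feature set (`"full"`), or skip evaluation (`"none"`).
#' @return list with `labels`, `features`, `evaluation` (or `NULL`),
#'   `comparison` (or `NULL`) and `manifest`, invisibly; all also written
#'   as TSV/JSON under `outDir`.
#' @export
runPipeline <- function(reference, homolog, ligand = NULL, outDir,
                        config = runConfig(), combinations = "full") {
  stage <- "parse"
  res <- tryCatch({
    if (is.character(reference))
      reference <- parsePdb(reference, ligand = ligand, requireLigand = TRUE)
    if (is.character(homolog))
      homolog <- parsePdb(homolog, ligand = ligand)
    if (!nrow(ligandAtoms(reference)))
      stop("reference structure has no ligand atoms; pass a ligand ",
           "selector so the binding pocket can be defined")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stages <- character()
    hash <- configHash(config)

    stage <- "label"
    labels <- labelWaters(reference, homolog, config$labeling)
    writeReport(labels, file.path(outDir, "labels.tsv"), config$digits)
    stages <- c(stages, "label")

    stage <- "featurize"
    feats <- featurizeStructure(reference, labels = labels,
                                config = config$features,
                                labelConfig = config$labeling)
    writeReport(feats, file.path(outDir, "features.tsv"), config$digits)
    stages <- c(stages, "featurize")

    evaluation <- NULL
    comparison <- NULL
    labeled <- feats[feats$label %in% c("CWM", "FWM"), , drop = FALSE]
    enough <- length(unique(labeled$label)) == 2L &&
      all(table(labeled$label) >= 5L)
    if (!identical(combinations, "none") && enough) {
      stage <- "evaluate"
      specs <- defaultModelSpecs(seed = config$seed)[config$models]
      if (identical(combinations, "all")) {
        evaluation <- evaluateCombinations(labeled, models = specs,
                                           seed = config$seed)
      } else {
        comboStr <- paste(FEATURE_LETTERS, collapse = "")
        rows <- lapply(names(specs), function(m) {
          met <- fiveFoldCv(labeled, specs[[m]], seed = config$seed)
          cbind(combination = comboStr, model = m, met, n_undefined =
                  sum(is.na(unlist(met))))
        })
        per <- do.call(rbind, rows)
        avg <- vapply(METRIC_NAMES,
                      function(m) mean(per[[m]], na.rm = TRUE), numeric(1))
        evaluation <- rbind(per, cbind(combination = comboStr,
                                       model = "average",
                                       as.data.frame(as.list(avg)),
                                       n_undefined = sum(is.na(per[, METRIC_NAMES]))))
      }
      writeReport(evaluation, file.path(outDir, "evaluation.tsv"),
                  config$digits)
      stages <- c(stages, "evaluate")

      stage <- "compare"
      comparison <- compareModels(labeled, models = specs,
                                  seed = config$seed)
      writeReport(comparison, file.path(outDir, "comparison.tsv"),
                  config$digits)
      stages <- c(stages, "compare")
    }

    stage <- "manifest"
    manifest <- list(
      package = "conswat",
      version = as.character(utils::packageVersion("conswat")),
      config_hash = hash, seed = config$seed, stages = as.list(stages),
      reference = structureId(reference), homolog = structureId(homolog),
      n_pocket_waters = sum(labels$in_pocket),
      n_labeled = sum(labels$label != "unlabeled"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(labels = labels, features = feats, evaluation = evaluation,
         comparison = comparison, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
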