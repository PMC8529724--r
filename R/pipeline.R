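## End-to-end orchestration. The exported functions are the interface;
## each stage is runnable standalone on files produced by any earlier
## stage. All randomness flows from one root seed expanded per stage
## (the synthetic generators add fixed per-stage offsets).

.stageOrder <- c("simulate", "growth", "doseresponse", "concord",
                 "enrich", "biomarker", "synergy", "qc")

#' Run the full analysis pipeline on a synthetic or supplied study
#'
#' Executes, in dependency order: data simulation (unless an input
#' directory with the expected files is supplied), in-vivo T/C
#' quantification, dose-response fitting with Cmax viabilities,
#' ordinal categorization and cross-platform concordance, ssGSEA and
#' GSEA enrichment, ROC biomarker discovery, combination synergy, and
#' matched-sample QC correlations. Every stage writes CSV/TSV outputs
#' under `outdir` and the run closes with a JSON manifest recording
#' the configuration hash, input checksums, seed and output paths.
#' A stage failure stops the run with an error naming the stage.
#'
#' @param outdir output directory, created if needed.
#' @param config a [syntheticConfig()] list, or a path to a YAML file
#'   of overrides (read by [readRunConfig()]).
#' @param seed root seed; overrides the config seed when given.
#' @param stages subset of stages to run (default: all).
#' @param nPerm permutations for the GSEA stage.
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(outdir, config = syntheticConfig(), seed = NULL,
                        stages = .stageOrder, nPerm = 1000) {
  if (is.character(config)) {
    ov <- readRunConfig(config)
    config <- do.call(syntheticConfig, ov)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- match.arg(stages, .stageOrder, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inputDir <- file.path(outdir, "inputs")
  outputs <- character()
  addOut <- function(path) outputs <<- c(outputs, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% stages)
    stage("simulate", generateStudy(config, inputDir))
  rd <- function(f, schema) readMeasurementTable(file.path(inputDir, f),
                                                 schema)

  if ("growth" %in% stages) stage("growth", {
    growth <- rd("growth.csv", "growth")
    tc <- tcTable(growth)
    addOut(writeResults(tc, file.path(outdir, "tc_results.csv")))
    ctl <- growth[growth$arm == "control", ]
    dts <- do.call(rbind, c(lapply(split(ctl, ctl$model), function(sub) {
      perDay <- tapply(tumorVolume(sub$width_mm, sub$length_mm),
                       sub$day, mean)
      cbind(model = sub$model[1],
            doublingTime(as.numeric(names(perDay)), as.numeric(perDay)))
    }), list(make.row.names = FALSE)))
    addOut(writeResults(dts, file.path(outdir, "doubling_times.csv")))
  })

  if ("doseresponse" %in% stages) stage("doseresponse", {
    viab <- rd("viability.csv", "viability")
    cmax <- utils::read.csv(file.path(inputDir, "cmax.csv"))
    drt <- doseResponseTable(viab, cmax)
    addOut(writeResults(drt$fitTable, file.path(outdir, "dose_response_fits.csv")))
    addOut(writeResults(drt$cmaxTable, file.path(outdir, "cmax_viability.csv")))
  })

  if ("concord" %in% stages) stage("concord", {
    resp <- rd("responses.csv", "response")
    pairs <- concordancePairs(resp)
    addOut(writeResults(pairs, file.path(outdir, "concordance_pairs.csv")))
    summ <- summarizeConcordance(pairs)
    addOut(writeResults(summ$perDrug, file.path(outdir, "concordance_summary.csv")))
    overall <- data.frame(overall_mean = summ$overallMean,
                          overall_sd = summ$overallSD,
                          pooled_percent = summ$pooledPercent)
    addOut(writeResults(overall, file.path(outdir, "concordance_overall.csv")))
  })

  if ("enrich" %in% stages) stage("enrich", {
    m <- readExpressionMatrix(file.path(inputDir, "expression_PDX.tsv"))
    gsc <- readGmt(file.path(inputDir, "genesets.gmt"))
    scores <- ssgseaMatrix(m, gsc)
    writeExpressionMatrix(scores, file.path(outdir, "ssgsea_scores.tsv"))
    addOut(file.path(outdir, "ssgsea_scores.tsv"))
    labels <- utils::read.csv(file.path(inputDir, "truth", "labels.csv"))
    lab <- labels$label[match(sub("_PDX$", "", colnames(m)), labels$model)]
    res <- gseaCollection(m, lab, gsc, nPerm = nPerm,
                          seed = config$seed + 505L,
                          positive = "responder")
    addOut(writeResults(res, file.path(outdir, "gsea_results.csv")))
  })

  if ("biomarker" %in% stages) stage("biomarker", {
    labels <- utils::read.csv(file.path(inputDir, "truth", "labels.csv"))
    recs <- list()
    for (pl in c("patient", "PDX", "PD3D")) {
      m <- readExpressionMatrix(file.path(
        inputDir, sprintf("expression_%s.tsv", pl)))
      lab <- labels$label[match(sub("_[^_]+$", "", colnames(m)),
                                labels$model)]
      if (pl == "PDX") {
        ct <- groupContrast(m, lab, scale = "linear",
                            positive = "responder")
        addOut(writeResults(ct, file.path(outdir, "group_contrast_PDX.csv")))
      }
      recs[[pl]] <- rocTable(log2(m + 1), lab, drug = "drug01",
                             sampleType = pl, positive = "responder")
    }
    rocs <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    addOut(writeResults(rocs, file.path(outdir, "roc_records.csv")))
    matched <- matchBiomarkers(rocs)
    addOut(writeResults(matched, file.path(outdir, "matched_biomarkers.csv"),
                        columns = names(matched)))
  })

  if ("synergy" %in% stages) stage("synergy", {
    comb <- rd("combination.csv", "combination")
    syn <- synergyTable(comb)
    addOut(writeResults(syn$cells, file.path(outdir, "synergy_cells.csv")))
    addOut(writeResults(syn$summary, file.path(outdir, "synergy_summary.csv")))
  })

  if ("qc" %in% stages) stage("qc", {
    mats <- lapply(c("patient", "PDX", "PD3D"), function(pl)
      readExpressionMatrix(file.path(inputDir,
                                     sprintf("expression_%s.tsv", pl))))
    m <- do.call(cbind, mats)
    models <- unique(sub("_[^_]+$", "", colnames(m)))
    pairing <- do.call(rbind, lapply(models, function(md) data.frame(
      sample_a = paste0(md, c("_patient", "_PDX", "_patient")),
      sample_b = paste0(md, c("_PDX", "_PD3D", "_PD3D")),
      relation = c("patient-PDX", "PDX-PD3D", "patient-PD3D"),
      layer = "transcriptome")))
    # a few unmatched pairs as reference distribution
    if (length(models) >= 2)
      pairing <- rbind(pairing, data.frame(
        sample_a = paste0(models[1], "_patient"),
        sample_b = paste0(models[2], "_PDX"),
        relation = "unmatched", layer = "transcriptome"))
    cors <- pairwiseCorrelations(m, pairing)
    addOut(writeResults(cors, file.path(outdir, "qc_correlations.csv")))
  })

  manifest <- buildManifest(outdir, config, stages, outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Build the run manifest
#'
#' The manifest hash covers the canonicalized configuration and the
#' checksums of all input files, so identical config + inputs give an
#' identical hash regardless of when the run happened (timestamps are
#' recorded separately and excluded from the hash).
#'
#' @param outdir run directory containing `inputs/`.
#' @param config the configuration list used.
#' @param stages stages that ran.
#' @param outputs character vector of output paths.
#' @return list with `config_hash`, `manifest_hash`,
#'   `input_checksums`, `seed`, `stages`, `outputs`, `package_version`,
#'   `timestamp`.
#' @export
buildManifest <- function(outdir, config, stages, outputs) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfgFile <- tempfile(); writeLines(as.character(cfgJson), cfgFile)
  cfgHash <- unname(tools::md5sum(cfgFile)); unlink(cfgFile)
  inputs <- sort(list.files(file.path(outdir, "inputs"), recursive = TRUE,
                            full.names = TRUE))
  sums <- tools::md5sum(inputs)
  names(sums) <- sub(paste0("^", outdir, "/?"), "", names(sums))
  hashFile <- tempfile()
  writeLines(c(cfgHash, paste(names(sums), unname(sums))), hashFile)
  mHash <- unname(tools::md5sum(hashFile)); unlink(hashFile)
  list(config_hash = cfgHash, manifest_hash = mHash,
       input_checksums = as.list(sums), seed = config$seed,
       stages = stages,
       outputs = sub(paste0("^", outdir, "/?"), "", outputs),
       package_version = as.character(utils::packageVersion("xenoScreen")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
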