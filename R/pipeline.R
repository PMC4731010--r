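# Staged pipeline orchestration: each stage runs one analysis step from a
# validated config, writes its outputs plus a reproducibility manifest.

pipelineStages <- c("synth", "extract", "fit-constants", "fit-levels",
                    "ara-transfer", "optimize", "simulate-grid",
                    "bifurcation")

fileDigests <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

writeManifest <- function(stage, config, inputs, outputs, seed, outdir) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE)
  manifest <- list(
    command = paste("runStage", stage),
    config_hash = unname(tools::md5sum(
      local({
        f <- tempfile()
        writeLines(cfgJson, f)
        f
      }))),
    inputs = fileDigests(inputs),
    outputs = fileDigests(outputs),
    seed = seed,
    package_version = as.character(utils::packageVersion("orthosignal")),
    timestamp = format(Sys.time(), tz = "UTC"),
    output_paths = as.list(outputs))
  path <- file.path(outdir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Run one pipeline stage
#'
#' Executes one step of the staged analysis -- synthetic-data generation,
#' ratiometric extraction, constants/levels inference, receiver-level
#' optimization, grid simulation or bifurcation scan -- from a config list,
#' writing outputs and a JSON run manifest (config hash, input/output file
#' digests, seed, package version, timestamps) into \code{config$outdir}.
#' Stages never mutate their inputs; deterministic stages re-run with an
#' identical manifest reproduce identical outputs.
#'
#' Config fields by stage (all stages: \code{outdir}, \code{seed}):
#' \describe{
#'   \item{synth}{\code{design} (a \linkS4class{PlateDesign} or preset
#'     name) -> values/conditions CSVs.}
#'   \item{extract}{\code{values}, \code{conditions} (CSV paths, e.g. from
#'     synth), \code{target}, \code{reference} -> tidy dose-response CSV.}
#'   \item{fit-constants}{\code{entries}, \code{promoters}, \code{free},
#'     \code{draws} -> posterior CSV (draw, parameter, value) + JSON
#'     summary.}
#'   \item{fit-levels}{\code{drCfp}, \code{drYfp}
#'     (\linkS4class{DoseResponse}), \code{device}, \code{draws} ->
#'     posterior CSV + JSON summary.}
#'   \item{optimize}{\code{device}, \code{rRange}, \code{sRange},
#'     \code{nGrid} -> landscape CSV (r, s, ratio) + JSON optimum.}
#'   \item{simulate-grid}{\code{layout}, \code{params}, \code{horizon} ->
#'     long trajectory CSV.}
#'   \item{bifurcation}{\code{params}, \code{scales} -> scan CSV + JSON
#'     threshold.}
#' }
#'
#' @param stage stage name.
#' @param config named list of stage settings.
#' @return A list with \code{manifest} and stage-specific \code{result}.
#' @export
runStage <- function(stage, config = list()) {
  stage <- match.arg(stage, pipelineStages)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  inputs <- character(0)
  outputs <- character(0)
  result <- NULL

  if (stage == "synth") {
    design <- config$design %||% "fig1C"
    if (is.character(design)) design <- designPreset(design, seed = seed)
    pe <- generatePlate(design)
    outputs <- file.path(outdir, c("plate_values.csv", "plate_conditions.csv"))
    writePlateCSV(pe, outputs[1], outputs[2])
    truthFile <- file.path(outdir, "plate_truth.csv")
    write.csv(S4Vectors::metadata(pe)$truth, truthFile, row.names = FALSE)
    outputs <- c(outputs, truthFile)
    result <- pe
  } else if (stage == "extract") {
    inputs <- c(config$values, config$conditions)
    for (f in inputs) if (!file.exists(f))
      stop("dependency error: missing input '", f,
           "'; run the 'synth' stage (or point to measured data) first")
    pe <- readPlateCSV(config$values, config$conditions)
    pe <- subtractBackground(pe)
    dr <- buildDoseResponse(pe, config$target %||% "YFP",
                            config$reference %||% "CFP")
    outputs <- file.path(outdir, "dose_response.csv")
    writeDoseResponseCSV(dr, outputs)
    result <- dr
  } else if (stage == "fit-constants") {
    if (is.null(config$entries))
      stop("dependency error: 'entries' missing; run the 'extract' stage first")
    ps <- fitCrosstalkMCMC(config$entries, config$promoters, config$free,
                           draws = config$draws %||% 5000, seed = seed)
    outputs <- file.path(outdir, c("posterior.csv", "posterior_summary.json"))
    writePosterior(ps, outputs[1], outputs[2])
    message(sprintf("fit-constants: %d parameters, acceptance %.2f, max Rhat %.3f",
                    length(ps@paramNames), ps@diagnostics$acceptance,
                    max(ps@diagnostics$rhat)))
    result <- ps
  } else if (stage == "fit-levels") {
    if (is.null(config$drCfp) || is.null(config$drYfp))
      stop("dependency error: channel dose responses missing; run 'extract' first")
    fit <- inferDeviceLevels(config$drCfp, config$drYfp, config$device,
                             draws = config$draws %||% 5000, seed = seed)
    outputs <- file.path(outdir, c("levels_posterior.csv",
                                   "levels_summary.json"))
    writePosterior(fit$posterior, outputs[1], outputs[2])
    result <- fit
  } else if (stage == "optimize") {
    device <- config$device %||% presetDevice()
    opt <- optimizeLevels(device,
                          rRange = config$rRange %||% c(0.1, 100),
                          sRange = config$sRange %||% c(0.1, 100),
                          nGrid = config$nGrid %||% 50)
    outputs <- file.path(outdir, c("landscape.csv", "optimum.json"))
    write.csv(opt$landscape, outputs[1], row.names = FALSE)
    jsonlite::write_json(list(r = opt$rStar, s = opt$sStar,
                              ratio = opt$ratioStar),
                         outputs[2], auto_unbox = TRUE, digits = NA)
    result <- opt
  } else if (stage == "simulate-grid") {
    layout <- config$layout %||% senderReceiverLayout()
    sp <- config$params %||% defaultSpatialParams()
    traj <- simulateGrid(layout, sp, horizon = config$horizon %||% 1500,
                         recordEvery = config$recordEvery %||% 100)
    outputs <- file.path(outdir, "trajectory.csv")
    writeGridCSV(traj, outputs)
    totals <- vapply(traj@states, function(s) sum(s@c6) + sum(s@c12),
                     numeric(1))
    message(sprintf("simulate-grid: %d snapshots; final total HSL %.4g nM",
                    length(traj@times), totals[length(totals)]))
    result <- traj
  } else if (stage == "bifurcation") {
    sp <- config$params %||% defaultSpatialParams()
    scan <- bifurcationScan(sp, scales = config$scales %||% seq(0, 4, 0.25),
                            horizon = config$horizon %||% 8000)
    outputs <- file.path(outdir, c("bifurcation.csv", "threshold.json"))
    write.csv(scan$scan, outputs[1], row.names = FALSE)
    jsonlite::write_json(list(threshold = scan$threshold), outputs[2],
                         auto_unbox = TRUE, digits = NA)
    result <- scan
  }

  manifest <- writeManifest(stage, config[setdiff(names(config),
                                                  c("entries", "promoters",
                                                    "device", "layout",
                                                    "params", "design",
                                                    "drCfp", "drYfp"))],
                            inputs, outputs, seed, outdir)
  list(manifest = manifest, result = result)
}

#' Write a posterior sample as CSV + JSON summary
#' @param ps a \linkS4class{PosteriorSample}.
#' @param csvFile long-format CSV (draw, parameter, value).
#' @param jsonFile JSON summary (median, 2.5\%, 97.5\% per parameter,
#'   log10 scale).
#' @return Invisibly, the paths.
#' @export
writePosterior <- function(ps, csvFile, jsonFile = NULL) {
  long <- data.frame(draw = rep(seq_len(nrow(ps@draws)), ncol(ps@draws)),
                     parameter = rep(ps@paramNames, each = nrow(ps@draws)),
                     value = as.vector(ps@draws))
  write.csv(long, csvFile, row.names = FALSE)
  if (!is.null(jsonFile)) {
    ci <- credibleIntervals(ps)
    summ <- lapply(seq_len(nrow(ci)), function(i)
      list(median = ci[i, "median"], lo = ci[i, "lo"], hi = ci[i, "hi"]))
    names(summ) <- rownames(ci)
    jsonlite::write_json(summ, jsonFile, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csvFile, jsonFile))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
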