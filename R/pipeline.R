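writeCsv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Echo every parameter (plus seed and package version) into a manifest so a
# run can be reproduced from its outputs alone. Deterministic content only.
writeManifest <- function(outDir, config) {
  manifest <- list(package = "VesiQuant",
                   version = as.character(packageVersion("VesiQuant")),
                   config = config)
  path <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches to the analysis stages, writes CSV result tables plus a
#' \code{manifest.yaml} echoing every parameter, the seed and the package
#' version into the output directory. Re-running from a manifest
#' (\code{runPipeline(yaml::read_yaml(m)$config)}) reproduces the outputs
#' bit-for-bit for a given seed.
#'
#' Stages and their parameters:
#' \describe{
#'   \item{simulate_tirf / simulate_cell / simulate_tracks}{\code{params}
#'     (generator parameters), \code{seed}; writes TIFFs, \code{truth.csv}
#'     and \code{truth.json}. \code{simulate_tracks} also takes
#'     \code{nStationary}, \code{nDynamic}, \code{thresholdUm}.}
#'   \item{membrane_quant}{\code{input} (TIFF), \code{axes},
#'     \code{blurSigma}, \code{sizeBounds}, \code{erodeCycles}; writes
#'     \code{membrane.csv}.}
#'   \item{tirf_coloc}{\code{input} (TIFF), \code{axes} (e.g. "tcyx" with
#'     named lengths), \code{pixelSizeUm}, \code{frameIntervalS},
#'     \code{coloc} (arguments for \code{\link{colocConfig}}), optional
#'     \code{masks} (TIFF of per-frame masks); writes \code{vesicles.csv}
#'     and \code{frames.csv}.}
#'   \item{coloc3d}{\code{inputA}, \code{inputB} (TIFF volumes, or one
#'     \code{input} with \code{axes} "zcyx" and \code{channelA/B}),
#'     \code{thresholdA}, \code{thresholdB}; writes \code{coloc3d.csv}.}
#'   \item{track}{\code{detections} (CSV with frame, y, x),
#'     \code{pixelSizeUm}, \code{frameIntervalS}, \code{tracking}
#'     (arguments for \code{\link{trackingConfig}}); writes
#'     \code{tracks.csv} and \code{track_points.csv}.}
#'   \item{profile}{\code{input} (TIFF), \code{axes}, \code{p0}, \code{p1},
#'     \code{width}, \code{pixelSizeUm}; writes \code{profile.csv}.}
#'   \item{compare}{\code{valuesA}, \code{valuesB} (numeric vectors or CSV
#'     paths with a \code{value} column), \code{welch}; writes
#'     \code{comparison.csv}.}
#' }
#'
#' @param config named list (or path to a YAML file) with \code{stage},
#'   \code{outDir}, optionally \code{seed}, and stage parameters as above.
#' @return Invisibly, a list with the stage results and the written paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$stage)) stop("config$stage is required", call. = FALSE)
  outDir <- config$outDir
  if (is.null(outDir)) stop("config$outDir is required", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("input", "inputA", "inputB", "detections", "masks")) {
    if (!is.null(config[[f]]) && is.character(config[[f]]) &&
        !file.exists(config[[f]]))
      stop("input path does not exist: ", config[[f]], call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  paths <- character()
  result <- switch(config$stage,
    simulate_tirf = {
      sim <- simulateTirfSeries(config$params %||% list(), seed)
      paths <- c(movie = writeStack(sim$stack,
                                    file.path(outDir, "movie.tif")),
                 truth = writeCsv(sim$truth@records,
                                  file.path(outDir, "truth.csv")),
                 truthJson = writeTruthJson(sim$truth,
                                            file.path(outDir, "truth.json")))
      sim
    },
    simulate_cell = {
      sim <- simulateConfocalCell(config$params %||% list(), seed)
      paths <- c(stack = writeStack(sim$stack,
                                    file.path(outDir, "cell.tif")),
                 truthJson = writeTruthJson(sim$truth,
                                            file.path(outDir, "truth.json")))
      sim
    },
    simulate_tracks = {
      sim <- simulateTracks(config$nStationary %||% 320L,
                            config$nDynamic %||% 109L,
                            config$thresholdUm %||% 0.67, seed,
                            config$params %||% list())
      paths <- c(detections = writeCsv(sim$detections,
                                       file.path(outDir, "detections.csv")),
                 truth = writeCsv(sim$truth@records,
                                  file.path(outDir, "truth.csv")))
      sim
    },
    membrane_quant = {
      stack <- readStack(config$input, config$axes %||% "zyx",
                         config$pixelSizeUm %||% 1)
      res <- quantifyMembrane(stack,
                              blurSigma = config$blurSigma %||% 0,
                              sizeBounds = unlist(config$sizeBounds %||%
                                                    c(500, Inf)),
                              erodeCycles = config$erodeCycles %||% 10L)
      tab <- membraneTable(res, image = basename(config$input))
      paths <- c(membrane = writeCsv(tab, file.path(outDir, "membrane.csv")))
      list(results = res, table = tab)
    },
    tirf_coloc = {
      ax <- axesWithLengths(config$axes %||% "tcyx", config$axisLengths)
      stack <- readStack(config$input, ax, config$pixelSizeUm %||% 0.1,
                         config$frameIntervalS %||% 10)
      cc <- do.call(colocConfig, config$coloc %||% list())
      masks <- NULL
      if (!is.null(config$masks)) {
        nt <- axisLength(stack, "time")
        mstack <- readStack(config$masks, "tyx")
        masks <- stackData(mstack) > 0
      }
      res <- analyzeTirfSeries(stack, cc, masks)
      paths <- c(vesicles = writeCsv(res$vesicles,
                                     file.path(outDir, "vesicles.csv")),
                 frames = writeCsv(res$frames,
                                   file.path(outDir, "frames.csv")))
      if (!is.null(res$reciprocal))
        paths <- c(paths,
                   reciprocal = writeCsv(res$reciprocal,
                                         file.path(outDir,
                                                   "reciprocal.csv")))
      res
    },
    coloc3d = {
      if (!is.null(config$input)) {
        ax <- axesWithLengths(config$axes %||% "zcyx", config$axisLengths)
        stack <- readStack(config$input, ax)
        d <- stackData(stack)
        chAxis <- match("channel", stackAxes(stack))
        pick <- function(ch) {
          idx <- lapply(seq_along(dim(d)), function(i)
            if (i == chAxis) ch else TRUE)
          arrOut <- do.call(`[`, c(list(d), idx, list(drop = FALSE)))
          array(arrOut, dim = dim(arrOut)[-chAxis])
        }
        a <- pick(config$channelA %||% 1L)
        b <- pick(config$channelB %||% 2L)
      } else {
        a <- stackData(readStack(config$inputA, config$axesA %||% "zyx"))
        b <- stackData(readStack(config$inputB, config$axesB %||% "zyx"))
      }
      res <- percentVolumeOverlap(a, b, config$thresholdA %||% "auto:otsu",
                                  config$thresholdB %||% "auto:otsu")
      tab <- data.frame(thresholdA = res@thresholdA,
                        thresholdB = res@thresholdB, nA = res@nA,
                        nB = res@nB, nAB = res@nAB,
                        percentAinB = res@percentAinB,
                        percentBinA = res@percentBinA)
      paths <- c(coloc3d = writeCsv(tab, file.path(outDir, "coloc3d.csv")))
      res
    },
    track = {
      det <- read.csv(config$detections)
      tc <- do.call(trackingConfig, config$tracking %||% list())
      ts <- linkDetections(det, tc, config$pixelSizeUm %||% 0.1,
                           config$frameIntervalS %||% 10)
      cl <- classifyTracks(ts)
      paths <- c(tracks = writeCsv(cl$metrics,
                                   file.path(outDir, "tracks.csv")),
                 points = writeCsv(trackPoints(ts),
                                   file.path(outDir, "track_points.csv")))
      list(tracks = ts, classification = cl)
    },
    profile = {
      stack <- readStack(config$input, config$axes %||% "yx",
                         config$pixelSizeUm %||% 1)
      prof <- lineProfile(stack, unlist(config$p0), unlist(config$p1),
                          config$width %||% 1L)
      paths <- c(profile = writeCsv(prof, file.path(outDir, "profile.csv")))
      prof
    },
    compare = {
      getValues <- function(v) {
        if (is.character(v) && length(v) == 1) read.csv(v)$value
        else as.numeric(unlist(v))
      }
      cmp <- compareGroups(getValues(config$valuesA),
                           getValues(config$valuesB),
                           labels = unlist(config$labels %||% c("A", "B")),
                           welch = isTRUE(config$welch))
      tab <- data.frame(group = cmp@labels, n = cmp@n, mean = cmp@groupMean,
                        sem = cmp@groupSem, t = cmp@statistic, df = cmp@df,
                        p = cmp@pValue, stars = cmp@stars)
      paths <- c(comparison = writeCsv(tab,
                                       file.path(outDir, "comparison.csv")))
      cmp
    },
    stop("unknown stage '", config$stage, "'", call. = FALSE))
  config$seed <- seed
  paths <- c(paths, manifest = writeManifest(outDir, config))
  invisible(list(result = result, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Attach page-axis lengths (given for the non-spatial axes, in order) to an
# axis spec, producing the named form readStack() expects.
axesWithLengths <- function(axes, lengths) {
  if (is.null(lengths)) return(axes)
  axn <- parseAxes(axes)
  lens <- rep(NA_integer_, length(axn))
  lead <- setdiff(axn, c("y", "x"))
  lens[match(lead, axn)] <- as.integer(unlist(lengths))
  setNames(lens, axn)
}

writeTruthJson <- function(truth, path) {
  obj <- list(type = truth@type, seed = truth@seed,
              params = truth@params, records = truth@records)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  path
}
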