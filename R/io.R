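#' @include AllClasses.R AllGenerics.R datamodel.R
NULL

# On-disk container: a directory of one CSV per trial (channels as columns,
# samples as rows, identical headers) plus a meta.json sidecar holding the
# sampling rate and, optionally, channel labels and a time axis.

#' Read multi-trial time series from a CSV directory
#'
#' @param path directory containing one numeric CSV per trial (files are
#'   read in lexicographic order) and optionally a \code{meta.json} with
#'   \code{sampling_rate}, \code{channel_labels}, \code{time_axis}.
#' @param samplingRate sampling rate in Hz; required when the directory has
#'   no \code{meta.json}.
#' @return a [TimeSeriesData-class].
#' @export
readTimeSeries <- function(path, samplingRate = NULL) {
  if (!dir.exists(path)) stop("'path' is not a directory: ", path)
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no trial CSV files found in ", path)
  metaFile <- file.path(path, "meta.json")
  labels <- NULL
  timeAxis <- numeric(0)
  if (file.exists(metaFile)) {
    meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
    if (is.null(samplingRate)) samplingRate <- meta$sampling_rate
    labels <- meta$channel_labels
    if (!is.null(meta$time_axis)) timeAxis <- as.numeric(meta$time_axis)
  }
  if (is.null(samplingRate))
    stop("sampling rate missing: supply 'samplingRate' or a meta.json with sampling_rate")
  trials <- lapply(files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("non-numeric cells in trial file ", basename(f))
    m
  })
  hdr <- colnames(trials[[1L]])
  for (i in seq_along(trials)) {
    if (!identical(colnames(trials[[i]]), hdr))
      stop("channel headers differ across trial files (first mismatch: ",
           basename(files[i]), ")")
    if (nrow(trials[[i]]) != nrow(trials[[1L]]))
      stop("sample counts differ across trial files (first mismatch: ",
           basename(files[i]), ")")
  }
  d <- length(hdr)
  N <- nrow(trials[[1L]])
  Y <- array(NA_real_, c(length(trials), d, N))
  for (i in seq_along(trials)) Y[i, , ] <- t(trials[[i]])
  if (is.null(labels)) labels <- hdr
  timeSeriesData(Y, samplingRate = samplingRate, channelLabels = labels,
                 timeAxis = timeAxis)
}

#' Write multi-trial time series to a CSV directory
#'
#' @param data a [TimeSeriesData-class].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(data, path) {
  stopifnot(is(data, "TimeSeriesData"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- nTrials(data)
  width <- max(3L, nchar(as.character(tr)))
  for (r in seq_len(tr)) {
    m <- t(matrix(data@values[r, , ], nChannels(data), nSamples(data)))
    colnames(m) <- data@channelLabels
    utils::write.csv(m,
      file.path(path, sprintf(paste0("trial_%0", width, "d.csv"), r)),
      row.names = FALSE)
  }
  meta <- list(sampling_rate = data@samplingRate,
               channel_labels = data@channelLabels)
  if (length(data@timeAxis)) meta$time_axis <- data@timeAxis
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structural-connectivity matrix from CSV
#'
#' Expects a square CSV with identical row and column label sets (rows =
#' receivers, columns = senders). Negative entries are rejected; whether the
#' matrix is already normalized (maximum 1) is detected and recorded on the
#' returned prior.
#'
#' @param path CSV file with row names in the first column.
#' @return a [StructuralPrior-class] (normalized flag as detected).
#' @export
readSC <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  W <- as.matrix(df)
  if (!is.numeric(W)) stop("non-numeric cells in SC matrix ", path)
  if (nrow(W) != ncol(W))
    stop("SC matrix must be square, got ", nrow(W), " x ", ncol(W))
  if (!identical(rownames(W), colnames(W)))
    stop("SC row and column labels differ")
  if (any(W < 0)) stop("SC matrix contains negative entries")
  dg <- diag(W)
  dv <- if (length(unique(dg)) == 1L) dg[1L] else NA_real_
  isNorm <- abs(max(W) - 1) <= 1e-12
  message(sprintf("SC matrix %s: %d nodes, %s",
                  basename(path), nrow(W),
                  if (isNorm) "normalized (max = 1)" else
                    sprintf("not normalized (max = %g)", max(W))))
  new("StructuralPrior", W = W, normalized = isNorm, diagonalValue = dv,
      labels = rownames(W))
}

#' Write a structural prior to CSV
#'
#' @param prior a [StructuralPrior-class].
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeSC <- function(prior, path) {
  stopifnot(is(prior, "StructuralPrior"))
  W <- prior@W
  labels <- if (length(prior@labels)) prior@labels
            else paste0("n", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  utils::write.csv(W, path, row.names = TRUE)
  invisible(path)
}

# Allowed configuration keys per section; unknown keys are rejected so a
# misspelled option can never fall back to a silent default.
configSchema <- list(
  top = c("seed", "stages", "output_dir", "simulate", "fit", "mdi"),
  simulate = c("nodes", "order", "samples", "trials", "onset", "offset",
               "driver", "scenario", "noise_sd"),
  fit = c("input", "order", "variance_fraction", "filter", "sc", "sc_min",
          "sc_max", "c_mode", "c_value"),
  mdi = c("mode")
)

checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(unknown) > 1L) "s" else "", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
}

#' Run a configured pipeline
#'
#' Executes the stages named in a YAML configuration (subset of
#' \code{simulate}, \code{fit}, \code{mdi}, in that order), writing outputs
#' and a provenance record (configuration checksum, package version, seed)
#' into the output directory. Unknown configuration keys are rejected.
#' Identical configuration and seed produce byte-identical outputs.
#'
#' @param path YAML configuration file. Recognized keys: top-level
#'   \code{seed}, \code{stages}, \code{output_dir} and per-stage sections
#'   \code{simulate} (nodes, order, samples, trials, onset, offset, driver,
#'   scenario, noise_sd), \code{fit} (input, order, variance_fraction,
#'   filter, sc, sc_min, sc_max, c_mode, c_value), \code{mdi} (mode).
#' @param quiet suppress stage messages.
#' @return invisible list with the objects produced by each stage.
#' @export
runConfig <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  checkKeys(cfg, configSchema$top, "top level")
  if (is.null(cfg$seed)) stop("configuration must set 'seed'")
  if (is.null(cfg$output_dir)) stop("configuration must set 'output_dir'")
  stages <- cfg$stages
  if (is.null(stages)) stop("configuration must list 'stages'")
  bad <- setdiff(stages, c("simulate", "fit", "mdi"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outDir <- cfg$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  produced <- list()

  if ("simulate" %in% stages) {
    sc <- cfg$simulate
    checkKeys(sc, configSchema$simulate, "'simulate'")
    say("stage simulate: %s nodes", sc$nodes %||% 5)
    spec <- evokedSimulationSpec(
      d = sc$nodes %||% 5, order = sc$order %||% 2,
      samples = sc$samples %||% 200, trials = sc$trials %||% 40,
      onset = sc$onset %||% 80, offset = sc$offset %||% 140,
      driver = sc$driver %||% 1, noiseSd = sc$noise_sd %||% 1,
      seed = cfg$seed)
    sim <- simulateTVMVAR(spec)
    writeTimeSeries(sim$data, file.path(outDir, "data"))
    prior <- scScenario(trueEdges(spec), sc$scenario %||% "concordant",
                        d = spec@d, labels = channelLabels(sim$data))
    writeSC(prior, file.path(outDir, "sc.csv"))
    produced$simulation <- sim
    produced$prior <- prior
  }

  if ("fit" %in% stages) {
    fc <- cfg$fit
    checkKeys(fc, configSchema$fit, "'fit'")
    data <- if (!is.null(produced$simulation)) produced$simulation$data
            else if (!is.null(fc$input)) readTimeSeries(fc$input)
            else stop("'fit' stage needs an 'input' directory when not preceded by 'simulate'")
    cMode <- fc$c_mode %||% "adaptive"
    cArg <- if (identical(cMode, "fixed")) fc$c_value %||%
              stop("c_mode 'fixed' needs 'c_value'") else "adaptive"
    filter <- fc$filter %||% "si_stok"
    say("stage fit: %s, order %s", filter, fc$order %||% 4)
    model <- if (identical(filter, "stok")) {
      stokFit(data, order = fc$order %||% 4,
              varianceFraction = fc$variance_fraction %||% 0.99, c = cArg)
    } else {
      prior <- if (!is.null(produced$prior)) produced$prior
               else if (!is.null(fc$sc)) readSC(fc$sc)
               else stop("si_stok fit needs an 'sc' file when not preceded by 'simulate'")
      siStokFit(data, order = fc$order %||% 4,
                varianceFraction = fc$variance_fraction %||% 0.99,
                prior = prior,
                scaling = c(fc$sc_min %||% 1e-4, fc$sc_max %||% 0.1),
                c = cArg)
    }
    produced$model <- model
  }

  if ("mdi" %in% stages) {
    mc <- cfg$mdi
    checkKeys(mc, configSchema$mdi, "'mdi'")
    if (is.null(produced$model))
      stop("'mdi' stage requires a preceding 'fit' stage")
    say("stage mdi: mode %s", mc$mode %||% "rss")
    m <- mdi(produced$model, mode = mc$mode %||% "rss")
    writeMDILong(m, file.path(outDir, "mdi.csv"))
    produced$mdi <- m
  }

  prov <- list(
    config_md5 = unname(tools::md5sum(path)),
    package_version = as.character(utils::packageVersion("sistok")),
    seed = cfg$seed,
    stages = stages)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(produced)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Long-format MDI table: receiver, sender, time, value (valid samples only).
writeMDILong <- function(m, path) {
  vals <- m@values
  d <- dim(vals)[1L]
  N <- dim(vals)[3L]
  labels <- if (length(m@channelLabels)) m@channelLabels
            else paste0("n", seq_len(d))
  tt <- m@validFrom:N
  df <- expand.grid(receiver = labels, sender = labels, time = tt,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- as.vector(vals[, , tt])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
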