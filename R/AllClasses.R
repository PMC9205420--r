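#' @import methods
NULL

#' Multi-trial, multichannel, uniformly sampled time series
#'
#' Container for epoched electrophysiological recordings (or simulated
#' analogues): a numeric array of dimension \code{trials x channels x samples},
#' a sampling rate in Hz, channel labels, and an optional time axis in
#' seconds. This is the observation matrix Y of the tv-MVAR model: at each
#' sample t the rows of Y across trials are regressed on their own recent
#' past.
#'
#' @slot values numeric array, \code{trials x channels x samples}; all finite.
#' @slot samplingRate sampling rate in Hz (scalar, > 0).
#' @slot channelLabels character vector, one label per channel.
#' @slot timeAxis numeric vector of length \code{samples} (seconds), or
#'   length 0 when no time axis is attached.
#'
#' @seealso [timeSeriesData()], [stokFit()], [siStokFit()]
#' @export
setClass("TimeSeriesData",
  representation(
    values = "array",
    samplingRate = "numeric",
    channelLabels = "character",
    timeAxis = "numeric"
  )
)

setValidity("TimeSeriesData", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a 3-d array [trials x channels x samples]")
  if (!all(is.finite(v)))
    return("'values' contains non-finite entries")
  if (dim(v)[1L] < 1L) return("at least one trial is required")
  if (dim(v)[2L] < 1L) return("at least one channel is required")
  if (length(object@channelLabels) != dim(v)[2L])
    return("length(channelLabels) must equal the number of channels")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    return("'samplingRate' must be a positive scalar (Hz)")
  if (length(object@timeAxis) != 0L &&
      length(object@timeAxis) != dim(v)[3L])
    return("'timeAxis' must be empty or have one entry per sample")
  TRUE
})

#' Lagged design at one time sample
#'
#' The regression design used at a single sample t: \code{H} stacks, for each
#' trial (row), the p most recent past samples of all channels; \code{z}
#' holds the present sample. Columns of \code{H} are ordered in lag-major
#' blocks of channels: (ch1 lag1, ..., chd lag1, ch1 lag2, ..., chd lagp),
#' so sender j at lag k sits in column \code{(k-1)*d + j}.
#'
#' @slot H numeric matrix \code{trials x (d*p)} of stacked past samples.
#' @slot z numeric matrix \code{trials x d} of present samples.
#' @slot tIndex the (1-based) sample index the design predicts.
#'
#' @seealso [buildLagDesign()]
#' @export
setClass("LagDesign",
  representation(H = "matrix", z = "matrix", tIndex = "integer")
)

setValidity("LagDesign", function(object) {
  if (nrow(object@H) != nrow(object@z))
    return("H and z must have the same number of rows (trials)")
  if (ncol(object@H) %% ncol(object@z) != 0L)
    return("ncol(H) must be a multiple of the channel count")
  TRUE
})

#' Normalized structural-connectivity prior
#'
#' A nonnegative d x d matrix of structural-connection weights with a fixed
#' receiver-from-sender orientation: \code{W[i, j]} is the anatomical weight
#' of the connection from node j to node i. When \code{normalized} is TRUE
#' the maximum entry is 1.
#'
#' @slot W nonnegative numeric matrix, receivers in rows, senders in columns.
#' @slot normalized logical flag; TRUE when \code{max(W) == 1}.
#' @slot diagonalValue the uniform value assigned to self-connections before
#'   normalization, or \code{NA_real_} when the diagonal is not uniform
#'   (e.g. a matrix read from disk as-is).
#' @slot labels character vector of node labels (may be empty).
#'
#' @seealso [normalizeSC()], [thresholdSC()], [scaleSC()]
#' @export
setClass("StructuralPrior",
  representation(
    W = "matrix",
    normalized = "logical",
    diagonalValue = "numeric",
    labels = "character"
  )
)

setValidity("StructuralPrior", function(object) {
  W <- object@W
  if (nrow(W) != ncol(W)) return("'W' must be square")
  if (any(!is.finite(W))) return("'W' contains non-finite entries")
  if (any(W < 0)) return("'W' must be nonnegative")
  if (isTRUE(object@normalized) && abs(max(W) - 1) > 1e-12)
    return("normalized prior must have max(W) == 1")
  if (length(object@labels) != 0L && length(object@labels) != nrow(W))
    return("'labels' must be empty or one per node")
  dv <- object@diagonalValue
  if (length(dv) != 1L) return("'diagonalValue' must be a scalar")
  if (!is.na(dv) && any(abs(diag(W) - dv) > 1e-12))
    return("diagonal entries must all equal 'diagonalValue'")
  TRUE
})

#' Fitted time-varying MVAR model
#'
#' Result of [stokFit()] or [siStokFit()]. The coefficient array \code{A}
#' follows the package-wide orientation: \code{A[i, j, k, t]} is the influence
#' of sender j on receiver i at lag k, estimated at sample t. Estimates are
#' defined from \code{validFrom = order + 1} onwards; earlier samples are NA
#' rather than padded.
#'
#' @slot A numeric array \code{d x d x p x N} of autoregressive coefficients.
#' @slot order model order p (number of lags).
#' @slot varianceFraction fraction of design variance retained by the damped
#'   pseudoinverse, in (0, 1].
#' @slot cTrace the adaptation constant used at each sample (NA before
#'   \code{validFrom}).
#' @slot innovations one-step residuals, \code{trials x d x N}.
#' @slot innovationCovariance d x d residual covariance over the default
#'   window (all valid samples); see [innovations()] for other windows.
#' @slot validFrom first sample index with a defined estimate (= p + 1).
#' @slot channelLabels channel labels carried over from the data.
#' @slot method \code{"stok"} or \code{"si_stok"}.
#' @slot prior for si-STOK fits, a list recording the structural prior and
#'   its scaling (provenance); NULL for plain STOK.
#'
#' @export
setClass("TVMVARModel",
  representation(
    A = "array",
    order = "integer",
    varianceFraction = "numeric",
    cTrace = "numeric",
    innovations = "array",
    innovationCovariance = "matrix",
    validFrom = "integer",
    channelLabels = "character",
    method = "character",
    prior = "ANY"
  )
)

setValidity("TVMVARModel", function(object) {
  dm <- dim(object@A)
  if (length(dm) != 4L || dm[1L] != dm[2L])
    return("'A' must be a d x d x p x N array")
  if (dm[3L] != object@order) return("dim(A)[3] must equal 'order'")
  if (object@validFrom != object@order + 1L)
    return("'validFrom' must be order + 1")
  N <- dm[4L]
  if (N >= object@validFrom) {
    sl <- object@A[, , , object@validFrom:N, drop = FALSE]
    if (any(!is.finite(sl)))
      return("'A' must be finite for all t >= validFrom")
    ct <- object@cTrace[object@validFrom:N]
    if (any(is.na(ct)) || any(ct < 0))
      return("'cTrace' must be nonnegative for all t >= validFrom")
  }
  TRUE
})

#' Magnitude of directed influence (MDI) tensor
#'
#' Per-edge, per-sample nonnegative directed-influence values derived from a
#' fitted tv-MVAR model: the norm over lags of the coefficients of each edge.
#' \code{values[i, j, t]} quantifies the influence of sender j on receiver i
#' at sample t; it is zero exactly when all lag coefficients of that edge are
#' zero.
#'
#' @slot values numeric array \code{d x d x N}, nonnegative where defined
#'   (NA before \code{validFrom}).
#' @slot validFrom first valid sample index, inherited from the model.
#' @slot mode \code{"rss"} (root-sum-square, default) or \code{"ss"}
#'   (sum of squares).
#' @slot channelLabels node labels.
#'
#' @seealso [mdi()], [summedOutflow()], [proportionalAdjacency()]
#' @export
setClass("MDITensor",
  representation(
    values = "array",
    validFrom = "integer",
    mode = "character",
    channelLabels = "character"
  )
)

setValidity("MDITensor", function(object) {
  dm <- dim(object@values)
  if (length(dm) != 3L || dm[1L] != dm[2L])
    return("'values' must be a d x d x N array")
  ok <- object@values[!is.na(object@values)]
  if (any(ok < 0)) return("MDI values must be nonnegative")
  if (!object@mode %in% c("rss", "ss"))
    return("'mode' must be 'rss' or 'ss'")
  TRUE
})

#' Group sign-flip permutation test result
#'
#' Observed group-mean differences together with permutation p-values from
#' random sign flips of per-subject differences, and the uncorrected
#' significance mask at the chosen alpha.
#'
#' @slot observed numeric array of observed group means (edges, or
#'   edges x time).
#' @slot pvalues two-sided permutation p-values, same shape as
#'   \code{observed}; each value lies in (0, 1].
#' @slot nPermutations number of random sign flips used.
#' @slot alpha significance threshold (uncorrected by default).
#' @slot significant logical mask, \code{pvalues < alpha} (after any
#'   adjustment).
#' @slot adjust multiplicity adjustment applied ("none" or "fdr").
#'
#' @seealso [signPermutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    observed = "array",
    pvalues = "array",
    nPermutations = "integer",
    alpha = "numeric",
    significant = "array",
    adjust = "character"
  )
)

setValidity("PermutationResult", function(object) {
  p <- object@pvalues
  if (any(p <= 0) || any(p > 1))
    return("p-values must lie in (0, 1]")
  if (!identical(dim(object@observed), dim(p)))
    return("'observed' and 'pvalues' must have identical shape")
  TRUE
})

#' Ground-truth tv-MVAR simulation specification
#'
#' A complete recipe for simulating a multi-trial tv-MVAR process: network
#' size, model order, sample count, trial count, innovation covariance, a
#' piecewise-constant coefficient schedule, and a mandatory seed. Every
#' scheduled coefficient tensor must yield a stable process (companion-matrix
#' spectral radius < 1); this is checked at construction.
#'
#' @slot d number of channels (nodes).
#' @slot p model order.
#' @slot N number of samples per trial.
#' @slot trials number of trials.
#' @slot sigma d x d innovation covariance.
#' @slot schedule list of segments, each \code{list(from, to, A)} with A a
#'   \code{d x d x p} coefficient tensor; segments must tile 1..N.
#' @slot burnIn samples simulated and discarded before sample 1.
#' @slot seed integer seed (mandatory).
#' @slot samplingRate sampling rate attached to the simulated data (Hz).
#'
#' @seealso [simulationSpec()], [evokedSimulationSpec()], [simulateTVMVAR()]
#' @export
setClass("SimulationSpec",
  representation(
    d = "integer",
    p = "integer",
    N = "integer",
    trials = "integer",
    sigma = "matrix",
    schedule = "list",
    burnIn = "integer",
    seed = "integer",
    samplingRate = "numeric"
  )
)

setValidity("SimulationSpec", function(object) {
  if (object@d < 1L || object@p < 1L || object@trials < 1L)
    return("d, p and trials must be >= 1")
  if (object@N <= object@p)
    return("N must exceed the model order p")
  if (!identical(dim(object@sigma), c(object@d, object@d)))
    return("'sigma' must be d x d")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a scalar integer 'seed' is mandatory")
  covered <- rep(FALSE, object@N)
  for (si in seq_along(object@schedule)) {
    seg <- object@schedule[[si]]
    if (!all(c("from", "to", "A") %in% names(seg)))
      return("each schedule segment needs 'from', 'to' and 'A'")
    if (!identical(dim(seg$A), c(object@d, object@d, object@p)))
      return(sprintf("segment %d: 'A' must be d x d x p", si))
    if (seg$from < 1L || seg$to > object@N || seg$from > seg$to)
      return(sprintf("segment %d: sample range [%d, %d] outside 1..%d",
                     si, seg$from, seg$to, object@N))
    rho <- spectralRadius(seg$A)
    if (rho >= 1)
      return(sprintf(
        "unstable coefficient schedule in segment %d (samples %d-%d): companion spectral radius %.3f >= 1",
        si, seg$from, seg$to, rho))
    idx <- seq.int(seg$from, seg$to)
    if (any(covered[idx]))
      return(sprintf("segment %d overlaps an earlier segment", si))
    covered[idx] <- TRUE
  }
  if (!all(covered))
    return("schedule segments must tile samples 1..N")
  TRUE
})

#' Noise-perturbation benchmark result
#'
#' Per-filter, per-noise-ratio, per-iteration consistency and driver-score
#' curves, with the zero-noise estimates of each filter as the baseline.
#'
#' @slot results data.frame with columns \code{filter}, \code{ratio},
#'   \code{iter}, \code{consistency}, \code{driverScore}.
#' @slot baselines per-filter list with the zero-noise adjacency and driver
#'   score.
#' @slot ratios noise mixing ratios evaluated.
#' @slot iters noise regenerations per ratio.
#' @slot keep proportion of strongest connections kept in the adjacency.
#' @slot peakT sample index at which adjacencies are extracted.
#' @slot driver index of the designated driver node.
#' @slot seed base seed of the benchmark.
#'
#' @seealso [runNoiseBenchmark()]
#' @export
setClass("BenchmarkResult",
  representation(
    results = "data.frame",
    baselines = "list",
    ratios = "numeric",
    iters = "integer",
    keep = "numeric",
    peakT = "integer",
    driver = "integer",
    seed = "integer"
  )
)

setValidity("BenchmarkResult", function(object) {
  need <- c("filter", "ratio", "iter", "consistency", "driverScore")
  if (!all(need %in% names(object@results)))
    return("'results' must have filter/ratio/iter/consistency/driverScore")
  cons <- object@results$consistency
  if (any(cons < 0 | cons > 1, na.rm = TRUE))
    return("consistency values must lie in [0, 1]")
  z <- object@results$consistency[object@results$ratio == 0]
  if (length(z) && any(abs(z - 1) > 1e-12))
    return("zero-noise consistency must equal 1")
  TRUE
})
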