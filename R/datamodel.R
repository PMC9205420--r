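#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TimeSeriesData object
#'
#' @param values numeric array \code{trials x channels x samples}. A matrix
#'   (\code{channels x samples}) is promoted to a single trial.
#' @param samplingRate sampling rate in Hz.
#' @param channelLabels channel labels; defaults to \code{ch1..chd}.
#' @param timeAxis optional time axis in seconds (length = samples).
#' @return a [TimeSeriesData-class] object.
#' @examples
#' y <- timeSeriesData(array(rnorm(2 * 3 * 50), c(2, 3, 50)), samplingRate = 1000)
#' nChannels(y)
#' @export
timeSeriesData <- function(values, samplingRate = 1,
                           channelLabels = NULL, timeAxis = numeric(0)) {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(dim(values)[2L]))
  new("TimeSeriesData",
      values = values,
      samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels),
      timeAxis = as.numeric(timeAxis))
}

#' @rdname nTrials
#' @export
setMethod("nTrials", "TimeSeriesData", function(x) dim(x@values)[1L])

#' @rdname nChannels
#' @export
setMethod("nChannels", "TimeSeriesData", function(x) dim(x@values)[2L])

#' @rdname nSamples
#' @export
setMethod("nSamples", "TimeSeriesData", function(x) dim(x@values)[3L])

#' @rdname tsValues
#' @export
setMethod("tsValues", "TimeSeriesData", function(x) x@values)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TimeSeriesData", function(x) x@samplingRate)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "TimeSeriesData", function(x) x@channelLabels)

setMethod("show", "TimeSeriesData", function(object) {
  dm <- dim(object@values)
  cat(sprintf("TimeSeriesData: %d trial(s) x %d channel(s) x %d sample(s) @ %g Hz\n",
              dm[1L], dm[2L], dm[3L], object@samplingRate))
  cat("  channels:", paste(utils::head(object@channelLabels, 8L),
                           collapse = ", "),
      if (dm[2L] > 8L) "..." else "", "\n")
})

#' Build the lagged regression design at one sample
#'
#' Constructs the design used by the recursive least-squares update at sample
#' t: each trial contributes one row of \code{H} holding its p most recent
#' past samples of all d channels, and one row of \code{z} holding the
#' present sample. Columns of \code{H} follow the package-wide lag-major
#' stacking: (ch1 lag1, ..., chd lag1, ch1 lag2, ..., chd lagp).
#'
#' @param data a [TimeSeriesData-class].
#' @param t sample index (1-based); must satisfy \code{p < t <= N}.
#' @param p model order (number of lags, >= 1).
#' @return a [LagDesign-class] with \code{H} (\code{trials x d*p}) and
#'   \code{z} (\code{trials x d}).
#' @examples
#' y <- timeSeriesData(matrix(c(2, 5, 7), 1, 3), samplingRate = 1)
#' ld <- buildLagDesign(y, t = 2, p = 1)
#' ld@H  # 2
#' ld@z  # 5
#' @export
buildLagDesign <- function(data, t, p) {
  stopifnot(is(data, "TimeSeriesData"))
  p <- as.integer(p)
  t <- as.integer(t)
  if (p < 1L) stop("model order 'p' must be >= 1")
  N <- nSamples(data)
  if (t <= p || t > N)
    stop(sprintf(
      "sample index t = %d is out of range: estimates are defined from valid_from = %d to %d",
      t, p + 1L, N))
  d <- nChannels(data)
  tr <- nTrials(data)
  H <- matrix(NA_real_, tr, d * p)
  for (k in seq_len(p))
    H[, (k - 1L) * d + seq_len(d)] <- matrix(data@values[, , t - k], tr, d)
  z <- matrix(data@values[, , t], tr, d)
  if (any(!is.finite(H)) || any(!is.finite(z)))
    stop("non-finite values in the lag design")
  new("LagDesign", H = H, z = z, tIndex = t)
}

#' Global z-score transformation
#'
#' Standardizes the whole dataset with a single mean and a single standard
#' deviation (population form) computed over all trials, channels and
#' samples, so relative amplitudes between channels are preserved. The
#' transform is idempotent.
#'
#' @param data a [TimeSeriesData-class] with positive global variance.
#' @return a [TimeSeriesData-class] with global mean 0 and global sd 1.
#' @export
zscoreGlobal <- function(data) {
  stopifnot(is(data, "TimeSeriesData"))
  v <- data@values
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s == 0)
    stop("global standard deviation is zero: cannot z-score a constant dataset")
  out <- data
  out@values <- (v - mean(v)) / s
  out
}

#' Normalize a structural-connectivity matrix into a prior
#'
#' Overwrites the main diagonal (self-connections) with \code{diagonalValue}
#' and then divides the whole matrix by its maximum, yielding weights in
#' [0, 1] with maximum 1. For rank-coded connectomes (e.g. weights 0..12)
#' the convention is to set the diagonal to the maximum rank before
#' normalizing, which is the default.
#'
#' @param raw square nonnegative numeric matrix, receiver-from-sender
#'   orientation (\code{raw[i, j]} = weight of j to i).
#' @param diagonalValue value written on the diagonal before normalization;
#'   defaults to \code{max(raw)}.
#' @param labels optional node labels.
#' @return a normalized [StructuralPrior-class].
#' @export
normalizeSC <- function(raw, diagonalValue = max(raw), labels = character(0)) {
  if (!is.matrix(raw) || nrow(raw) != ncol(raw))
    stop("'raw' must be a square matrix")
  if (any(!is.finite(raw))) stop("'raw' contains non-finite entries")
  if (any(raw < 0)) stop("'raw' contains negative entries")
  W <- raw
  diag(W) <- diagonalValue
  mx <- max(W)
  if (mx <= 0) stop("all-zero structural matrix cannot be normalized")
  W <- W / mx
  if (length(labels) == 0L && !is.null(rownames(raw)))
    labels <- rownames(raw)
  dimnames(W) <- if (length(labels)) list(labels, labels) else NULL
  new("StructuralPrior", W = W, normalized = TRUE,
      diagonalValue = diagonalValue / mx, labels = as.character(labels))
}

#' @rdname scMatrix
#' @export
setMethod("scMatrix", "StructuralPrior", function(x) x@W)

setMethod("show", "StructuralPrior", function(object) {
  d <- nrow(object@W)
  nz <- sum(object@W[offDiagonal(d)] > 0)
  cat(sprintf("StructuralPrior: %d x %d, %d/%d nonzero off-diagonal weights%s\n",
              d, d, nz, d * (d - 1L),
              if (isTRUE(object@normalized)) ", normalized (max = 1)" else ""))
})
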