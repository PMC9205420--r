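#' @include AllClasses.R
NULL

#' Number of trials
#' @param x a [TimeSeriesData-class].
#' @return integer count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of channels (nodes)
#' @param x a [TimeSeriesData-class] or [TVMVARModel-class].
#' @return integer count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of samples per trial
#' @param x a [TimeSeriesData-class] or [TVMVARModel-class].
#' @return integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Raw value array of a time-series object
#' @param x a [TimeSeriesData-class].
#' @return numeric array \code{trials x channels x samples}.
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' Sampling rate in Hz
#' @param x a [TimeSeriesData-class].
#' @return numeric scalar.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel (node) labels
#' @param x a [TimeSeriesData-class], [TVMVARModel-class] or
#'   [MDITensor-class].
#' @return character vector.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Structural weight matrix of a prior
#' @param x a [StructuralPrior-class].
#' @return d x d nonnegative matrix, receiver rows, sender columns.
#' @export
setGeneric("scMatrix", function(x) standardGeneric("scMatrix"))

#' Autoregressive coefficient array of a fitted model
#' @param x a [TVMVARModel-class].
#' @return numeric array \code{d x d x p x N}; \code{A[i, j, k, t]} is the
#'   influence of sender j on receiver i at lag k, sample t.
#' @export
setGeneric("coefArray", function(x) standardGeneric("coefArray"))

#' Model order (number of lags)
#' @param x a [TVMVARModel-class].
#' @return integer.
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' First sample with a defined estimate
#' @param x a [TVMVARModel-class] or [MDITensor-class].
#' @return integer (= order + 1).
#' @export
setGeneric("validFrom", function(x) standardGeneric("validFrom"))

#' Adaptation-constant trace of a fitted model
#' @param x a [TVMVARModel-class].
#' @return numeric vector of length N (NA before \code{validFrom}).
#' @export
setGeneric("cTrace", function(x) standardGeneric("cTrace"))

#' Innovations (one-step residuals) of a fitted model
#'
#' @param model a [TVMVARModel-class].
#' @param ... further arguments passed to methods (see the method for
#'   \code{TVMVARModel}).
#' @export
setGeneric("innovations", function(model, ...) standardGeneric("innovations"))

#' Magnitude of directed influence
#'
#' @param object a fitted [TVMVARModel-class].
#' @param ... further arguments passed to methods.
#' @export
setGeneric("mdi", function(object, ...) standardGeneric("mdi"))

#' MDI value array
#' @param x an [MDITensor-class].
#' @return numeric array \code{d x d x N}.
#' @export
setGeneric("mdiValues", function(x) standardGeneric("mdiValues"))

#' Benchmark result table
#' @param x a [BenchmarkResult-class].
#' @return data.frame with one row per filter/ratio/iteration.
#' @export
setGeneric("benchmarkResults", function(x) standardGeneric("benchmarkResults"))

#' Permutation p-values
#' @param x a [PermutationResult-class].
#' @return array of two-sided p-values.
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
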