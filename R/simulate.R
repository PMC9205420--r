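#' @include AllClasses.R AllGenerics.R datamodel.R
NULL

#' Construct a simulation specification
#'
#' @param d number of nodes.
#' @param p model order.
#' @param N samples per trial.
#' @param trials number of trials.
#' @param schedule list of segments \code{list(from, to, A)} with A a
#'   \code{d x d x p} coefficient tensor (receiver x sender x lag); the
#'   segments must tile 1..N and every tensor must be stable.
#' @param sigma innovation covariance (default identity).
#' @param burnIn samples simulated and discarded before sample 1.
#' @param seed mandatory integer seed.
#' @param samplingRate sampling rate attached to the output (Hz).
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(d, p, N, trials, schedule, sigma = diag(d),
                           burnIn = 100, seed, samplingRate = 1000) {
  if (missing(seed)) stop("'seed' is mandatory")
  new("SimulationSpec",
      d = as.integer(d), p = as.integer(p), N = as.integer(N),
      trials = as.integer(trials), sigma = sigma, schedule = schedule,
      burnIn = as.integer(burnIn), seed = as.integer(seed),
      samplingRate = as.numeric(samplingRate))
}

#' Default evoked-response simulation specification
#'
#' A sparse 5-node, order-2 network emulating event-related dynamics: every
#' node has stable self-dynamics (lag-1 coefficient 0.5, lag-2 coefficient
#' -0.1) and two static cross connections exist throughout (node 2 to node 5
#' at lag 1, coefficient 0.3; node 3 to node 4 at lag 2, coefficient 0.25).
#' During the active window [onset, offset] a designated driver node sends
#' three additional step connections (to the next three nodes, lag 1,
#' coefficient 0.35), emulating an evoked burst with a defined peak-latency
#' analogue; outside the window the network returns to baseline.
#'
#' @param d number of nodes (>= 5 for the default edge layout).
#' @param order model order (2).
#' @param samples samples per trial.
#' @param trials number of trials.
#' @param onset,offset sample range of the active (evoked) window.
#' @param driver index of the driver node.
#' @param noiseSd innovation standard deviation (identity covariance scale).
#' @param seed mandatory integer seed.
#' @return a [SimulationSpec-class].
#' @export
evokedSimulationSpec <- function(d = 5, order = 2, samples = 200,
                                 trials = 60, onset = 80, offset = 140,
                                 driver = 1, noiseSd = 1, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  ten <- evokedTensors(d, order, driver)
  base <- ten$base
  act <- ten$act
  p <- as.integer(order)
  schedule <- list(
    list(from = 1L, to = as.integer(onset - 1L), A = base),
    list(from = as.integer(onset), to = as.integer(offset), A = act),
    list(from = as.integer(offset + 1L), to = as.integer(samples), A = base))
  simulationSpec(d = d, p = p, N = samples, trials = trials,
                 schedule = schedule, sigma = diag(d) * noiseSd^2,
                 seed = seed)
}

# Baseline and active coefficient tensors of the default sparse 5-node
# layout shared by the evoked and stationary fixtures.
evokedTensors <- function(d, order, driver) {
  d <- as.integer(d)
  if (d < 5L) stop("the default sparse layout needs at least 5 nodes")
  p <- as.integer(order)
  if (p < 2L) stop("the default sparse layout uses order >= 2")
  base <- array(0, c(d, d, p))
  for (i in seq_len(d)) {
    base[i, i, 1L] <- 0.5
    base[i, i, 2L] <- -0.1
  }
  base[5L, 2L, 1L] <- 0.3    # 5 <- 2, static
  base[4L, 3L, 2L] <- 0.25   # 4 <- 3, static
  act <- base
  targets <- setdiff(seq_len(d), driver)[1:3]
  for (i in targets) act[i, driver, 1L] <- 0.35
  list(base = base, act = act)
}

#' Stationary sparse simulation specification
#'
#' The same sparse 5-node network as [evokedSimulationSpec()] but with the
#' driver connections active over the whole recording (a single
#' time-invariant segment). This is the fixture for coefficient-recovery
#' checks: the ground truth is constant, so time-averaged estimates can be
#' compared to it directly.
#'
#' @inheritParams evokedSimulationSpec
#' @return a [SimulationSpec-class].
#' @export
stationarySimulationSpec <- function(d = 5, order = 2, samples = 300,
                                     trials = 100, driver = 1, noiseSd = 1,
                                     seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  ten <- evokedTensors(d, order, driver)
  schedule <- list(list(from = 1L, to = as.integer(samples), A = ten$act))
  simulationSpec(d = d, p = as.integer(order), N = samples, trials = trials,
                 schedule = schedule, sigma = diag(d) * noiseSd^2,
                 seed = seed)
}

#' True off-diagonal edge set of a simulation specification
#'
#' All (receiver, sender) pairs with a nonzero coefficient at any lag in any
#' schedule segment.
#'
#' @param spec a [SimulationSpec-class].
#' @return two-column integer matrix (receiver, sender).
#' @export
trueEdges <- function(spec) {
  d <- spec@d
  any0 <- matrix(FALSE, d, d)
  for (seg in spec@schedule)
    any0 <- any0 | apply(seg$A != 0, c(1L, 2L), any)
  diag(any0) <- FALSE
  which(any0, arr.ind = TRUE, useNames = FALSE)
}

#' Simulate a multi-trial tv-MVAR process
#'
#' Generates trials of the autoregressive recursion
#' \code{Y_t = sum_k A[,,k,t] Y_{t-k} + eps_t} under the piecewise-constant
#' coefficient schedule of the specification, with Gaussian innovations of
#' the given covariance. Each trial starts from a burn-in period simulated
#' under the first segment's coefficients and discarded, so sample 1 is
#' already in the stationary regime of the baseline.
#'
#' @param spec a [SimulationSpec-class] (stability is enforced at
#'   construction).
#' @return list with \code{data} (a [TimeSeriesData-class]) and
#'   \code{coefficients} (the ground-truth \code{d x d x p x N} array).
#' @export
simulateTVMVAR <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  d <- spec@d; p <- spec@p; N <- spec@N; tr <- spec@trials
  Atrue <- array(0, c(d, d, p, N))
  for (seg in spec@schedule)
    Atrue[, , , seg$from:seg$to] <- seg$A
  Abase <- spec@schedule[[1L]]$A
  L <- chol(spec@sigma)
  burn <- max(spec@burnIn, p)
  Y <- array(NA_real_, c(tr, d, N))
  withSeed(spec@seed, {
    for (r in seq_len(tr)) {
      eps <- matrix(stats::rnorm((burn + N) * d), burn + N, d) %*% L
      x <- matrix(0, burn + N, d)
      for (t in seq_len(burn + N)) {
        At <- if (t <= burn) Abase
              else array(Atrue[, , , t - burn], c(d, d, p))
        acc <- eps[t, ]
        for (k in seq_len(p)) {
          if (t - k < 1L) next
          acc <- acc + matrix(At[, , k], d, d) %*% x[t - k, ]
        }
        x[t, ] <- acc
      }
      Y[r, , ] <- t(x[(burn + 1L):(burn + N), , drop = FALSE])
    }
  })
  list(data = timeSeriesData(Y, samplingRate = spec@samplingRate),
       coefficients = Atrue)
}

#' Structural-prior scenarios for simulated networks
#'
#' Builds structural priors that agree with or deliberately contradict a
#' ground-truth functional edge set, for probing how the prior shapes the
#' estimate:
#' \describe{
#'   \item{concordant}{weight 1 on every true edge, 0 elsewhere.}
#'   \item{sc_false_negative}{concordant, but one true edge is zeroed — the
#'     structural map misses a real connection.}
#'   \item{sc_false_positive}{concordant, plus weight 1 on one edge with no
#'     true functional connection.}
#'   \item{dense_uniform}{weight 1 everywhere.}
#' }
#' The diagonal is always 1.
#'
#' @param edges two-column (receiver, sender) matrix of true off-diagonal
#'   edges (e.g. from [trueEdges()]).
#' @param scenario one of the four scenario names.
#' @param d number of nodes.
#' @param edge for the false-negative/false-positive scenarios, the
#'   manipulated edge as \code{c(receiver, sender)}; defaults to the first
#'   true edge (false negative) or the first off-diagonal null edge (false
#'   positive).
#' @param labels optional node labels.
#' @return a normalized [StructuralPrior-class].
#' @export
scScenario <- function(edges, scenario = c("concordant", "sc_false_negative",
                                           "sc_false_positive",
                                           "dense_uniform"),
                       d, edge = NULL, labels = character(0)) {
  scenario <- match.arg(scenario)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("true edges must be off-diagonal")
  W <- matrix(0, d, d)
  W[edges] <- 1
  if (scenario == "dense_uniform") W[] <- 1
  if (scenario == "sc_false_negative") {
    if (is.null(edge)) edge <- edges[1L, ]
    if (W[edge[1L], edge[2L]] != 1)
      stop("sc_false_negative needs an existing true edge to remove")
    W[edge[1L], edge[2L]] <- 0
  }
  if (scenario == "sc_false_positive") {
    if (is.null(edge)) {
      off <- which(W == 0 & diag(d) == 0, arr.ind = TRUE)
      if (nrow(off) == 0L)
        stop("sc_false_positive needs a null edge, but none exists")
      edge <- off[1L, ]
    }
    if (edge[1L] == edge[2L] || W[edge[1L], edge[2L]] != 0)
      stop("sc_false_positive needs an off-diagonal edge without true FC")
    W[edge[1L], edge[2L]] <- 1
  }
  diag(W) <- 1
  if (length(labels)) dimnames(W) <- list(labels, labels)
  new("StructuralPrior", W = W, normalized = TRUE, diagonalValue = 1,
      labels = as.character(labels))
}

#' Mix data with white noise at a fixed ratio
#'
#' Convex mixture \code{(1 - r) * data + r * noise}, where the noise is
#' i.i.d. (Gaussian by default) with standard deviation set to the 95th
#' percentile of the absolute data values — so "amplitude" tracks the
#' near-maximal excursions of the signal. \code{r = 0} returns the input
#' unchanged.
#'
#' @param data a [TimeSeriesData-class].
#' @param ratio noise mixing ratio in [0, 1).
#' @param seed mandatory integer seed.
#' @param dist noise distribution, \code{"gaussian"} (default) or
#'   \code{"uniform"} (matched standard deviation).
#' @param percentile percentile of the absolute data defining the noise
#'   amplitude (default 0.95).
#' @param absolute use the percentile of absolute values (default) or of
#'   signed values.
#' @return a [TimeSeriesData-class].
#' @export
mixNoise <- function(data, ratio, seed, dist = c("gaussian", "uniform"),
                     percentile = 0.95, absolute = TRUE) {
  stopifnot(is(data, "TimeSeriesData"))
  dist <- match.arg(dist)
  assertScalar(ratio, "ratio", lo = 0, hi = 1 - 1e-12)
  if (ratio == 0) return(data)
  if (missing(seed)) stop("'seed' is mandatory")
  v <- data@values
  amp <- stats::quantile(if (absolute) abs(v) else v, percentile,
                         names = FALSE)
  n <- length(v)
  eta <- withSeed(seed, switch(dist,
    gaussian = stats::rnorm(n, sd = amp),
    uniform = stats::runif(n, -amp * sqrt(3), amp * sqrt(3))))
  out <- data
  out@values <- (1 - ratio) * v + ratio * array(eta, dim(v))
  out
}

#' Noise-perturbation benchmark of STOK versus si-STOK
#'
#' For each filter, the model is first fitted to the clean data and its
#' thresholded adjacency at the peak sample is taken as the zero-noise
#' baseline. The data are then mixed with regenerated white noise at each
#' ratio, refitted, and two criteria are recorded per iteration: the
#' consistency of the thresholded network with that filter's own zero-noise
#' network, and the driver score of the designated driver node. Noise
#' realizations are shared between the filters within an iteration so the
#' comparison is paired.
#'
#' @param data a [TimeSeriesData-class] (clean).
#' @param prior a normalized [StructuralPrior-class] for the si-STOK filter.
#' @param ratios noise mixing ratios; ratio 0 rows report the baseline
#'   (consistency exactly 1).
#' @param iters noise regenerations per nonzero ratio.
#' @param peakT sample index at which adjacencies and driver scores are
#'   extracted.
#' @param driver driver node index.
#' @param keep proportion of strongest connections kept in the adjacency.
#' @param filters subset of \code{c("stok", "si_stok")}.
#' @param order,varianceFraction,scaling,c passed to the fitters.
#' @param seed mandatory base seed; per-iteration noise seeds are derived
#'   from it.
#' @return a [BenchmarkResult-class].
#' @export
runNoiseBenchmark <- function(data, prior, ratios = seq(0, 0.5, by = 0.1),
                              iters = 30, peakT, driver, keep = 0.5,
                              filters = c("stok", "si_stok"),
                              order = 2, varianceFraction = 0.99,
                              scaling = c(1e-4, 0.1), c = "adaptive",
                              seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  filters <- match.arg(filters, c("stok", "si_stok"), several.ok = TRUE)
  peakT <- as.integer(peakT)
  if (peakT <= order || peakT > nSamples(data))
    stop("'peakT' must lie within the valid sample range")
  fitOne <- function(filter, dat) {
    if (filter == "stok")
      stokFit(dat, order = order, varianceFraction = varianceFraction, c = c)
    else
      siStokFit(dat, order = order, varianceFraction = varianceFraction,
                prior = prior, scaling = scaling, c = c)
  }
  slice <- function(model) {
    M <- mdiValues(mdi(model))[, , peakT]
    M
  }
  baselines <- list()
  for (filt in filters) {
    sl <- slice(fitOne(filt, data))
    baselines[[filt]] <- list(
      adjacency = proportionalAdjacency(sl, keep),
      driverScore = driverScore(sl, driver))
  }
  rows <- list()
  for (filt in filters) {
    if (0 %in% ratios) {
      b <- baselines[[filt]]
      rows[[length(rows) + 1L]] <- data.frame(
        filter = filt, ratio = 0, iter = 0L,
        consistency = consistency(b$adjacency, b$adjacency),
        driverScore = b$driverScore)
    }
  }
  nz <- ratios[ratios > 0]
  for (ri in seq_along(nz)) {
    for (it in seq_len(iters)) {
      noiseSeed <- (as.integer(seed) + 7919L * ri + it) %% .Machine$integer.max
      noisy <- mixNoise(data, nz[ri], seed = noiseSeed)
      for (filt in filters) {
        sl <- slice(fitOne(filt, noisy))
        adj <- proportionalAdjacency(sl, keep)
        rows[[length(rows) + 1L]] <- data.frame(
          filter = filt, ratio = nz[ri], iter = it,
          consistency = consistency(adj, baselines[[filt]]$adjacency),
          driverScore = driverScore(sl, driver))
      }
    }
  }
  new("BenchmarkResult",
      results = do.call(rbind, rows),
      baselines = baselines,
      ratios = as.numeric(ratios), iters = as.integer(iters),
      keep = keep, peakT = peakT, driver = as.integer(driver),
      seed = as.integer(seed))
}

#' @rdname benchmarkResults
#' @export
setMethod("benchmarkResults", "BenchmarkResult", function(x) x@results)

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf(
    "BenchmarkResult: ratios %s, %d iteration(s), keep = %g, peak t = %d\n",
    paste(object@ratios, collapse = "/"), object@iters, object@keep,
    object@peakT))
  agg <- stats::aggregate(consistency ~ filter + ratio, object@results,
                          stats::median)
  print(utils::head(agg, 12L))
})
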