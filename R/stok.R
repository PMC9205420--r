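#' @include AllClasses.R AllGenerics.R datamodel.R
NULL

#' Damped Moore-Penrose pseudoinverse
#'
#' Singular value decomposition of the design with attenuation of small
#' singular values: the smallest leading set of singular values whose
#' cumulative squared sum reaches a fraction \code{f} of the total squared
#' sum is retained, the rest are set to zero. With \code{f = 1} this is the
#' exact Moore-Penrose pseudoinverse; smaller \code{f} suppresses the
#' ill-conditioned directions of the design that amplify noise.
#'
#' @param H numeric matrix (finite entries).
#' @param f fraction of variance (squared singular values) to retain,
#'   in (0, 1].
#' @return a list with the damped pseudoinverse \code{pinv}
#'   (\code{ncol(H) x nrow(H)}) and the damped factors \code{u}, \code{d}
#'   (damped singular values, zeros for dropped directions), \code{v} and the
#'   retained \code{rank}, for reuse by the Tikhonov solver.
#' @examples
#' dampedPinv(diag(c(2, 1, 1e-9)), f = 0.99)$pinv  # diag(0.5, 1, 0)
#' @export
dampedPinv <- function(H, f = 0.99) {
  if (!is.matrix(H)) H <- as.matrix(H)
  if (any(!is.finite(H))) stop("'H' contains non-finite entries")
  assertScalar(f, "f")
  if (f <= 0 || f > 1) stop("'f' must lie in (0, 1]")
  sv <- svd(H)
  d2 <- sv$d^2
  tot <- sum(d2)
  if (tot == 0) {
    warning("all-zero design: damped pseudoinverse is the zero operator")
    dd <- rep(0, length(sv$d))
  } else {
    k <- which(cumsum(d2) >= f * tot - 1e-15 * tot)[1L]
    # singular values tied with the last retained one are kept: equal
    # directions carry equal variance and cannot be ranked against each other
    while (k < length(sv$d) && sv$d[k + 1L] >= sv$d[k] * (1 - 1e-12))
      k <- k + 1L
    dd <- sv$d
    if (k < length(dd)) dd[(k + 1L):length(dd)] <- 0
  }
  inv <- ifelse(dd > 0, 1 / dd, 0)
  pinv <- sv$v %*% (t(sv$u) * inv)
  list(pinv = pinv, u = sv$u, d = dd, v = sv$v, rank = sum(dd > 0))
}

# Resolve the adaptation-constant specification into a closure returning c_t.
# Adaptive rule: c_t = clip(cBase * e_t / ema(e_t), cMin, cMax), where e_t is
# the mean squared one-step innovation against the prior state and the EMA
# has a configurable half-life (in samples).
makeCUpdater <- function(c, cBase, cMin, cMax, halfLife) {
  if (is.numeric(c)) {
    if (length(c) != 1L || is.na(c) || c < 0)
      stop("fixed 'c' must be a nonnegative scalar (Inf allowed)")
    cFixed <- c
    function(e) cFixed
  } else if (identical(c, "adaptive")) {
    lambda <- 2^(-1 / halfLife)
    ebar <- NULL
    function(e) {
      ebar <<- if (is.null(ebar)) e else lambda * ebar + (1 - lambda) * e
      if (ebar <= 0) return(cMin)
      min(max(cBase * e / ebar, cMin), cMax)
    }
  } else {
    stop("'c' must be \"adaptive\" or a nonnegative number")
  }
}

# Shared recursive estimation loop. `solver(fac, z)` maps the damped design
# factorization and the present samples to a (d*p x d) measurement estimate;
# plugging in the damped OLS solution gives STOK, the per-receiver Tikhonov
# solution gives si-STOK.
fitLoop <- function(data, p, f, c, cBase, cMin, cMax, halfLife,
                    solver, method, prior = NULL) {
  stopifnot(is(data, "TimeSeriesData"))
  p <- as.integer(p)
  if (p < 1L) stop("model order must be >= 1")
  d <- nChannels(data)
  N <- nSamples(data)
  tr <- nTrials(data)
  if (p >= N)
    stop(sprintf("model order %d must be smaller than the sample count %d", p, N))
  sds <- apply(matrix(aperm(data@values, c(1L, 3L, 2L)), tr * N, d), 2L,
               stats::sd)
  flat <- which(!is.finite(sds) | sds == 0)
  if (length(flat))
    stop("constant (zero-variance) channel(s): ",
         paste(data@channelLabels[flat], collapse = ", "))
  assertScalar(f, "f")
  if (f <= 0 || f > 1) stop("'f' must lie in (0, 1]")

  nextC <- makeCUpdater(c, cBase, cMin, cMax, halfLife)
  x <- matrix(0, d * p, d)                      # state: column i = receiver i
  A <- array(NA_real_, c(d, d, p, N))
  cTrace <- rep(NA_real_, N)
  innov <- array(NA_real_, c(tr, d, N))

  # precompute lag-stacked designs for all t
  Hall <- array(NA_real_, c(tr, d * p, N))
  for (k in seq_len(p))
    Hall[, (k - 1L) * d + seq_len(d), (k + 1L):N] <-
      array(data@values[, , seq_len(N - k), drop = FALSE], c(tr, d, N - k))

  for (t in (p + 1L):N) {
    H <- matrix(Hall[, , t], tr, d * p)
    z <- matrix(data@values[, , t], tr, d)
    fac <- dampedPinv(H, f)
    est <- solver(fac, z)
    e <- mean((z - H %*% x)^2)
    ct <- nextC(e)
    x <- if (is.infinite(ct)) est else (x + ct * est) / (1 + ct)
    innov[, , t] <- z - H %*% x
    A[, , , t] <- aperm(array(x, c(d, p, d)), c(3L, 1L, 2L))
    cTrace[t] <- ct
  }

  vf <- p + 1L
  E <- matrix(aperm(innov[, , vf:N, drop = FALSE], c(1L, 3L, 2L)),
              tr * (N - p), d)
  new("TVMVARModel",
      A = A, order = p, varianceFraction = f, cTrace = cTrace,
      innovations = innov,
      innovationCovariance = stats::cov(E),
      validFrom = vf, channelLabels = data@channelLabels,
      method = method, prior = prior)
}

#' Fit a tv-MVAR model with the self-tuning optimized Kalman (STOK) filter
#'
#' Recursive least-squares estimation of time-varying MVAR coefficients. At
#' every sample t the present values of all trials are regressed on their
#' lag-stacked past via a damped pseudoinverse, and the state is updated as a
#' weighted average of the previous coefficient estimate and this measurement
#' estimate, \code{x+ = (x- + c * pinv(H) z) / (1 + c)}. The adaptation
#' constant c controls the speed/stability trade-off of the filter; the
#' default self-tuning rule speeds the filter up when one-step residuals rise
#' above their recent average.
#'
#' @param data a [TimeSeriesData-class].
#' @param order model order p (lags).
#' @param varianceFraction fraction of design variance retained by the
#'   damped pseudoinverse (0.99 suits low-dimensional recordings; 0.9 is a
#'   common choice for high-dimensional source data).
#' @param c \code{"adaptive"} (default) or a fixed nonnegative number
#'   (\code{Inf} reduces the update to the pure measurement estimate;
#'   \code{0} freezes the state at its initialization).
#' @param cBase,cMin,cMax parameters of the adaptive rule
#'   \code{c_t = clip(cBase * e_t / ema(e_t), cMin, cMax)}.
#' @param halfLife half-life (samples) of the exponential moving average of
#'   the mean squared innovation used by the adaptive rule.
#' @return a [TVMVARModel-class].
#' @seealso [siStokFit()] for the structurally informed variant, [mdi()] for
#'   the derived directed-influence metric.
#' @export
stokFit <- function(data, order = 4, varianceFraction = 0.99,
                    c = "adaptive", cBase = 0.05, cMin = 1e-3, cMax = 1,
                    halfLife = 10) {
  solver <- function(fac, z) fac$pinv %*% z
  fitLoop(data, order, varianceFraction, c, cBase, cMin, cMax, halfLife,
          solver, method = "stok")
}

#' @describeIn innovations residuals of a fitted tv-MVAR model. With
#'   \code{data} supplied the residuals \code{z_t - H_t x_t} are recomputed
#'   against that dataset; otherwise the residuals stored at fit time are
#'   used. The innovation covariance is estimated over \code{window}
#'   (a range of sample indices; default all valid samples).
#' @param data optional [TimeSeriesData-class] matching the model shape.
#' @param window integer vector of sample indices (>= \code{validFrom}).
#' @return list with \code{residuals} (\code{trials x d x N}) and
#'   \code{covariance} (\code{d x d}).
#' @export
setMethod("innovations", "TVMVARModel", function(model, data = NULL,
                                                 window = NULL) {
  d <- dim(model@A)[1L]
  N <- dim(model@A)[4L]
  p <- model@order
  if (is.null(data)) {
    eps <- model@innovations
  } else {
    stopifnot(is(data, "TimeSeriesData"))
    if (nChannels(data) != d || nSamples(data) != N)
      stop("data shape does not match the fitted model")
    tr <- nTrials(data)
    eps <- array(NA_real_, c(tr, d, N))
    for (t in model@validFrom:N) {
      ld <- buildLagDesign(data, t, p)
      x <- matrix(aperm(array(model@A[, , , t], c(d, d, p)), c(2L, 3L, 1L)),
                  d * p, d)
      eps[, , t] <- ld@z - ld@H %*% x
    }
  }
  if (is.null(window)) window <- model@validFrom:N
  if (any(window < model@validFrom) || any(window > N))
    stop("window must lie within valid samples")
  tr <- dim(eps)[1L]
  E <- matrix(aperm(eps[, , window, drop = FALSE], c(1L, 3L, 2L)),
              tr * length(window), d)
  list(residuals = eps, covariance = stats::cov(E))
})

#' @rdname coefArray
#' @export
setMethod("coefArray", "TVMVARModel", function(x) x@A)

#' @rdname modelOrder
#' @export
setMethod("modelOrder", "TVMVARModel", function(x) x@order)

#' @rdname validFrom
#' @export
setMethod("validFrom", "TVMVARModel", function(x) x@validFrom)

#' @rdname validFrom
#' @export
setMethod("validFrom", "MDITensor", function(x) x@validFrom)

#' @rdname cTrace
#' @export
setMethod("cTrace", "TVMVARModel", function(x) x@cTrace)

#' @rdname nChannels
#' @export
setMethod("nChannels", "TVMVARModel", function(x) dim(x@A)[1L])

#' @rdname nSamples
#' @export
setMethod("nSamples", "TVMVARModel", function(x) dim(x@A)[4L])

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "TVMVARModel", function(x) x@channelLabels)

setMethod("show", "TVMVARModel", function(object) {
  dm <- dim(object@A)
  cat(sprintf("TVMVARModel (%s): d = %d, order = %d, N = %d samples\n",
              object@method, dm[1L], dm[3L], dm[4L]))
  cat(sprintf("  variance fraction %.3g, valid from sample %d\n",
              object@varianceFraction, object@validFrom))
  if (!is.null(object@prior))
    cat(sprintf("  structural prior: scaled to [%g, %g] (%s map)\n",
                object@prior$scaling[1L], object@prior$scaling[2L],
                object@prior$scaleMethod))
})
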