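#' @include AllClasses.R AllGenerics.R stok.R
NULL

#' @describeIn mdi magnitude of directed influence of a fitted model: for
#'   every edge (receiver i, sender j) and sample t, the norm over lags of
#'   the autoregressive coefficients. The default \code{"rss"} mode takes the
#'   root of the sum of squared lag coefficients; \code{"ss"} reports the
#'   plain sum of squares. The mode used is recorded in the result.
#' @param mode \code{"rss"} (root-sum-square, default) or \code{"ss"}.
#' @return an [MDITensor-class].
#' @examples
#' spec <- evokedSimulationSpec(trials = 5, samples = 60, seed = 1)
#' sim <- simulateTVMVAR(spec)
#' m <- mdi(stokFit(sim$data, order = 2))
#' dim(mdiValues(m))
#' @export
setMethod("mdi", "TVMVARModel", function(object, mode = c("rss", "ss")) {
  mode <- match.arg(mode)
  ss <- apply(object@A^2, c(1L, 2L, 4L), sum)
  vals <- if (mode == "rss") sqrt(ss) else ss
  new("MDITensor", values = vals, validFrom = object@validFrom,
      mode = mode, channelLabels = object@channelLabels)
})

#' @rdname mdiValues
#' @export
setMethod("mdiValues", "MDITensor", function(x) x@values)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "MDITensor", function(x) x@channelLabels)

setMethod("show", "MDITensor", function(object) {
  dm <- dim(object@values)
  cat(sprintf("MDITensor (%s): %d x %d nodes, %d samples (valid from %d)\n",
              object@mode, dm[1L], dm[2L], dm[3L], object@validFrom))
})

#' Summed outgoing directed influence per node
#'
#' For each sender node j, the summed magnitude of its outgoing directed
#' influences to all other nodes, averaged over a time window:
#' \code{mean_t sum_{i != j} MDI[i, j, t]}. Self-connections are excluded
#' by default.
#'
#' @param m an [MDITensor-class].
#' @param window integer vector of sample indices within the valid range.
#' @param includeSelf include the diagonal (self-influence) in the sum.
#' @return named numeric vector of per-node outflow.
#' @export
summedOutflow <- function(m, window, includeSelf = FALSE) {
  stopifnot(is(m, "MDITensor"))
  N <- dim(m@values)[3L]
  if (length(window) == 0L) stop("empty time window")
  if (any(window < m@validFrom) || any(window > N))
    stop(sprintf("window must lie within valid samples [%d, %d]",
                 m@validFrom, N))
  sl <- m@values[, , window, drop = FALSE]
  if (!includeSelf) {
    d <- dim(sl)[1L]
    mask <- array(rep(1 - diag(d), dim(sl)[3L]), dim(sl))
    sl <- sl * mask
  }
  out <- apply(sl, 2L, sum) / dim(sl)[3L]
  names(out) <- if (length(m@channelLabels)) m@channelLabels
  out
}

#' Rank nodes by outflow
#'
#' Stable descending sort of a per-node outflow (or outflow-difference)
#' vector; ties are broken by node label order.
#'
#' @param delta named numeric vector (e.g. from [summedOutflow()], or a
#'   difference of two such vectors).
#' @return data.frame with columns \code{node}, \code{outflow}, \code{rank}.
#' @export
rankOutflows <- function(delta) {
  if (is.null(names(delta))) names(delta) <- as.character(seq_along(delta))
  o <- order(-delta, names(delta), method = "radix")
  data.frame(node = names(delta)[o], outflow = unname(delta[o]),
             rank = seq_along(delta), row.names = NULL)
}

#' Proportional thresholding into a binary directed adjacency
#'
#' Retains the top \code{ceiling(keep * count)} off-diagonal entries of a
#' connectivity slice as edges (value 1) and zeroes the rest. Ties at the
#' cutoff value are all retained; the diagonal is always 0.
#'
#' @param slice d x d numeric matrix (e.g. an MDI slice at peak latency).
#' @param keep proportion of off-diagonal connections to keep, in (0, 1].
#' @return binary d x d matrix with attribute \code{keep}.
#' @export
proportionalAdjacency <- function(slice, keep = 0.5) {
  if (!is.matrix(slice) || nrow(slice) != ncol(slice))
    stop("'slice' must be a square matrix")
  assertScalar(keep, "keep", lo = 0, hi = 1)
  if (keep <= 0) stop("'keep' must lie in (0, 1]")
  d <- nrow(slice)
  off <- offDiagonal(d)
  w <- slice[off]
  nKeep <- ceiling(keep * length(off))
  cutoff <- sort(w, decreasing = TRUE)[nKeep]
  adj <- matrix(0, d, d)
  adj[off] <- as.numeric(w >= cutoff)
  attr(adj, "keep") <- keep
  adj
}

#' Consistency of a thresholded network against a reference
#'
#' The proportion of binary connections in the reference adjacency that are
#' also present in \code{adj} — used to quantify how much of the zero-noise
#' network survives a noise perturbation. By construction the consistency of
#' an adjacency with itself is 1.
#'
#' @param adj,adjRef binary directed adjacency matrices of equal dimension,
#'   thresholded with the same keep proportion.
#' @param denominator \code{"reference"} (default): divide the edge-set
#'   intersection by the reference edge count; \code{"union"}: Jaccard
#'   index.
#' @return proportion in [0, 1].
#' @export
consistency <- function(adj, adjRef,
                        denominator = c("reference", "union")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(adj), dim(adjRef)))
    stop("adjacency matrices must have identical dimensions")
  kA <- attr(adj, "keep"); kR <- attr(adjRef, "keep")
  if (!is.null(kA) && !is.null(kR) && kA != kR)
    stop("adjacencies were thresholded with different edge-count conventions")
  eA <- which(adj != 0)
  eR <- which(adjRef != 0)
  if (length(eR) == 0L) stop("reference adjacency has no edges")
  inter <- length(intersect(eA, eR))
  switch(denominator,
    reference = inter / length(eR),
    union = inter / length(union(eA, eR)))
}

#' Driver score of a node
#'
#' The excess outflow of a node over the network-average outflow at one
#' connectivity slice: positive when the node drives the network more than
#' average. Scores sum to zero across nodes.
#'
#' @param slice d x d connectivity matrix (e.g. MDI at peak latency).
#' @param node node index (or label, when the matrix has dimnames).
#' @param includeSelf include self-connections in outflows (default FALSE).
#' @return a number: \code{outflow(node) - mean(outflow)}.
#' @export
driverScore <- function(slice, node, includeSelf = FALSE) {
  if (!is.matrix(slice) || nrow(slice) != ncol(slice))
    stop("'slice' must be a square matrix")
  if (is.character(node)) node <- match(node, colnames(slice))
  if (is.na(node) || node < 1 || node > ncol(slice))
    stop("invalid 'node'")
  s <- slice
  if (!includeSelf) diag(s) <- 0
  out <- colSums(s)
  out[node] - mean(out)
}

#' Group-level sign-flip permutation test
#'
#' Tests, for every edge (and time point), whether the group-mean difference
#' deviates from zero by randomly flipping the sign of each subject's
#' difference. One-sided exceedance proportions are computed with the add-one
#' correction \code{(1 + count) / (nPerm + 1)} and doubled into a two-sided
#' p-value; significance is assessed at \code{alpha} uncorrected by default.
#'
#' @param diffs per-subject differences: a \code{subjects x edges} matrix or
#'   a \code{subjects x edges x time} array.
#' @param nPerm number of random sign-flip permutations.
#' @param alpha significance threshold.
#' @param seed mandatory integer seed.
#' @param adjust \code{"none"} (default, matching an uncorrected threshold)
#'   or \code{"fdr"} (Benjamini-Hochberg across all edges/times).
#' @return a [PermutationResult-class].
#' @export
signPermutationTest <- function(diffs, nPerm = 100000, alpha = 0.01, seed,
                                adjust = c("none", "fdr")) {
  adjust <- match.arg(adjust)
  if (missing(seed)) stop("'seed' is mandatory for a reproducible test")
  dm <- dim(diffs)
  if (is.null(dm) || length(dm) < 2L)
    stop("'diffs' must be a subjects x edges matrix or subjects x edges x time array")
  S <- dm[1L]
  if (S < 2L) stop("at least two subjects are required")
  if (nPerm < 100) warning("fewer than 100 permutations: p-values will be coarse")
  D <- matrix(diffs, nrow = S)              # subjects x q
  q <- ncol(D)
  obs <- colMeans(D)
  countHi <- countLo <- numeric(q)
  withSeed(seed, {
    chunk <- max(1L, min(nPerm, floor(2e7 / max(q, 1L))))
    done <- 0L
    while (done < nPerm) {
      nb <- min(chunk, nPerm - done)
      signs <- matrix(sample(c(-1, 1), nb * S, replace = TRUE), nb, S)
      means <- (signs %*% D) / S
      obsM <- matrix(obs, nb, q, byrow = TRUE)
      countHi <- countHi + colSums(means >= obsM)
      countLo <- countLo + colSums(means <= obsM)
      done <- done + nb
    }
  })
  pHi <- (1 + countHi) / (nPerm + 1)
  pLo <- (1 + countLo) / (nPerm + 1)
  p <- pmin(1, 2 * pmin(pHi, pLo))
  pAdj <- if (adjust == "fdr") stats::p.adjust(p, "fdr") else p
  shape <- if (length(dm) == 2L) dm[2L] else dm[-1L]
  new("PermutationResult",
      observed = array(obs, shape),
      pvalues = array(p, shape),
      nPermutations = as.integer(nPerm),
      alpha = alpha,
      significant = array(pAdj < alpha, shape),
      adjust = adjust)
}

#' @rdname pValues
#' @export
setMethod("pValues", "PermutationResult", function(x) x@pvalues)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: %d tests, %d sign-flip permutations, alpha = %g (%s)\n",
    length(object@pvalues), object@nPermutations, object@alpha,
    object@adjust))
  cat(sprintf("  significant: %d\n", sum(object@significant)))
})
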