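# Fixtures and small independent oracles shared across test files.

# White-noise multi-trial data.
randomTimeSeries <- function(trials = 4, d = 3, N = 40, seed = 1,
                             samplingRate = 1000) {
  set.seed(seed)
  timeSeriesData(array(rnorm(trials * d * N), c(trials, d, N)),
                 samplingRate = samplingRate)
}

# Mean MDI over a window of valid samples, as a d x d matrix.
windowMeanMDI <- function(model, window) {
  vals <- mdiValues(mdi(model))
  apply(vals[, , window, drop = FALSE], c(1, 2), mean)
}

# Off-diagonal index set of a d x d matrix (column-major).
offDiag <- function(d) which(diag(d) == 0)

# Independent normal-equations ridge oracle: (H'H + diag(q))^-1 H'z.
ridgeOracle <- function(H, z, q) {
  solve(crossprod(H) + diag(q, nrow = ncol(H)), crossprod(H, z))
}

# The default evoked fixture used across prior/benchmark tests; the active
# window scales with the epoch length.
evokedFixture <- function(seed, trials = 60, samples = 200) {
  spec <- evokedSimulationSpec(trials = trials, samples = samples,
                               onset = round(samples * 0.4),
                               offset = round(samples * 0.7),
                               seed = seed)
  sim <- simulateTVMVAR(spec)
  list(spec = spec, data = sim$data, truth = sim$coefficients,
       edges = trueEdges(spec))
}

# Null (no true FC) off-diagonal edges of a spec, excluding `exclude` rows.
nullEdges <- function(spec, exclude = NULL) {
  d <- spec@d
  all <- which(diag(d) == 0, arr.ind = FALSE)
  te <- trueEdges(spec)
  teIdx <- (te[, 2] - 1) * d + te[, 1]
  out <- setdiff(all, teIdx)
  if (!is.null(exclude))
    out <- setdiff(out, (exclude[2] - 1) * d + exclude[1])
  out
}
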