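# Build a TVMVARModel directly from a coefficient array (for metric tests).
modelFromA <- function(A, validFrom = dim(A)[3] + 1L) {
  d <- dim(A)[1]; p <- dim(A)[3]; N <- dim(A)[4]
  new("TVMVARModel", A = A, order = as.integer(p), varianceFraction = 1,
      cTrace = rep(1, N), innovations = array(0, c(1, d, N)),
      innovationCovariance = diag(d), validFrom = as.integer(p + 1L),
      channelLabels = paste0("n", seq_len(d)), method = "stok",
      prior = NULL)
}

test_that("MDI is the per-edge norm over lags", {
  A <- array(0, c(3, 3, 2, 10))
  m0 <- mdi(modelFromA(A))
  expect_true(all(mdiValues(m0)[, , 3:10] == 0))

  A[2, 1, 1, 5] <- 3
  A[2, 1, 2, 5] <- 4
  m <- mdi(modelFromA(A))
  expect_equal(mdiValues(m)[2, 1, 5], 5)          # 3-4-5 triangle
  expect_equal(mdiValues(mdi(modelFromA(A), mode = "ss"))[2, 1, 5], 25)

  set.seed(51)
  Ar <- array(rnorm(4 * 4 * 3 * 6), c(4, 4, 3, 6))
  got <- mdiValues(mdi(modelFromA(Ar)))
  for (t in 4:6)
    for (i in 1:4)
      for (j in 1:4)
        expect_equal(got[i, j, t], sqrt(sum(Ar[i, j, , t]^2)),
                     tolerance = 1e-12)
  # zero iff all lag coefficients zero
  expect_identical(unname(got[, , 4] == 0),
                   unname(apply(Ar[, , , 4]^2, c(1, 2), sum) == 0))
})

test_that("summed outflow averages over the window and excludes self-influence", {
  vals <- array(0, c(3, 3, 8))
  vals[2, 1, ] <- 2          # single edge 1 -> 2, constant
  vals[1, 1, ] <- 9          # self, excluded
  m <- new("MDITensor", values = vals, validFrom = 2L, mode = "rss",
           channelLabels = c("a", "b", "c"))
  out <- summedOutflow(m, window = 3:6)
  expect_equal(unname(out), c(2, 0, 0))
  expect_equal(names(out), c("a", "b", "c"))
  expect_equal(unname(summedOutflow(m, 3:6, includeSelf = TRUE)),
               c(11, 0, 0))
  expect_error(summedOutflow(m, integer(0)), "empty")
  expect_error(summedOutflow(m, 1:3), "valid")

  set.seed(52)
  vr <- array(abs(rnorm(4 * 4 * 10)), c(4, 4, 10))
  mr <- new("MDITensor", values = vr, validFrom = 2L, mode = "rss",
            channelLabels = paste0("n", 1:4))
  out <- summedOutflow(mr, 4:9)
  # sum-then-mean oracle
  ora <- sapply(1:4, function(j)
    mean(sapply(4:9, function(t) sum(vr[-j, j, t]))))
  expect_equal(unname(out), ora, tolerance = 1e-12)
  # node permutation equivariance
  pm <- c(3, 1, 4, 2)
  mp <- new("MDITensor", values = vr[pm, pm, , drop = FALSE], validFrom = 2L,
            mode = "rss", channelLabels = paste0("n", 1:4)[pm])
  expect_equal(unname(summedOutflow(mp, 4:9)), unname(out[pm]),
               tolerance = 1e-12)
})

test_that("outflow ranking is stable descending with label tie-breaks", {
  x <- c(b = 2, a = 5, c = 1)
  r <- rankOutflows(x)
  expect_equal(r$node, c("a", "b", "c"))
  expect_equal(r$outflow, c(5, 2, 1))
  tied <- c(z = 3, a = 3, m = 7)
  expect_equal(rankOutflows(tied)$node, c("m", "a", "z"))
  same <- c(q = 1, b = 1, a = 1)
  expect_equal(rankOutflows(same)$node, c("a", "b", "q"))
})

test_that("proportional adjacency keeps the strongest edges, ties included", {
  sl <- matrix(0, 3, 3)
  sl[offDiag(3)] <- c(6, 5, 4, 3, 2, 1)
  adj <- proportionalAdjacency(sl, keep = 0.5)
  expect_equal(sum(adj), 3)
  expect_true(all(adj[sl >= 4 & diag(3) == 0] == 1))
  expect_equal(unname(diag(adj)), rep(0, 3))

  expect_equal(sum(proportionalAdjacency(sl, keep = 1)), 6)

  set.seed(53)
  for (rep in 1:5) {
    s <- matrix(runif(36), 6, 6)
    keep <- sample(c(0.25, 0.5, 0.75), 1)
    adj <- proportionalAdjacency(s, keep)
    off <- offDiag(6)
    cutoff <- sort(s[off], decreasing = TRUE)[ceiling(keep * 30)]
    expect_equal(which(adj == 1), off[s[off] >= cutoff])
  }
})

test_that("consistency is the preserved fraction of reference edges", {
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 3] <- a[3, 1] <- 1
  expect_equal(consistency(a, a), 1)
  b <- matrix(0, 3, 3); b[2, 1] <- b[3, 2] <- b[1, 3] <- 1
  expect_equal(consistency(b, a), 0)
  half <- a; half[1, 2] <- 0; half[2, 1] <- 1
  expect_equal(consistency(half, a), 2 / 3)
  expect_equal(consistency(half, a, denominator = "union"), 0.5)

  set.seed(54)
  for (rep in 1:5) {
    x <- matrix(rbinom(25, 1, 0.4), 5, 5); diag(x) <- 0
    y <- matrix(rbinom(25, 1, 0.4), 5, 5); diag(y) <- 0
    if (sum(y) == 0) next
    ora <- length(intersect(which(x == 1), which(y == 1))) / sum(y)
    expect_equal(consistency(x, y), ora)
  }

  k1 <- a; attr(k1, "keep") <- 0.5
  k2 <- a; attr(k2, "keep") <- 0.25
  expect_error(consistency(k1, k2), "edge-count conventions")
  expect_error(consistency(a, matrix(0, 4, 4)), "identical dimensions")
})

test_that("driver score is the excess outflow over the network mean", {
  u <- matrix(1, 4, 4)
  for (n in 1:4) expect_equal(driverScore(u, n), 0)
  set.seed(55)
  s <- matrix(abs(rnorm(16)), 4, 4)
  scores <- sapply(1:4, function(n) driverScore(s, n))
  expect_equal(sum(scores), 0, tolerance = 1e-12)
})

test_that("a simulated dominant driver earns a positive driver score", {
  fx <- evokedFixture(seed = 56, trials = 40, samples = 150)
  m <- stokFit(fx$data, order = 2)
  peak <- round(150 * 0.55)
  sl <- mdiValues(mdi(m))[, , peak]
  expect_gt(driverScore(sl, 1), 0)
})

test_that("sign permutation test returns p = 1 for identically zero differences", {
  D <- matrix(0, 6, 4)
  res <- signPermutationTest(D, nPerm = 500, seed = 3)
  expect_true(all(pValues(res) == 1))
  expect_true(all(!res@significant))
})

test_that("Monte-Carlo permutation p-values agree with exhaustive sign enumeration", {
  set.seed(57)
  S <- 5
  D <- matrix(rnorm(S * 6, mean = rep(c(0, 0, 0.4, 1, -1, 2), each = S)),
              S, 6)
  obs <- colMeans(D)
  # exhaustive oracle over all 2^5 = 32 sign patterns
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
  nullMeans <- (signs %*% D) / S
  cHi <- colSums(nullMeans >= matrix(obs, 32, 6, byrow = TRUE))
  cLo <- colSums(nullMeans <= matrix(obs, 32, 6, byrow = TRUE))
  # expected Monte-Carlo value: with n samples, (1 + n*c/32)/(n + 1) -> c/32
  pEx <- pmin(1, 2 * pmin(cHi, cLo) / 32)

  res <- signPermutationTest(D, nPerm = 40000, seed = 11)
  # Monte-Carlo error of a proportion at n = 40000 is < 0.005 at 2 sd
  expect_lt(max(abs(as.numeric(pValues(res)) - pEx)), 0.02)
})

test_that("permutation test validates input and preserves edge/time shape", {
  expect_error(signPermutationTest(matrix(0, 1, 3), seed = 1),
               "two subjects")
  expect_error(signPermutationTest(matrix(0, 4, 3)), "seed")
  expect_warning(signPermutationTest(matrix(rnorm(12), 4, 3), nPerm = 50,
                                     seed = 1),
                 "fewer than 100")
  arr <- array(rnorm(5 * 3 * 7), c(5, 3, 7))
  res <- signPermutationTest(arr, nPerm = 200, seed = 2)
  expect_equal(dim(pValues(res)), c(3, 7))
  # reproducible under the same seed
  res2 <- signPermutationTest(arr, nPerm = 200, seed = 2)
  expect_identical(pValues(res), pValues(res2))
})
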