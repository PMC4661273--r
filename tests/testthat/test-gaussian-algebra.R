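# Gaussian algebra: KL divergence, robust log-det/inverse, Bayesian model
# reduction. Oracles: closed forms, Monte-Carlo estimates and direct
# conjugate refits.

randomSPD <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(0.1, d)
}

test_that("robustLogdetInv matches closed forms and a dense-solver oracle", {
  r <- robustLogdetInv(diag(3))
  expect_equal(r$logdet, 0)
  expect_equal(r$inv, diag(3))
  r <- robustLogdetInv(diag(c(2, 8)))
  expect_equal(r$logdet, log(16))
  expect_equal(r$inv, diag(c(0.5, 0.125)))
  M <- randomSPD(5, 11)
  r <- robustLogdetInv(M)
  expect_lt(max(abs(r$inv - solve(M))) / max(abs(solve(M))), 1e-8)
  expect_equal(r$logdet, as.numeric(determinant(M)$modulus), tolerance = 1e-10)
  expect_error(robustLogdetInv(matrix(1:4, 2)), "symmetric")
})

test_that("robustLogdetInv floors eigenvalues for rank-deficient input", {
  v <- c(1, 2, 3)
  M <- tcrossprod(v)            # rank 1
  r <- robustLogdetInv(M)
  ## acts as identity on the retained subspace
  expect_equal(as.numeric(r$inv %*% M %*% v), v, tolerance = 1e-6)
  expect_true(is.finite(r$logdet))
})

test_that("klGaussian matches closed forms and is zero iff identical", {
  q <- gaussianDensity(1, 1, "a")
  p <- gaussianDensity(0, 1, "a")
  expect_equal(klGaussian(q, p), 0.5)
  for (s in 1:3) {
    d <- gaussianDensity(rnorm(3, 0, 2), randomSPD(3, s), c("x", "y", "z"))
    expect_equal(klGaussian(d, d), 0)
  }
  q3 <- gaussianDensity(c(0.3, -0.5, 1), randomSPD(3, 21), c("x", "y", "z"))
  p3 <- gaussianDensity(c(0, 0.2, 0.5), randomSPD(3, 22), c("x", "y", "z"))
  expect_gt(klGaussian(q3, p3), 0)
  expect_error(klGaussian(q, p3), "name sets differ")
})

test_that("klGaussian matches a Monte-Carlo oracle within 3 standard errors", {
  q <- gaussianDensity(c(0.3, -0.5, 1), randomSPD(3, 31), c("x", "y", "z"))
  p <- gaussianDensity(c(0, 0.2, 0.5), randomSPD(3, 32), c("x", "y", "z"))
  logDens <- function(X, d) {
    L <- chol(d@cov)
    z <- backsolve(L, t(X) - d@mean, transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * 3 * log(2 * pi)
  }
  set.seed(99)
  n <- 1e6
  X <- matrix(rnorm(3 * n), n, 3) %*% chol(q@cov) +
    matrix(q@mean, n, 3, byrow = TRUE)
  w <- logDens(X, q) - logDens(X, p)
  se <- sd(w) / sqrt(n)
  expect_lt(abs(klGaussian(q, p) - mean(w)), 3 * se)
})

test_that("identity reduction returns the full posterior with deltaF = 0", {
  prior <- gaussianDensity(c(0, 1), randomSPD(2, 41), c("a", "b"))
  post <- gaussianDensity(c(0.5, 0.7), randomSPD(2, 42) / 4, c("a", "b"))
  r <- bayesReduce(prior, post, prior)
  expect_equal(r$deltaF, 0, tolerance = 1e-10)
  expect_equal(r$reducedPosterior@mean, post@mean, tolerance = 1e-10)
  expect_equal(r$reducedPosterior@cov, post@cov, tolerance = 1e-10)
})

test_that("reduction matches the 1-D conjugate closed form", {
  ## y ~ N(theta, 1), prior N(0, 1), observed y = 2:
  ## posterior N(1, 1/2); under prior N(b, v) the log-evidence is
  ## ln N(y; b, 1 + v), all computable in closed form.
  y <- 2
  prior <- gaussianDensity(0, 1, "a")
  post <- gaussianDensity(1, 0.5, "a")
  for (b in c(-1, 0, 0.7, 2)) {
    for (v in c(0.25, 1, 3)) {
      red <- bayesReduce(prior, post, gaussianDensity(b, v, "a"))
      dExpect <- dnorm(y, b, sqrt(1 + v), log = TRUE) -
        dnorm(y, 0, sqrt(2), log = TRUE)
      expect_equal(red$deltaF, dExpect, tolerance = 1e-9)
      pr <- 1 / v + 1
      expect_equal(red$reducedPosterior@mean, (y + b / v) / pr,
                   tolerance = 1e-9)
      expect_equal(as.numeric(red$reducedPosterior@cov), 1 / pr,
                   tolerance = 1e-9)
    }
  }
})

test_that("a near-zero-variance reduced prior pins the parameter to zero", {
  prior <- gaussianDensity(c(0, 0), c(1, 1), c("a", "b"))
  post <- gaussianDensity(c(0.8, 1.2), randomSPD(2, 51) / 4, c("a", "b"))
  rp <- gaussianDensity(c(0, 0), diag(c(1, 1e-8)), c("a", "b"))
  r <- bayesReduce(prior, post, rp)
  expect_lt(abs(r$reducedPosterior@mean[2]), 1e-3)
})

test_that("reduction composes over nested priors", {
  prior <- gaussianDensity(c(0, 0, 0), c(1, 1, 1), c("a", "b", "c"))
  post <- gaussianDensity(c(0.5, -0.3, 0.9), randomSPD(3, 61) / 3,
                          c("a", "b", "c"))
  pA <- gaussianDensity(c(0.1, 0, 0), c(0.5, 1, 0.25), c("a", "b", "c"))
  pB <- gaussianDensity(c(0.1, -0.2, 0), c(0.5, 0.1, 0.05), c("a", "b", "c"))
  full2B <- bayesReduce(prior, post, pB)
  full2A <- bayesReduce(prior, post, pA)
  A2B <- bayesReduce(pA, full2A$reducedPosterior, pB)
  expect_equal(full2A$deltaF + A2B$deltaF, full2B$deltaF, tolerance = 1e-6)
  expect_equal(A2B$reducedPosterior@mean, full2B$reducedPosterior@mean,
               tolerance = 1e-6)
})

test_that("reduction is exact for a linear-Gaussian model (GLS refit oracle)", {
  fx <- linearFixture(seed = 5)
  full <- linearOracle(fx)
  ## direct conjugate refit under a reduced prior
  rPrior <- gaussianDensity(c(0, 0, 0), c(0.2, 1e-6, 0.5),
                            parameterNames(fx$prior))
  fxr <- fx; fxr$prior <- rPrior
  reducedOracle <- linearOracle(fxr)
  red <- bayesReduce(fx$prior,
                     gaussianDensity(full$mean, full$cov,
                                     parameterNames(fx$prior)),
                     rPrior)
  expect_equal(red$reducedPosterior@mean, reducedOracle$mean,
               tolerance = 1e-6)
  expect_equal(red$deltaF, reducedOracle$logEv - full$logEv,
               tolerance = 1e-6)
})

test_that("reduction reports an indefinite reduced precision clearly", {
  prior <- gaussianDensity(0, 0.1, "a")
  post <- gaussianDensity(0.5, 0.2, "a")   # posterior wider than the prior
  expect_error(bayesReduce(prior, post, gaussianDensity(0, 100, "a")),
               "variance floor")
})

test_that("GaussianDensity validity enforces symmetry and dimensions", {
  expect_error(gaussianDensity(c(0, 1), matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")
  expect_error(new("GaussianDensity", names = "a", mean = c(0, 1),
                   cov = diag(2)), "length")
  d <- gaussianDensity(c(a = 1, b = 2), c(1, 4))
  expect_identical(parameterNames(d), c("a", "b"))
  expect_equal(meanVec(d), c(a = 1, b = 2))
  expect_equal(covMat(d), diag(c(1, 4), 2), ignore_attr = TRUE)
})
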