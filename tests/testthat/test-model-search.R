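# Exhaustive model search and Bayesian model averaging.

test_that("a strongly supported effect has inclusion probability near 1 (closed form)", {
  ## 1-D: prior N(0,1), posterior N(3, 0.01): the evidence ratio for
  ## "off" (prior N(0, v0)) is computable in closed form via the same
  ## conjugate identities used for KL tests
  prior <- gaussianDensity(0, 1, "a")
  post <- gaussianDensity(3, 0.01, "a")
  v0 <- 1e-4
  sp <- exhaustiveSearch(
    new("FirstLevelFit", posterior = post, lambda = 0,
        lambdaCov = matrix(1), freeEnergy = 0, nIterations = 1L,
        converged = TRUE, trajectory = 0),
    "a", offVariance = v0, prior = prior)
  expect_gt(inclusionProb(sp)["a"], 0.95)
  ## independent closed form: deltaF_off for a Gaussian (prior, posterior)
  P <- 1 / 0.01; Pi <- 1; Pir <- 1 / v0
  Pr <- P + Pir - Pi
  mur <- (P * 3) / Pr
  dFoff <- 0.5 * (log(P) + log(Pir) - log(Pi) - log(Pr)) +
    0.5 * (mur^2 * Pr - 3^2 * P)
  pOn <- 1 / (1 + exp(dFoff))
  expect_equal(unname(inclusionProb(sp)["a"]), pOn, tolerance = 1e-6)
})

test_that("a posterior equal to an off-variance prior gives a uniform model space", {
  K <- 3
  prior <- gaussianDensity(rep(0, K), rep(1e-4, K), c("a", "b", "c"))
  fit <- new("FirstLevelFit", posterior = prior, lambda = 0,
             lambdaCov = matrix(1), freeEnergy = 0, nIterations = 1L,
             converged = TRUE, trajectory = 0)
  sp <- exhaustiveSearch(fit, c("a", "b", "c"), offVariance = 1e-4,
                         prior = prior)
  expect_equal(sum(sp@modelPosterior), 1, tolerance = 1e-10)
  expect_equal(sp@modelPosterior, rep(2^-K, 2^K), tolerance = 1e-8)
  expect_equal(unname(inclusionProb(sp)), rep(0.5, K), tolerance = 1e-8)
})

test_that("an independent 2-D search factorizes into two 1-D searches", {
  prior <- gaussianDensity(c(0, 0), c(1, 1), c("a", "b"))
  post <- gaussianDensity(c(0.6, 0.2), c(0.05, 0.08), c("a", "b"))
  fit <- function(p, q) new("FirstLevelFit", posterior = q, lambda = 0,
                            lambdaCov = matrix(1), freeEnergy = 0,
                            nIterations = 1L, converged = TRUE,
                            trajectory = 0)
  joint <- exhaustiveSearch(fit(prior, post), c("a", "b"), prior = prior)
  for (k in c("a", "b")) {
    p1 <- gaussianDensity(0, 1, k)
    q1 <- gaussianDensity(meanVec(post)[k], covMat(post)[k, k], k)
    single <- exhaustiveSearch(fit(p1, q1), k, prior = p1)
    expect_equal(unname(inclusionProb(joint)[k]),
                 unname(inclusionProb(single)[k]), tolerance = 1e-6)
  }
})

test_that("model-average moments match a Monte-Carlo mixture oracle", {
  prior <- gaussianDensity(c(0, 0), c(1, 1), c("a", "b"))
  post <- gaussianDensity(c(0.4, 0.3),
                          matrix(c(0.05, 0.02, 0.02, 0.08), 2), c("a", "b"))
  fit <- new("FirstLevelFit", posterior = post, lambda = 0,
             lambdaCov = matrix(1), freeEnergy = 0, nIterations = 1L,
             converged = TRUE, trajectory = 0)
  sp <- exhaustiveSearch(fit, c("a", "b"), prior = prior)
  set.seed(123)
  n <- 1e6
  comp <- sample.int(length(sp@modelPosterior), n, replace = TRUE,
                     prob = sp@modelPosterior)
  draws <- matrix(0, n, 2)
  for (mIdx in unique(comp)) {
    idx <- which(comp == mIdx)
    d <- sp@reducedPosteriors[[mIdx]]
    draws[idx, ] <- matrix(rnorm(2 * length(idx)), ncol = 2) %*%
      chol(d@cov) + matrix(d@mean, length(idx), 2, byrow = TRUE)
  }
  bma <- bmaDensity(sp)
  seMean <- apply(draws, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(draws) - bma@mean) < 3 * seMean))
  expect_lt(max(abs(cov(draws) - bma@cov)), 5e-3)
})

test_that("single-model dominance returns that model's posterior as the BMA", {
  prior <- gaussianDensity(0, 1, "a")
  post <- gaussianDensity(5, 0.001, "a")   # overwhelming evidence for "on"
  fit <- new("FirstLevelFit", posterior = post, lambda = 0,
             lambdaCov = matrix(1), freeEnergy = 0, nIterations = 1L,
             converged = TRUE, trajectory = 0)
  sp <- exhaustiveSearch(fit, "a", prior = prior)
  expect_equal(bmaDensity(sp)@mean, post@mean, tolerance = 1e-6)
  expect_equal(as.numeric(bmaDensity(sp)@cov), as.numeric(post@cov),
               tolerance = 1e-6)
})

test_that("weak parameters are shrunk toward zero by model averaging", {
  st <- packagedStudy()
  peb <- st$fit@iterations[[st$fit@selectedIteration]]$peb
  cand <- grep("^mean:B_", parameterNames(peb@betaPosterior), value = TRUE)
  sp <- exhaustiveSearch(peb, cand)
  weak <- names(which(inclusionProb(sp) < 0.5))
  full <- meanVec(posterior(peb))
  bma <- meanVec(bmaDensity(sp))
  for (k in weak) expect_lt(abs(bma[k]), abs(full[k]))
})

test_that("more than 16 candidates are refused with guidance", {
  prior <- gaussianDensity(rep(0, 17), rep(1, 17), paste0("p", 1:17))
  fit <- new("FirstLevelFit", posterior = prior, lambda = 0,
             lambdaCov = matrix(1), freeEnergy = 0, nIterations = 1L,
             converged = TRUE, trajectory = 0)
  expect_error(exhaustiveSearch(fit, paste0("p", 1:17), prior = prior),
               "restrict")
})
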