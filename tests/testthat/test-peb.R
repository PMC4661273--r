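# Second-level (PEB) estimation: joint-model exactness, precision
# weighting, hyperparameter behavior and empirical-prior properties.

## shared 2-subject linear hierarchy with known variances
pebLinearFixture <- function(N = 2, seed = 2, sdNoise = 0.3,
                             s2true = c(0.05, 0.1), betaT = c(0.8, -0.5)) {
  set.seed(seed)
  n <- 30; p <- 2
  X <- matrix(rnorm(n * p), n, p)
  prior <- gaussianDensity(rep(0, p), rep(1, p), c("a", "b"))
  m <- linearModel(X, prior)
  lp <- gaussianDensity(log(1 / sdNoise^2), 1e-8, "lambda_1")
  ylist <- lapply(seq_len(N), function(i) {
    thi <- betaT + rnorm(p, 0, sqrt(s2true))
    matrix(as.numeric(X %*% thi) + rnorm(n, 0, sdNoise), n, 1)
  })
  fits <- lapply(ylist, function(y) fitFirstLevel(m, y, lambdaPrior = lp))
  ## gamma pinned at the generating variances
  design <- secondLevelDesign(prior, N, paramNames = c("a", "b"),
    Q = list(c(s2true[1], 0), c(0, s2true[2])),
    gammaPrior = gaussianDensity(rep(0, 2), rep(1e-10, 2), c("g1", "g2")))
  list(X = X, prior = prior, model = m, ylist = ylist, fits = fits,
       design = design, s2true = s2true, sdNoise = sdNoise)
}

test_that("the beta posterior matches the joint two-level GLS oracle", {
  fx <- pebLinearFixture()
  peb <- fitSecondLevel(fx$fits, fx$prior, fx$design)
  ## closed-form joint solution: y_i ~ N(X beta, X Sigma2 X' + noise)
  n <- nrow(fx$X)
  Vi <- solve(fx$X %*% diag(fx$s2true) %*% t(fx$X) +
                diag(n) * fx$sdNoise^2)
  P <- solve(fx$prior@cov)
  rhs <- P %*% fx$prior@mean
  for (y in fx$ylist) {
    P <- P + t(fx$X) %*% Vi %*% fx$X
    rhs <- rhs + t(fx$X) %*% Vi %*% y
  }
  expect_lt(max(abs(peb@betaPosterior@mean - solve(P, rhs))), 1e-5)
  expect_lt(max(abs(peb@betaPosterior@cov - solve(P))), 1e-5)
})

test_that("identical subjects drive the between-subject variance down", {
  set.seed(10)
  fx <- pebLinearFixture(N = 2, seed = 3)
  y <- fx$ylist[[1]]
  lp <- gaussianDensity(log(1 / fx$sdNoise^2), 1e-8, "lambda_1")
  fits <- lapply(1:4, function(i) fitFirstLevel(fx$model, y,
                                                lambdaPrior = lp))
  design <- secondLevelDesign(fx$prior, 4, paramNames = c("a", "b"))
  peb <- fitSecondLevel(fits, fx$prior, design)
  gamma <- meanVec(peb@gammaPosterior)
  expect_true(all(gamma > 0))   # precisions pushed above the prior mean
  s2hat <- pebgroup:::.sigma2Diag(design, gamma)
  s2prior <- pebgroup:::.sigma2Diag(design, design@gammaPrior@mean)
  expect_true(all(s2hat < s2prior))
})

test_that("with gamma fixed, beta is the precision-weighted subject average", {
  fx <- pebLinearFixture(N = 4, seed = 5)
  ## flatten the beta prior so only the subject information matters
  design <- fx$design
  design@X <- matrix(1, 4, 1)
  design@betaPrior <- gaussianDensity(c(0, 0), c(1e6, 1e6),
                                      parameterNames(design@betaPrior))
  peb <- fitSecondLevel(fx$fits, fx$prior, design)
  ## oracle: remove the full prior from each GLS posterior, then combine
  ## with weights (Ctilde_i + Sigma2)^-1
  S2 <- diag(fx$s2true)
  Pi0 <- solve(fx$prior@cov)
  num <- 0; den <- 0
  for (f in fx$fits) {
    Pi <- solve(f@posterior@cov)
    Ct <- solve(Pi - Pi0)
    mt <- Ct %*% (Pi %*% f@posterior@mean - Pi0 %*% fx$prior@mean)
    W <- solve(Ct + S2)
    num <- num + W %*% mt
    den <- den + W
  }
  expect_lt(max(abs(peb@betaPosterior@mean - solve(den, num))), 1e-4)
})

test_that("empirical priors are symmetric, shrinking and sane in the flat limit", {
  fx <- pebLinearFixture(N = 2, seed = 6)
  y <- fx$ylist[[1]]
  lp <- gaussianDensity(log(1 / fx$sdNoise^2), 1e-8, "lambda_1")
  fits2 <- list(fitFirstLevel(fx$model, y, lambdaPrior = lp),
                fitFirstLevel(fx$model, y, lambdaPrior = lp))
  design <- secondLevelDesign(fx$prior, 2, paramNames = c("a", "b"))
  peb <- fitSecondLevel(fits2, fx$prior, design)
  ep <- empiricalPriors(peb)
  ## identical subjects get identical empirical priors
  expect_equal(ep[[1]]@mean, ep[[2]]@mean)
  expect_equal(ep[[1]]@cov, ep[[2]]@cov)
  ## shrinkage direction: empirical-prior mean between the full-prior mean
  ## and the centroid of the subject posterior means
  centroid <- rowMeans(vapply(fits2, function(f) f@posterior@mean,
                              numeric(2)))
  for (k in 1:2) {
    lo <- min(fx$prior@mean[k], centroid[k]) - 1e-6
    hi <- max(fx$prior@mean[k], centroid[k]) + 1e-6
    expect_gte(ep[[1]]@mean[k], lo)
    expect_lte(ep[[1]]@mean[k], hi)
  }
  ## uninformative limit: a very imprecise gamma gives empirical priors at
  ## least as wide as the full prior, centred near its mean
  designFlat <- secondLevelDesign(fx$prior, 2, paramNames = c("a", "b"),
    gammaPrior = gaussianDensity(rep(-8, 2), rep(1e-10, 2), c("g1", "g2")))
  pebFlat <- fitSecondLevel(fits2, fx$prior, designFlat)
  epF <- empiricalPriors(pebFlat)[[1]]
  expect_true(all(diag(epF@cov) >= diag(fx$prior@cov)))
  expect_lt(max(abs(epF@mean - fx$prior@mean)), 0.1)
})

test_that("gamma precision controls pooling of re-inverted subjects", {
  fx <- pebLinearFixture(N = 3, seed = 7)
  lp <- gaussianDensity(log(1 / fx$sdNoise^2), 1e-8, "lambda_1")
  refit <- function(gamma0) {
    design <- secondLevelDesign(fx$prior, 3, paramNames = c("a", "b"),
      gammaPrior = gaussianDensity(rep(gamma0, 2), rep(1e-10, 2),
                                   c("g1", "g2")))
    peb <- fitSecondLevel(fx$fits, fx$prior, design)
    ep <- empiricalPriors(peb)
    vapply(1:3, function(i)
      fitFirstLevel(fx$model, fx$ylist[[i]], prior = ep[[i]],
                    lambdaPrior = lp)@posterior@mean, numeric(2))
  }
  spread <- function(M) max(apply(M, 1, function(r) diff(range(r))))
  original <- vapply(fx$fits, function(f) f@posterior@mean, numeric(2))
  pooled <- refit(8)      # tiny between-subject variance: full pooling
  unpooled <- refit(-8)   # huge between-subject variance: no pooling
  ## the propagated group-mean uncertainty keeps a ~1/N variance floor in
  ## the empirical priors, so the collapse is strong but not total
  expect_lt(spread(pooled), spread(original) / 3)
  expect_lt(max(abs(unpooled - original)), 0.05)
})

test_that("the between-subject SD is recovered within a factor of 2 at n = 16", {
  st <- packagedStudy()
  sel <- st$fit@iterations[[st$fit@selectedIteration]]
  design <- sel$peb@design
  s2hat <- pebgroup:::.sigma2Diag(design, meanVec(sel$peb@gammaPosterior))
  prior <- st$model@prior
  pv <- diag(prior@cov)[match(design@paramNames, parameterNames(prior))]
  trueSD <- sqrt(pv / 16)
  ## backward condition effects are generated without random effects
  active <- !(design@paramNames %in% c("B_bwd_21", "B_bwd_32"))
  ratio <- sqrt(s2hat[active]) / trueSD[active]
  expect_lt(abs(mean(log(ratio))), log(2))
  expect_true(all(ratio > 0.35 & ratio < 3))
})

test_that("design validation catches rank and size errors", {
  prior <- gaussianDensity(rep(0, 2), rep(1, 2), c("a", "b"))
  expect_error(secondLevelDesign(prior, 2, X = matrix(1, 2, 2)),
               "full column rank")
  fx <- pebLinearFixture(N = 2, seed = 9)
  expect_error(fitSecondLevel(fx$fits[1], fx$prior, fx$design),
               "at least 2 subjects")
})
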