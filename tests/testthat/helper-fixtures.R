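# Shared fixtures, built in code. The expensive objects (the packaged
# 16-subject study and its group inversion) are computed lazily once per
# test run and shared across files.

## small linear-Gaussian problem with known noise (near-delta lambda prior)
linearFixture <- function(n = 30, p = 3, seed = 1, sdNoise = 0.2,
                          priorVar = c(1, 2, 0.5),
                          priorMean = c(0.5, -0.2, 0)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  prior <- gaussianDensity(priorMean[seq_len(p)], priorVar[seq_len(p)],
                           letters[seq_len(p)])
  theta <- rnorm(p, prior@mean, 0.7)
  y <- as.numeric(X %*% theta) + rnorm(n, 0, sdNoise)
  lam0 <- log(1 / sdNoise^2)
  list(X = X, prior = prior, theta = theta, y = matrix(y, n, 1),
       model = linearModel(X, prior),
       lambdaPrior = gaussianDensity(lam0, 1e-8, "lambda_1"),
       noisePrec = 1 / sdNoise^2)
}

## closed-form GLS posterior + log evidence for a linear fixture
linearOracle <- function(fx) {
  Pi0 <- solve(fx$prior@cov)
  P <- fx$noisePrec * crossprod(fx$X) + Pi0
  mu <- solve(P, fx$noisePrec * crossprod(fx$X, fx$y) + Pi0 %*% fx$prior@mean)
  S <- diag(nrow(fx$X)) / fx$noisePrec + fx$X %*% fx$prior@cov %*% t(fx$X)
  r <- fx$y - fx$X %*% fx$prior@mean
  logEv <- -0.5 * (nrow(fx$X) * log(2 * pi) +
                     as.numeric(determinant(S)$modulus) +
                     as.numeric(crossprod(r, solve(S, r))))
  list(mean = as.numeric(mu), cov = solve(P), logEv = logEv)
}

## the packaged 16-subject evoked-response study and everything derived
## from it, computed once
packagedStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- erpNetworkModel()
      group <- generateGroup(model, config = simulationConfig())
      fit <- suppressMessages(fitGroup(group, model))
      report <- recoveryReport(fit, groupTruth(group))
      cache <<- list(model = model, group = group, fit = fit,
                     report = report)
    }
    cache
  }
})

## grand-average arm of the packaged study (single first-level inversion)
packagedGrandAverage <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- packagedStudy()
      ga <- grandAverage(st$group)
      gfit <- fitFirstLevel(st$model, ga@data[[1]])
      cache <<- list(ga = ga, fit = gfit)
    }
    cache
  }
})
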