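# Second-level (parametric empirical Bayes) model: subject parameters are a
# general linear model of group effects plus Gaussian random effects,
# theta_i = (X_i kron I) beta + eps,  eps ~ N(0, Sigma2(gamma)),
# estimated by maximizing the second-level free energy built from reduced
# first-level free energies (Bayesian model reduction), so the first-level
# inversions are never repeated while (beta, gamma) are optimized.

#' Construct a second-level design
#'
#' The default design carries a single constant column (one group mean per
#' parameter), one diagonal between-subject covariance component per
#' parameter (scaled to 1/16 of the full prior variance at gamma = 0), a
#' beta prior equal to the full first-level prior over the included
#' parameters (for the constant effect; further effects are zero-mean with
#' the same variances), and a N(0, 1/16) prior per component log-precision.
#' Observation-gain parameters are excluded from the second level by
#' default (within-subject nuisance).
#'
#' @param model a \linkS4class{ModelSpec} (or a
#'   \linkS4class{GaussianDensity} full prior).
#' @param nSubjects number of subjects.
#' @param X subjects x effects design matrix (default a constant column).
#' @param paramNames first-level parameters entering the second level
#'   (default: all except \code{gain_*}).
#' @param Q optional list of diagonal covariance-component weight vectors
#'   over \code{paramNames}.
#' @param betaPrior,gammaPrior optional hyperprior overrides.
#' @return a \linkS4class{SecondLevelDesign}.
#' @export
secondLevelDesign <- function(model, nSubjects, X = NULL, paramNames = NULL,
                              Q = NULL, betaPrior = NULL, gammaPrior = NULL) {
  prior <- if (is(model, "GaussianDensity")) model else model@prior
  allNames <- parameterNames(prior)
  if (is.null(paramNames))
    paramNames <- allNames[!grepl("^gain_", allNames)]
  stopifnot(all(paramNames %in% allNames))
  if (is.null(X)) X <- matrix(1, nSubjects, 1,
                              dimnames = list(NULL, "mean"))
  X <- as.matrix(X)
  effectNames <- colnames(X)
  if (is.null(effectNames)) effectNames <- paste0("effect_", seq_len(ncol(X)))
  p <- length(paramNames)
  pv <- diag(prior@cov)[match(paramNames, allNames)]
  if (is.null(Q))
    Q <- lapply(seq_len(p), function(k) {
      q <- numeric(p); q[k] <- pv[k] / 16; q
    })
  if (is.null(betaPrior)) {
    bm <- rep(0, p * ncol(X))
    bv <- rep(pv, ncol(X))
    bm[seq_len(p)] <- prior@mean[match(paramNames, allNames)]
    betaPrior <- gaussianDensity(bm, bv,
      as.vector(outer(paramNames, effectNames,
                      function(a, b) paste(b, a, sep = ":"))))
  }
  if (is.null(gammaPrior))
    gammaPrior <- gaussianDensity(rep(0, length(Q)), rep(1 / 16, length(Q)),
                                  paste0("gamma_", seq_along(Q)))
  new("SecondLevelDesign", X = X, paramNames = paramNames,
      effectNames = effectNames, Q = Q, betaPrior = betaPrior,
      gammaPrior = gammaPrior)
}

## between-subject covariance diagonal at gamma
.sigma2Diag <- function(design, gamma) {
  Reduce(`+`, lapply(seq_along(design@Q),
                     function(k) exp(-gamma[k]) * design@Q[[k]]))
}

## per-subject sufficient statistics for the second-level objective
.pebSubject <- function(fit, fullPrior, sIdx) {
  d <- length(fullPrior@mean)
  nIdx <- setdiff(seq_len(d), sIdx)
  if (length(nIdx) &&
      max(abs(fullPrior@cov[sIdx, nIdx, drop = FALSE])) > 1e-12)
    stop("full prior must not correlate second-level and nuisance parameters")
  Pi0 <- robustLogdetInv(fullPrior@cov)
  P <- robustLogdetInv(fit@posterior@cov)
  ldSnn <- if (length(nIdx))
    robustLogdetInv(fullPrior@cov[nIdx, nIdx, drop = FALSE]) else
    list(logdet = 0, inv = matrix(0, 0, 0))
  list(Pi0 = Pi0$inv, ldS0 = Pi0$logdet, eta0 = fullPrior@mean,
       P = P$inv, ldC = P$logdet, mu = fit@posterior@mean,
       nIdx = nIdx, PiNN = ldSnn$inv, ldSnn = ldSnn$logdet,
       F1 = fit@freeEnergy)
}

## reduced-free-energy pieces for one subject at (beta, gamma)
.pebDeltaF <- function(sub, sIdx, Ti, beta, pi2, ldS2) {
  d <- length(sub$eta0)
  Pir <- matrix(0, d, d)
  if (length(sub$nIdx)) Pir[sub$nIdx, sub$nIdx] <- sub$PiNN
  Pir[cbind(sIdx, sIdx)] <- pi2
  etar <- sub$eta0
  etar[sIdx] <- as.numeric(Ti %*% beta)
  r <- .bmrPrecision(sub$Pi0, sub$ldS0, sub$eta0,
                     Pir, ldS2 + sub$ldSnn, etar,
                     sub$P, sub$ldC, sub$mu)
  list(deltaF = r$deltaF, murS = r$mean[sIdx],
       CrSS = r$cov[sIdx, sIdx, drop = FALSE], etarS = etar[sIdx])
}

#' Fit the second-level model over subject posteriors
#'
#' Maximizes the second-level free energy
#' F2 = sum_i [dF_i(beta, gamma) + F1_i] - KL(q(beta) || p(beta))
#'      - KL(q(gamma) || p(gamma)),
#' where dF_i is the reduced free energy of subject i under the empirical
#' prior with mean (X_i kron I) beta and covariance Sigma2(gamma) on the
#' second-level parameters (nuisance parameters keep their first-level
#' prior). Because dF_i is exactly quadratic in beta, the beta posterior is
#' closed-form given gamma; gamma is optimized by damped (diagonal) Newton
#' steps on the profile objective, accepting only increases.
#'
#' @param fits list of per-subject \linkS4class{FirstLevelFit} objects.
#' @param fullPriors the priors under which those fits were obtained: a
#'   single \linkS4class{GaussianDensity} (shared) or a list, one per
#'   subject.
#' @param design a \linkS4class{SecondLevelDesign}.
#' @param maxIter,tol outer iteration cap and F2 tolerance.
#' @return a \linkS4class{PEBResult}; its \code{empiricalPriors} slot holds
#'   the per-subject empirical priors implied by the estimate.
#' @export
fitSecondLevel <- function(fits, fullPriors, design, maxIter = 32L,
                           tol = 1e-2) {
  N <- length(fits)
  if (N < 2) stop("at least 2 subjects are required")
  if (is(fullPriors, "GaussianDensity"))
    fullPriors <- rep(list(fullPriors), N)
  stopifnot(length(fullPriors) == N, nrow(design@X) == N)
  pn <- parameterNames(fits[[1]]@posterior)
  for (f in fits) stopifnot(identical(parameterNames(f@posterior), pn))
  sIdx <- match(design@paramNames, pn)
  if (anyNA(sIdx)) stop("design parameters missing from the fits")
  E <- ncol(design@X)
  p <- length(sIdx)
  if (N < E) stop("fewer subjects than second-level effects")
  subs <- lapply(seq_len(N), function(i) {
    tryCatch(.pebSubject(fits[[i]], alignDensity(fits[[i]]@posterior,
                                                 fullPriors[[i]], "full prior"),
                         sIdx),
             error = function(e) stop(sprintf("subject %d: %s", i,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  Ti <- lapply(seq_len(N),
               function(i) kronecker(matrix(design@X[i, ], 1, E), diag(p)))
  Pb0 <- robustLogdetInv(design@betaPrior@cov)
  g0 <- design@gammaPrior@mean
  PiG <- robustLogdetInv(design@gammaPrior@cov)$inv
  sumF1 <- sum(vapply(subs, function(s) s$F1, 0))

  ## closed-form beta posterior and objective pieces at a given gamma
  solveBeta <- function(gamma) {
    s2 <- .sigma2Diag(design, gamma)
    pi2 <- 1 / s2
    ldS2 <- sum(log(s2))
    beta <- design@betaPrior@mean
    H <- Pb0$inv
    g <- rep(0, length(beta))
    parts <- vector("list", N)
    for (i in seq_len(N)) {
      r <- .pebDeltaF(subs[[i]], sIdx, Ti[[i]], beta, pi2, ldS2)
      parts[[i]] <- r
      M <- diag(pi2, p) - (pi2 * r$CrSS) * rep(pi2, each = p)
      H <- H + crossprod(Ti[[i]], M %*% Ti[[i]])
      g <- g + as.numeric(crossprod(Ti[[i]], pi2 * (r$murS - r$etarS)))
    }
    H <- (H + t(H)) / 2
    Sb <- robustLogdetInv(H)$inv
    betaHat <- beta + as.numeric(Sb %*% g)   # prior-gradient term is 0 at beta0
    dF <- vapply(seq_len(N), function(i)
      .pebDeltaF(subs[[i]], sIdx, Ti[[i]], betaHat, pi2, ldS2)$deltaF, 0)
    qb <- gaussianDensity(betaHat, Sb, parameterNames(design@betaPrior))
    klb <- klGaussian(qb, design@betaPrior)
    klgQuad <- 0.5 * sum((gamma - g0) * (PiG %*% (gamma - g0)))
    list(F2 = sum(dF) + sumF1 - klb - klgQuad, beta = qb, dF = dF)
  }

  gamma <- g0
  cur <- solveBeta(gamma)
  traj <- cur$F2
  K <- length(gamma)
  h <- 1e-3
  for (it in seq_len(maxIter)) {
    grad <- numeric(K); curv <- numeric(K)
    for (k in seq_len(K)) {
      gp <- gamma; gp[k] <- gp[k] + h
      gm <- gamma; gm[k] <- gm[k] - h
      fp <- solveBeta(gp)$F2; fm <- solveBeta(gm)$F2
      grad[k] <- (fp - fm) / (2 * h)
      curv[k] <- (fp - 2 * cur$F2 + fm) / h^2
    }
    step <- grad / pmax(abs(curv), 1)
    step <- pmax(pmin(step, 2), -2)
    t <- 1; improved <- FALSE
    while (t > 1e-4) {
      cand <- solveBeta(gamma + t * step)
      if (is.finite(cand$F2) && cand$F2 > cur$F2) {
        gamma <- gamma + t * step
        dF2 <- cand$F2 - cur$F2
        cur <- cand
        traj <- c(traj, cur$F2)
        improved <- TRUE
        break
      }
      t <- t / 2
    }
    if (!improved) break
    if (dF2 < tol) break
  }

  ## gamma posterior covariance from the (diagonal) profile curvature
  curv <- numeric(K)
  for (k in seq_len(K)) {
    gp <- gamma; gp[k] <- gp[k] + h
    gm <- gamma; gm[k] <- gm[k] - h
    curv[k] <- (solveBeta(gp)$F2 - 2 * cur$F2 + solveBeta(gm)$F2) / h^2
  }
  gammaCov <- diag(1 / pmax(-curv, 1e-6), K)
  qg <- gaussianDensity(gamma, gammaCov, parameterNames(design@gammaPrior))
  klg <- klGaussian(qg, design@gammaPrior)
  klgQuad <- 0.5 * sum((gamma - g0) * (PiG %*% (gamma - g0)))
  F2 <- cur$F2 + klgQuad - klg
  emp <- .makeEmpiricalPriors(cur$beta, gamma, design, fullPriors)
  new("PEBResult", betaPosterior = cur$beta, gammaPosterior = qg, F2 = F2,
      empiricalPriors = emp, perSubjectDeltaF = cur$dF, design = design,
      trajectory = traj)
}

.makeEmpiricalPriors <- function(betaPost, gamma, design, fullPriors) {
  p <- length(design@paramNames)
  E <- ncol(design@X)
  s2 <- .sigma2Diag(design, gamma)
  lapply(seq_along(fullPriors), function(i) {
    fp <- fullPriors[[i]]
    sIdx <- match(design@paramNames, parameterNames(fp))
    Ti <- kronecker(matrix(design@X[i, ], 1, E), diag(p))
    m <- fp@mean
    V <- fp@cov
    m[sIdx] <- as.numeric(Ti %*% betaPost@mean)
    V[sIdx, ] <- 0; V[, sIdx] <- 0
    V[sIdx, sIdx] <- diag(s2, p) + Ti %*% betaPost@cov %*% t(Ti)
    gaussianDensity(m, V, parameterNames(fp))
  })
}

#' Per-subject empirical priors of a second-level estimate
#'
#' Subject i's empirical prior has mean (X_i kron I) E[beta] and covariance
#' Sigma2(E[gamma]) + (X_i kron I) Cov[beta] (X_i kron I)' over the
#' second-level parameters (the group-mean uncertainty is propagated);
#' parameters excluded from the second level keep their original prior.
#'
#' @param peb a \linkS4class{PEBResult}.
#' @param fullPriors optional per-subject priors to rebuild the empirical
#'   priors against; by default the stored ones are returned.
#' @return list of per-subject \linkS4class{GaussianDensity} priors.
#' @export
empiricalPriors <- function(peb, fullPriors = NULL) {
  if (is.null(fullPriors)) return(peb@empiricalPriors)
  if (is(fullPriors, "GaussianDensity"))
    fullPriors <- rep(list(fullPriors), nrow(peb@design@X))
  .makeEmpiricalPriors(peb@betaPosterior, peb@gammaPosterior@mean,
                       peb@design, fullPriors)
}
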