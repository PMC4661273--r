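# First-level inversion: Gauss-Newton / Levenberg-Marquardt maximization of
# the variational free energy under the Laplace approximation, with
# closed-form-gradient (Newton) updates of the noise log-precisions.

.defaultLambdaPrior <- function(model) {
  k <- length(model@noiseComponents)
  gaussianDensity(rep(0, k), rep(16, k), paste0("lambda_", seq_len(k)))
}

## full evaluation of the (profile) free energy at a parameter mean:
## residuals, Jacobian, noise precisions optimized by damped Newton,
## posterior covariance and the three free-energy terms.
.vlState <- function(model, y, mu, prior, lambdaPrior, lam, Pi0, ld0, qw) {
  pred <- .predictStacked(model, mu)
  e <- y - pred
  if (!all(is.finite(e))) stop("non-finite residuals")
  J <- .jacobianStacked(model, mu)
  n <- length(y)
  K <- length(qw)
  lam0 <- lambdaPrior@mean
  PiL <- robustLogdetInv(lambdaPrior@cov)
  eQe <- vapply(qw, function(q) sum(q * e * e), 0)

  lamObj <- function(lam, Sq) {
    Pie <- Reduce(`+`, lapply(seq_len(K), function(k) exp(lam[k]) * qw[[k]]))
    JS <- J %*% Sq
    Tk <- vapply(seq_len(K), function(k) sum(JS * (qw[[k]] * J)), 0)
    g <- vapply(seq_len(K), function(k) {
      0.5 * exp(lam[k]) * sum(qw[[k]] / Pie) -
        0.5 * exp(lam[k]) * (eQe[k] + Tk[k])
    }, 0) - as.numeric(PiL$inv %*% (lam - lam0))
    H <- matrix(0, K, K)
    for (k in seq_len(K)) for (l in seq_len(K)) {
      H[k, l] <- -0.5 * exp(lam[k] + lam[l]) *
        sum(qw[[k]] * qw[[l]] / Pie^2)
      if (k == l)
        H[k, l] <- H[k, l] + 0.5 * exp(lam[k]) * sum(qw[[k]] / Pie) -
          0.5 * exp(lam[k]) * (eQe[k] + Tk[k])
    }
    H <- H - PiL$inv
    list(g = g, H = H, Pie = Pie, Tk = Tk)
  }

  ## alternate posterior covariance and lambda (Newton) to a fixed point
  for (rep in seq_len(12)) {
    Pie <- Reduce(`+`, lapply(seq_len(K), function(k) exp(lam[k]) * qw[[k]]))
    P <- crossprod(J, J * Pie) + Pi0
    Sq <- robustLogdetInv(P)$inv
    ob <- lamObj(lam, Sq)
    step <- tryCatch(solve(ob$H, -ob$g), error = function(e) -ob$g * 0)
    step <- pmax(pmin(step, 4), -4)
    lamNew <- lam + step
    if (max(abs(lamNew - lam)) < 1e-6) { lam <- lamNew; break }
    lam <- lamNew
  }
  Pie <- Reduce(`+`, lapply(seq_len(K), function(k) exp(lam[k]) * qw[[k]]))
  Pfull <- crossprod(J, J * Pie) + Pi0
  rP <- robustLogdetInv(Pfull)
  Sq <- rP$inv
  ob <- lamObj(lam, Sq)
  lamCov <- robustLogdetInv(-(ob$H + t(ob$H)) / 2)$inv

  accuracy <- -0.5 * sum(Pie * e * e) - 0.5 * sum(ob$Tk * exp(lam)) +
    0.5 * sum(log(Pie)) - 0.5 * n * log(2 * pi)
  post <- gaussianDensity(mu, Sq, parameterNames(prior))
  klTheta <- klGaussian(post, prior)
  klLam <- klGaussian(gaussianDensity(lam, lamCov, parameterNames(lambdaPrior)),
                      lambdaPrior)
  list(mu = mu, lam = lam, lamCov = lamCov, e = e, J = J, Pie = Pie,
       P = Pfull, Sq = Sq, posterior = post,
       F = accuracy - klTheta - klLam, accuracy = accuracy)
}

#' Fit a forward model by variational Laplace
#'
#' Maximizes the variational free energy
#' F = E_q[ln p(y | theta, lambda)] - KL(q(theta) || p(theta))
#'     - KL(q(lambda) || p(lambda))
#' over a Gaussian posterior q(theta) and noise log-precisions lambda, by
#' Levenberg-Marquardt-damped Gauss-Newton updates of the posterior mean
#' interleaved with Newton updates of lambda. A step is accepted only if F
#' increases (damping is multiplied by 8 on rejection, halved on
#' acceptance); the scheme stops when the free-energy gain stays below
#' \code{tol} for four consecutive accepted steps, or after \code{maxIter}
#' proposals. Conditions are fitted jointly by stacking residuals, with one
#' lambda shared across conditions.
#'
#' @param model a \linkS4class{ModelSpec}.
#' @param data channels x bins x conditions array (a matrix is treated as a
#'   single condition).
#' @param prior Gaussian prior over parameters (default the model's).
#' @param lambdaPrior Gaussian prior over noise log-precisions; the default
#'   is a weakly informative N(0, 16) per component, letting the data set
#'   the noise scale.
#' @param init optional starting value for the posterior mean (default the
#'   prior mean).
#' @param maxIter,tol iteration cap and free-energy tolerance.
#' @return a \linkS4class{FirstLevelFit}.
#' @export
fitFirstLevel <- function(model, data, prior = model@prior,
                          lambdaPrior = .defaultLambdaPrior(model),
                          init = NULL, maxIter = 64L, tol = 1e-2) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(dim(data)[1] == model@nChannels, dim(data)[2] == model@nBins,
            dim(data)[3] == model@nConditions)
  prior <- alignDensity(gaussianDensity(rep(0, length(model@paramNames)),
                                        rep(1, length(model@paramNames)),
                                        model@paramNames),
                        prior, "first-level prior")
  y <- as.numeric(data)
  qw <- lapply(seq_along(model@noiseComponents),
               function(k) .noiseWeight(model, k))
  Pi0r <- robustLogdetInv(prior@cov)
  mu <- if (is.null(init)) prior@mean else as.numeric(init)
  lam <- lambdaPrior@mean

  cur <- tryCatch(
    .vlState(model, y, mu, prior, lambdaPrior, lam, Pi0r$inv, Pi0r$logdet, qw),
    error = function(e) stop("diverged fit at initialization: ",
                             conditionMessage(e), call. = FALSE))
  Finit <- cur$F
  best <- cur
  traj <- cur$F
  nu <- 1 / 32
  nAccepted <- 0L
  converged <- FALSE
  slow <- 0L

  for (it in seq_len(maxIter)) {
    g <- as.numeric(crossprod(cur$J, cur$Pie * cur$e)) -
      as.numeric(Pi0r$inv %*% (cur$mu - prior@mean))
    D <- diag(pmax(diag(cur$P), 1e-12), length(g))
    step <- tryCatch(as.numeric(solve(cur$P + nu * D, g)),
                     error = function(e) rep(0, length(g)))
    cand <- tryCatch(
      .vlState(model, y, cur$mu + step, prior, lambdaPrior, cur$lam,
               Pi0r$inv, Pi0r$logdet, qw),
      error = function(e) NULL)
    if (!is.null(cand) && is.finite(cand$F) && cand$F > cur$F) {
      dF <- cand$F - cur$F
      cur <- cand
      nAccepted <- nAccepted + 1L
      traj <- c(traj, cur$F)
      if (cur$F > best$F) best <- cur
      nu <- max(nu / 2, 1e-8)
      slow <- if (dF < tol) slow + 1L else 0L
      if (slow >= 4L) { converged <- TRUE; break }
    } else {
      ## a rejected step that would change F by less than tol means the
      ## objective has stabilized; count it toward convergence
      if (!is.null(cand) && is.finite(cand$F) && cur$F - cand$F < tol) {
        slow <- slow + 1L
        if (slow >= 4L) { converged <- TRUE; break }
      }
      nu <- nu * 8
      if (nu > 1e8) break
    }
  }

  new("FirstLevelFit", posterior = best$posterior, lambda = best$lam,
      lambdaCov = best$lamCov, freeEnergy = max(best$F, Finit),
      nIterations = nAccepted, converged = converged, trajectory = traj)
}

#' Variational free energy of a given posterior
#'
#' Pure function of its arguments: the quantity \code{\link{fitFirstLevel}}
#' maximizes, evaluated at a supplied Gaussian posterior and noise
#' log-precisions. The accuracy term is the expected log-likelihood under
#' the posterior (Gauss-Newton approximation: residuals at the posterior
#' mean plus the Jacobian-propagated posterior-covariance trace term).
#'
#' @inheritParams fitFirstLevel
#' @param posterior Gaussian posterior over model parameters.
#' @param lambda noise log-precision vector.
#' @param lambdaCov optional posterior covariance of lambda; if omitted,
#'   lambda is treated as a point estimate and its KL term reduces to the
#'   prior quadratic penalty.
#' @return free energy in nats.
#' @export
freeEnergyVL <- function(model, data, posterior, prior = model@prior,
                         lambda = NULL,
                         lambdaPrior = .defaultLambdaPrior(model),
                         lambdaCov = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (is.null(lambda)) lambda <- lambdaPrior@mean
  y <- as.numeric(data)
  n <- length(y)
  qw <- lapply(seq_along(model@noiseComponents),
               function(k) .noiseWeight(model, k))
  K <- length(qw)
  e <- y - .predictStacked(model, posterior@mean)
  J <- .jacobianStacked(model, posterior@mean)
  Pie <- Reduce(`+`, lapply(seq_len(K), function(k) exp(lambda[k]) * qw[[k]]))
  JS <- J %*% posterior@cov
  trTerm <- sum(vapply(seq_len(K), function(k)
    exp(lambda[k]) * sum(JS * (qw[[k]] * J)), 0))
  accuracy <- -0.5 * sum(Pie * e * e) - 0.5 * trTerm +
    0.5 * sum(log(Pie)) - 0.5 * n * log(2 * pi)
  klTheta <- klGaussian(posterior, prior)
  klLam <- if (is.null(lambdaCov)) {
    dl <- lambda - lambdaPrior@mean
    0.5 * sum(dl * (robustLogdetInv(lambdaPrior@cov)$inv %*% dl))
  } else {
    klGaussian(gaussianDensity(lambda, lambdaCov,
                               parameterNames(lambdaPrior)), lambdaPrior)
  }
  accuracy - klTheta - klLam
}
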