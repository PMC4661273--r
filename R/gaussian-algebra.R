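# Gaussian-density algebra: robust log-determinants/inverses, KL divergence,
# and analytic Bayesian model reduction. Everything downstream (free energies,
# empirical priors, model search) is built on these three primitives.

#' Robust log-determinant and inverse of a symmetric matrix
#'
#' Eigenvalues below \code{tol * lambda_max} are floored at that value before
#' taking logs and inverting, so rank-deficient matrices yield
#' pseudo-inverse-style results instead of errors. This conditioning is
#' applied uniformly to every covariance/precision inversion in the package.
#'
#' @param M symmetric numeric matrix.
#' @param tol relative eigenvalue floor (default 1e-8).
#' @return list with elements \code{logdet} and \code{inv}.
#' @examples
#' robustLogdetInv(diag(c(2, 8)))
#' @export
robustLogdetInv <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("M must be a square matrix")
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > 1e-8 * scale)
    stop("M must be symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lmax <- max(e$values, .Machine$double.xmin)
  floorv <- tol * lmax
  vals <- pmax(e$values, floorv)
  inv <- e$vectors %*% (t(e$vectors) / vals)
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- dimnames(M)
  list(logdet = sum(log(vals)), inv = inv)
}

## align the parameter ordering of y to that of x; identical sets required
alignDensity <- function(x, y, what = "density") {
  if (identical(x@names, y@names)) return(y)
  if (!setequal(x@names, y@names))
    stop(sprintf(
      "parameter name sets differ (%s): missing {%s}, extra {%s}",
      what,
      paste(setdiff(x@names, y@names), collapse = ", "),
      paste(setdiff(y@names, x@names), collapse = ", ")))
  idx <- match(x@names, y@names)
  gaussianDensity(y@mean[idx], y@cov[idx, idx, drop = FALSE], x@names)
}

#' Kullback-Leibler divergence between two Gaussian densities
#'
#' Computes KL(q || p) in nats. Parameters are aligned by name; densities
#' with different name sets are an error.
#'
#' @param q,p \linkS4class{GaussianDensity} objects of the same dimension.
#' @return nonnegative scalar (nats).
#' @examples
#' q <- gaussianDensity(1, 1, "a"); p <- gaussianDensity(0, 1, "a")
#' klGaussian(q, p)  # 0.5
#' @export
klGaussian <- function(q, p) {
  p <- alignDensity(q, p, "klGaussian")
  d <- length(q@mean)
  ev <- eigen(p@cov, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) {
    stop(sprintf("p.cov is singular beyond the regularization threshold (parameters: %s)",
                 paste(q@names, collapse = ", ")))
  }
  rp <- robustLogdetInv(p@cov)
  ldq <- robustLogdetInv(q@cov)$logdet
  dm <- p@mean - q@mean
  kl <- 0.5 * (sum(diag(rp$inv %*% q@cov)) + sum(dm * (rp$inv %*% dm)) -
               d + rp$logdet - ldq)
  max(kl, 0)
}

#' Bayesian model reduction of a (prior, posterior) pair
#'
#' Given a full prior, the posterior obtained under it, and a new (reduced)
#' prior, returns the posterior and the change in log evidence one would
#' have obtained by inverting the model under the reduced prior - without
#' touching the data. Exact for linear-Gaussian models; the workhorse behind
#' empirical priors and exhaustive model search.
#'
#' @param fullPrior,fullPosterior,reducedPrior \linkS4class{GaussianDensity}
#'   objects over the same parameters.
#' @return list with \code{reducedPosterior} (a GaussianDensity) and
#'   \code{deltaF} (nats; 0 when \code{reducedPrior} equals \code{fullPrior},
#'   positive when the reduced model is better supported).
#' @export
bayesReduce <- function(fullPrior, fullPosterior, reducedPrior) {
  fullPosterior <- alignDensity(fullPrior, fullPosterior, "bayesReduce posterior")
  reducedPrior <- alignDensity(fullPrior, reducedPrior, "bayesReduce reduced prior")
  Pi0 <- robustLogdetInv(fullPrior@cov)
  Pir <- robustLogdetInv(reducedPrior@cov)
  P <- robustLogdetInv(fullPosterior@cov)
  r <- .bmrPrecision(Pi0$inv, Pi0$logdet, fullPrior@mean,
                     Pir$inv, Pir$logdet, reducedPrior@mean,
                     P$inv, P$logdet, fullPosterior@mean)
  list(reducedPosterior = gaussianDensity(r$mean, r$cov, fullPrior@names),
       deltaF = r$deltaF)
}

## core BMR in precision form (logdets of the COVARIANCES are passed in).
## deltaF = 1/2(lndet P + lndet Pi_r - lndet Pi - lndet P_r)
##        + 1/2(mu_r' P_r mu_r + eta' Pi eta - mu' P mu - eta_r' Pi_r eta_r)
.bmrPrecision <- function(Pi0, ldS0, eta0, Pir, ldSr, etar, P, ldC, mu) {
  Pr <- P + Pir - Pi0
  Pr <- (Pr + t(Pr)) / 2
  ev <- eigen(Pr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev)))
    stop(paste("reduced posterior precision is not positive definite;",
               "increase the reduced-prior variance floor"))
  m <- as.numeric(P %*% mu + Pir %*% etar - Pi0 %*% eta0)
  Cr <- robustLogdetInv(Pr)
  mur <- as.numeric(Cr$inv %*% m)
  ## logdet precision = -logdet covariance
  deltaF <- 0.5 * ((-ldC) + (-ldSr) - (-ldS0) - Cr$logdet) +
    0.5 * (sum(mur * (Pr %*% mur)) + sum(eta0 * (Pi0 %*% eta0)) -
           sum(mu * (P %*% mu)) - sum(etar * (Pir %*% etar)))
  if (!is.finite(deltaF))
    stop("non-finite reduced free energy")
  list(mean = mur, cov = Cr$inv, deltaF = deltaF)
}
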