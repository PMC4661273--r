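#' @import methods
#' @importFrom stats cor dnorm qnorm rnorm sd var setNames
#' @useDynLib pebgroup, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Gaussian density over a named parameter vector
#'
#' The universal currency of the package: priors, posteriors and empirical
#' priors are all multivariate Gaussians over an ordered, named parameter
#' vector.
#'
#' @slot names ordered parameter labels.
#' @slot mean numeric mean vector.
#' @slot cov symmetric positive-semidefinite covariance matrix.
#' @export
setClass("GaussianDensity",
  representation(names = "character", mean = "numeric", cov = "matrix"))

setValidity("GaussianDensity", function(object) {
  d <- length(object@mean)
  if (length(object@names) != d)
    return("length(names) != length(mean)")
  if (!is.numeric(object@cov) || nrow(object@cov) != d || ncol(object@cov) != d)
    return("cov must be a d x d numeric matrix")
  if (anyDuplicated(object@names))
    return("parameter names must be unique")
  if (!all(is.finite(object@mean)) || !all(is.finite(object@cov)))
    return("mean and cov must be finite")
  asym <- max(abs(object@cov - t(object@cov)))
  scale <- max(abs(object@cov), 1e-300)
  if (asym > 1e-10 * scale)
    return("cov is not symmetric (relative tolerance 1e-10)")
  ev <- eigen((object@cov + t(object@cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  lmax <- max(ev, 0)
  if (min(ev) < -1e-8 * max(lmax, 1e-300))
    return("cov has eigenvalues below -1e-8 * lambda_max")
  TRUE
})

#' Construct a GaussianDensity
#'
#' @param mean numeric mean vector (a scalar is allowed for 1-D densities).
#' @param cov covariance matrix, or a vector of variances (expanded to a
#'   diagonal matrix), or a scalar variance for 1-D densities.
#' @param names parameter labels; defaults to names of \code{mean} or
#'   \code{par1, par2, ...}.
#' @return A \linkS4class{GaussianDensity}.
#' @examples
#' gaussianDensity(c(a = 0, b = 1), c(1, 0.25))
#' @export
gaussianDensity <- function(mean, cov, names = NULL) {
  mean <- unlist(mean)
  d <- length(mean)
  if (is.null(names)) {
    nm <- base::names(mean)
    names <- if (!is.null(nm)) nm else paste0("par", seq_len(d))
  }
  mean <- as.numeric(mean)
  if (is.matrix(cov)) {
    asym <- max(abs(cov - t(cov)))
    if (asym > 1e-8 * max(abs(cov), 1e-300))
      stop("cov is not symmetric")
  }
  if (!is.matrix(cov)) {
    cov <- as.numeric(cov)
    if (length(cov) == 1L && d > 1L) cov <- rep(cov, d)
    stopifnot(length(cov) == d)
    cov <- diag(cov, nrow = d)
  }
  dimnames(cov) <- list(names, names)
  cov <- (cov + t(cov)) / 2
  new("GaussianDensity", names = as.character(names),
      mean = as.numeric(mean), cov = cov)
}

#' @describeIn gaussianDensity parameter labels of a density.
#' @param x a \code{GaussianDensity}.
#' @export
parameterNames <- function(x) x@names

#' @describeIn gaussianDensity mean vector (named).
#' @export
meanVec <- function(x) setNames(x@mean, x@names)

#' @describeIn gaussianDensity covariance matrix.
#' @export
covMat <- function(x) x@cov

setMethod("show", "GaussianDensity", function(object) {
  d <- length(object@mean)
  cat(sprintf("GaussianDensity over %d parameter%s\n", d,
              if (d == 1) "" else "s"))
  k <- min(d, 6L)
  m <- meanVec(object)[seq_len(k)]
  s <- sqrt(pmax(diag(object@cov), 0))[seq_len(k)]
  for (i in seq_len(k))
    cat(sprintf("  %-12s %9.4f (sd %.4f)\n", names(m)[i], m[i], s[i]))
  if (d > k) cat(sprintf("  ... and %d more\n", d - k))
})

#' Forward-model contract
#'
#' A \code{ModelSpec} maps a named parameter vector to a predicted
#' channels x time matrix per experimental condition, and carries the prior
#' over its parameters plus a description of the observation-noise model.
#'
#' @slot paramNames ordered parameter labels.
#' @slot prior \linkS4class{GaussianDensity} prior over the parameters.
#' @slot nChannels,nBins,nConditions output dimensions.
#' @slot noiseComponents list of diagonal precision-component weight vectors
#'   over channels (each expanded over bins and conditions); the default
#'   single component weights all channels equally.
#' @slot predict function(theta, condition) -> channels x bins matrix;
#'   deterministic in theta.
#' @slot info free-form list (configuration snapshot and such).
#' @export
setClass("ModelSpec",
  representation(paramNames = "character", prior = "GaussianDensity",
                 nChannels = "integer", nBins = "integer",
                 nConditions = "integer", noiseComponents = "list",
                 predict = "function", info = "list"))

setValidity("ModelSpec", function(object) {
  if (!identical(object@paramNames, parameterNames(object@prior)))
    return("prior parameter names must equal paramNames")
  if (length(object@noiseComponents) < 1L)
    return("at least one noise component is required")
  for (q in object@noiseComponents) {
    if (length(q) != object@nChannels || any(q < 0))
      return("noise components must be nonnegative weight vectors over channels")
  }
  TRUE
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d parameters, %d channel(s) x %d bin(s) x %d condition(s)\n",
              length(object@paramNames), object@nChannels, object@nBins,
              object@nConditions))
})

#' First-level (within-subject) variational-Laplace fit
#'
#' @slot posterior Gaussian posterior over model parameters.
#' @slot lambda posterior mean of the noise log-precisions (one per noise
#'   component).
#' @slot lambdaCov posterior covariance of lambda.
#' @slot freeEnergy variational free energy (nats) at the returned posterior.
#' @slot nIterations accepted Gauss-Newton iterations performed.
#' @slot converged logical convergence flag.
#' @slot trajectory numeric vector of accepted free-energy values.
#' @export
setClass("FirstLevelFit",
  representation(posterior = "GaussianDensity", lambda = "numeric",
                 lambdaCov = "matrix", freeEnergy = "numeric",
                 nIterations = "integer", converged = "logical",
                 trajectory = "numeric"))

setMethod("show", "FirstLevelFit", function(object) {
  cat(sprintf("FirstLevelFit: F = %.3f nats, %d iteration(s)%s\n",
              object@freeEnergy, object@nIterations,
              if (object@converged) ", converged" else ""))
})

#' Free energy accessor
#' @param object a fitted object.
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))

#' @describeIn FirstLevelFit free energy of the fit.
#' @param object a \code{FirstLevelFit}.
#' @export
setMethod("freeEnergy", "FirstLevelFit", function(object) object@freeEnergy)

#' Posterior accessor
#' @param object a fitted object.
#' @export
setGeneric("posterior", function(object) standardGeneric("posterior"))

#' @describeIn FirstLevelFit posterior density of the fit.
#' @export
setMethod("posterior", "FirstLevelFit", function(object) object@posterior)

#' Second-level (between-subject) design
#'
#' Specifies the general linear model over subject parameters,
#' theta_i = (X_i kron I) beta + eps, the between-subject covariance
#' components Sigma2(gamma) = sum_k exp(-gamma_k) Q_k, and the hyperpriors.
#'
#' @slot X subjects x effects design matrix (default a single constant
#'   column: one group mean per parameter).
#' @slot paramNames the first-level parameters entering the second level.
#' @slot effectNames labels of the design columns.
#' @slot Q list of between-subject covariance components (diagonal weight
#'   vectors over paramNames).
#' @slot betaPrior Gaussian prior over the second-level parameters beta
#'   (ordered effect-major: effect 1 over all parameters, then effect 2...).
#' @slot gammaPrior Gaussian prior over component log-precisions gamma.
#' @export
setClass("SecondLevelDesign",
  representation(X = "matrix", paramNames = "character",
                 effectNames = "character", Q = "list",
                 betaPrior = "GaussianDensity", gammaPrior = "GaussianDensity"))

setValidity("SecondLevelDesign", function(object) {
  if (qr(object@X)$rank < ncol(object@X))
    return("design matrix X must have full column rank")
  if (ncol(object@X) != length(object@effectNames))
    return("effectNames must label the columns of X")
  p <- length(object@paramNames)
  if (length(object@betaPrior@mean) != p * ncol(object@X))
    return("betaPrior dimension must be n_params * n_effects")
  if (length(object@gammaPrior@mean) != length(object@Q))
    return("gammaPrior dimension must equal the number of Q components")
  for (q in object@Q)
    if (length(q) != p || any(q < 0))
      return("each Q component must be a nonnegative weight vector over paramNames")
  TRUE
})

setMethod("show", "SecondLevelDesign", function(object) {
  cat(sprintf("SecondLevelDesign: %d subject(s) x %d effect(s) over %d parameter(s), %d covariance component(s)\n",
              nrow(object@X), ncol(object@X), length(object@paramNames),
              length(object@Q)))
})

#' Second-level (PEB) estimate
#'
#' @slot betaPosterior Gaussian posterior over second-level parameters.
#' @slot gammaPosterior Gaussian posterior over component log-precisions.
#' @slot F2 second-level free energy (nats).
#' @slot empiricalPriors per-subject empirical-prior densities over the full
#'   first-level parameter space.
#' @slot perSubjectDeltaF per-subject reduced-free-energy increments at the
#'   optimum.
#' @slot design the \linkS4class{SecondLevelDesign} used.
#' @slot trajectory accepted F2 values during optimization.
#' @export
setClass("PEBResult",
  representation(betaPosterior = "GaussianDensity",
                 gammaPosterior = "GaussianDensity", F2 = "numeric",
                 empiricalPriors = "list", perSubjectDeltaF = "numeric",
                 design = "SecondLevelDesign", trajectory = "numeric"))

setMethod("show", "PEBResult", function(object) {
  cat(sprintf("PEBResult: F2 = %.3f nats, %d subject(s), %d second-level parameter(s)\n",
              object@F2, length(object@empiricalPriors),
              length(object@betaPosterior@mean)))
})

#' @describeIn PEBResult second-level free energy.
#' @param object a \code{PEBResult}.
#' @export
setMethod("freeEnergy", "PEBResult", function(object) object@F2)

#' @describeIn PEBResult posterior over second-level parameters.
#' @export
setMethod("posterior", "PEBResult", function(object) object@betaPosterior)

#' Multi-subject dataset
#'
#' @slot data list (one per subject) of channels x bins x conditions arrays.
#' @slot truth parameters x subjects matrix of generating values (synthetic
#'   data only; otherwise a 0 x 0 matrix).
#' @slot groupMeans named numeric vector of generating group means (synthetic
#'   only; otherwise empty).
#' @slot config list snapshot of the generating configuration.
#' @slot seed integer seed used for generation (NA for observed data).
#' @export
setClass("GroupDataset",
  representation(data = "list", truth = "matrix", groupMeans = "numeric",
                 config = "list", seed = "integer"))

setValidity("GroupDataset", function(object) {
  if (length(object@data) < 1L) return("at least one subject is required")
  dims <- lapply(object@data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("each subject's data must be a channels x bins x conditions array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("all subjects must share data dimensions")
  if (ncol(object@truth) > 0 && ncol(object@truth) != length(object@data))
    return("truth must have one column per subject")
  TRUE
})

#' @describeIn GroupDataset number of subjects.
#' @param object a \code{GroupDataset}.
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname GroupDataset-class
#' @export
setMethod("nSubjects", "GroupDataset", function(object) length(object@data))

#' @describeIn GroupDataset generating parameters (synthetic data only).
#' @export
setGeneric("groupTruth", function(object) standardGeneric("groupTruth"))

#' @rdname GroupDataset-class
#' @export
setMethod("groupTruth", "GroupDataset", function(object) object@truth)

setMethod("show", "GroupDataset", function(object) {
  d <- dim(object@data[[1]])
  cat(sprintf("GroupDataset: %d subject(s), %d channel(s) x %d bin(s) x %d condition(s)%s\n",
              length(object@data), d[1], d[2], d[3],
              if (ncol(object@truth) > 0) ", with ground truth" else ""))
})

#' Iterative group-inversion result
#'
#' @slot iterations list of per-iteration records; each holds
#'   \code{fits} (per-subject \linkS4class{FirstLevelFit}), \code{priors}
#'   (the priors those fits were obtained under), \code{peb}
#'   (\linkS4class{PEBResult}), \code{F2} and \code{meanLogdetPostCov}.
#' @slot selectedIteration index of the iteration selected by the
#'   log-determinant convergence rule.
#' @slot design the second-level design used.
#' @export
setClass("GroupFitResult",
  representation(iterations = "list", selectedIteration = "integer",
                 design = "SecondLevelDesign"))

setMethod("show", "GroupFitResult", function(object) {
  cat(sprintf("GroupFitResult: %d iteration(s), selected %d\n",
              length(object@iterations), object@selectedIteration))
  for (i in seq_along(object@iterations)) {
    it <- object@iterations[[i]]
    cat(sprintf("  iter %d: F2 = %10.3f, mean logdet post-cov = %8.3f\n",
                i, it$F2, it$meanLogdetPostCov))
  }
})

#' Exhaustive second-level model space
#'
#' @slot candidates labels of the switched parameters.
#' @slot patterns 2^K x K logical on/off matrix.
#' @slot deltaF per-model log-evidence increments (nats, relative to the
#'   full model).
#' @slot modelPosterior per-model posterior probabilities (flat model prior).
#' @slot inclusionProb per-candidate posterior inclusion probabilities.
#' @slot bma moment-matched Bayesian-model-average density.
#' @slot reducedPosteriors list of per-model reduced posteriors (kept when
#'   K <= 10).
#' @export
setClass("ModelSpace",
  representation(candidates = "character", patterns = "matrix",
                 deltaF = "numeric", modelPosterior = "numeric",
                 inclusionProb = "numeric", bma = "GaussianDensity",
                 reducedPosteriors = "list"))

setMethod("show", "ModelSpace", function(object) {
  cat(sprintf("ModelSpace: %d models over %d candidate parameter(s)\n",
              nrow(object@patterns), length(object@candidates)))
  ip <- sort(object@inclusionProb, decreasing = TRUE)
  for (i in seq_len(min(length(ip), 8L)))
    cat(sprintf("  P(include %s) = %.3f\n", names(ip)[i], ip[i]))
})

#' @describeIn ModelSpace per-candidate inclusion probabilities.
#' @param object a \code{ModelSpace}.
#' @export
setGeneric("inclusionProb", function(object) standardGeneric("inclusionProb"))

#' @rdname ModelSpace-class
#' @export
setMethod("inclusionProb", "ModelSpace", function(object) object@inclusionProb)
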