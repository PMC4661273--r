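# Exhaustive second-level model comparison: every on/off combination of a
# set of candidate parameters is scored by Bayesian model reduction
# ("off" = a shrinkage prior with mean zero and a very small variance),
# yielding model posteriors, per-parameter inclusion probabilities and a
# moment-matched Bayesian model average.

#' Exhaustive model search over parameter combinations
#'
#' @param object a \linkS4class{PEBResult} (search over the second-level
#'   posterior) or a \linkS4class{FirstLevelFit} (search over a
#'   single-subject posterior, e.g. a grand-average inversion).
#' @param candidates parameter labels to switch on/off (at most 16).
#' @param offVariance prior variance given to a switched-off parameter
#'   (default 1e-4); its prior mean is set to zero.
#' @param prior the prior paired with the posterior (required for the
#'   \code{FirstLevelFit} method; for \code{PEBResult} the design's beta
#'   prior is used).
#' @return a \linkS4class{ModelSpace}.
#' @export
setGeneric("exhaustiveSearch",
           function(object, candidates, offVariance = 1e-4, prior = NULL)
             standardGeneric("exhaustiveSearch"))

.searchPair <- function(prior, post, candidates, offVariance) {
  pn <- parameterNames(prior)
  stopifnot(all(candidates %in% pn))
  K <- length(candidates)
  if (K > 16)
    stop("more than 16 candidate parameters; restrict the candidate set")
  cIdx <- match(candidates, pn)
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), K)))
  colnames(patterns) <- candidates
  nM <- nrow(patterns)
  deltaF <- numeric(nM)
  means <- matrix(0, nM, length(pn))
  covs <- vector("list", nM)
  for (m in seq_len(nM)) {
    off <- cIdx[!patterns[m, ]]
    rm <- prior@mean
    rc <- prior@cov
    if (length(off)) {
      rm[off] <- 0
      rc[off, ] <- 0; rc[, off] <- 0
      rc[cbind(off, off)] <- offVariance
    }
    red <- bayesReduce(prior, post, gaussianDensity(rm, rc, pn))
    deltaF[m] <- red$deltaF
    means[m, ] <- red$reducedPosterior@mean
    covs[[m]] <- red$reducedPosterior@cov
  }
  w <- exp(deltaF - max(deltaF))
  pM <- w / sum(w)
  incl <- vapply(seq_len(K), function(k) sum(pM[patterns[, k]]), 0)
  names(incl) <- candidates
  bmaMean <- as.numeric(crossprod(means, pM))
  bmaCov <- Reduce(`+`, lapply(seq_len(nM), function(m)
    pM[m] * (covs[[m]] + tcrossprod(means[m, ])))) - tcrossprod(bmaMean)
  bmaCov <- (bmaCov + t(bmaCov)) / 2
  ev <- eigen(bmaCov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) bmaCov <- bmaCov + diag(-min(ev) + 1e-12, nrow(bmaCov))
  keep <- if (K <= 10)
    lapply(seq_len(nM), function(m) gaussianDensity(means[m, ], covs[[m]], pn))
  else list()
  new("ModelSpace", candidates = candidates, patterns = patterns,
      deltaF = deltaF, modelPosterior = pM, inclusionProb = incl,
      bma = gaussianDensity(bmaMean, bmaCov, pn),
      reducedPosteriors = keep)
}

#' @rdname exhaustiveSearch
#' @export
setMethod("exhaustiveSearch", "PEBResult",
  function(object, candidates, offVariance = 1e-4, prior = NULL) {
    if (is.null(prior)) prior <- object@design@betaPrior
    .searchPair(prior, object@betaPosterior, candidates, offVariance)
  })

#' @rdname exhaustiveSearch
#' @export
setMethod("exhaustiveSearch", "FirstLevelFit",
  function(object, candidates, offVariance = 1e-4, prior = NULL) {
    if (is.null(prior))
      stop("supply the prior the fit was obtained under")
    .searchPair(prior, object@posterior, candidates, offVariance)
  })

#' Bayesian-model-average density of a model space
#'
#' Single moment-matched Gaussian over the mixture of reduced posteriors:
#' mean = sum_m p_m mu_m, cov = sum_m p_m (Sigma_m + mu_m mu_m') - mu mu'.
#'
#' @param space a \linkS4class{ModelSpace}.
#' @return a \linkS4class{GaussianDensity}.
#' @export
bmaDensity <- function(space) space@bma

#' Report table of a model search
#'
#' The tabular summary reported after a search: full-posterior mean, BMA
#' mean, 90 percent credible interval and inclusion probability per
#' candidate parameter.
#'
#' @param space a \linkS4class{ModelSpace}.
#' @param fullPosterior the unreduced posterior the search started from.
#' @return a data.frame.
#' @export
searchReport <- function(space, fullPosterior) {
  bma <- space@bma
  idx <- match(space@candidates, parameterNames(bma))
  z <- qnorm(0.95)
  sdv <- sqrt(pmax(diag(bma@cov)[idx], 0))
  data.frame(parameter = space@candidates,
             fullMean = fullPosterior@mean[match(space@candidates,
                                                 parameterNames(fullPosterior))],
             bmaMean = bma@mean[idx],
             ci90Lower = bma@mean[idx] - z * sdv,
             ci90Upper = bma@mean[idx] + z * sdv,
             inclusionProb = as.numeric(space@inclusionProb))
}
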