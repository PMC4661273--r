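# Forward models: the nonlinear evoked-response network stand-in (a small
# coupled damped-oscillator network with tanh coupling and log-scale
# connection parameters) and a linear model used for exactness tests.

#' Configuration of the evoked-response network model
#'
#' A desk-scale network of coupled sources with hierarchical (forward /
#' backward / intrinsic) connections. Each source has two states (x, v):
#'   dx/dt = v
#'   dv/dt = kappa^2 (sum_k w_jk(c) tanh(x_k) + g_j u(t) - x_j) - 2 kappa v
#' with w_jk(c) = a_jk exp(theta_jk + [c == 2] mask_jk thetaB_jk), a signed
#' adjacency a_jk, rate constant kappa = kappa0 exp(theta_kappa) and a
#' Gaussian-bump input u(t) = exp(-(t - muU exp(theta_u))^2 / (2 sigmaU^2))
#' delivered to designated input sources. Channels observe a fixed random
#' mixing of the x states with per-channel log gains.
#'
#' @param nSources number of sources (default 3).
#' @param adjacency signed nSources x nSources structure matrix (entry
#'   [j, k] couples source k into source j). The default is a 3-source
#'   hierarchy: negative intrinsic self-connections, excitatory forward
#'   connections 1->2->3 and inhibitory backward connections 2->1, 3->2.
#' @param conditionEffectMask logical matrix over the adjacency support
#'   marking which connections carry condition-specific log-scalings
#'   (default: every connection, so backward effects are estimated even
#'   when the generating values are zero).
#' @param nChannels,nBins,binMs observation geometry (default 8 channels,
#'   128 bins of 4 ms).
#' @param kappa0 base rate constant in 1/s (default 25).
#' @param inputSources indices of sources receiving the exogenous input.
#' @param muU,sigmaU input-latency centre and width in seconds.
#' @param substeps RK4 sub-steps per time bin (default 2).
#' @return a list of class \code{erpNetworkConfig}.
#' @export
erpNetworkConfig <- function(nSources = 3L,
                             adjacency = NULL,
                             conditionEffectMask = NULL,
                             nChannels = 8L, nBins = 128L, binMs = 4,
                             kappa0 = 25, inputSources = 1L,
                             muU = 0.100, sigmaU = 0.016,
                             substeps = 2L) {
  nSources <- as.integer(nSources)
  if (is.null(adjacency)) {
    stopifnot(nSources == 3L)
    adjacency <- matrix(0, 3, 3)
    diag(adjacency) <- -1               # intrinsic self-connections
    adjacency[2, 1] <- adjacency[3, 2] <- 1    # forward, excitatory
    adjacency[1, 2] <- adjacency[2, 3] <- -1   # backward, inhibitory
  }
  stopifnot(nrow(adjacency) == nSources, ncol(adjacency) == nSources)
  if (is.null(conditionEffectMask)) conditionEffectMask <- adjacency != 0
  if (any(conditionEffectMask & adjacency == 0))
    stop("conditionEffectMask must be a subset of the adjacency support")
  structure(list(nSources = nSources, adjacency = adjacency,
                 conditionEffectMask = conditionEffectMask,
                 nChannels = as.integer(nChannels),
                 nBins = as.integer(nBins), binMs = binMs,
                 kappa0 = kappa0, inputSources = as.integer(inputSources),
                 muU = muU, sigmaU = sigmaU,
                 substeps = as.integer(substeps)),
            class = "erpNetworkConfig")
}

## edge bookkeeping: intrinsic first, then forward (lower triangle), then
## backward (upper triangle), each in column-major order of the adjacency.
.edgeTable <- function(config) {
  A <- config$adjacency
  idx <- which(A != 0, arr.ind = TRUE)
  j <- idx[, 1]; k <- idx[, 2]
  kind <- ifelse(j == k, "int", ifelse(j > k, "fwd", "bwd"))
  ord <- order(match(kind, c("int", "fwd", "bwd")), k, j)
  idx <- idx[ord, , drop = FALSE]
  kind <- kind[ord]
  lab <- ifelse(kind == "int", paste0("int_", idx[, 1]),
                paste0(kind, "_", idx[, 2], idx[, 1]))
  data.frame(j = idx[, 1], k = idx[, 2], kind = kind, label = lab,
             masked = config$conditionEffectMask[idx],
             stringsAsFactors = FALSE)
}

## fixed random channel mixing, frozen by an internal seed (the stand-in
## for a lead field); leaves the caller's RNG state untouched.
.defaultMixing <- function(nChannels, nSources) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(170519L)
  matrix(rnorm(nChannels * nSources), nChannels, nSources)
}

#' Evoked-response network forward model
#'
#' Builds the \linkS4class{ModelSpec} for the coupled-source network of
#' \code{\link{erpNetworkConfig}}. Free parameters: one log scaling per
#' connection, one condition-specific log scaling per masked connection,
#' the rate-constant and input-latency log scalings, and one log gain per
#' channel. All priors are zero-mean; connection and condition-effect
#' log scalings have prior variance 1/4, rate/latency/gain parameters 1/16.
#'
#' @param config an \code{\link{erpNetworkConfig}}.
#' @param mixing optional channels x sources observation matrix; by default
#'   a fixed (internally seeded) standard-normal mixing is used.
#' @return a \linkS4class{ModelSpec} whose \code{predict(theta, condition)}
#'   integrates the network with fixed-step RK4.
#' @export
erpNetworkModel <- function(config = erpNetworkConfig(), mixing = NULL) {
  edges <- .edgeTable(config)
  if (is.null(mixing))
    mixing <- .defaultMixing(config$nChannels, config$nSources)
  stopifnot(nrow(mixing) == config$nChannels,
            ncol(mixing) == config$nSources)
  connNames <- edges$label
  bNames <- paste0("B_", edges$label[edges$masked])
  gainNames <- paste0("gain_", seq_len(config$nChannels))
  paramNames <- c(connNames, bNames, "kappa", "latency", gainNames)
  pv <- c(rep(1 / 4, length(connNames)), rep(1 / 4, length(bNames)),
          1 / 16, 1 / 16, rep(1 / 16, length(gainNames)))
  prior <- gaussianDensity(rep(0, length(paramNames)), pv, paramNames)
  gvec <- numeric(config$nSources)
  gvec[config$inputSources] <- 1
  binS <- config$binMs / 1000

  nConn <- length(connNames)
  maskedRows <- which(edges$masked)
  predict <- function(theta, condition = 1L) {
    theta <- as.numeric(theta)
    stopifnot(length(theta) == length(paramNames))
    thW <- theta[seq_len(nConn)]
    thB <- theta[nConn + seq_along(maskedRows)]
    kappa <- config$kappa0 * exp(theta[nConn + length(maskedRows) + 1L])
    muU <- config$muU * exp(theta[nConn + length(maskedRows) + 2L])
    gains <- exp(theta[nConn + length(maskedRows) + 2L +
                         seq_len(config$nChannels)])
    logw <- thW
    if (condition == 2L && length(maskedRows))
      logw[maskedRows] <- logw[maskedRows] + thB
    W <- matrix(0, config$nSources, config$nSources)
    W[cbind(edges$j, edges$k)] <- config$adjacency[cbind(edges$j, edges$k)] *
      exp(logw)
    tryCatch(
      .erpIntegrate(W, gvec, kappa, muU, config$sigmaU, mixing, gains,
                    config$nBins, binS, config$substeps),
      error = function(e) {
        stop(sprintf("diverged trajectory at theta = [%s]",
                     paste(signif(theta, 3), collapse = ", ")),
             call. = FALSE)
      })
  }

  new("ModelSpec", paramNames = paramNames, prior = prior,
      nChannels = config$nChannels, nBins = config$nBins,
      nConditions = 2L,
      noiseComponents = list(rep(1, config$nChannels)),
      predict = predict,
      info = list(config = config, mixing = mixing, edges = edges,
                  connNames = connNames, bNames = bNames,
                  gainNames = gainNames))
}

#' Linear forward model
#'
#' \code{predict(theta) = design \%*\% theta}, reshaped to a channels x bins
#' matrix (one row per output element, a single time bin per row by
#' convention). Used as the exactness oracle for the Laplace and empirical
#' Bayes machinery: for this model Bayesian model reduction and direct
#' inversion agree to numerical precision.
#'
#' @param design numeric matrix; rows are flattened data elements, columns
#'   are parameters.
#' @param prior \linkS4class{GaussianDensity} over the columns of
#'   \code{design}.
#' @return a \linkS4class{ModelSpec} with one condition.
#' @export
linearModel <- function(design, prior) {
  design <- as.matrix(design)
  stopifnot(ncol(design) == length(prior@mean))
  predict <- function(theta, condition = 1L) {
    matrix(as.numeric(design %*% as.numeric(theta)), nrow(design), 1L)
  }
  new("ModelSpec", paramNames = parameterNames(prior), prior = prior,
      nChannels = nrow(design), nBins = 1L, nConditions = 1L,
      noiseComponents = list(rep(1, nrow(design))),
      predict = predict,
      info = list(design = design, linear = TRUE))
}

#' Jacobian of a forward model by central finite differences
#'
#' @param model a \linkS4class{ModelSpec}.
#' @param theta parameter vector at which to differentiate.
#' @param condition condition index.
#' @param step base step size; the per-parameter step is
#'   \code{step * max(1, abs(theta_i))}.
#' @return a (channels * bins) x n_params matrix, columns ordered as
#'   \code{model@paramNames}; the output is flattened channel-fastest.
#' @export
modelJacobian <- function(model, theta, condition = 1L, step = 1e-4) {
  if (isTRUE(model@info$linear)) return(model@info$design)
  theta <- as.numeric(theta)
  stopifnot(all(is.finite(theta)))
  np <- length(theta)
  J <- matrix(0, model@nChannels * model@nBins, np)
  for (i in seq_len(np)) {
    h <- step * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (as.numeric(model@predict(tp, condition)) -
                 as.numeric(model@predict(tm, condition))) / (2 * h)
  }
  colnames(J) <- model@paramNames
  J
}

## stacked prediction and Jacobian over all conditions (channel-fastest,
## conditions slowest)
.predictStacked <- function(model, theta) {
  unlist(lapply(seq_len(model@nConditions),
                function(c) as.numeric(model@predict(theta, c))))
}

.jacobianStacked <- function(model, theta, step = 1e-4) {
  do.call(rbind, lapply(seq_len(model@nConditions),
                        function(c) modelJacobian(model, theta, c, step)))
}

## diagonal weight of noise component k over the flattened stacked data
.noiseWeight <- function(model, k) {
  rep(rep(model@noiseComponents[[k]], model@nBins), model@nConditions)
}
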