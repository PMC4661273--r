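# Synthetic multi-subject, two-condition evoked-response study: subject
# parameters are group means plus Gaussian random effects with variance a
# fixed fraction (default 1/16) of the prior variances; sensor noise is
# white Gaussian convolved with an 8-bin smoothing kernel and rescaled to a
# fixed fraction (default 1/8) of the signal SD.

#' Simulation configuration
#'
#' @param nSubjects number of subjects (default 16).
#' @param betweenSubjectVarianceScale between-subject variance as a fraction
#'   of the prior variances (default 1/16).
#' @param noiseSdFraction observation-noise SD as a fraction of the signal
#'   SD, matched per subject (default 1/8).
#' @param noiseSmoothingBins width of the temporal smoothing kernel applied
#'   to the noise, in time bins (default 8).
#' @param conditionEffects named vector of group-mean condition-specific
#'   log-scalings (names must be condition-effect parameters of the model);
#'   \code{NULL} selects the packaged defaults of
#'   \code{\link{defaultGroupMeans}}.
#' @param seed integer seed controlling all randomness.
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nSubjects = 16L,
                             betweenSubjectVarianceScale = 1 / 16,
                             noiseSdFraction = 1 / 8,
                             noiseSmoothingBins = 8L,
                             conditionEffects = NULL,
                             seed = 1L) {
  stopifnot(nSubjects >= 1, betweenSubjectVarianceScale >= 0,
            noiseSdFraction >= 0, noiseSmoothingBins >= 1)
  structure(list(nSubjects = as.integer(nSubjects),
                 betweenSubjectVarianceScale = betweenSubjectVarianceScale,
                 noiseSdFraction = noiseSdFraction,
                 noiseSmoothingBins = as.integer(noiseSmoothingBins),
                 conditionEffects = conditionEffects,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

#' Default generating group means for the packaged study
#'
#' Connection log-scalings are modest values around zero; condition-specific
#' effects are positive on intrinsic and forward connections (magnitudes
#' two to three times the between-subject SD) and exactly zero on backward
#' connections, whose changes the study design deliberately precludes.
#' Rate, latency and gain parameters have zero group mean.
#'
#' @param model an evoked-response network \linkS4class{ModelSpec}.
#' @param conditionEffects optional named replacement for the default
#'   condition-effect means.
#' @return named numeric vector over the model's parameters.
#' @export
defaultGroupMeans <- function(model, conditionEffects = NULL) {
  pn <- model@paramNames
  gm <- setNames(rep(0, length(pn)), pn)
  connDefaults <- c(int_1 = -0.2, int_2 = 0.1, int_3 = 0,
                    fwd_12 = 0.3, fwd_23 = 0.15,
                    bwd_21 = -0.1, bwd_32 = 0.05)
  bDefaults <- c(B_int_1 = 0.4, B_int_2 = 0.3, B_int_3 = 0.35,
                 B_fwd_12 = 0.3, B_fwd_23 = 0.25,
                 B_bwd_21 = 0, B_bwd_32 = 0)
  for (nm in intersect(names(connDefaults), pn)) gm[nm] <- connDefaults[nm]
  for (nm in intersect(names(bDefaults), pn)) gm[nm] <- bDefaults[nm]
  if (!is.null(conditionEffects)) {
    stopifnot(all(names(conditionEffects) %in% pn))
    gm[names(conditionEffects)] <- conditionEffects
  }
  gm
}

## truncated-Gaussian smoothing kernel (unit sum) applied along bins via a
## banded 'same'-mode convolution matrix
.smoothingMatrix <- function(nBins, width) {
  w <- dnorm(seq_len(width), mean = (width + 1) / 2, sd = width / 4)
  w <- w / sum(w)
  C <- matrix(0, nBins, nBins)
  off <- floor((width + 1) / 2)
  for (j in seq_len(width)) {
    s <- seq_len(nBins) + j - off
    ok <- s >= 1 & s <= nBins
    C[cbind(which(ok), s[ok])] <- C[cbind(which(ok), s[ok])] + w[j]
  }
  C
}

#' Generate a synthetic multi-subject group study
#'
#' Subject parameters are \code{groupMeans} plus Gaussian random effects
#' with variance \code{betweenSubjectVarianceScale} times the prior
#' variances; condition-effect parameters whose group mean is zero are held
#' at exactly zero across subjects (the precluded backward changes). Noise
#' is white Gaussian per channel, convolved along time with a normalized
#' truncated-Gaussian kernel, then rescaled per subject so its SD over all
#' channels, bins and conditions equals \code{noiseSdFraction} times the
#' signal SD.
#'
#' @param model a \linkS4class{ModelSpec} (two conditions).
#' @param groupMeans named generating group means (default
#'   \code{\link{defaultGroupMeans}}).
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{GroupDataset} carrying the data, the per-subject
#'   generating parameters, the group means and the configuration.
#' @export
generateGroup <- function(model, groupMeans = NULL,
                          config = simulationConfig()) {
  if (is.null(groupMeans))
    groupMeans <- defaultGroupMeans(model, config$conditionEffects)
  stopifnot(identical(names(groupMeans), model@paramNames))
  set.seed(config$seed)
  pv <- diag(model@prior@cov)
  reSD <- sqrt(pv * config$betweenSubjectVarianceScale)
  bNames <- model@info$bNames
  clamp <- names(groupMeans) %in% bNames & groupMeans == 0
  C <- .smoothingMatrix(model@nBins, config$noiseSmoothingBins)
  nC <- model@nConditions
  dataList <- vector("list", config$nSubjects)
  truth <- matrix(0, length(groupMeans), config$nSubjects,
                  dimnames = list(names(groupMeans), NULL))
  for (i in seq_len(config$nSubjects)) {
    signal <- NULL
    for (try in seq_len(5)) {
      eps <- rnorm(length(groupMeans), 0, reSD)
      eps[clamp] <- 0
      theta <- groupMeans + eps
      signal <- tryCatch(
        vapply(seq_len(nC), function(c) model@predict(theta, c),
               matrix(0, model@nChannels, model@nBins)),
        error = function(e) NULL)
      if (!is.null(signal)) break
      message(sprintf("subject %d: diverged signal, resampling (try %d)",
                      i, try))
    }
    if (is.null(signal))
      stop(sprintf("subject %d: signal diverged after 5 resampling attempts", i))
    noise <- array(rnorm(length(signal)), dim(signal))
    for (c in seq_len(nC))
      noise[, , c] <- noise[, , c] %*% t(C)
    if (config$noiseSdFraction > 0) {
      noise <- noise * (config$noiseSdFraction * sd(signal) / sd(noise))
    } else noise[] <- 0
    dataList[[i]] <- signal + noise
    truth[, i] <- theta
  }
  new("GroupDataset", data = dataList, truth = truth,
      groupMeans = groupMeans,
      config = list(simulation = unclass(config)),
      seed = config$seed)
}

#' Grand average of a group dataset
#'
#' Element-wise mean of the subject responses, per condition, returned as a
#' single-subject dataset. It carries no ground-truth parameters: for a
#' nonlinear model the parameters generating an average response are not
#' the average of the generating parameters.
#'
#' @param group a \linkS4class{GroupDataset}.
#' @return a single-subject \linkS4class{GroupDataset}.
#' @export
grandAverage <- function(group) {
  stopifnot(nSubjects(group) >= 1)
  avg <- Reduce(`+`, group@data) / length(group@data)
  new("GroupDataset", data = list(avg),
      truth = matrix(0, 0, 0), groupMeans = numeric(0),
      config = c(group@config, list(grandAverage = TRUE)),
      seed = group@seed)
}
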