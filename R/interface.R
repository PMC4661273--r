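# Configuration, serialization and the end-to-end pipeline:
# simulate -> fit-group -> search -> report. Each stage consumes the
# previous stage's serialized outputs, so stages can be re-run
# independently; a manifest records the configuration hash, seed and a
# checksummed file inventory.

#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
#' @importFrom utils write.table read.table packageVersion
NULL

densityToList <- function(d) {
  list(names = d@names, mean = d@mean, cov = d@cov)
}

listToDensity <- function(l) {
  gaussianDensity(unlist(l$mean),
                  matrix(unlist(l$cov), length(unlist(l$mean))),
                  unlist(l$names))
}

.writeJSON <- function(x, path) {
  write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
             pretty = FALSE)
}

#' Write / read a Gaussian density as JSON
#'
#' Full-precision structured-text serialization; densities round-trip to
#' within 1e-12.
#'
#' @param d a \linkS4class{GaussianDensity}.
#' @param path file path.
#' @return \code{readDensity} returns a \linkS4class{GaussianDensity}.
#' @export
writeDensity <- function(d, path) .writeJSON(densityToList(d), path)

#' @rdname writeDensity
#' @export
readDensity <- function(path) listToDensity(read_json(path))

#' Write / read a group dataset as delimited text
#'
#' One tab-separated file per subject and condition (channels x bins), a
#' truth table for synthetic data, and a JSON manifest carrying the
#' configuration, seed and checksummed file inventory.
#'
#' @param group a \linkS4class{GroupDataset}.
#' @param dir output directory (created if needed).
#' @return \code{readGroupData} returns a \linkS4class{GroupDataset};
#'   \code{writeGroupData} returns \code{dir} invisibly.
#' @export
writeGroupData <- function(group, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(nSubjects(group))) {
    for (c in seq_len(dim(group@data[[i]])[3])) {
      f <- sprintf("subject_%02d_cond%d.tsv", i, c)
      write.table(group@data[[i]][, , c], file.path(dir, f),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
      files <- c(files, f)
    }
  }
  if (ncol(group@truth) > 0) {
    write.table(data.frame(parameter = rownames(group@truth), group@truth,
                           check.names = FALSE),
                file.path(dir, "truth.tsv"), sep = "\t", row.names = FALSE)
    files <- c(files, "truth.tsv")
  }
  man <- list(nSubjects = nSubjects(group),
              dims = dim(group@data[[1]]),
              seed = group@seed,
              groupMeans = as.list(group@groupMeans),
              config = group@config,
              files = as.list(tools::md5sum(file.path(dir, files))))
  names(man$files) <- files
  .writeJSON(man, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname writeGroupData
#' @export
readGroupData <- function(dir) {
  manPath <- file.path(dir, "manifest.json")
  if (!file.exists(manPath))
    stop(sprintf("no manifest.json in '%s'", dir))
  man <- read_json(manPath)
  dims <- as.integer(unlist(man$dims))
  dat <- lapply(seq_len(man$nSubjects), function(i) {
    arr <- array(0, dims)
    for (c in seq_len(dims[3])) {
      f <- file.path(dir, sprintf("subject_%02d_cond%d.tsv", i, c))
      if (!file.exists(f)) stop(sprintf("missing data file '%s'", f))
      arr[, , c] <- as.matrix(read.table(f, sep = "\t"))
    }
    arr
  })
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath)) {
    tt <- read.table(truthPath, sep = "\t", header = TRUE,
                     check.names = FALSE)
    m <- as.matrix(tt[, -1, drop = FALSE])
    rownames(m) <- tt$parameter
    m
  } else matrix(0, 0, 0)
  gm <- unlist(man$groupMeans)
  new("GroupDataset", data = dat, truth = truth,
      groupMeans = if (is.null(gm)) numeric(0) else gm,
      config = if (is.null(man$config)) list() else man$config,
      seed = as.integer(man$seed))
}

## ---- configuration ---------------------------------------------------

.defaultConfig <- function() {
  list(schema = 1L,
       seed = 1L,
       stages = list("simulate", "fit-group", "search", "report"),
       model = list(n_channels = 8L, n_bins = 128L, bin_ms = 4),
       simulation = list(n_subjects = 16L,
                         between_subject_variance_scale = 1 / 16,
                         noise_sd_fraction = 1 / 8,
                         noise_smoothing_bins = 8L),
       group = list(max_iter = 8L),
       search = list(candidates = NULL, off_variance = 1e-4))
}

.validateConfig <- function(cfg) {
  def <- .defaultConfig()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  out <- def
  for (nm in names(cfg)) {
    if (is.list(def[[nm]]) && nm != "stages" && nm != "search") {
      sub <- cfg[[nm]]
      badSub <- setdiff(names(sub), names(def[[nm]]))
      if (length(badSub))
        stop(sprintf("unknown config field(s) in '%s': %s", nm,
                     paste(badSub, collapse = ", ")))
      out[[nm]][names(sub)] <- sub
    } else out[[nm]] <- cfg[[nm]]
  }
  if (!identical(as.integer(out$schema), 1L))
    stop("config field 'schema' must be 1")
  known <- c("simulate", "fit-group", "search", "report")
  stages <- unlist(out$stages)
  if (!all(stages %in% known))
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", ")))
  out$stages <- stages
  out
}

#' Read a pipeline configuration
#'
#' @param path YAML file; missing fields take packaged defaults, unknown
#'   fields are an error naming the field.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) .validateConfig(read_yaml(path))

## ---- pipeline --------------------------------------------------------

.pebToList <- function(peb) {
  d <- peb@design
  list(betaPosterior = densityToList(peb@betaPosterior),
       gammaPosterior = densityToList(peb@gammaPosterior),
       F2 = peb@F2,
       perSubjectDeltaF = peb@perSubjectDeltaF,
       empiricalPriors = lapply(peb@empiricalPriors, densityToList),
       design = list(X = d@X, paramNames = d@paramNames,
                     effectNames = d@effectNames, Q = d@Q,
                     betaPrior = densityToList(d@betaPrior),
                     gammaPrior = densityToList(d@gammaPrior)))
}

.listToPEB <- function(l) {
  dl <- l$design
  p <- length(unlist(dl$paramNames))
  design <- new("SecondLevelDesign",
                X = matrix(unlist(dl$X), ncol = length(unlist(dl$effectNames))),
                paramNames = unlist(dl$paramNames),
                effectNames = unlist(dl$effectNames),
                Q = lapply(dl$Q, function(q) as.numeric(unlist(q))),
                betaPrior = listToDensity(dl$betaPrior),
                gammaPrior = listToDensity(dl$gammaPrior))
  new("PEBResult", betaPosterior = listToDensity(l$betaPosterior),
      gammaPosterior = listToDensity(l$gammaPosterior),
      F2 = as.numeric(l$F2),
      empiricalPriors = lapply(l$empiricalPriors, listToDensity),
      perSubjectDeltaF = as.numeric(unlist(l$perSubjectDeltaF)),
      design = design, trajectory = as.numeric(l$F2))
}

#' Run the packaged analysis pipeline
#'
#' Executes the requested stages in order: \code{simulate} writes the
#' synthetic group study as delimited text; \code{fit-group} reads it back,
#' runs the iterative empirical-Bayes inversion and serializes the group
#' trajectory and the selected second-level estimate; \code{search} runs
#' the exhaustive model comparison over the condition-specific effects;
#' \code{report} recomputes the recovery and model-average tables from the
#' serialized results. Every stage reads only the previous stage's files,
#' so a stage run without its upstream file fails with a named error.
#'
#' @param config path to a YAML configuration, or a configuration list
#'   (defaults are used for missing fields).
#' @param outDir output directory.
#' @param seed optional seed overriding the configuration.
#' @param stages optional character vector overriding the configured
#'   stages.
#' @param verbose print per-stage progress.
#' @return invisibly, the path to the written manifest.
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL,
                        stages = NULL, verbose = FALSE) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
    else .validateConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(stages)) {
    cfg$stages <- stages
    cfg <- .validateConfig(cfg)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list()
  note <- function(...) if (verbose) message(sprintf(...))

  buildModel <- function() {
    erpNetworkModel(erpNetworkConfig(
      nChannels = as.integer(cfg$model$n_channels),
      nBins = as.integer(cfg$model$n_bins),
      binMs = cfg$model$bin_ms))
  }
  dataDir <- file.path(outDir, "data")

  for (stage in cfg$stages) {
    note("stage %s ...", stage)
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    if (stage == "simulate") {
      model <- buildModel()
      sim <- simulationConfig(
        nSubjects = as.integer(cfg$simulation$n_subjects),
        betweenSubjectVarianceScale =
          cfg$simulation$between_subject_variance_scale,
        noiseSdFraction = cfg$simulation$noise_sd_fraction,
        noiseSmoothingBins = as.integer(cfg$simulation$noise_smoothing_bins),
        seed = cfg$seed)
      group <- generateGroup(model, config = sim)
      writeGroupData(group, dataDir)
    } else if (stage == "fit-group") {
      if (!dir.exists(dataDir) ||
          !file.exists(file.path(dataDir, "manifest.json")))
        stop("stage 'fit-group': no simulated data found; run 'simulate' first")
      group <- readGroupData(dataDir)
      model <- buildModel()
      res <- fitGroup(group, model, verbose = verbose)
      sel <- res@iterations[[res@selectedIteration]]
      out <- list(
        selectedIteration = res@selectedIteration,
        paramNames = model@paramNames,
        iterations = lapply(res@iterations, function(it) list(
          F2 = it$F2, meanLogdetPostCov = it$meanLogdetPostCov,
          posteriorMeans = vapply(it$fits, function(f) f@posterior@mean,
                                  numeric(length(model@paramNames))),
          posteriorVars = vapply(it$fits, function(f) diag(f@posterior@cov),
                                 numeric(length(model@paramNames))))))
      .writeJSON(out, file.path(outDir, "group_fit.json"))
      .writeJSON(.pebToList(sel$peb), file.path(outDir, "peb.json"))
    } else if (stage == "search") {
      pebPath <- file.path(outDir, "peb.json")
      if (!file.exists(pebPath))
        stop("stage 'search': no peb.json found; run 'fit-group' first")
      peb <- .listToPEB(read_json(pebPath))
      cand <- unlist(cfg$search$candidates)
      if (is.null(cand))
        cand <- grep("^mean:B_", parameterNames(peb@betaPosterior),
                     value = TRUE)
      space <- exhaustiveSearch(peb, cand,
                                offVariance = cfg$search$off_variance)
      .writeJSON(list(candidates = space@candidates,
                      deltaF = space@deltaF,
                      modelPosterior = space@modelPosterior,
                      inclusionProb = as.list(space@inclusionProb),
                      bma = densityToList(space@bma)),
                 file.path(outDir, "model_space.json"))
      write.table(searchReport(space, peb@betaPosterior),
                  file.path(outDir, "bma_report.tsv"),
                  sep = "\t", row.names = FALSE)
    } else if (stage == "report") {
      gfPath <- file.path(outDir, "group_fit.json")
      if (!file.exists(gfPath))
        stop("stage 'report': no group_fit.json found; run 'fit-group' first")
      gf <- read_json(gfPath)
      truthPath <- file.path(dataDir, "truth.tsv")
      pn <- unlist(gf$paramNames)
      rows <- lapply(seq_along(gf$iterations), function(i) {
        it <- gf$iterations[[i]]
        pm <- matrix(unlist(it$posteriorMeans), length(pn))
        pv <- matrix(unlist(it$posteriorVars), length(pn))
        bRows <- grep("^B_", pn)
        r <- data.frame(iteration = i, F2 = as.numeric(it$F2),
                        meanLogdetPostCov = as.numeric(it$meanLogdetPostCov),
                        postVarEffects = mean(pv[bRows, ]))
        if (file.exists(truthPath)) {
          tt <- read.table(truthPath, sep = "\t", header = TRUE,
                           check.names = FALSE)
          truth <- as.matrix(tt[match(pn, tt$parameter), -1, drop = FALSE])
          r$corAll <- cor(as.vector(pm), as.vector(truth))
          r$corEffects <- cor(as.vector(pm[bRows, ]),
                              as.vector(truth[bRows, ]))
        }
        r
      })
      write.table(do.call(rbind, rows),
                  file.path(outDir, "recovery_report.tsv"),
                  sep = "\t", row.names = FALSE)
    }
    stamp[[stage]] <- list(start = t0,
                           end = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  cfgFile <- file.path(outDir, "config_resolved.json")
  .writeJSON(cfg, cfgFile)
  inv <- setdiff(list.files(outDir, recursive = TRUE), "manifest.json")
  man <- list(configHash = unname(tools::md5sum(cfgFile)),
              seed = cfg$seed,
              packageVersion = as.character(packageVersion("pebgroup")),
              stages = stamp,
              files = as.list(tools::md5sum(file.path(outDir, inv))))
  names(man$files) <- inv
  .writeJSON(man, file.path(outDir, "manifest.json"))
  invisible(file.path(outDir, "manifest.json"))
}
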