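## End-to-end study replica: generate synthetic sessions, persist them in
## the canonical format, then run the occupancy/context, decoding,
## proxemics and walk-model stages, writing CSV/JSON artifacts per stage
## and a consolidated JSON report with provenance. Stage failures are
## recorded per stage; independent later stages still run.

#' Build a study configuration
#'
#' Assembles and validates the nested specifications driving
#' \code{\link{runStudy}}. The defaults are the package's demo scale:
#' 5 quadruple and 4 triplet sessions (one removal of each individual) of
#' 10 minutes at 15 Hz, rather than the study's 19 + 10 sessions of 3 h.
#'
#' @param setup list with geometry/footprints/social/roster, as returned by
#'   \code{\link{defaultStudySetup}}.
#' @param nQuadruple number of full-roster sessions.
#' @param tripletPlan named integer vector of removals (default one triplet
#'   per roster member).
#' @param durationS session length in seconds.
#' @param rateHz sampling rate.
#' @param missingRate occlusion rate.
#' @param seed master seed; per-session and per-stage seeds derive from it.
#' @param outDir output directory.
#' @param decoding list of decoding options (nFolds, nShuffles,
#'   maxPerClass).
#' @param walk list of walk-fit options (nSamples, values).
#' @return A validated config list of class \code{"studyConfig"}.
#' @export
studyConfig <- function(setup = defaultStudySetup(), nQuadruple = 5L,
                        tripletPlan = NULL, durationS = 600, rateHz = 15,
                        missingRate = 0.05, seed = 1L,
                        outDir = tempfile("sociospace_study_"),
                        decoding = list(nFolds = 10L, nShuffles = 50L,
                                        maxPerClass = 5000L),
                        walk = list(nSamples = 10000L,
                                    values = seq(0.10, 0.90, by = 0.05))) {
  if (is.null(setup$footprints) || length(setup$footprints) == 0L)
    stop("invalid config: no footprints", call. = FALSE)
  if (!is(setup$geometry, "CageGeometry") || !is(setup$social, "SocialSpec"))
    stop("invalid config: geometry/social specification missing",
         call. = FALSE)
  roster <- vapply(setup$footprints, function(f) f@individualId,
                   character(1))
  if (is.null(tripletPlan))
    tripletPlan <- stats::setNames(rep(1L, length(roster)), roster)
  cfg <- list(geometry = setup$geometry, footprints = setup$footprints,
              social = setup$social, roster = roster,
              nQuadruple = as.integer(nQuadruple),
              tripletPlan = tripletPlan, durationS = durationS,
              rateHz = rateHz, missingRate = missingRate,
              seed = as.integer(seed), outDir = outDir,
              decoding = decoding, walk = walk)
  class(cfg) <- "studyConfig"
  cfg
}

runStage <- function(report, name, fun) {
  res <- tryCatch(list(status = "ok", value = fun()),
                  error = function(e)
                    list(status = "error", value = conditionMessage(e)))
  if (res$status == "error")
    warning("stage '", name, "' failed: ", res$value, call. = FALSE)
  report$stages[[name]] <- res$status
  if (res$status == "ok") report$values[[name]] <- res$value
  else report$errors[[name]] <- res$value
  report
}

#' Run the full study replica
#'
#' Executes generate, catalog/validate, context, decode, proxemics and
#' walk-fit stages on synthetic sessions, writing per-stage CSV/JSON files
#' under \code{config$outDir} and returning a consolidated report. Fully
#' reproducible from (config, seed).
#'
#' @param config a \code{"studyConfig"} from \code{\link{studyConfig}}.
#' @return Invisibly, a report list: \code{stages} (status per stage),
#'   \code{files} (artifact paths), \code{summary} (decoding matrix, D
#'   table with tests, affiliation metrics, fitted pStay per pair) and
#'   \code{provenance} (seed, config hash, package version). The report is
#'   also written to \code{outDir/report.json}.
#' @export
runStudy <- function(config) {
  if (!inherits(config, "studyConfig"))
    stop("config must come from studyConfig()", call. = FALSE)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  report <- list(stages = list(), values = list(), errors = list())

  # --- generate -----------------------------------------------------------
  report <- runStage(report, "generate", function() {
    generateStudy(config$geometry, config$footprints, config$social,
                  config$nQuadruple, config$tripletPlan,
                  baseSeed = config$seed, durationS = config$durationS,
                  rateHz = config$rateHz, missingRate = config$missingRate)
  })
  sessions <- report$values$generate
  if (is.null(sessions))
    stop("generation failed; aborting: ", report$errors$generate,
         call. = FALSE)

  # --- persist + validate -------------------------------------------------
  report <- runStage(report, "validate", function() {
    sesDir <- file.path(config$outDir, "sessions")
    dir.create(sesDir, showWarnings = FALSE)
    files <- vapply(sessions, function(s) {
      f <- file.path(sesDir, paste0(sessionId(s), ".csv"))
      writeSession(s, f)
      f
    }, character(1))
    # round-trip the first session through the parser as a format check
    invisible(readSession(files[[1L]], geometry = config$geometry))
    cat <- sessionCatalog(sessions, fullRoster = config$roster,
                          paths = files)
    writeSessionCatalog(cat, file.path(config$outDir, "catalog.json"))
    cat
  })
  catalog <- report$values$validate
  quads <- sessions[vapply(sessions, function(s)
    setequal(roster(s), config$roster), logical(1))]
  trips <- sessions[!vapply(sessions, function(s)
    setequal(roster(s), config$roster), logical(1))]

  # --- context ------------------------------------------------------------
  report <- runStage(report, "context", function() {
    dtab <- contextChangeTable(sessions, fullRoster = config$roster)
    utils::write.csv(dtab, file.path(config$outDir, "context_D.csv"),
                     row.names = FALSE)
    tests <- NULL
    for (ind in config$roster) {
      base <- dtab$D[dtab$individual == ind & dtab$condition == "4in-vs-4in"]
      for (cond in setdiff(unique(dtab$condition[dtab$individual == ind]),
                           "4in-vs-4in")) {
        cd <- dtab$D[dtab$individual == ind & dtab$condition == cond]
        pt <- permutationContextTest(base, cd, seed = config$seed + 17L)
        tests <- rbind(tests, data.frame(
          individual = ind, condition = cond, mean_p = pt@meanP,
          mean_t = mean(pt@tValues), n_baseline = length(base),
          n_condition = length(cd), stringsAsFactors = FALSE))
      }
    }
    jsonlite::write_json(tests, file.path(config$outDir,
                                          "context_tests.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    med <- medianPositions(sessions, individuals = config$roster)
    utils::write.csv(med$medians,
                     file.path(config$outDir, "median_positions.csv"),
                     row.names = FALSE)
    list(D = dtab, tests = tests, medians = med)
  })

  # --- decode -------------------------------------------------------------
  report <- runStage(report, "decode", function() {
    dec <- config$decoding
    within <- decodingMatrix(quads[[1L]], nFolds = dec$nFolds,
                             nShuffles = 0L,
                             maxPerClass = dec$maxPerClass,
                             seed = config$seed + 101L)
    prs <- utils::combn(config$roster, 2L)
    cross <- list(); crossCtx <- list()
    for (c in seq_len(ncol(prs))) {
      pair <- prs[, c]
      if (length(quads) > 1L)
        cross[[paste(pair, collapse = "-")]] <- crossSessionDecode(
          quads[[1L]], quads[-1L], pair, nShuffles = dec$nShuffles,
          maxPerClass = dec$maxPerClass, seed = config$seed + 211L + c)
      if (length(trips))
        crossCtx[[paste(pair, collapse = "-")]] <- suppressWarnings(
          crossContextDecode(quads[[1L]], trips, pair,
                             nShuffles = dec$nShuffles,
                             maxPerClass = dec$maxPerClass,
                             seed = config$seed + 307L + c))
    }
    utils::write.csv(as.data.frame(within$matrix),
                     file.path(config$outDir, "decoding_matrix.csv"))
    acc <- function(lst) vapply(lst, meanAccuracy, numeric(1))
    jsonlite::write_json(
      list(within_cv = acc(within$results),
           cross_session = if (length(cross)) acc(cross) else NULL,
           cross_context = if (length(crossCtx)) acc(crossCtx) else NULL,
           cross_session_p = if (length(cross))
             vapply(cross, pValue, numeric(1)) else NULL),
      file.path(config$outDir, "decoding.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    list(within = within, cross = cross, crossContext = crossCtx)
  })

  # --- proxemics ----------------------------------------------------------
  report <- runStage(report, "proxemics", function() {
    mdm <- meanDistanceMatrix(quads, rankOrder = config$roster)
    utils::write.csv(as.data.frame(mdm$matrix),
                     file.path(config$outDir, "mean_distance_matrix.csv"))
    prs <- utils::combn(config$roster, 2L)
    pooled <- list()
    for (c in seq_len(ncol(prs))) {
      pair <- prs[, c]
      pooled[[paste(pair, collapse = "-")]] <- unlist(lapply(quads,
        function(s) distances(distanceSeries(s, pair[1L], pair[2L]))))
    }
    avgDens <- distanceDistribution(unlist(pooled))
    thr <- findAffiliationThresholds(avgDens)
    closeCm <- if (is.na(thr$closeCm)) presetThresholds()$closeCm else
      thr$closeCm
    farCm <- if (is.na(thr$farCm)) presetThresholds()$farCm else thr$farCm
    jsonlite::write_json(list(close_cm = closeCm, far_cm = farCm,
                              modes_cm = thr$modesCm,
                              unimodal = thr$unimodal),
                         file.path(config$outDir, "thresholds.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    aff <- do.call(rbind, lapply(quads, function(s) {
      do.call(rbind, lapply(config$roster, function(ind) data.frame(
        session_id = sessionId(s), individual = ind,
        strength_s = affiliativeStrength(s, ind, closeCm),
        weakness_s = affiliativeWeakness(s, ind, farCm),
        stringsAsFactors = FALSE)))
    }))
    utils::write.csv(aff, file.path(config$outDir, "affiliation.csv"),
                     row.names = FALSE)
    chunks <- lapply(seq_len(ncol(prs)), function(c) {
      pair <- prs[, c]
      durs <- unlist(lapply(quads, function(s)
        chunkDurations(proximityChunks(distanceSeries(s, pair[1L],
                                                      pair[2L])))))
      new("ChunkSet", pair = pair, durationsS = durs, thresholdCm = 50,
          rateHz = config$rateHz)
    })
    names(chunks) <- apply(prs, 2L, paste, collapse = "-")
    chunkDf <- do.call(rbind, lapply(names(chunks), function(nm)
      if (length(chunkDurations(chunks[[nm]])))
        data.frame(pair = nm, duration_s = chunkDurations(chunks[[nm]]),
                   stringsAsFactors = FALSE) else NULL))
    if (!is.null(chunkDf))
      utils::write.csv(chunkDf, file.path(config$outDir, "chunks.csv"),
                       row.names = FALSE)
    ksRep <- tryCatch(suppressWarnings(chunkHistogramsCompare(chunks)),
                      error = function(e) NULL)
    if (!is.null(ksRep) && !is.null(ksRep$ks))
      jsonlite::write_json(ksRep$ks,
                           file.path(config$outDir, "chunk_ks.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
    list(meanDistance = mdm, thresholds = thr, closeCm = closeCm,
         farCm = farCm, affiliation = aff, chunks = chunks,
         pooledDistances = pooled)
  })

  # --- walk fit -----------------------------------------------------------
  report <- runStage(report, "walk", function() {
    pooled <- report$values$proxemics$pooledDistances
    if (is.null(pooled))
      stop("proxemics stage did not produce pooled distances")
    cfg <- walkConfig(nSamples = config$walk$nSamples,
                      seed = config$seed + 977L)
    rescale <- cfg@gridX / config$geometry@lengthCm
    fits <- lapply(pooled, function(d)
      fitPStay(d, cfg, values = config$walk$values, rescale = rescale))
    fitted <- vapply(fits, function(f) f$best, numeric(1))
    jsonlite::write_json(
      list(fitted_p_stay = as.list(fitted),
           correlations = lapply(fits, function(f) f$correlations)),
      file.path(config$outDir, "walk_fit.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    list(fits = fits, fitted = fitted)
  })

  # --- consolidated report ------------------------------------------------
  cfgPath <- file.path(config$outDir, "config.json")
  jsonlite::write_json(
    list(roster = config$roster, n_quadruple = config$nQuadruple,
         triplet_plan = as.list(config$tripletPlan),
         duration_s = config$durationS, rate_hz = config$rateHz,
         missing_rate = config$missingRate, seed = config$seed),
    cfgPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- list.files(config$outDir, recursive = TRUE, full.names = TRUE)
  provenance <- list(seed = config$seed,
                     config_hash = unname(tools::md5sum(cfgPath)),
                     package_version =
                       as.character(utils::packageVersion("SocioSpace")))
  summary <- list(
    decoding_matrix = if (!is.null(report$values$decode))
      report$values$decode$within$matrix else NULL,
    context_tests = if (!is.null(report$values$context))
      report$values$context$tests else NULL,
    thresholds = if (!is.null(report$values$proxemics))
      list(close_cm = report$values$proxemics$closeCm,
           far_cm = report$values$proxemics$farCm) else NULL,
    fitted_p_stay = if (!is.null(report$values$walk))
      report$values$walk$fitted else NULL)
  out <- list(stages = report$stages, errors = report$errors,
              files = files, summary = summary, provenance = provenance,
              values = report$values)
  jsonlite::write_json(
    list(stages = report$stages, errors = report$errors,
         files = files, provenance = provenance),
    file.path(config$outDir, "report.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(out)
}
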