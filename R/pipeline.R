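## Config-driven orchestration of the full analysis: thin -> bias ->
## background -> screen -> fit/evaluate -> project -> threshold -> change
## accounting -> migration vectors -> limiting factors, with a JSON run
## manifest.

pipelineDefaults <- function() list(
  stackDirs = NULL,          # named list: period -> directory of grids
  occurrencePath = NULL,
  trainingPeriod = "present",
  minDistKm = 10,
  biasRadiusKm = 60,
  corrThreshold = 0.85,
  priority = character(),
  beta = 1,
  replicates = 10,
  trainFraction = 0.75,
  backgroundN = 10000,
  thresholdRule = "mtss",    # "mtss" or "10tp"
  blockKm = 60,
  seed = 1,
  outDir = NULL,
  doJackknife = TRUE,
  nHingeKnots = 16,
  verbose = TRUE)

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and out-of-range values. The
#' configuration may be an R list or the path of a flat `key = value`
#' text file (periods are given as `stack.<period> = <dir>` lines, kept
#' in file order; `priority` is a comma-separated list).
#'
#' @param config named list or path to a flat key-value file.
#' @return the completed configuration list (class `RunConfig`).
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1) config <- readConfigFile(config)
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$stackDirs) || is.null(names(cfg$stackDirs)))
    stop("config error: stackDirs must be a named list of period directories")
  if (is.null(cfg$occurrencePath))
    stop("config error: occurrencePath is required")
  if (is.null(cfg$outDir)) stop("config error: outDir is required")
  if (!cfg$trainingPeriod %in% names(cfg$stackDirs))
    stop("config error: trainingPeriod '", cfg$trainingPeriod,
         "' has no stack")
  num <- c("minDistKm", "biasRadiusKm", "beta", "replicates",
           "backgroundN", "blockKm", "nHingeKnots")
  for (k in num) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    stop("config error: ", k, " must be positive")
  if (cfg$trainFraction <= 0 || cfg$trainFraction >= 1)
    stop("config error: trainFraction must lie strictly in (0, 1)")
  if (cfg$corrThreshold <= 0 || cfg$corrThreshold > 1)
    stop("config error: corrThreshold must lie in (0, 1]")
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("config error: seed must be a non-negative integer")
  if (!cfg$thresholdRule %in% c("mtss", "10tp"))
    stop("config error: thresholdRule must be 'mtss' or '10tp'")
  structure(cfg, class = "RunConfig")
}

#' @rdname validateConfig
#' @param path flat key-value config file.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(stackDirs = list())
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("config error: unparseable line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (startsWith(key, "stack.")) {
      cfg$stackDirs[[sub("^stack\\.", "", key)]] <- val
    } else if (key == "priority") {
      cfg[[key]] <- trimws(strsplit(val, ",")[[1]])
    } else {
      numval <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(numval)) numval
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
    }
  }
  if (!length(cfg$stackDirs)) cfg$stackDirs <- NULL
  cfg
}

#' Run the full range-dynamics pipeline
#'
#' Executes every stage in order, writes all artefacts under
#' `config$outDir`, and returns (and writes) a run manifest recording the
#' configuration, per-file MD5 hashes, the evaluation summary, the
#' thresholds and the change tables. Fully deterministic given the seed:
#' each stage draws from its own stream derived from the master seed, so
#' e.g. changing the replicate count cannot perturb the background draw.
#' On a stage failure the manifest (with the failed stage recorded) is
#' still written before the error propagates.
#'
#' @param config a list or file accepted by [validateConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  out <- cfg$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "verbose")],
                   version = as.character(utils::packageVersion("RangeDynamics")),
                   stages = character(0), files = list(),
                   warnings = character(0))
  t0 <- Sys.time()
  note <- function(stage, what = "") {
    if (isTRUE(cfg$verbose))
      message(sprintf("[%s] %s (%.1fs elapsed)", stage, what,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  addFile <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }
  stage <- "init"
  res <- withCallingHandlers(
    tryCatch({
      ## ---- load ----
      stage <- "load"
      stacks <- lapply(names(cfg$stackDirs), function(p)
        readStackDir(cfg$stackDirs[[p]], p))
      names(stacks) <- names(cfg$stackDirs)
      occ <- readOccurrences(cfg$occurrencePath)
      training <- stacks[[cfg$trainingPeriod]]
      note(stage, sprintf("%d periods, %d occurrences", length(stacks),
                          nrow(occ@points)))

      ## ---- thin ----
      stage <- "thin"
      thinned <- thinOccurrences(occ, cfg$minDistKm)
      writeOccurrences(thinned, file.path(out, "occurrences_thinned.csv"))
      addFile(file.path(out, "occurrences_thinned.csv"))
      manifest$nOccurrences <- nrow(occ@points)
      manifest$nThinned <- nrow(thinned@points)
      note(stage, sprintf("%d -> %d localities", nrow(occ@points),
                          nrow(thinned@points)))

      ## ---- bias ----
      stage <- "bias"
      bias <- biasSurface(thinned, training@layers[[1]], cfg$biasRadiusKm)
      writeGrid(bias, file.path(out, "bias.asc"))
      addFile(file.path(out, "bias.asc"))
      note(stage, "kernel density surface")

      ## ---- background ----
      stage <- "background"
      bg <- sampleBackground(bias, cfg$backgroundN,
                             stageSeed(cfg$seed, "background"))
      utils::write.csv(bg@points, file.path(out, "background.csv"),
                       row.names = FALSE, quote = FALSE)
      addFile(file.path(out, "background.csv"))
      note(stage, sprintf("%d cells", cfg$backgroundN))

      ## ---- screen ----
      stage <- "screen"
      corr <- correlationMatrix(training)
      utils::write.csv(data.frame(variable = corr$variables,
                                  round(corr$r, 6)),
                       file.path(out, "correlation.csv"),
                       row.names = FALSE, quote = FALSE)
      addFile(file.path(out, "correlation.csv"))
      kept <- pruneCorrelated(corr, cfg$corrThreshold, cfg$priority)
      writeLines(kept, file.path(out, "kept_variables.txt"))
      addFile(file.path(out, "kept_variables.txt"))
      manifest$keptVariables <- kept
      pv <- extractValues(training, thinned, kept)
      bv <- extractValues(training, bg, kept)
      if (isTRUE(cfg$doJackknife)) {
        jk <- jackknifeContribution(pv, bv, beta = cfg$beta,
                                    nHingeKnots = cfg$nHingeKnots)
        jkdf <- jk$perVariable
        jkdf$gainAll <- jk$gainAll
        jkdf$aucAll <- jk$aucAll
        utils::write.csv(format(jkdf, digits = 8),
                         file.path(out, "jackknife.csv"),
                         row.names = FALSE, quote = FALSE)
        addFile(file.path(out, "jackknife.csv"))
      }
      note(stage, paste("kept:", paste(kept, collapse = ", ")))

      ## ---- fit / evaluate ----
      stage <- "fit"
      trainingKept <- buildStack(training@layers[kept], cfg$trainingPeriod)
      eval <- replicateRuns(thinned, bg, trainingKept, k = cfg$replicates,
                            trainFraction = cfg$trainFraction,
                            beta = cfg$beta, seed = cfg$seed,
                            nHingeKnots = cfg$nHingeKnots)
      utils::write.csv(format(eval$replicates, digits = 8),
                       file.path(out, "eval_report.csv"),
                       row.names = FALSE, quote = FALSE)
      addFile(file.path(out, "eval_report.csv"))
      writeLambdas(eval$model, file.path(out, "model_lambdas.json"))
      addFile(file.path(out, "model_lambdas.json"))
      manifest$meanTrainAUC <- eval$meanTrainAUC
      manifest$meanTestAUC <- eval$meanTestAUC
      note(stage, sprintf("mean AUC train %.4f / test %.4f",
                          eval$meanTrainAUC, eval$meanTestAUC))

      ## ---- thresholds ----
      stage <- "threshold"
      sp <- predictScores(eval$model, extractValues(trainingKept, thinned))
      sb <- predictScores(eval$model, extractValues(trainingKept, bg))
      thr <- c(mtss = mtssThreshold(sp, sb),
               `10tp` = tenPercentTPThreshold(sp))
      utils::write.csv(data.frame(rule = names(thr), threshold = thr),
                       file.path(out, "thresholds.csv"),
                       row.names = FALSE, quote = FALSE)
      addFile(file.path(out, "thresholds.csv"))
      manifest$thresholds <- as.list(thr)
      tUse <- thr[[cfg$thresholdRule]]
      note(stage, sprintf("mtss %.4f, 10tp %.4f", thr[["mtss"]],
                          thr[["10tp"]]))

      ## ---- project + binarise ----
      stage <- "project"
      preds <- list(); bmaps <- list(); areas <- list()
      for (p in names(stacks)) {
        stk <- buildStack(stacks[[p]]@layers[kept], p)
        pred <- predictLogistic(eval$model, stk, clamp = TRUE)
        writeGrid(pred, file.path(out, paste0("prediction_", p, ".asc")))
        addFile(file.path(out, paste0("prediction_", p, ".asc")))
        preds[[p]] <- pred
        bmaps[[p]] <- binarize(pred, tUse, p)
        areas[[p]] <- data.frame(
          period = p,
          mtss = areaOf(binarize(pred, thr[["mtss"]], p)@suitable,
                        cellAreaKm2(pred)),
          tenTP = areaOf(binarize(pred, thr[["10tp"]], p)@suitable,
                         cellAreaKm2(pred)))
      }
      areas <- do.call(rbind, areas)
      utils::write.csv(areas, file.path(out, "areas.csv"),
                       row.names = FALSE, quote = FALSE)
      addFile(file.path(out, "areas.csv"))
      manifest$areas <- areas
      note(stage, sprintf("%d periods projected", length(preds)))

      ## ---- dynamics ----
      stage <- "dynamics"
      periods <- names(stacks)
      pairs <- if (length(periods) > 1)
        Map(c, periods[-length(periods)], periods[-1]) else list()
      changeTables <- list(); cmaps <- list()
      cvecs <- list(); blocks <- list()
      for (p in periods) blocks[[p]] <- blockCentroids(bmaps[[p]],
                                                       cfg$blockKm)
      for (pr in pairs) {
        lbl <- paste0(pr[1], "->", pr[2])
        slug <- paste0(pr[1], "_", pr[2])
        cm <- changeMap(bmaps[[pr[1]]], bmaps[[pr[2]]])
        cmaps[[lbl]] <- cm
        cls <- cm@classes
        cls[is.na(cls)] <- -9999L
        writeGrid(newGrid(cls, xll = cm@xll, yll = cm@yll,
                          cellSize = cm@cellSize, mask = cm@mask),
                  file.path(out, paste0("change_", slug, ".asc")))
        addFile(file.path(out, paste0("change_", slug, ".asc")))
        ct <- changeTable(cm)
        utils::write.csv(ct, file.path(out,
                                       paste0("change_table_", slug, ".csv")),
                         row.names = FALSE, quote = FALSE)
        addFile(file.path(out, paste0("change_table_", slug, ".csv")))
        changeTables[[lbl]] <- ct
        if (any(bmaps[[pr[1]]]@suitable) && any(bmaps[[pr[2]]]@suitable)) {
          cvecs[[lbl]] <- cbind(pair = lbl,
                                centroidVector(bmaps[[pr[1]]],
                                               bmaps[[pr[2]]]))
          mv <- migrationVectors(blocks[[pr[1]]], blocks[[pr[2]]], lbl)
          utils::write.csv(format(mv, digits = 10),
                           file.path(out, paste0("migration_vectors_",
                                                 slug, ".csv")),
                           row.names = FALSE, quote = FALSE)
          addFile(file.path(out, paste0("migration_vectors_", slug,
                                        ".csv")))
        } else {
          warning("transition ", lbl,
                  " has an empty range; centroid/migration vectors skipped")
        }
      }
      if (length(cvecs)) {
        cvdf <- do.call(rbind, cvecs)
        utils::write.csv(format(cvdf, digits = 10),
                         file.path(out, "centroid_vectors.csv"),
                         row.names = FALSE, quote = FALSE)
        addFile(file.path(out, "centroid_vectors.csv"))
      }
      manifest$changeTables <- changeTables
      note(stage, sprintf("%d transitions", length(pairs)))

      ## ---- limiting factors ----
      stage <- "limits"
      presenceMeans <- colMeans(pv, na.rm = TRUE)
      shares <- list()
      for (pr in pairs) {
        lbl <- paste0(pr[1], "->", pr[2])
        slug <- paste0(pr[1], "_", pr[2])
        stkLate <- buildStack(stacks[[pr[2]]]@layers[kept], pr[2])
        lf <- limitingFactorMap(eval$model, stkLate, presenceMeans)
        codes <- lf@factorIndex
        codes[is.na(codes) & !lf@mask] <- 0L
        codes[lf@mask] <- -9999L
        writeGrid(newGrid(codes, xll = lf@xll, yll = lf@yll,
                          cellSize = lf@cellSize, mask = lf@mask),
                  file.path(out, paste0("limiting_", slug, ".asc")))
        addFile(file.path(out, paste0("limiting_", slug, ".asc")))
        rows <- lapply(c("contraction", "expansion"), function(cl) {
          fs <- factorShares(lf, cmaps[[lbl]], cl)
          if (!nrow(fs$shares)) return(NULL)
          cbind(pair = lbl, class = cl, fs$shares,
                nonePct = fs$nonePct, nCells = fs$nCells)
        })
        rows <- do.call(rbind, rows)
        utils::write.csv(rows,
                         file.path(out, paste0("factor_shares_", slug,
                                               ".csv")),
                         row.names = FALSE, quote = FALSE)
        addFile(file.path(out, paste0("factor_shares_", slug, ".csv")))
        shares[[lbl]] <- rows
      }
      legend <- data.frame(code = c(0, seq_along(kept)),
                           variable = c("(none)", kept))
      utils::write.csv(legend, file.path(out, "limiting_legend.csv"),
                       row.names = FALSE, quote = FALSE)
      addFile(file.path(out, "limiting_legend.csv"))
      manifest$factorShares <- shares
      note(stage, "attribution complete")
      TRUE
    }, error = function(e) {
      manifest$failedStage <<- stage
      manifest$error <<- conditionMessage(e)
      FALSE
    }),
    warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  if (!res)
    stop("pipeline failed at stage '", manifest$failedStage, "': ",
         manifest$error)
  invisible(manifest)
}
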