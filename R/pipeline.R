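#' Default pipeline configuration
#'
#' Defaults reproduce the study design: 54 sites x 4 treatments (216
#' samples), warming +4.5 degC over the 25 degC control, N deposition
#' equivalent to 25 kg N ha-1 yr-1, 50\% water holding capacity, 4
#' drying-wetting cycles of 2-day wetting + 5-day natural drying, a 1-month
#' incubation; 999 permutations, 500 trees, alpha 0.05, log10 transform
#' before Hellinger/RDA, mean-mode group resistance. The treatment block is
#' carried as annotation only -- the simulated disturbances are effect models,
#' not incubation physics.
#'
#' @return nested named list (YAML-serializable)
#' @export
defaultPipelineConfig <- function() {
  list(
    simulate = list(n_sites = 54L),
    input = list(sites = NULL, abundance = NULL, curves = NULL),
    treatments = list(control_temp_c = 25, warming_delta_c = 4.5,
                      n_dose_kg_ha_yr = 25, whc_percent = 50,
                      dw_cycles = 4L, dw_wet_days = 2L, dw_dry_days = 5L,
                      incubation = "1 month"),
    analysis = list(n_perm = 999L, n_trees = 500L, importance_n_perm = 99L,
                    alpha = 0.05, log10_transform = TRUE,
                    group_resistance_mode = "mean",
                    efficiency_correction = "none"),
    seed = 1L)
}

# Recursive key check against the default schema; unknown keys are rejected.
mergeConfig <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  stopIfNot(is.list(user), paste0("config section '", path, "' must be a map"))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s)", if (nzchar(path)) paste0(" in '", path, "'"),
         ": ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- defaults
  for (k in names(user)) {
    if (is.null(user[[k]]))            # explicit null disables the section
      out[k] <- list(NULL)
    else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      out[[k]] <- mergeConfig(user[[k]], defaults[[k]],
                              if (nzchar(path)) paste(path, k, sep = ".") else k)
    else out[[k]] <- user[[k]]
  }
  out
}

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' @param path config file; keys not in [defaultPipelineConfig()] are
#'   rejected
#' @return validated config list merged over the defaults
#' @export
readPipelineConfig <- function(path) {
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  mergeConfig(user, defaultPipelineConfig())
}

#' Build a StoichExperiment from external site and abundance tables
#'
#' @param sites site table (see [readSiteTable()])
#' @param abundance long-format abundance data.frame (see
#'   [readAbundanceTable()])
#' @param panel gene panel; defaults to [defaultGenePanel()] restricted to the
#'   genes present
#' @return a [StoichExperiment-class]
#' @export
makeStoichExperiment <- function(sites, abundance, panel = NULL) {
  genes <- unique(abundance$gene)
  if (is.null(panel)) {
    panel <- defaultGenePanel()
    unknown <- setdiff(genes, panel$gene)
    if (length(unknown))
      stop("gene(s) not in the default panel (supply `panel`): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    panel <- panel[match(genes, panel$gene), , drop = FALSE]
  }
  treatments <- intersect(.TREATMENTS, unique(abundance$treatment))
  mats <- lapply(treatments, function(tr) {
    m <- longToMatrix(abundance, tr)
    m[panel$gene, sites$site_id, drop = FALSE]
  })
  assayMat <- do.call(cbind, mats)
  treatVec <- rep(treatments, each = nrow(sites))
  colnames(assayMat) <- paste(rep(sites$site_id, times = length(treatments)),
                              treatVec, sep = ".")
  cd <- S4Vectors::DataFrame(
    site_id = rep(sites$site_id, times = length(treatments)),
    treatment = treatVec,
    sites[rep(seq_len(nrow(sites)), times = length(treatments)),
          intersect(c("province", .SITE_PREDICTORS), colnames(sites))],
    row.names = colnames(assayMat))
  se <- SummarizedExperiment(assays = SimpleList(copies = assayMat),
                             colData = cd,
                             rowData = S4Vectors::DataFrame(panel,
                                                            row.names = panel$gene))
  new("StoichExperiment", se)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or external tables),
#' optional qPCR efficiency correction, per-gene resistance for the three
#' stressors, group normalization and group resistance, variance partitioning
#' per group, random-forest predictor importance per group x stressor, and
#' path analysis per group x stressor. Each stage writes a TSV under
#' \code{outDir} and the run is summarized in a machine-readable JSON report.
#' Identical config + seed give identical outputs; all randomness flows from
#' the single seed through named substreams.
#'
#' @param config config list (see [defaultPipelineConfig()])
#' @param outDir output directory (created if needed)
#' @param seed overrides \code{config$seed} when non-NULL
#' @return the run report (list), invisibly; written as \code{report.json}
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = tempfile(),
                        seed = NULL) {
  config <- mergeConfig(config, defaultPipelineConfig())
  if (!is.null(seed)) config$seed <- seed
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, seed = config$seed, outputs = list(),
                 warnings = character(), started = format(Sys.time()))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(outDir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(name) file.path(outDir, name)
  an <- config$analysis

  # stage 1: data
  x <- stage("data", {
    if (!is.null(config$input$sites) && !is.null(config$input$abundance)) {
      makeStoichExperiment(readSiteTable(config$input$sites),
                           readAbundanceTable(config$input$abundance))
    } else if (!is.null(config$simulate)) {
      generateExperiment(defaultEffectConfig(),
                         nSites = config$simulate$n_sites,
                         seed = config$seed)
    } else {
      stop("config must provide either an `input` section with sites and ",
           "abundance paths or a `simulate` section")
    }
  })
  writeSiteTable(siteTable(x), out("site_table.tsv"))
  writeAbundanceTable(x, out("abundance.tsv"))
  report$outputs$site_table <- out("site_table.tsv")
  report$outputs$abundance <- out("abundance.tsv")
  report$n_samples <- ncol(x)
  report$n_sites <- length(unique(colData(x)$site_id))

  # stage 2: qPCR efficiency correction
  x <- stage("quantify", {
    if (!is.null(config$input$curves)) {
      curves <- readStandardCurves(config$input$curves)
      m <- assay(x, "copies")
      corrected <- efficiencyCorrect(m, curves,
                                     method = an$efficiency_correction)
      SummarizedExperiment::assay(x, "copies") <- corrected
      report$efficiency_correction <- an$efficiency_correction
      x
    } else {
      report$efficiency_correction <- "none (no curves supplied)"
      x
    }
  })

  # stage 3: resistance
  rec <- stage("resistance", experimentResistance(x))
  writeNumericTSV(rec, out("resistance.tsv"))
  report$outputs$resistance <- out("resistance.tsv")

  # stage 4: group normalization + group resistance
  panel <- as.data.frame(rowData(x))
  stage("normalize", {
    control <- abundanceMatrix(x, "control")
    gs <- do.call(rbind, lapply(.GROUPS, function(g) {
      genes <- panel$gene[panel$group == g]
      sc <- normalizeGroup(t(control), genes)
      data.frame(sample_id = names(sc), group = g, score = as.numeric(sc),
                 stringsAsFactors = FALSE)
    }))
    writeNumericTSV(gs, out("group_scores.tsv"))
    gr <- do.call(rbind, lapply(unique(rec$stressor), function(s) {
      do.call(rbind, lapply(.GROUPS, function(g) {
        genes <- panel$gene[panel$group == g]
        v <- groupResistance(rec[rec$stressor == s, ], genes,
                             mode = an$group_resistance_mode)
        data.frame(site_id = names(v), group = g, stressor = s,
                   resistance = as.numeric(v), stringsAsFactors = FALSE)
      }))
    }))
    writeNumericTSV(gr, out("group_resistance.tsv"))
  })
  report$outputs$group_scores <- out("group_scores.tsv")
  report$outputs$group_resistance <- out("group_resistance.tsv")

  # stage 5: variance partitioning
  vp <- stage("varpart", varpartGroups(x, log10Transform = an$log10_transform,
                                       nPerm = an$n_perm,
                                       seed = subSeed(config$seed, 51L)))
  writeNumericTSV(vp, out("varpart.tsv"))
  report$outputs$varpart <- out("varpart.tsv")

  # stage 6: random-forest predictor importance
  imp <- stage("importance", {
    combos <- expand.grid(group = .GROUPS, stressor = .STRESSORS,
                          stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      resistanceImportance(x, combos$group[i], combos$stressor[i],
                           nTrees = an$n_trees,
                           seed = subSeed(config$seed, 60L + i),
                           nPerm = an$importance_n_perm)))
  })
  writeNumericTSV(imp, out("importance.tsv"))
  report$outputs$importance <- out("importance.tsv")

  # stage 7: path analysis
  stage("sem", {
    combos <- expand.grid(group = .GROUPS, stressor = .STRESSORS,
                          stringsAsFactors = FALSE)
    edgesTab <- list(); fitTab <- list()
    for (i in seq_len(nrow(combos))) {
      pa <- resistancePathAnalysis(x, combos$group[i], combos$stressor[i],
                                   alpha = an$alpha)
      lab <- paste(combos$group[i], combos$stressor[i], sep = ".")
      for (kind in c("apriori", "fit")) {
        f <- if (kind == "apriori") pa$apriori else pa$fit
        if (nrow(f@edges))
          edgesTab[[paste(lab, kind)]] <- data.frame(
            response = lab, model = if (kind == "fit") "optimal" else "apriori",
            f@edges, stringsAsFactors = FALSE)
        fitTab[[paste(lab, kind)]] <- data.frame(
          response = lab, model = if (kind == "fit") "optimal" else "apriori",
          chi2 = f@chi2, df = f@df, p = f@pFit, rmsea = f@rmsea, aic = f@aic,
          n = f@nObs, stringsAsFactors = FALSE)
      }
    }
    writeNumericTSV(do.call(rbind, edgesTab), out("sem_edges.tsv"))
    writeNumericTSV(do.call(rbind, fitTab), out("sem_fit.tsv"))
  })
  report$outputs$sem_edges <- out("sem_edges.tsv")
  report$outputs$sem_fit <- out("sem_fit.tsv")

  report$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report$outputs$report <- file.path(outDir, "report.json")
  invisible(report)
}

cliUsage <- function() {
  cat("usage: stoichpipe <subcommand> [options]\n",
      "subcommands: simulate quantify resistance normalize varpart",
      " importance sem run-all\n",
      "common flags: --seed <int> --config <yaml> --out <path>",
      " --out-dir <dir> --verbose\n", sep = "")
}

cliArgValue <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  stopIfNot(i[1L] < length(args), paste("missing value for", flag))
  args[i[1L] + 1L]
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; each subcommand maps to one
#' module entry point. Returns an exit code (0 success, 1 failure, 2 usage
#' error) rather than quitting, so it is scriptable and testable; the
#' installed \code{exec/stoichpipe} wrapper forwards the code to the shell.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit code
#' @export
cliMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { cliUsage(); return(2L) }
  sub <- argv[1L]; args <- argv[-1L]
  verbose <- "--verbose" %in% args
  known <- c("simulate", "quantify", "resistance", "normalize", "varpart",
             "importance", "sem", "run-all")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub)
    cliUsage()
    return(2L)
  }
  seed <- as.integer(cliArgValue(args, "--seed", "1"))
  note <- function(...) if (verbose) message(...)
  tryCatch({
    switch(sub,
      "simulate" = {
        outDir <- cliArgValue(args, "--out-dir", ".")
        nSites <- as.integer(cliArgValue(args, "--n-sites", "54"))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        x <- generateExperiment(nSites = nSites, seed = seed)
        writeSiteTable(siteTable(x), file.path(outDir, "site_table.tsv"))
        writeAbundanceTable(x, file.path(outDir, "abundance.tsv"))
        note("wrote ", ncol(x), " samples to ", outDir)
      },
      "quantify" = {
        ab <- readAbundanceTable(cliArgValue(args, "--abundance"))
        curves <- readStandardCurves(cliArgValue(args, "--curves"))
        outPath <- cliArgValue(args, "--out", "abundance_corrected.tsv")
        corrected <- do.call(rbind, lapply(unique(ab$treatment), function(tr) {
          m <- efficiencyCorrect(longToMatrix(ab, tr), curves)
          data.frame(site_id = rep(colnames(m), each = nrow(m)),
                     gene = rep(rownames(m), times = ncol(m)),
                     treatment = tr, copies_per_g = as.vector(m),
                     stringsAsFactors = FALSE)
        }))
        writeAbundanceTable(corrected, outPath)
      },
      "resistance" = {
        control <- readAbundanceTable(cliArgValue(args, "--control"))
        treated <- readAbundanceTable(cliArgValue(args, "--treated"))
        stressor <- cliArgValue(args, "--stressor", "disturbance")
        rec <- resistanceTable(longToMatrix(control, unique(control$treatment)[1L]),
                               longToMatrix(treated, unique(treated$treatment)[1L]),
                               stressor)
        writeNumericTSV(rec, cliArgValue(args, "--out", "resistance.tsv"))
      },
      "normalize" = {
        ab <- readAbundanceTable(cliArgValue(args, "--abundance"))
        m <- t(longToMatrix(ab, unique(ab$treatment)[1L]))
        panel <- defaultGenePanel()
        gs <- do.call(rbind, lapply(.GROUPS, function(g) {
          genes <- intersect(panel$gene[panel$group == g], colnames(m))
          stopIfNot(length(genes) > 0L, paste("no genes present for", g))
          sc <- normalizeGroup(m, genes)
          data.frame(sample_id = names(sc), group = g, score = as.numeric(sc))
        }))
        writeNumericTSV(gs, cliArgValue(args, "--out", "group_scores.tsv"))
      },
      "varpart" = {
        sites <- readSiteTable(cliArgValue(args, "--sites"))
        ab <- readAbundanceTable(cliArgValue(args, "--abundance"))
        x <- makeStoichExperiment(sites, ab)
        vp <- varpartGroups(x, nPerm = as.integer(cliArgValue(args, "--n-perm",
                                                              "999")),
                            seed = seed)
        writeNumericTSV(vp, cliArgValue(args, "--out", "varpart.tsv"))
      },
      "importance" = {
        sites <- readSiteTable(cliArgValue(args, "--sites"))
        ab <- readAbundanceTable(cliArgValue(args, "--abundance"))
        x <- makeStoichExperiment(sites, ab)
        imp <- resistanceImportance(x, cliArgValue(args, "--group"),
                                    cliArgValue(args, "--stressor"),
                                    seed = seed)
        writeNumericTSV(imp, cliArgValue(args, "--out", "importance.tsv"))
      },
      "sem" = {
        sites <- readSiteTable(cliArgValue(args, "--sites"))
        ab <- readAbundanceTable(cliArgValue(args, "--abundance"))
        x <- makeStoichExperiment(sites, ab)
        modelPath <- cliArgValue(args, "--model")
        model <- if (is.null(modelPath)) aprioriPathModel()
                 else readPathModel(modelPath)
        pa <- resistancePathAnalysis(x, cliArgValue(args, "--group"),
                                     cliArgValue(args, "--stressor"),
                                     model = model)
        writeNumericTSV(pa$fit@edges, cliArgValue(args, "--out", "sem.tsv"))
      },
      "run-all" = {
        cfgPath <- cliArgValue(args, "--config")
        config <- if (is.null(cfgPath)) defaultPipelineConfig()
                  else readPipelineConfig(cfgPath)
        outDir <- cliArgValue(args, "--out-dir", "stoichpipe_out")
        runPipeline(config, outDir,
                    seed = if ("--seed" %in% args) seed else NULL)
        note("pipeline outputs in ", outDir)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
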