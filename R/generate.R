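#' Generate a table of sampling sites along climate gradients
#'
#' Draws per-site mean annual temperature and precipitation uniformly over the
#' configured gradients, then generates soil total C and N with a log-linear
#' dependence on the (gradient-standardized) climate plus log-normal noise, and
#' total P near-independently, so that climate drives stoichiometry the way a
#' path model can later recover. Ratios are computed from the totals.
#'
#' @param nSites number of sites (>= 2)
#' @param seed integer seed
#' @param config an [EffectConfig-class]
#' @return data.frame with columns \code{site_id}, \code{province}, \code{mat},
#'   \code{map}, \code{total_c}, \code{total_n}, \code{total_p}, \code{cn},
#'   \code{cp}, \code{np}; one row per site.
#' @examples
#' sites <- generateSites(10, seed = 1)
#' stopifnot(all(abs(sites$cn - sites$total_c / sites$total_n) < 1e-9))
#' @export
generateSites <- function(nSites, seed = 1L, config = defaultEffectConfig()) {
  stopIfNot(is.numeric(nSites) && length(nSites) == 1L && nSites >= 2,
            "invalid argument: nSites must be >= 2")
  stopIfNot(is(config, "EffectConfig"), "config must be an EffectConfig")
  validObject(config)
  nSites <- as.integer(nSites)
  set.seed(seed)
  cl <- config@climate
  mat <- runif(nSites, cl$matRange[1], cl$matRange[2])
  map <- runif(nSites, cl$mapRange[1], cl$mapRange[2])
  zMat <- zscoreUniform(mat, cl$matRange)
  zMap <- zscoreUniform(map, cl$mapRange)
  drawTotal <- function(p) {
    exp(p$mu + p$bMap * zMap + p$bMat * zMat + rnorm(nSites, 0, p$sd))
  }
  tc <- drawTotal(config@stoich$logC)
  tn <- drawTotal(config@stoich$logN)
  tp <- drawTotal(config@stoich$logP)
  data.frame(
    site_id = sprintf("S%03d", seq_len(nSites)),
    province = sprintf("P%02d", rep_len(seq_len(21L), nSites)),
    mat = mat, map = map,
    total_c = tc, total_n = tn, total_p = tp,
    cn = tc / tn, cp = tc / tp, np = tn / tp,
    stringsAsFactors = FALSE)
}

# Standardized site-predictor matrix (sites x predictors).
sitePredictorZ <- function(sites) {
  z <- vapply(.SITE_PREDICTORS, function(p) zscore(sites[[p]]),
              numeric(nrow(sites)))
  rownames(z) <- sites$site_id
  z
}

#' Generate control-treatment gene abundances
#'
#' Biomass markers (bacterial 16S, fungal ITS) are generated first from the
#' soil covariates; each functional gene's log10 abundance is then an
#' intercept plus the configured standardized effect slopes times the
#' standardized predictors (climate, stoichiometry, biomass, bacteria:fungi
#' ratio) plus log-normal noise. All returned copy numbers are strictly
#' positive.
#'
#' @param sites site table from [generateSites()]
#' @param panel gene panel data.frame
#' @param config an [EffectConfig-class]
#' @param seed integer seed
#' @return numeric matrix of copies per g dry soil, genes in rows
#'   (panel order), sites in columns.
#' @export
generateControlAbundances <- function(sites, panel = defaultGenePanel(),
                                      config = defaultEffectConfig(),
                                      seed = 1L) {
  stopIfNot(is.data.frame(sites) && nrow(sites) >= 1L,
            "sites must be a non-empty site table")
  stopIfNot(all(functionalGenes(panel) %in% rownames(config@slopes)),
            "invalid config: slope matrix does not cover the gene panel")
  extra <- setdiff(rownames(config@slopes), panel$gene)
  if (length(extra))
    stop("invalid config: unknown gene(s) in slope matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  n <- nrow(sites)
  set.seed(seed)
  z <- sitePredictorZ(sites)
  bm <- config@biomass
  drawBiomass <- function(marker) {
    sl <- bm$slopes[[marker]] %||% numeric()
    eff <- if (length(sl)) as.vector(z[, names(sl), drop = FALSE] %*% sl)
           else rep(0, n)
    bm$intercepts[[marker]] + eff + rnorm(n, 0, bm$noiseSd)
  }
  logBac <- drawBiomass("bac16S")
  logFun <- drawBiomass("fungITS")
  zAll <- cbind(z, bac16S = zscore(logBac), fungITS = zscore(logFun),
                bf_ratio = zscore(logBac - logFun))
  fun <- functionalGenes(panel)
  s <- config@slopes[fun, colnames(zAll), drop = FALSE]
  log10A <- sweep(s %*% t(zAll), 1L, config@intercepts[fun], "+") +
    matrix(rnorm(length(fun) * n, 0, config@noiseSd), nrow = length(fun))
  out <- matrix(NA_real_, nrow = nrow(panel), ncol = n,
                dimnames = list(panel$gene, sites$site_id))
  out[fun, ] <- 10^log10A
  if ("bac16S" %in% panel$gene) out["bac16S", ] <- 10^logBac
  if ("fungITS" %in% panel$gene) out["fungITS", ] <- 10^logFun
  stopIfNot(all(is.finite(out)) && all(out > 0),
            "internal error: nonpositive abundances generated")
  out
}

#' Apply a simulated global-change disturbance to control abundances
#'
#' The treated abundance is \code{control * exp(-m)} (multiplicative
#' suppression), where the per-gene, per-site log-effect magnitude \code{m} is
#' a gene-specific baseline plus the stressor's standardized
#' stoichiometry/climate slopes (and any group-specific extra slopes) plus
#' Gaussian noise, floored at zero. Because the resistance index depends only
#' on the relative change, this makes resistance linearly predictable from the
#' configured drivers.
#'
#' @param control genes x sites abundance matrix
#' @param sites matching site table
#' @param stressor one of \code{"drying_wetting"}, \code{"warming"},
#'   \code{"n_deposition"}
#' @param config an [EffectConfig-class]
#' @param seed integer seed
#' @return treated abundance matrix of the same shape, strictly positive.
#' @export
applyDisturbance <- function(control, sites, stressor,
                             config = defaultEffectConfig(), seed = 1L) {
  if (!(is.character(stressor) && length(stressor) == 1L &&
        stressor %in% .STRESSORS))
    stop("invalid argument: unknown stressor '", paste(stressor, collapse = ","),
         "'; expected one of ", paste(.STRESSORS, collapse = ", "),
         call. = FALSE)
  stopIfNot(all(sites$site_id %in% colnames(control)),
            "control table must cover all sites")
  d <- config@disturbance[[stressor]]
  panel <- config@genePanel
  genes <- rownames(control)
  stopIfNot(all(genes %in% panel$gene), "control rows must match the panel")
  set.seed(seed)
  z <- sitePredictorZ(sites)
  siteEff <- if (length(d$slopes))
    as.vector(z[, names(d$slopes), drop = FALSE] %*% d$slopes)
  else rep(0, nrow(sites))
  groupOf <- panel$group[match(genes, panel$gene)]
  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(sites),
              dimnames = dimnames(control))
  for (i in seq_along(genes)) {
    extra <- d$groupSlopes[[groupOf[i]]]
    ge <- if (length(extra))
      as.vector(z[, names(extra), drop = FALSE] %*% extra)
    else 0
    m[i, ] <- d$baseline[[genes[i]]] + siteEff + ge
  }
  m <- m + matrix(rnorm(length(m), 0, d$noiseSd), nrow = nrow(m))
  m <- pmax(m, 0)
  control[, sites$site_id, drop = FALSE] * exp(-m)
}

#' Generate a complete simulated multi-site microcosm experiment
#'
#' Composes [generateSites()], [generateControlAbundances()] and
#' [applyDisturbance()] for the three stressors into one
#' [StoichExperiment-class] covering all sites under the four treatments
#' (environmental control, drying-wetting cycles, warming, N deposition). The
#' generating parameters are stored in \code{metadata(x)$groundTruth} so that
#' recovery analyses can compare against truth, and the bundle is reproducible
#' from \code{(config, nSites, seed)} alone.
#'
#' @param config an [EffectConfig-class]
#' @param nSites number of sites (default 54, giving 216 samples)
#' @param seed integer seed; per-stage substreams are derived from it
#' @return a [StoichExperiment-class]
#' @examples
#' x <- generateExperiment(nSites = 4, seed = 1)
#' ncol(x)  # 16 samples: 4 sites x 4 treatments
#' @export
generateExperiment <- function(config = defaultEffectConfig(), nSites = 54L,
                               seed = 1L) {
  validObject(config)
  sites <- generateSites(nSites, subSeed(seed, 1L), config)
  panel <- config@genePanel
  control <- generateControlAbundances(sites, panel, config, subSeed(seed, 2L))
  mats <- list(control = control)
  for (i in seq_along(.STRESSORS)) {
    s <- .STRESSORS[i]
    mats[[s]] <- applyDisturbance(control, sites, s, config,
                                  subSeed(seed, 2L + i))
  }
  assayMat <- do.call(cbind, mats)
  treatments <- rep(names(mats), each = ncol(control))
  colnames(assayMat) <- paste(rep(colnames(control), times = length(mats)),
                              treatments, sep = ".")
  cd <- S4Vectors::DataFrame(
    site_id = rep(sites$site_id, times = length(mats)),
    treatment = treatments,
    sites[rep(seq_len(nrow(sites)), times = length(mats)),
          c("province", .SITE_PREDICTORS)],
    row.names = colnames(assayMat))
  rd <- S4Vectors::DataFrame(panel, row.names = panel$gene)
  se <- SummarizedExperiment(assays = SimpleList(copies = assayMat),
                             colData = cd, rowData = rd)
  out <- new("StoichExperiment", se)
  metadata(out)$groundTruth <- list(config = config, nSites = nSites,
                                    seed = seed)
  validObject(out)
  out
}

#' Per-site covariate table of an experiment
#'
#' @param x a [StoichExperiment-class]
#' @return data.frame with one row per site (covariates are site-level and
#'   identical across treatments).
#' @export
siteTable <- function(x) {
  stopIfNot(is(x, "StoichExperiment"), "x must be a StoichExperiment")
  cd <- as.data.frame(colData(x))
  cd <- cd[!duplicated(cd$site_id), , drop = FALSE]
  rownames(cd) <- NULL
  cd[, c("site_id", "province", .SITE_PREDICTORS)]
}

#' Genes-by-sites abundance matrix for one treatment
#'
#' @param x a [StoichExperiment-class]
#' @param treatment one of control, drying_wetting, warming, n_deposition
#' @return numeric matrix, genes in rows, site ids as column names.
#' @export
abundanceMatrix <- function(x, treatment = "control") {
  stopIfNot(is(x, "StoichExperiment"), "x must be a StoichExperiment")
  stopIfNot(treatment %in% .TREATMENTS, "unknown treatment label")
  keep <- colData(x)$treatment == treatment
  m <- assay(x, "copies")[, keep, drop = FALSE]
  colnames(m) <- colData(x)$site_id[keep]
  m
}
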