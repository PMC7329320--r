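#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.STRESSORS <- c("drying_wetting", "warming", "n_deposition")
.TREATMENTS <- c("control", .STRESSORS)
.GROUPS <- c("C_cycling", "N_cycling", "P_cycling")

# Site-level predictors usable as abundance / disturbance drivers.
.SITE_PREDICTORS <- c("mat", "map", "total_c", "total_n", "total_p",
                      "cn", "cp", "np")
.BIOMASS_PREDICTORS <- c("bac16S", "fungITS", "bf_ratio")
.ALL_PREDICTORS <- c(.SITE_PREDICTORS, .BIOMASS_PREDICTORS)

#' Container for a multi-site functional-gene qPCR experiment
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"copies"} assay holds
#' gene copy numbers per g dry soil (genes in rows, samples in columns); the
#' column data carry \code{site_id}, \code{treatment} and the per-site climate
#' (\code{mat}, \code{map}) and stoichiometry covariates (\code{total_c},
#' \code{total_n}, \code{total_p}, \code{cn}, \code{cp}, \code{np}); the row
#' data carry each gene's functional \code{group} and \code{process}.
#'
#' @seealso [generateExperiment()], [siteTable()], [abundanceMatrix()]
#' @export
setClass("StoichExperiment", contains = "SummarizedExperiment")

setValidity("StoichExperiment", function(object) {
  msgs <- character()
  if (!"copies" %in% names(assays(object)))
    msgs <- c(msgs, "assay 'copies' is required")
  else if (any(!is.finite(assay(object, "copies"))) ||
           any(assay(object, "copies") <= 0))
    msgs <- c(msgs, "all abundances must be finite and strictly positive")
  cd <- colData(object)
  need <- c("site_id", "treatment", .SITE_PREDICTORS)
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste("missing colData columns:",
                          paste(miss, collapse = ", ")))
  if ("treatment" %in% colnames(cd) &&
      !all(cd$treatment %in% .TREATMENTS))
    msgs <- c(msgs, "treatment labels must be control/drying_wetting/warming/n_deposition")
  if (!all(c("gene", "group") %in% colnames(rowData(object))))
    msgs <- c(msgs, "rowData must contain 'gene' and 'group'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StoichExperiment", function(object) {
  cat("StoichExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  sites:", length(unique(colData(object)$site_id)),
      " treatments:", paste(unique(colData(object)$treatment), collapse = ", "),
      "\n")
  cat("  groups:",
      paste(names(table(rowData(object)$group)), collapse = ", "), "\n")
})

#' qPCR standard curve
#'
#' Linear calibration of quantification cycle (Cq) against log10 template
#' copies. The amplification efficiency is \eqn{E = 10^{-1/slope} - 1}, so a
#' slope of -3.32 corresponds to perfect doubling (E = 1, i.e. 100\%).
#'
#' @slot gene gene name
#' @slot slope Cq change per log10 copies (negative for valid curves)
#' @slot intercept Cq at one copy
#' @slot r2 coefficient of determination of the calibration fit
#' @slot efficiency amplification efficiency on the 0--1 scale
#' @seealso [fitStandardCurve()], [quantifyCopies()], [efficiencyCorrect()]
#' @export
setClass("StandardCurve",
         representation(gene = "character", slope = "numeric",
                        intercept = "numeric", r2 = "numeric",
                        efficiency = "numeric"))

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope >= 0)
    msgs <- c(msgs, "slope must be a single finite negative number")
  if (length(object@r2) != 1L || object@r2 < 0 || object@r2 > 1 + 1e-12)
    msgs <- c(msgs, "r2 must lie in [0, 1]")
  if (length(object@slope) == 1L && is.finite(object@slope) &&
      object@slope < 0) {
    e <- 10^(-1 / object@slope) - 1
    if (abs(e - object@efficiency) > 1e-8)
      msgs <- c(msgs, "efficiency inconsistent with slope")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve[%s]: Cq = %.4f * log10(copies) + %.4f  (R2 = %.4f, E = %.1f%%)\n",
              object@gene, object@slope, object@intercept, object@r2,
              100 * object@efficiency))
})

#' Parameters of the synthetic multi-site microcosm generator
#'
#' Holds everything the simulator needs: the gene panel, per-gene abundance
#' intercepts (log10 copies per g), the standardized effect-slope matrix of
#' site predictors on log10 abundance, biomass-marker parameters, climate
#' gradients, the climate-to-stoichiometry dependence, and one disturbance
#' model per stressor (per-gene baseline log-effect, stoichiometry slopes,
#' noise SD).
#'
#' @seealso [defaultEffectConfig()], [generateExperiment()]
#' @export
setClass("EffectConfig",
         representation(genePanel = "data.frame", intercepts = "numeric",
                        slopes = "matrix", noiseSd = "numeric",
                        biomass = "list", climate = "list", stoich = "list",
                        disturbance = "list"))

setValidity("EffectConfig", function(object) {
  msgs <- character()
  fun <- functionalGenes(object@genePanel)
  if (!all(fun %in% rownames(object@slopes)))
    msgs <- c(msgs, "slope matrix must cover every functional gene")
  if (!all(colnames(object@slopes) %in% .ALL_PREDICTORS))
    msgs <- c(msgs, paste("unknown predictor in slope matrix; allowed:",
                          paste(.ALL_PREDICTORS, collapse = ", ")))
  if (!all(is.finite(object@slopes)))
    msgs <- c(msgs, "non-finite slope values")
  if (!all(is.finite(object@intercepts)))
    msgs <- c(msgs, "non-finite intercepts")
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be a single finite value >= 0")
  for (s in names(object@disturbance)) {
    d <- object@disturbance[[s]]
    if (!is.finite(d$noiseSd) || d$noiseSd < 0)
      msgs <- c(msgs, paste0("disturbance noiseSd for ", s, " must be >= 0"))
    if (!all(is.finite(d$baseline)) || !all(is.finite(d$slopes)))
      msgs <- c(msgs, paste0("non-finite disturbance parameters for ", s))
    if (!all(names(d$slopes) %in% .SITE_PREDICTORS))
      msgs <- c(msgs, paste0("disturbance slopes for ", s,
                             " must use site predictors"))
  }
  ok <- vapply(object@stoich, function(p)
    all(vapply(p, function(v) all(is.finite(v)), logical(1))), logical(1))
  if (!all(ok)) msgs <- c(msgs, "non-finite stoichiometry parameters")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EffectConfig", function(object) {
  cat("EffectConfig:", nrow(object@genePanel), "genes;",
      ncol(object@slopes), "predictors; stressors:",
      paste(names(object@disturbance), collapse = ", "), "\n")
})

#' Directed acyclic path model
#'
#' An observed-variable recursive path model: a set of variables and directed
#' edges (cause, effect). Variables with no incoming edge are exogenous.
#'
#' @slot variables character vector of variable names
#' @slot edges two-column character matrix (\code{from}, \code{to})
#' @seealso [pathModel()], [fitPathModel()], [pruneToOptimal()]
#' @export
setClass("PathModel",
         representation(variables = "character", edges = "matrix"))

setValidity("PathModel", function(object) {
  msgs <- character()
  e <- object@edges
  if (ncol(e) != 2L) msgs <- c(msgs, "edges must have two columns")
  else {
    bad <- setdiff(c(e[, 1L], e[, 2L]), object@variables)
    if (length(bad))
      msgs <- c(msgs, paste("edge endpoints not declared as variables:",
                            paste(unique(bad), collapse = ", ")))
    if (nrow(e) && anyDuplicated(paste(e[, 1L], e[, 2L])))
      msgs <- c(msgs, "duplicated edges")
    if (!isAcyclic(object@variables, e))
      msgs <- c(msgs, "path model graph must be acyclic")
  }
  if (length(msgs)) msgs else TRUE
})

# Kahn-style elimination: a DAG always has a node with no incoming edge.
isAcyclic <- function(vars, edges) {
  remaining <- vars
  e <- edges
  repeat {
    if (!length(remaining)) return(TRUE)
    noIncoming <- setdiff(remaining, e[, 2L])
    if (!length(noIncoming)) return(FALSE)
    remaining <- setdiff(remaining, noIncoming)
    e <- e[e[, 1L] %in% remaining & e[, 2L] %in% remaining, , drop = FALSE]
  }
}

setMethod("show", "PathModel", function(object) {
  cat("PathModel:", length(object@variables), "variables,",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat(paste0("  ", object@edges[, 1L], " -> ", object@edges[, 2L],
               collapse = "\n"), "\n")
})

#' Fitted path model
#'
#' Standardized path coefficients with per-edge p-values, per-endogenous-node
#' R-squared, and the global fit statistics chi-square, df, Fisher's P, RMSEA
#' and AIC computed from the maximum-likelihood discrepancy between the
#' model-implied and observed correlation matrices.
#'
#' @seealso [fitPathModel()], [evaluateFit()]
#' @export
setClass("PathFit",
         representation(model = "PathModel", edges = "data.frame",
                        r2 = "numeric", chi2 = "numeric", df = "numeric",
                        pFit = "numeric", rmsea = "numeric", aic = "numeric",
                        nObs = "numeric", freeParams = "numeric",
                        saturated = "logical", implied = "matrix",
                        observed = "matrix"))

setMethod("show", "PathFit", function(object) {
  cat(sprintf("PathFit: chi2 = %.4f (df = %d, P = %.4f), RMSEA = %.4f, AIC = %.2f, n = %d%s\n",
              object@chi2, as.integer(object@df), object@pFit, object@rmsea,
              object@aic, as.integer(object@nObs),
              if (object@saturated) " [saturated]" else ""))
  if (nrow(object@edges)) {
    df <- object@edges
    cat(paste0(sprintf("  %s -> %s: beta = %+.3f (p = %.4g)",
                       df$from, df$to, df$beta, df$p), collapse = "\n"), "\n")
  }
  if (length(object@r2))
    cat("  R2:", paste(sprintf("%s %.3f", names(object@r2), object@r2),
                       collapse = ", "), "\n")
})

# Genes carrying a C/N/P-cycling annotation (excludes biomass markers).
functionalGenes <- function(panel) {
  panel$gene[panel$group %in% .GROUPS]
}
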