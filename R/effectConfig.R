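#' Default functional-gene panel
#'
#' The 16 marker genes of the major soil C, N and P cycling processes
#' (cellulose/starch/xylan degradation, nitrification, N fixation, nitrate
#' reduction, denitrification, organic-P mineralization, inorganic-P
#' dissolution) plus the bacterial 16S rRNA and fungal ITS biomass markers.
#'
#' @return data.frame with columns \code{gene}, \code{group}, \code{process}.
#' @examples
#' table(defaultGenePanel()$group)
#' @export
defaultGenePanel <- function() {
  data.frame(
    gene = c("fungcbhIR", "GH74", "GH31", "GH51",
             "amoA-a", "amoA-b", "nifH", "narG", "nirK", "nirS", "nosZ",
             "norB",
             "phoD", "phoC", "BPP", "pqqC",
             "bac16S", "fungITS"),
    group = c(rep("C_cycling", 4), rep("N_cycling", 8), rep("P_cycling", 4),
              rep("biomass_marker", 2)),
    process = c("cellulose degradation", "cellulose degradation",
                "starch degradation", "xylan/arabinan degradation",
                "nitrification (archaeal)", "nitrification (bacterial)",
                "N fixation", "nitrate reduction", "denitrification",
                "denitrification", "denitrification", "denitrification",
                "organic P mineralization", "organic P mineralization",
                "phytic acid mineralization", "inorganic P dissolution",
                "bacterial biomass", "fungal biomass"),
    stringsAsFactors = FALSE)
}

# Default standardized effect-slope matrix (functional genes x predictors),
# on the log10-abundance scale. Encodes the sign structure of the control-soil
# correlation heat map: total N, C/P and N/P positive with all functional
# genes; total C positive with amoA-b/nifH/narG/nirS/nosZ; total P negative
# with phoD/pqqC; C/N negative with phoD/phoC/pqqC/nirK/fungcbhIR/GH74;
# climate linked only to nirK/phoC/pqqC/fungcbhIR; biomass markers positive
# with most genes; the bacteria:fungi ratio linked to the C-cycling genes.
defaultSlopeMatrix <- function(panel = defaultGenePanel(), magnitude = 0.3) {
  fun <- functionalGenes(panel)
  m <- matrix(0, nrow = length(fun), ncol = length(.ALL_PREDICTORS),
              dimnames = list(fun, .ALL_PREDICTORS))
  m[, "total_n"] <- magnitude
  m[, "cp"] <- magnitude
  m[, "np"] <- magnitude
  m[c("amoA-b", "nifH", "narG", "nirS", "nosZ"), "total_c"] <- magnitude
  m[c("phoD", "pqqC"), "total_p"] <- -magnitude
  m[c("phoD", "phoC", "pqqC", "nirK", "fungcbhIR", "GH74"), "cn"] <- -magnitude
  m[c("nirK", "phoC"), "mat"] <- 2 / 3 * magnitude
  m[c("pqqC", "fungcbhIR"), "map"] <- 2 / 3 * magnitude
  m[setdiff(fun, "fungcbhIR"), "bac16S"] <- 2 / 3 * magnitude
  m[c("fungcbhIR", "GH74", "GH31", "GH51"), "fungITS"] <- 2 / 3 * magnitude
  m[c("fungcbhIR", "GH74", "GH31", "GH51"), "bf_ratio"] <- -2 / 3 * magnitude
  m
}

defaultIntercepts <- function(panel = defaultGenePanel()) {
  ic <- c(fungcbhIR = 6.7, GH74 = 6.4, GH31 = 6.6, GH51 = 6.3,
          `amoA-a` = 7.0, `amoA-b` = 7.2, nifH = 7.5, narG = 7.8,
          nirK = 7.5, nirS = 7.3, nosZ = 7.0, norB = 6.8,
          phoD = 7.6, phoC = 6.9, BPP = 6.5, pqqC = 7.0)
  ic[functionalGenes(panel)]
}

# Per-stressor disturbance models. Baselines (log-effect magnitude) encode the
# observed resistance ordering: phoD/phoC least resistant to drying-wetting;
# nosZ and GH51 least resistant to warming, amoA-a most; C-cycling genes
# (GH31/GH51/GH74) least resistant to N deposition while amoA-b/nirS/narG/norB
# are most resistant; BPP less resistant to N deposition than to the other two.
# Slopes make resistance predictable from the stoichiometry/climate drivers:
# MAP for drying-wetting, MAT for warming, C/P plus total C and N for N
# deposition, with total C/N/C:N additionally driving the P-cycling group
# under every stressor.
defaultDisturbance <- function(panel = defaultGenePanel()) {
  genes <- panel$gene
  base <- function(default, ...) {
    b <- rep(default, length(genes)); names(b) <- genes
    ov <- c(...)
    b[names(ov)] <- ov
    b[panel$group == "biomass_marker"] <- 0.4
    b
  }
  pSlopes <- c(total_c = -0.15, total_n = -0.15, cn = -0.1)
  list(
    drying_wetting = list(
      baseline = base(0.5, phoD = 0.9, phoC = 0.8, nosZ = 0.3),
      slopes = c(map = -0.25),
      groupSlopes = list(P_cycling = pSlopes),
      noiseSd = 0.1),
    warming = list(
      baseline = base(0.5, nosZ = 0.8, GH51 = 0.8, `amoA-a` = 0.3),
      slopes = c(mat = -0.25),
      groupSlopes = list(P_cycling = pSlopes),
      noiseSd = 0.1),
    n_deposition = list(
      baseline = base(0.5, GH31 = 0.85, GH51 = 0.9, GH74 = 0.85,
                      fungcbhIR = 0.7, `amoA-b` = 0.3, nirS = 0.3,
                      narG = 0.3, norB = 0.3, BPP = 0.7),
      slopes = c(cp = -0.25, total_c = -0.15, total_n = -0.15),
      groupSlopes = list(P_cycling = pSlopes),
      noiseSd = 0.1))
}

#' Default generator configuration
#'
#' The study conditions of the simulated multi-site microcosm experiment:
#' climate gradients MAT 0--20 degC and MAP 100--1600 mm (uniform), soil total
#' C and N depending log-linearly on MAP (positively) and MAT (weakly
#' negatively) so that climate drives stoichiometry, total P near-independent
#' of climate, standardized abundance effect slopes of magnitude 0.3 log10
#' units with log-normal noise (SD 0.25 log10 units), and per-stressor
#' multiplicative disturbance models whose magnitude depends on the
#' stoichiometry/climate drivers (see [defaultGenePanel()]).
#'
#' @param panel gene panel data.frame (default [defaultGenePanel()])
#' @param slopeMagnitude standardized effect-slope magnitude on log10 abundance
#' @param noiseSd residual SD of log10 abundance
#' @return an [EffectConfig-class] object
#' @examples
#' cfg <- defaultEffectConfig()
#' cfg
#' @export
defaultEffectConfig <- function(panel = defaultGenePanel(),
                                slopeMagnitude = 0.3, noiseSd = 0.25) {
  new("EffectConfig",
      genePanel = panel,
      intercepts = defaultIntercepts(panel),
      slopes = defaultSlopeMatrix(panel, slopeMagnitude),
      noiseSd = noiseSd,
      biomass = list(
        intercepts = c(bac16S = 10.5, fungITS = 9.0),
        slopes = list(bac16S = c(total_n = 0.25, total_c = 0.15),
                      fungITS = c(total_c = 0.2)),
        noiseSd = 0.2),
      climate = list(matRange = c(0, 20), mapRange = c(100, 1600)),
      stoich = list(
        logC = list(mu = log(12), bMap = 0.35, bMat = -0.15, sd = 0.25),
        logN = list(mu = log(1.2), bMap = 0.40, bMat = -0.10, sd = 0.25),
        logP = list(mu = log(0.7), bMap = 0, bMat = 0, sd = 0.30)),
      disturbance = defaultDisturbance(panel))
}
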