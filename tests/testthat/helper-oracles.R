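# Independent oracles and small fixture builders shared across the suite.

# direct arithmetic evaluation of the resistance index
oracleRS <- function(c0, treated) {
  d0 <- abs(treated - c0)
  1 - 2 * d0 / (c0 + d0)
}

# column-wise univariate OLS oracle for the multivariate R2
oracleMultR2 <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  tot <- 0; expl <- 0
  for (j in seq_len(ncol(Y))) {
    fit <- lm(Y[, j] ~ X)
    yc <- Y[, j] - mean(Y[, j])
    tot <- tot + sum(yc^2)
    expl <- expl + sum(yc^2) - sum(residuals(fit)^2)
  }
  expl / tot
}

oracleAdjR2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

# inclusion-exclusion over the three adjusted R2 values
oracleVarpart <- function(Y, XM, XS) {
  Y <- as.matrix(Y); XM <- as.matrix(XM); XS <- as.matrix(XS)
  n <- nrow(Y)
  aM <- oracleAdjR2(oracleMultR2(Y, XM), n, ncol(XM))
  aS <- oracleAdjR2(oracleMultR2(Y, XS), n, ncol(XS))
  aMS <- oracleAdjR2(oracleMultR2(Y, cbind(XM, XS)), n, ncol(XM) + ncol(XS))
  c(frac_unique_M = aMS - aS, frac_shared = aM + aS - aMS,
    frac_unique_S = aMS - aM, frac_residual = 1 - aMS)
}

# generator configuration with every noise source and effect slope silenced
quietConfig <- function() {
  cfg <- defaultEffectConfig()
  cfg@slopes[] <- 0
  cfg@noiseSd <- 0
  cfg@biomass$noiseSd <- 0
  cfg@biomass$slopes <- list(bac16S = numeric(0), fungITS = numeric(0))
  cfg@stoich$logC$sd <- 0
  cfg@stoich$logN$sd <- 0
  cfg@stoich$logP$sd <- 0
  for (s in names(cfg@disturbance)) {
    cfg@disturbance[[s]]$baseline[] <- 0
    cfg@disturbance[[s]]$slopes[] <- 0
    cfg@disturbance[[s]]$groupSlopes <- list()
    cfg@disturbance[[s]]$noiseSd <- 0
  }
  cfg
}

# standardized MAP -> total N -> resistance chain with known path betas
semChainData <- function(n, b1 = 0.6, b2 = 0.5, seed = 1) {
  set.seed(seed)
  map <- rnorm(n)
  total_n <- b1 * map + rnorm(n, 0, sqrt(1 - b1^2))
  resistance <- b2 * total_n + rnorm(n, 0, sqrt(1 - b2^2))
  data.frame(map = map, total_n = total_n, resistance = resistance)
}

# small all-positive long abundance table for I/O tests
tinyLongTable <- function() {
  expand.grid(site_id = c("S001", "S002", "S003"),
              gene = c("nifH", "phoD"),
              treatment = c("control", "warming"),
              stringsAsFactors = FALSE) |>
    transform(copies_per_g = exp(seq_len(12)))
}
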