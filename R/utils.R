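#' @importFrom stats sd rnorm runif lm pchisq pf pt cor kruskal.test p.adjust
#'   complete.cases coef pnorm quantile var predict setNames oneway.test
#'   t.test cor.test
#' @importFrom utils read.delim write.table head combn
#' @importFrom SummarizedExperiment assay<-
#' @import methods
NULL

# Deterministic substream seed derivation: one user-facing seed fans out to
# independent per-stage streams. Kept below 2^31 - 1.
subSeed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 1009 + 97 * k) %% 2147483587) + 1L
}

# z-scores with a guard for constant columns (returned as all-zero).
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Standardization against a configured uniform gradient rather than the sample,
# so zero-noise site generation lands exactly on the regression surface.
zscoreUniform <- function(x, range) {
  mu <- mean(range)
  s <- diff(range) / sqrt(12)
  (x - mu) / s
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
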