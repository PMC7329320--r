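#' Hellinger transform of a community abundance matrix
#'
#' Each entry becomes the square root of its row-proportion:
#' \code{sqrt(x[i,j] / rowSums(x)[i])}, so every output row has unit sum of
#' squares and Euclidean distances between rows become Hellinger distances --
#' the standard preparation of community matrices for RDA.
#'
#' @param x samples x genes matrix with nonnegative entries and no all-zero
#'   rows
#' @return transformed matrix of the same shape
#' @examples
#' hellinger(rbind(c(4, 0), c(1, 1)))
#' @export
hellinger <- function(x) {
  stopIfNot(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  if (any(x < 0))
    stop("invalid input: negative entries are not allowed", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("degenerate row (all zero): row ",
         paste(which(rs == 0), collapse = ", "), call. = FALSE)
  sqrt(sweep(x, 1L, rs, "/"))
}

# Multivariate OLS R2 (trace of explained SS over total SS of column-centered
# Y), with an informative collinearity error. With allowRankDeficient the fit
# projects onto the column space and reports the effective rank (used for the
# union model in varpart2, where overlapping sets are legitimate).
multR2 <- function(Y, X, allowRankDeficient = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopIfNot(nrow(Y) == nrow(X), "Y and X must have matching rows")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  q <- qr(Xc)
  if (q$rank < ncol(Xc) && !allowRankDeficient) {
    dep <- colnames(Xc)[q$pivot[seq(q$rank + 1L, ncol(Xc))]]
    stop("collinearity: predictor column(s) linearly dependent: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  stopIfNot(nrow(X) > q$rank + 1L, "need more samples than predictors + 1")
  tot <- sum(Yc^2)
  stopIfNot(tot > 0, "Y has zero total variance")
  structure(sum(qr.fitted(q, Yc)^2) / tot, rank = q$rank)
}

#' Redundancy-analysis R-squared and Ezekiel-adjusted R-squared
#'
#' Multivariate least squares of the (column-centered) response matrix on the
#' predictors; R2 is the trace of the fitted sum of squares over the total sum
#' of squares, and the adjusted value uses the Ezekiel correction
#' \code{1 - (1 - R2) (n - 1) / (n - p - 1)}.
#'
#' @param Y samples x responses matrix
#' @param X samples x predictors matrix (full column rank after centering)
#' @return named list with \code{r2} and \code{adj_r2}
#' @export
rdaAdjR2 <- function(Y, X) {
  r2 <- as.numeric(multR2(Y, X))
  n <- nrow(as.matrix(Y)); p <- ncol(as.matrix(X))
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

#' Two-set variance partitioning of a response matrix
#'
#' Inclusion-exclusion decomposition of adjusted R2 between a climate set
#' (e.g. MAT + MAP) and a stoichiometry set: with \code{aM = adjR2(M)},
#' \code{aS = adjR2(S)}, \code{aMS = adjR2(M u S)}, the unique fractions are
#' \code{aMS - aS} (climate) and \code{aMS - aM} (stoichiometry), the shared
#' fraction is \code{aM + aS - aMS}, and the residual is \code{1 - aMS}.
#' Adjusted fractions can be slightly negative; they are reported as computed
#' and flagged, never truncated.
#'
#' @param Y samples x responses matrix (typically Hellinger-transformed log10
#'   abundances)
#' @param XM climate predictor matrix
#' @param XS stoichiometry predictor matrix
#' @return one-row data.frame with columns \code{frac_unique_M},
#'   \code{frac_shared}, \code{frac_unique_S}, \code{frac_residual},
#'   \code{adjR2_M}, \code{adjR2_S}, \code{adjR2_full},
#'   \code{negative_fraction} flag
#' @export
varpart2 <- function(Y, XM, XS) {
  XM <- as.matrix(XM); XS <- as.matrix(XS)
  n <- nrow(as.matrix(Y))
  aM <- rdaAdjR2(Y, XM)$adj_r2
  aS <- rdaAdjR2(Y, XS)$adj_r2
  # overlap between the sets is legitimate here: the union fit projects onto
  # the joint column space and adjusts by its effective rank
  r2MS <- multR2(Y, cbind(XM, XS), allowRankDeficient = TRUE)
  pEff <- attr(r2MS, "rank")
  aMS <- 1 - (1 - as.numeric(r2MS)) * (n - 1) / (n - pEff - 1)
  a <- aMS - aS
  c_ <- aMS - aM
  b <- aM + aS - aMS
  res <- 1 - aMS
  data.frame(frac_unique_M = a, frac_shared = b, frac_unique_S = c_,
             frac_residual = res, adjR2_M = aM, adjR2_S = aS,
             adjR2_full = aMS,
             negative_fraction = any(c(a, b, c_) < 0))
}

#' Permutation test for a variance-partitioning fraction
#'
#' Tests the unique contribution of one predictor set conditional on the
#' other (or the full model) with Freedman-Lane residual permutation: rows of
#' the reduced-model residuals of Y are permuted, added back to the
#' reduced-model fit, and the semipartial R2 recomputed;
#' \code{p = (1 + #permuted >= observed) / (1 + nPerm)}.
#'
#' @param Y samples x responses matrix
#' @param XM climate predictor matrix
#' @param XS stoichiometry predictor matrix
#' @param which \code{"M"} (unique climate), \code{"S"} (unique
#'   stoichiometry) or \code{"full"} (joint model, rows of Y permuted)
#' @param nPerm number of permutations (>= 99)
#' @param seed integer seed
#' @return named list with the observed \code{statistic} (semipartial R2) and
#'   permutation \code{p}
#' @export
permutationTestFraction <- function(Y, XM, XS, which = c("M", "S", "full"),
                                    nPerm = 999L, seed = 1L) {
  which <- match.arg(which)
  if (!is.numeric(nPerm) || nPerm < 99)
    stop("invalid argument: nPerm must be >= 99", call. = FALSE)
  Y <- as.matrix(Y); XM <- as.matrix(XM); XS <- as.matrix(XS)
  n <- nrow(Y)
  set.seed(seed)
  if (which == "full") {
    X <- cbind(XM, XS)
    obs <- as.numeric(multR2(Y, X))
    perm <- vapply(seq_len(nPerm), function(i)
      as.numeric(multR2(Y[sample.int(n), , drop = FALSE], X)), numeric(1))
  } else {
    B <- if (which == "M") XS else XM
    X <- cbind(XM, XS)
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    qB <- qr(scale(B, center = TRUE, scale = FALSE))
    fitB <- qr.fitted(qB, Yc)
    resB <- Yc - fitB
    stat <- function(Ystar)
      as.numeric(multR2(Ystar, X)) - as.numeric(multR2(Ystar, B))
    obs <- stat(Y)
    perm <- vapply(seq_len(nPerm), function(i)
      stat(fitB + resB[sample.int(n), , drop = FALSE]), numeric(1))
  }
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (1 + nPerm))
}

#' Pearson correlation heat-map statistics
#'
#' Pearson r and two-sided p for every (site variable, gene) pair, with the
#' conventional star categories (* p < 0.05, ** p < 0.01, *** p < 0.001;
#' empty when p >= 0.05). Constant columns yield an undefined-correlation
#' flag rather than an error.
#'
#' @param siteVars samples x variables matrix or data.frame (numeric)
#' @param geneAbundances samples x genes matrix (typically log10 copies)
#' @return data.frame with columns \code{var_x}, \code{var_y}, \code{r},
#'   \code{p}, \code{stars}, \code{undefined}
#' @export
correlationHeatmapStats <- function(siteVars, geneAbundances) {
  sv <- as.matrix(as.data.frame(siteVars)[vapply(as.data.frame(siteVars),
                                                 is.numeric, logical(1))])
  ga <- as.matrix(geneAbundances)
  stopIfNot(nrow(sv) == nrow(ga), "matching sample rows required")
  stopIfNot(nrow(sv) >= 4L, "need at least 4 paired observations")
  out <- expand.grid(var_x = colnames(sv), var_y = colnames(ga),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  out$stars <- ""; out$undefined <- FALSE
  for (k in seq_len(nrow(out))) {
    x <- sv[, out$var_x[k]]; y <- ga[, out$var_y[k]]
    if (sd(x) == 0 || sd(y) == 0) {
      out$undefined[k] <- TRUE
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    out$r[k] <- unname(ct$estimate)
    out$p[k] <- ct$p.value
    out$stars[k] <- if (ct$p.value < 0.001) "***"
      else if (ct$p.value < 0.01) "**"
      else if (ct$p.value < 0.05) "*" else ""
  }
  out
}

#' Variance partitioning of each functional group of an experiment
#'
#' For each of the C, N and P cycling groups, builds the control-treatment
#' samples x member-genes matrix (log10-transformed by default, then
#' Hellinger-transformed), partitions its variance between the climate set
#' (MAT, MAP) and the stoichiometry set (total C/N/P and C/N, C/P, N/P), and
#' attaches Freedman-Lane permutation p-values for the two unique fractions.
#'
#' @param x a [StoichExperiment-class]
#' @param log10Transform log10 the copy numbers first (default TRUE)
#' @param nPerm permutations for the unique-fraction tests (>= 99)
#' @param seed integer seed
#' @return data.frame with one row per group: fractions, adjusted R2s and
#'   \code{p_M}, \code{p_S}
#' @export
varpartGroups <- function(x, log10Transform = TRUE, nPerm = 999L, seed = 1L) {
  stopIfNot(is(x, "StoichExperiment"), "x must be a StoichExperiment")
  sites <- siteTable(x)
  control <- abundanceMatrix(x, "control")
  XM <- as.matrix(sites[, c("mat", "map")])
  XS <- as.matrix(sites[, c("total_c", "total_n", "total_p", "cn", "cp", "np")])
  panel <- as.data.frame(rowData(x))
  out <- list()
  for (g in .GROUPS) {
    genes <- panel$gene[panel$group == g]
    Y <- t(control[genes, sites$site_id, drop = FALSE])
    if (log10Transform) Y <- log10(Y)
    Y <- hellinger(Y)
    vp <- varpart2(Y, XM, XS)
    vp$group <- g
    vp$p_M <- permutationTestFraction(Y, XM, XS, "M", nPerm,
                                      subSeed(seed, 11L))$p
    vp$p_S <- permutationTestFraction(Y, XM, XS, "S", nPerm,
                                      subSeed(seed, 12L))$p
    out[[g]] <- vp
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("group", "frac_unique_M", "frac_shared", "frac_unique_S",
         "frac_residual", "adjR2_M", "adjR2_S", "adjR2_full",
         "negative_fraction", "p_M", "p_S")]
}
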