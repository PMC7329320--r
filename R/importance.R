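#' Random-forest mean predictor importance (%IncMSE)
#'
#' Fits a regression random forest (bootstrap sampling, \code{mtry =
#' max(1, floor(p/3))} by default, 500 trees as is conventional) and reports
#' each predictor's out-of-bag permutation importance -- the increase in
#' out-of-bag mean squared error when that predictor is shuffled, averaged
#' over the trees -- expressed as a percentage of the forest's out-of-bag MSE.
#' Raw (unitful, possibly negative) values and a percent-of-total
#' normalization over positive importances are reported alongside.
#'
#' @param X samples x predictors data.frame or matrix
#' @param y numeric response (n >= 10, non-constant)
#' @param nTrees number of trees (>= 100; default 500)
#' @param seed integer seed
#' @param mtry predictors tried per split (default regression convention)
#' @return data.frame with columns \code{predictor}, \code{mpi_raw},
#'   \code{mpi} (percent of OOB MSE) and \code{mpi_norm} (percent of total
#'   positive importance)
#' @export
fitImportance <- function(X, y, nTrees = 500L, seed = 1L,
                          mtry = max(1L, floor(ncol(X) / 3))) {
  X <- as.data.frame(X)
  stopIfNot(nrow(X) >= 10L, "need at least 10 samples")
  if (!is.numeric(nTrees) || nTrees < 100)
    stop("invalid argument: nTrees must be >= 100", call. = FALSE)
  if (sd(y) == 0)
    stop("degenerate response: y is constant", call. = FALSE)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = nTrees, mtry = mtry,
                                   importance = TRUE, replace = TRUE)
  raw <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  # a predictor that never reaches an out-of-bag evaluation (possible in very
  # small forests) carries no importance information; count it as zero
  raw[!is.finite(raw)] <- 0
  oobMse <- mean((y - rf$predicted)^2, na.rm = TRUE)
  mpi <- 100 * raw / oobMse
  pos <- pmax(mpi, 0)
  norm <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(0, length(pos))
  data.frame(predictor = colnames(X), mpi_raw = unname(raw),
             mpi = unname(mpi), mpi_norm = unname(norm),
             stringsAsFactors = FALSE)
}

#' Response-permutation significance of random-forest importance
#'
#' Builds each predictor's null importance distribution by refitting the whole
#' forest to row-permutations of the response and reports
#' \code{p = (1 + #null >= observed) / (1 + nPerm)} per predictor. The full
#' refit at \code{nTrees} per permutation is the default despite its cost; a
#' faster approximation that fits each null forest with a fifth of the trees
#' (importance means stabilize quickly) is available via \code{refit = FALSE}
#' and labelled as such in the output attribute \code{"method"}.
#'
#' @param X samples x predictors data.frame or matrix
#' @param y numeric response
#' @param nPerm number of response permutations (>= 99)
#' @param nTrees trees per forest (>= 100)
#' @param seed integer seed
#' @param alpha significance level for the flag column
#' @param refit refit the forest for every permutation (default TRUE)
#' @return data.frame with columns \code{predictor}, \code{mpi}, \code{p},
#'   \code{significant}
#' @export
permutationSignificance <- function(X, y, nPerm = 99L, nTrees = 500L,
                                    seed = 1L, alpha = 0.05, refit = TRUE) {
  if (!is.numeric(nPerm) || nPerm < 99)
    stop("invalid argument: nPerm must be >= 99", call. = FALSE)
  X <- as.data.frame(X)
  obs <- fitImportance(X, y, nTrees = nTrees, seed = subSeed(seed, 0L))
  n <- length(y)
  exceed <- integer(nrow(obs))
  if (refit) {
    for (b in seq_len(nPerm)) {
      set.seed(subSeed(seed, 1000L + b))
      yPerm <- y[sample.int(n)]
      nullImp <- fitImportance(X, yPerm, nTrees = nTrees,
                               seed = subSeed(seed, 2000L + b))
      exceed <- exceed + (nullImp$mpi >= obs$mpi)
    }
  } else {
    # Reduced-forest approximation: null importances from forests a fifth the
    # size (>= 100 trees); their means are already stable at that depth.
    for (b in seq_len(nPerm)) {
      set.seed(subSeed(seed, 1000L + b))
      yPerm <- y[sample.int(n)]
      nullImp <- fitImportance(X, yPerm, nTrees = max(100L, nTrees %/% 5L),
                               seed = subSeed(seed, 2000L + b))
      exceed <- exceed + (nullImp$mpi >= obs$mpi)
    }
  }
  out <- data.frame(predictor = obs$predictor, mpi = obs$mpi,
                    p = (1 + exceed) / (1 + nPerm),
                    significant = (1 + exceed) / (1 + nPerm) < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- if (refit) "full_refit" else "reduced_forest"
  out
}

#' Predictor importance for a functional group's resistance
#'
#' Composes [experimentResistance()], [groupResistance()] and
#' [fitImportance()]: the response is the per-site group resistance to one
#' stressor, the predictors are the site's climate (MAT, MAP) and
#' stoichiometry (total C/N/P and ratios).
#'
#' @param x a [StoichExperiment-class]
#' @param group one of C_cycling, N_cycling, P_cycling
#' @param stressor one of drying_wetting, warming, n_deposition
#' @param nTrees trees (default 500)
#' @param seed integer seed
#' @param nPerm if non-NULL, also run [permutationSignificance()] with this
#'   many permutations
#' @return data.frame of importances (with p-values when \code{nPerm} is set),
#'   plus the response vector as attribute \code{"response"}
#' @export
resistanceImportance <- function(x, group, stressor, nTrees = 500L, seed = 1L,
                                 nPerm = NULL) {
  stopIfNot(group %in% .GROUPS, "unknown functional group")
  panel <- as.data.frame(rowData(x))
  genes <- panel$gene[panel$group == group]
  rec <- experimentResistance(x, stressor)
  y <- groupResistance(rec, genes)
  sites <- siteTable(x)
  X <- sites[match(names(y), sites$site_id),
             c("mat", "map", "total_c", "total_n", "total_p", "cn", "cp", "np")]
  out <- if (is.null(nPerm)) {
    fitImportance(X, as.numeric(y), nTrees = nTrees, seed = seed)
  } else {
    permutationSignificance(X, as.numeric(y), nPerm = nPerm, nTrees = nTrees,
                            seed = seed)
  }
  out$response <- paste(group, stressor, sep = ".")
  attr(out, "response") <- y
  out
}
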