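#' Construct a path model
#'
#' @param edges either a character vector of \code{"source -> target"} strings
#'   or a two-column matrix/data.frame of (from, to) pairs
#' @param variables optional explicit variable set (defaults to the edge
#'   endpoints)
#' @return a [PathModel-class]
#' @examples
#' pathModel(c("map -> total_n", "total_n -> resistance"))
#' @export
pathModel <- function(edges, variables = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(trimws(edges), "\\s*->\\s*")
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("malformed edge specification: ", edges[bad][1L], call. = FALSE)
    edges <- do.call(rbind, parts)
  }
  edges <- as.matrix(edges)
  colnames(edges) <- c("from", "to")
  variables <- variables %||% unique(c(edges[, 1L], edges[, 2L]))
  new("PathModel", variables = variables, edges = edges)
}

#' Read a path model from a plain-text edge list
#'
#' One \code{"source -> target"} edge per line; \code{#} starts a comment.
#'
#' @param path file path
#' @return a [PathModel-class]
#' @export
readPathModel <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  pathModel(lines[nzchar(lines)])
}

#' Exogenous variables of a path model
#' @param model a [PathModel-class]
#' @return character vector of variables with no incoming edge
#' @export
exogenousVariables <- function(model) {
  setdiff(model@variables, model@edges[, 2L])
}

#' Fit a recursive path model by per-equation standardized OLS
#'
#' All variables are standardized internally; each endogenous variable is
#' regressed on its parents (exactly the maximum-likelihood solution for a
#' recursive path model with uncorrelated errors), giving standardized path
#' coefficients with t-test p-values and a per-equation R2. The model-implied
#' correlation matrix is assembled from the path coefficients (with exogenous
#' covariances fixed at their observed values) and compared with the observed
#' matrix by the ML discrepancy: \code{chi2 = (n - 1) * F_ML}, \code{df} =
#' distinct moments minus free parameters, \code{RMSEA =
#' sqrt(max(chi2 - df, 0) / (df (n - 1)))} (0 with a saturated flag at df =
#' 0), \code{AIC = chi2 + 2 * free parameters}.
#'
#' @param model a [PathModel-class]
#' @param data data.frame containing every model variable (complete cases)
#' @return a [PathFit-class]
#' @export
fitPathModel <- function(model, data) {
  stopIfNot(is(model, "PathModel"), "model must be a PathModel")
  validObject(model)
  vars <- model@variables
  miss <- setdiff(vars, colnames(data))
  if (length(miss))
    stop("data missing model variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  edges <- model@edges
  maxIn <- if (nrow(edges)) max(table(edges[, 2L])) else 0L
  stopIfNot(n > maxIn + 1L, "too few observations for the largest equation")
  Z <- scale(as.matrix(d))
  if (any(!is.finite(Z)))
    stop("constant model variable: cannot standardize", call. = FALSE)
  S <- stats::cor(as.matrix(d))
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  endo <- unique(edges[, 2L])
  exo <- setdiff(vars, endo)
  edgeTab <- data.frame(from = character(), to = character(),
                        beta = numeric(), se = numeric(), p = numeric(),
                        stringsAsFactors = FALSE)
  r2 <- setNames(numeric(0), character(0))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi[exo, exo] <- S[exo, exo, drop = FALSE]
  for (v in endo) {
    parents <- edges[edges[, 2L] == v, 1L]
    Xp <- Z[, parents, drop = FALSE]
    XtX <- crossprod(Xp)
    if (rcond(XtX) < 1e-12)
      stop("collinearity among the parents of ", v, ": ",
           paste(parents, collapse = ", "), call. = FALSE)
    beta <- solve(XtX, crossprod(Xp, Z[, v]))
    fittedV <- Xp %*% beta
    resid <- Z[, v] - fittedV
    dfres <- n - length(parents) - 1L
    sigma2 <- sum(resid^2) / dfres
    seBeta <- sqrt(diag(solve(XtX)) * sigma2)
    tval <- beta / seBeta
    pval <- 2 * pt(-abs(tval), dfres)
    edgeTab <- rbind(edgeTab, data.frame(
      from = parents, to = v, beta = as.vector(beta), se = as.vector(seBeta),
      p = as.vector(pval), stringsAsFactors = FALSE))
    ssTot <- sum(Z[, v]^2)
    r2[v] <- 1 - sum(resid^2) / ssTot
    B[v, parents] <- as.vector(beta)
    # residual variance consistent with the correlation metric
    Psi[v, v] <- max(1 - as.vector(crossprod(beta, S[parents, parents,
                                                     drop = FALSE] %*% beta)),
                     1e-12)
  }
  A <- diag(p) - B
  Ainv <- solve(A)
  implied <- Ainv %*% Psi %*% t(Ainv)
  dimnames(implied) <- list(vars, vars)
  free <- nrow(edges) + length(endo) + length(exo) + choose(length(exo), 2L)
  df <- p * (p + 1) / 2 - free
  fml <- as.numeric(determinant(implied, logarithm = TRUE)$modulus) -
    as.numeric(determinant(S, logarithm = TRUE)$modulus) +
    sum(diag(S %*% solve(implied))) - p
  chi2 <- max((n - 1) * fml, 0)
  saturated <- df <= 0
  pFit <- if (saturated) 1 else pchisq(chi2, df, lower.tail = FALSE)
  rmsea <- if (saturated) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  new("PathFit", model = model, edges = edgeTab, r2 = r2, chi2 = chi2,
      df = as.numeric(df), pFit = pFit, rmsea = rmsea,
      aic = chi2 + 2 * free, nObs = as.numeric(n),
      freeParams = as.numeric(free), saturated = saturated,
      implied = implied, observed = S)
}

#' Evaluate goodness of fit of a path model
#'
#' A model fits well when RMSEA < 0.05 and Fisher's P lies in (0.05, 1]; the
#' chi-square and AIC are reported for comparison between candidate models
#' (lower is better). A saturated model (df = 0) passes by convention and is
#' flagged.
#'
#' @param fit a [PathFit-class]
#' @param rmseaMax RMSEA threshold (default 0.05)
#' @param pMin lower bound for the fit p-value (default 0.05)
#' @return list with \code{good} (logical verdict), per-criterion detail and
#'   the reported indices
#' @export
evaluateFit <- function(fit, rmseaMax = 0.05, pMin = 0.05) {
  stopIfNot(is(fit, "PathFit"), "fit must be a PathFit")
  rmseaOk <- fit@rmsea < rmseaMax
  pOk <- fit@pFit > pMin & fit@pFit <= 1
  list(good = rmseaOk && pOk,
       criteria = data.frame(
         criterion = c("rmsea", "p_fit"),
         value = c(fit@rmsea, fit@pFit),
         threshold = c(rmseaMax, pMin),
         pass = c(rmseaOk, pOk)),
       chi2 = fit@chi2, df = fit@df, aic = fit@aic,
       saturated = fit@saturated)
}

#' Backward-prune a path model to its optimal form
#'
#' Starting from the a-priori model, repeatedly removes the least significant
#' edge (largest p >= alpha; ties broken by smaller absolute coefficient, then
#' lexicographic edge name) and refits, stopping when every retained edge is
#' significant. Both the a-priori and optimal fits are returned.
#'
#' @param model the a-priori [PathModel-class]
#' @param data data.frame with the model variables
#' @param alpha retention threshold (default 0.05)
#' @return list with \code{apriori} (PathFit), \code{model} (pruned
#'   PathModel), \code{fit} (final PathFit), and \code{removed} (edge-label
#'   character vector in removal order)
#' @export
pruneToOptimal <- function(model, data, alpha = 0.05) {
  aprioriFit <- fitPathModel(model, data)
  cur <- model
  fit <- aprioriFit
  removed <- character()
  repeat {
    et <- fit@edges
    if (!nrow(et)) {
      warning("pruned to an edgeless model", call. = FALSE)
      break
    }
    cand <- et[et$p >= alpha, , drop = FALSE]
    if (!nrow(cand)) break
    ord <- order(-cand$p, abs(cand$beta),
                 paste(cand$from, cand$to))
    drop <- cand[ord[1L], ]
    removed <- c(removed, paste(drop$from, "->", drop$to))
    keep <- !(cur@edges[, 1L] == drop$from & cur@edges[, 2L] == drop$to)
    cur <- new("PathModel", variables = cur@variables,
               edges = cur@edges[keep, , drop = FALSE])
    if (!nrow(cur@edges)) {
      warning("pruned to an edgeless model", call. = FALSE)
      fit <- fitPathModel(cur, data)
      break
    }
    fit <- fitPathModel(cur, data)
  }
  list(apriori = aprioriFit, model = cur, fit = fit, removed = removed)
}

#' Default a-priori path model for group resistance
#'
#' Climate (MAT, MAP) drives soil total C, total N and the C/P ratio, which in
#' turn drive the functional group's resistance; the a-priori model also
#' includes the direct MAT/MAP -> resistance paths whose pruning the analysis
#' examines.
#'
#' @return a [PathModel-class] over \code{mat}, \code{map}, \code{total_c},
#'   \code{total_n}, \code{cp} and \code{resistance}
#' @export
aprioriPathModel <- function() {
  pathModel(c(
    "mat -> total_c", "map -> total_c",
    "mat -> total_n", "map -> total_n",
    "mat -> cp", "map -> cp",
    "total_c -> resistance", "total_n -> resistance", "cp -> resistance",
    "mat -> resistance", "map -> resistance"))
}

#' Path analysis of a functional group's resistance
#'
#' Builds the per-site data (climate, stoichiometry, group resistance to the
#' stressor), fits the a-priori model and prunes it to the optimal model.
#'
#' @param x a [StoichExperiment-class]
#' @param group functional group
#' @param stressor stressor label
#' @param model a-priori model (default [aprioriPathModel()])
#' @param alpha pruning threshold
#' @return as [pruneToOptimal()], plus the assembled \code{data}
#' @export
resistancePathAnalysis <- function(x, group, stressor,
                                   model = aprioriPathModel(), alpha = 0.05) {
  stopIfNot(group %in% .GROUPS, "unknown functional group")
  panel <- as.data.frame(rowData(x))
  genes <- panel$gene[panel$group == group]
  rec <- experimentResistance(x, stressor)
  y <- groupResistance(rec, genes)
  sites <- siteTable(x)
  d <- sites[match(names(y), sites$site_id), , drop = FALSE]
  d$resistance <- as.numeric(y)
  out <- pruneToOptimal(model, d, alpha = alpha)
  out$data <- d
  out
}
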