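#' Orwin-Wardle resistance index
#'
#' \deqn{RS = 1 - \frac{2|D_0|}{C_0 + |D_0|}}{RS = 1 - 2|D0| / (C0 + |D0|)}
#' where \eqn{C_0} is the control value of the response variable at the end of
#' the incubation and \eqn{D_0} is the treated-minus-control difference. RS is
#' +1 for complete resistance (no change), 0 for a 100\% change relative to
#' the control, and approaches (never attains) -1 as the change grows without
#' bound. Because the index is standardized by the control value it is
#' undefined for a zero control, which is an error here rather than -1.
#'
#' @param c0 control value(s), strictly positive
#' @param treated treated value(s), nonnegative
#' @return RS value(s) in (-1, 1]
#' @examples
#' resistanceIndex(100, 100)  # 1: no change
#' resistanceIndex(50, 100)   # 0: |D0| equals C0
#' @export
resistanceIndex <- function(c0, treated) {
  if (any(!is.finite(c0)) || any(c0 <= 0))
    stop("undefined control: the resistance index is standardized by the ",
         "control value, which must be > 0", call. = FALSE)
  stopIfNot(all(is.finite(treated)) && all(treated >= 0),
            "treated values must be finite and >= 0")
  d0 <- abs(treated - c0)
  1 - 2 * d0 / (c0 + d0)
}

#' Per-gene, per-site resistance records for one stressor
#'
#' Aligns a control and a treated abundance table on (site, gene) and computes
#' the resistance index for every pair. Key mismatches are an error listing
#' the missing keys; genes with a zero control are reported and excluded
#' rather than silently dropped.
#'
#' @param control genes x sites matrix (or long data.frame) of control
#'   abundances
#' @param treated matching matrix/data.frame of treated abundances
#' @param stressor stressor label attached to the records
#' @return data.frame with columns \code{site_id}, \code{gene},
#'   \code{stressor}, \code{c0}, \code{treated}, \code{rs}
#' @seealso [resistanceIndex()], [experimentResistance()]
#' @export
resistanceTable <- function(control, treated, stressor = "disturbance") {
  if (is.data.frame(control)) control <- longToMatrix(control, unique(control$treatment)[1L])
  if (is.data.frame(treated)) treated <- longToMatrix(treated, unique(treated$treatment)[1L])
  missC <- setdiff(colnames(treated), colnames(control))
  missT <- setdiff(colnames(control), colnames(treated))
  missG <- c(setdiff(rownames(control), rownames(treated)),
             setdiff(rownames(treated), rownames(control)))
  if (length(missC) || length(missT) || length(missG))
    stop("alignment error: ",
         if (length(missT)) paste0("site(s) missing in treated: ",
                                   paste(missT, collapse = ", "), "; "),
         if (length(missC)) paste0("site(s) missing in control: ",
                                   paste(missC, collapse = ", "), "; "),
         if (length(missG)) paste0("gene(s) not shared: ",
                                   paste(unique(missG), collapse = ", ")),
         call. = FALSE)
  treated <- treated[rownames(control), colnames(control), drop = FALSE]
  df <- data.frame(
    site_id = rep(colnames(control), each = nrow(control)),
    gene = rep(rownames(control), times = ncol(control)),
    stressor = stressor,
    c0 = as.vector(control),
    treated = as.vector(treated),
    stringsAsFactors = FALSE)
  bad <- df$c0 <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " record(s) with zero control abundance: ",
            paste(head(unique(df$gene[bad]), 5L), collapse = ", "),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$rs <- resistanceIndex(df$c0, df$treated)
  rownames(df) <- NULL
  df
}

#' Resistance records for every stressor of an experiment
#'
#' @param x a [StoichExperiment-class] containing the control and at least one
#'   stressor treatment
#' @param stressors stressor labels to use (default: all present)
#' @return data.frame of stacked resistance records (see [resistanceTable()])
#' @export
experimentResistance <- function(x, stressors = NULL) {
  stopIfNot(is(x, "StoichExperiment"), "x must be a StoichExperiment")
  present <- intersect(.STRESSORS, unique(colData(x)$treatment))
  stressors <- stressors %||% present
  stopIfNot(all(stressors %in% present),
            "requested stressor not present in the experiment")
  control <- abundanceMatrix(x, "control")
  do.call(rbind, lapply(stressors, function(s)
    resistanceTable(control, abundanceMatrix(x, s), s)))
}

#' Normalized functional-group abundance
#'
#' For each gene in a group, each sample's abundance is converted to its share
#' of the gene's total over samples, and the shares are averaged over the
#' group's genes:
#' \deqn{x' = \left[\sum_{g=1}^{n} x_{ig} / \sum_{i} x_{ig}\right] / n}
#' so the scores of any group sum to 1 across samples and are invariant to
#' rescaling any single gene.
#'
#' @param values samples x genes nonnegative matrix (sample ids as rownames)
#' @param groupGenes character vector of member-gene column names (default:
#'   all columns)
#' @return named numeric vector of per-sample scores, summing to 1
#' @examples
#' m <- cbind(g1 = c(1, 3), g2 = c(2, 2))
#' normalizeGroup(m)  # 0.375 0.625
#' @export
normalizeGroup <- function(values, groupGenes = colnames(values)) {
  stopIfNot(is.matrix(values) && nrow(values) >= 1L,
            "values must be a samples x genes matrix")
  stopIfNot(length(groupGenes) >= 1L, "at least one gene is required")
  miss <- setdiff(groupGenes, colnames(values))
  if (length(miss))
    stop("gene(s) absent from the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sub <- values[, groupGenes, drop = FALSE]
  if (any(sub < 0))
    stop("invalid input: abundances must be nonnegative", call. = FALSE)
  tot <- colSums(sub)
  if (any(tot == 0))
    stop("degenerate gene (all-zero across samples): ",
         paste(groupGenes[tot == 0], collapse = ", "), call. = FALSE)
  shares <- sweep(sub, 2L, tot, "/")
  score <- rowMeans(shares)
  names(score) <- rownames(values)
  score
}

#' Aggregate per-gene resistance to a functional-group score per site
#'
#' The default is the per-site arithmetic mean of the member genes' RS values.
#' Because RS can be negative while the share-based group normalization
#' presumes nonnegative values, an alternative \code{"eq2"} mode first shifts
#' RS by +1 and then applies the share-based normalization across sites.
#'
#' @param records resistance data.frame from [resistanceTable()] (one
#'   stressor)
#' @param groupGenes member genes; every site must cover all of them
#' @param mode \code{"mean"} (default) or \code{"eq2"}
#' @return named numeric vector of per-site group resistance scores
#' @export
groupResistance <- function(records, groupGenes, mode = c("mean", "eq2")) {
  mode <- match.arg(mode)
  sub <- records[records$gene %in% groupGenes, , drop = FALSE]
  sites <- unique(records$site_id)
  cnt <- table(sub$site_id)
  bad <- sites[!(sites %in% names(cnt)) | cnt[sites] < length(groupGenes)]
  if (length(bad)) {
    missing <- lapply(bad, function(s)
      setdiff(groupGenes, sub$gene[sub$site_id == s]))
    stop("incomplete gene coverage at site(s) ",
         paste(bad, collapse = ", "), "; missing: ",
         paste(unique(unlist(missing)), collapse = ", "), call. = FALSE)
  }
  if (mode == "mean") {
    agg <- tapply(sub$rs, sub$site_id, mean)
    return(setNames(as.numeric(agg[sites]), sites))
  }
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(groupGenes),
              dimnames = list(sites, groupGenes))
  m[cbind(match(sub$site_id, sites), match(sub$gene, groupGenes))] <-
    sub$rs + 1
  normalizeGroup(m)
}

# Dunn's rank-based post-hoc test with ties correction (two-sided normal
# p-values). Returns one row per group pair.
dunnTest <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    out$z[k] <- z
    out$p[k] <- 2 * pnorm(-abs(z))
  }
  out
}

#' Compare a gene's resistance across stressors
#'
#' Per gene, an omnibus Kruskal-Wallis test across the stressor RS
#' distributions, followed by Dunn's rank-based pairwise post-hoc test;
#' omnibus p-values are Benjamini-Hochberg corrected across genes. RS is
#' bounded and typically skewed, so rank tests are the default; a parametric
#' one-way ANOVA (with pairwise Welch t-tests) is available via
#' \code{method = "anova"}.
#'
#' @param records stacked resistance data.frame covering >= 2 stressors (see
#'   [experimentResistance()])
#' @param genes genes to test (default: all in \code{records})
#' @param method \code{"kruskal"} (default) or \code{"anova"}
#' @param alpha significance level for the asterisk flag
#' @return list with \code{omnibus} (gene, statistic, p, p_adj, signif) and
#'   \code{pairwise} (gene, group1, group2, statistic, p, p_adj within gene)
#' @export
compareStressors <- function(records, genes = NULL,
                             method = c("kruskal", "anova"), alpha = 0.05) {
  method <- match.arg(method)
  genes <- genes %||% unique(records$gene)
  stressors <- unique(records$stressor)
  if (length(stressors) < 2L)
    stop("invalid input: need at least two stressor groups", call. = FALSE)
  omni <- data.frame(gene = genes, statistic = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
  pw <- list()
  for (i in seq_along(genes)) {
    sub <- records[records$gene == genes[i], , drop = FALSE]
    cnt <- table(sub$stressor)
    if (length(cnt) < 2L || any(cnt < 2L))
      stop("invalid input: need >= 2 sites per stressor for gene ", genes[i],
           call. = FALSE)
    if (method == "kruskal") {
      kw <- kruskal.test(sub$rs, factor(sub$stressor))
      omni$statistic[i] <- unname(kw$statistic)
      omni$p[i] <- kw$p.value
      d <- dunnTest(sub$rs, sub$stressor)
      d <- data.frame(gene = genes[i], group1 = d$group1, group2 = d$group2,
                      statistic = d$z, p = d$p, stringsAsFactors = FALSE)
    } else {
      fit <- stats::oneway.test(rs ~ stressor, data = sub, var.equal = FALSE)
      omni$statistic[i] <- unname(fit$statistic)
      omni$p[i] <- fit$p.value
      prs <- utils::combn(sort(unique(sub$stressor)), 2L)
      d <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
        tt <- stats::t.test(sub$rs[sub$stressor == prs[1L, k]],
                            sub$rs[sub$stressor == prs[2L, k]])
        data.frame(gene = genes[i], group1 = prs[1L, k], group2 = prs[2L, k],
                   statistic = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
      }))
    }
    d$p_adj <- p.adjust(d$p, "BH")
    pw[[i]] <- d
  }
  omni$p_adj <- p.adjust(omni$p, "BH")
  omni$signif <- omni$p_adj < alpha
  list(omnibus = omni, pairwise = do.call(rbind, pw))
}
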