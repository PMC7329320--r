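#' Fit a qPCR standard curve
#'
#' Ordinary least squares of the quantification cycle (Cq) on log10 template
#' copies over a serial dilution of a known standard. The amplification
#' efficiency is derived from the slope as \eqn{E = 10^{-1/slope} - 1}; a
#' perfectly doubling reaction has slope -3.3219 and E = 1 (100\%).
#'
#' @param log10Copies log10 copy numbers of the dilution series (>= 3 values)
#' @param cq matching Cq values
#' @param gene gene name to attach to the curve
#' @return a [StandardCurve-class]
#' @examples
#' x <- 2:7
#' fitStandardCurve(x, -3.3219 * x + 38, "nifH")
#' @export
fitStandardCurve <- function(log10Copies, cq, gene = "gene") {
  stopIfNot(length(log10Copies) == length(cq),
            "log10Copies and cq must be paired")
  if (length(log10Copies) < 3L)
    stop("insufficient data: a standard curve needs at least 3 points",
         call. = FALSE)
  if (sd(log10Copies) == 0)
    stop("degenerate input: log10Copies has zero variance", call. = FALSE)
  fit <- lm(cq ~ log10Copies)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate input: fitted slope is not negative (Cq must decrease ",
         "with template amount)", call. = FALSE)
  ssTot <- sum((cq - mean(cq))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 1
  new("StandardCurve", gene = gene, slope = slope,
      intercept = unname(coef(fit)[1L]), r2 = min(max(r2, 0), 1),
      efficiency = 10^(-1 / slope) - 1)
}

#' Predicted Cq for a copy number under a standard curve
#'
#' @param copies template copy number (> 0)
#' @param curve a [StandardCurve-class]
#' @return Cq value(s)
#' @export
predictCq <- function(copies, curve) {
  stopIfNot(is(curve, "StandardCurve"), "curve must be a StandardCurve")
  stopIfNot(all(copies > 0), "copies must be positive")
  curve@intercept + curve@slope * log10(copies)
}

#' Back-calculate copies per g soil from a Cq value
#'
#' Inverts the standard curve (\code{copies = 10^((cq - intercept)/slope)}),
#' then scales by the dilution factor and normalizes by the extracted soil
#' mass. Cq values outside the calibration range are extrapolated with a
#' warning rather than rejected.
#'
#' @param cq observed quantification cycle(s)
#' @param curve a [StandardCurve-class]
#' @param dilutionFactor template dilution factor (default 1)
#' @param soilMassG grams of dry soil extracted (> 0)
#' @param cqRange optional calibration Cq range used for the extrapolation
#'   warning
#' @return copies per g dry soil
#' @examples
#' cv <- fitStandardCurve(2:7, -3.3219 * (2:7) + 38, "nifH")
#' quantifyCopies(cv@intercept, cv)  # one copy
#' @export
quantifyCopies <- function(cq, curve, dilutionFactor = 1, soilMassG = 1,
                           cqRange = NULL) {
  stopIfNot(is(curve, "StandardCurve"), "curve must be a StandardCurve")
  if (!is.numeric(soilMassG) || any(soilMassG <= 0))
    stop("invalid argument: soilMassG must be positive", call. = FALSE)
  if (!is.null(cqRange) && (any(cq < min(cqRange)) || any(cq > max(cqRange))))
    warning("Cq outside the standard-curve range; extrapolating", call. = FALSE)
  10^((cq - curve@intercept) / curve@slope) * dilutionFactor / soilMassG
}

#' Efficiency-correct an abundance table
#'
#' Rescales each gene's abundances by \code{(2 / (1 + E))^CqRef}, where E is
#' the gene's amplification efficiency and CqRef is the gene's mean observed
#' Cq equivalent under its curve: genes amplifying slower than doubling are
#' revised upward. Correction with E = 1 is the identity. This rank-preserving
#' ratio-to-ideal convention can be switched off with
#' \code{method = "none"}.
#'
#' @param abundances genes x samples matrix of copies per g
#' @param curves named list of [StandardCurve-class] objects covering every
#'   gene in the table
#' @param method \code{"ratio_to_ideal"} (default) or \code{"none"}
#' @return corrected matrix of the same shape
#' @export
efficiencyCorrect <- function(abundances, curves,
                              method = c("ratio_to_ideal", "none")) {
  method <- match.arg(method)
  stopIfNot(is.matrix(abundances) && !is.null(rownames(abundances)),
            "abundances must be a genes x samples matrix with rownames")
  if (method == "none") return(abundances)
  miss <- setdiff(rownames(abundances), names(curves))
  if (length(miss))
    stop("missing curve for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- abundances
  for (g in rownames(abundances)) {
    cv <- curves[[g]]
    stopIfNot(is(cv, "StandardCurve"), "curves must contain StandardCurve objects")
    cqRef <- mean(predictCq(abundances[g, ], cv))
    out[g, ] <- abundances[g, ] * (2 / (1 + cv@efficiency))^cqRef
  }
  out
}

#' Read / write standard-curve tables
#'
#' Plain TSV with columns \code{gene}, \code{slope}, \code{intercept},
#' \code{r2}; efficiency is recomputed from the slope on read.
#'
#' @param curves named list of [StandardCurve-class]
#' @param path file path
#' @return \code{readStandardCurves} returns a named list of
#'   [StandardCurve-class] objects.
#' @export
writeStandardCurves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(gene = cv@gene, slope = cv@slope, intercept = cv@intercept,
               r2 = cv@r2)))
  writeNumericTSV(df, path)
  invisible(path)
}

#' @rdname writeStandardCurves
#' @export
readStandardCurves <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("gene", "slope", "intercept", "r2") %in% colnames(df)),
            "curve file must have gene, slope, intercept, r2 columns")
  out <- lapply(seq_len(nrow(df)), function(i)
    new("StandardCurve", gene = df$gene[i], slope = df$slope[i],
        intercept = df$intercept[i], r2 = df$r2[i],
        efficiency = 10^(-1 / df$slope[i]) - 1))
  names(out) <- df$gene
  out
}
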