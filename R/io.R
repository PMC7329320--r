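# Full-precision decimal rendering so numeric TSV round-trips are bit-exact.
writeNumericTSV <- function(df, path, sep = "\t") {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-abundance table (long or wide layout, auto-detected)
#'
#' Long layout has columns \code{site_id}, \code{gene}, \code{treatment},
#' \code{copies_per_g}; wide layout has \code{site_id} (and optionally
#' \code{treatment}) plus one numeric column per gene. The layout is detected
#' from the header. Duplicate (site, gene, treatment) keys and non-numeric
#' abundances are rejected with informative errors.
#'
#' @param path file path
#' @param sep field delimiter (default tab; use "," for CSV)
#' @param dec decimal mark
#' @return long-format data.frame with columns \code{site_id}, \code{gene},
#'   \code{treatment}, \code{copies_per_g}
#' @export
readAbundanceTable <- function(path, sep = "\t", dec = ".") {
  raw <- read.delim(path, sep = sep, dec = dec, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  stopIfNot("site_id" %in% colnames(raw),
            "abundance table must have a site_id column")
  if ("gene" %in% colnames(raw)) {           # long layout
    stopIfNot("copies_per_g" %in% colnames(raw),
              "long layout requires a copies_per_g column")
    if (!"treatment" %in% colnames(raw)) raw$treatment <- "control"
    vals <- suppressWarnings(as.numeric(raw$copies_per_g))
    bad <- which(is.na(vals) & !is.na(raw$copies_per_g))
    if (length(bad))
      stop("parse error: non-numeric abundance at data row ", bad[1L],
           " ('", raw$copies_per_g[bad[1L]], "')", call. = FALSE)
    df <- data.frame(site_id = raw$site_id, gene = raw$gene,
                     treatment = raw$treatment, copies_per_g = vals,
                     stringsAsFactors = FALSE)
  } else {                                    # wide layout
    if (!"treatment" %in% colnames(raw)) raw$treatment <- "control"
    geneCols <- setdiff(colnames(raw), c("site_id", "treatment", "province"))
    stopIfNot(length(geneCols) >= 1L, "wide layout has no gene columns")
    pieces <- lapply(geneCols, function(g) {
      vals <- suppressWarnings(as.numeric(raw[[g]]))
      bad <- which(is.na(vals) & !is.na(raw[[g]]))
      if (length(bad))
        stop("parse error: non-numeric abundance for gene ", g,
             " at data row ", bad[1L], call. = FALSE)
      data.frame(site_id = raw$site_id, gene = g, treatment = raw$treatment,
                 copies_per_g = vals, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
  }
  key <- paste(df$site_id, df$gene, df$treatment, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate key (site_id, gene, treatment): ",
         key[duplicated(key)][1L], call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a gene-abundance table as TSV
#'
#' @param x long-format abundance data.frame (as returned by
#'   [readAbundanceTable()]) or a [StoichExperiment-class]
#' @param path output path
#' @param layout \code{"long"} (default) or \code{"wide"} (one column per
#'   gene; only for a single treatment or with a treatment column)
#' @param sep field delimiter
#' @return the path, invisibly
#' @export
writeAbundanceTable <- function(x, path, layout = c("long", "wide"),
                                sep = "\t") {
  layout <- match.arg(layout)
  if (is(x, "StoichExperiment")) x <- abundanceLong(x)
  stopIfNot(is.data.frame(x) &&
              all(c("site_id", "gene", "treatment", "copies_per_g") %in%
                    colnames(x)),
            "x must be a long abundance data.frame or StoichExperiment")
  if (layout == "long") {
    writeNumericTSV(x[, c("site_id", "gene", "treatment", "copies_per_g")],
                    path, sep = sep)
  } else {
    genes <- unique(x$gene)
    keys <- unique(x[, c("site_id", "treatment")])
    wide <- keys
    for (g in genes) {
      sub <- x[x$gene == g, ]
      idx <- match(paste(keys$site_id, keys$treatment),
                   paste(sub$site_id, sub$treatment))
      wide[[g]] <- sub$copies_per_g[idx]
    }
    writeNumericTSV(wide, path, sep = sep)
  }
  invisible(path)
}

#' Long-format abundance table of an experiment
#'
#' @param x a [StoichExperiment-class]
#' @return data.frame with columns \code{site_id}, \code{gene},
#'   \code{treatment}, \code{copies_per_g}
#' @export
abundanceLong <- function(x) {
  stopIfNot(is(x, "StoichExperiment"), "x must be a StoichExperiment")
  m <- assay(x, "copies")
  cd <- colData(x)
  data.frame(site_id = rep(cd$site_id, each = nrow(m)),
             gene = rep(rownames(m), times = ncol(m)),
             treatment = rep(cd$treatment, each = nrow(m)),
             copies_per_g = as.vector(m), stringsAsFactors = FALSE)
}

# Long data.frame -> genes x sites matrix for one treatment.
longToMatrix <- function(df, treatment = "control") {
  sub <- df[df$treatment == treatment, , drop = FALSE]
  stopIfNot(nrow(sub) > 0L, paste("no rows for treatment", treatment))
  genes <- unique(sub$gene)
  sites <- unique(sub$site_id)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(sites),
              dimnames = list(genes, sites))
  m[cbind(match(sub$gene, genes), match(sub$site_id, sites))] <- sub$copies_per_g
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("incomplete abundance table: no value for gene ", genes[miss[1L]],
         " at site ", sites[miss[2L]], call. = FALSE)
  }
  m
}

#' Read / write a site-covariate table as TSV
#'
#' @param sites site table from [generateSites()]
#' @param path file path
#' @return \code{readSiteTable} returns the site data.frame with the ratio
#'   identities validated.
#' @export
writeSiteTable <- function(sites, path) {
  writeNumericTSV(sites, path)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", .SITE_PREDICTORS)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("site table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- abs(df$cn - df$total_c / df$total_n) > 1e-6 |
    abs(df$cp - df$total_c / df$total_p) > 1e-6 |
    abs(df$np - df$total_n / df$total_p) > 1e-6
  if (any(bad))
    stop("site table ratio identity violated at row ", which(bad)[1L],
         call. = FALSE)
  df
}
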