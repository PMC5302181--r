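#' @include comet-fit.R
NULL

readDelimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistic file with a header
#' and optional \code{#} comment lines. Columns \code{snp}, \code{beta} and
#' \code{se} are required; \code{chr}, \code{pos}, \code{p} and \code{n} are
#' carried through when present (coordinates are 1-based and never required,
#' as all computation is keyed on SNP id). Rows with non-numeric or missing
#' beta/se, or non-positive se, are rejected with a logged count; duplicate
#' SNP ids are an error.
#'
#' @param path file path.
#' @param verbose report rejected-row counts.
#' @return validated summary-statistic \code{data.frame}.
#' @export
readSummaryStats <- function(path, verbose = TRUE) {
  df <- readDelimited(path)
  need <- c("snp", "beta", "se")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary-statistic file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("summary-statistic file ", path, " has a header but no rows")
    df$snp <- character(0); df$beta <- numeric(0); df$se <- numeric(0)
    return(df)
  }
  df$snp <- as.character(df$snp)
  df$beta <- suppressWarnings(as.numeric(df$beta))
  df$se <- suppressWarnings(as.numeric(df$se))
  bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0
  if (any(bad)) {
    if (verbose)
      message(sum(bad), " row(s) with invalid beta/se rejected from ", path)
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$snp))
    stop("duplicated SNP id(s) in ", path, ": ",
         paste(utils::head(unique(df$snp[duplicated(df$snp)]), 5),
               collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write summary statistics
#'
#' Tab-delimited writer matching the [readSummaryStats()] contract.
#'
#' @param stats summary-statistic \code{data.frame}.
#' @param path output path.
#' @export
writeSummaryStats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binary annotation table
#'
#' Accepts either the wide format (a \code{snp} column plus one 0/1 column
#' per category) or the long format (two columns: \code{snp},
#' \code{category}), auto-detected. Returns a binary matrix; when
#' \code{snpOrder} is given, rows are aligned to that order, SNPs absent
#' from the file get all-zero rows (with a logged count) and SNPs unknown to
#' \code{snpOrder} are dropped with a warning.
#'
#' @param path file path.
#' @param snpOrder optional character vector fixing the row order.
#' @param verbose report alignment counts.
#' @return binary matrix with SNP-id rownames.
#' @export
readAnnotations <- function(path, snpOrder = NULL, verbose = TRUE) {
  df <- readDelimited(path)
  if (ncol(df) < 2L) stop("annotation file needs at least two columns")
  long <- ncol(df) == 2L && !is.numeric(df[[2]])
  if (long) {
    snp <- as.character(df[[1]])
    cat <- as.character(df[[2]])
    lev <- sort(unique(cat))
    ids <- unique(snp)
    X <- matrix(0, length(ids), length(lev), dimnames = list(ids, lev))
    X[cbind(match(snp, ids), match(cat, lev))] <- 1
  } else {
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicated SNP ids in ", path)
    X <- as.matrix(df[, -1, drop = FALSE])
    if (any(!X %in% c(0, 1)))
      stop("annotation file ", path, " has non-binary entries")
    rownames(X) <- ids
  }
  storage.mode(X) <- "double"
  if (is.null(snpOrder)) return(X)
  unknown <- setdiff(rownames(X), snpOrder)
  if (length(unknown))
    warning(length(unknown), " annotated SNP(s) not in the analysis set; ",
            "ignored")
  alignAnnotations(X, snpOrder, verbose = verbose)
}

#' Read a pairwise LD table
#'
#' Three-column delimited table (snp_a, snp_b, r2); pairs absent from the
#' table are treated as independent by [greedyClump()].
#'
#' @param path file path.
#' @return \code{data.frame} with columns \code{snpA}, \code{snpB},
#'   \code{r2}.
#' @export
readLDPairs <- function(path) {
  df <- readDelimited(path)
  if (ncol(df) < 3L) stop("LD file needs columns snp_a, snp_b, r2")
  out <- data.frame(snpA = as.character(df[[1]]),
                    snpB = as.character(df[[2]]),
                    r2 = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  if (any(!is.finite(out$r2)) || any(out$r2 < 0) || any(out$r2 > 1))
    stop("r2 values in ", path, " must lie in [0, 1]")
  out
}

#' Read a per-SNP MAF table
#'
#' Two-column delimited table (snp_id, maf).
#'
#' @param path file path.
#' @return named numeric vector of MAFs.
#' @export
readMAFTable <- function(path) {
  df <- readDelimited(path)
  if (ncol(df) < 2L) stop("MAF file needs columns snp, maf")
  maf <- as.numeric(df[[2]])
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf >= 1))
    stop("MAF values in ", path, " must lie strictly in (0, 1)")
  stats::setNames(maf, as.character(df[[1]]))
}

fmt6 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6,
                                                   format = "g"))

#' Write analysis results
#'
#' Emits two files into \code{dir}: \code{results.tsv}, the machine-readable
#' long-format table (columns model, term, estimate, se, z, p_one_sided,
#' p_two_sided, count; floating point at 6 significant digits), and
#' \code{results_pretty.txt}, a per-model block layout with one column per
#' covariate (excluded covariates show estimate 0, p 1 and SE NA).
#'
#' @param fit a [CometFit-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCometResults <- function(fit, dir) {
  stopifnot(is(fit, "CometFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- fit@results
  tsv <- file.path(dir, "results.tsv")
  num <- vapply(res, is.numeric, logical(1))
  resOut <- res
  resOut[num] <- lapply(res[num], fmt6)
  utils::write.table(resOut, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pretty <- file.path(dir, "results_pretty.txt")
  con <- file(pretty, "w")
  on.exit(close(con))
  for (mod in unique(res$model)) {
    block <- res[res$model == mod, ]
    writeLines(paste0("== ", mod, " =="), con)
    mat <- rbind(estimate = fmt6(block$estimate), se = fmt6(block$se),
                 p_one_sided = fmt6(block$p_one_sided),
                 p_two_sided = fmt6(block$p_two_sided),
                 count = fmt6(block$count))
    colnames(mat) <- block$term
    utils::write.table(cbind(quantity = rownames(mat), mat), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("", con)
  }
  invisible(c(tsv, pretty))
}

#' Write calibration outputs
#'
#' Emits \code{calibration.tsv} (method, covariate, nReps, rate, ciLo, ciHi,
#' lambda, lambdaPos) and one two-column QQ file per covariate
#' (\code{qq_<covariate>.tsv}) holding the overlap-model standardized
#' estimates against standard-normal quantiles.
#'
#' @param cal a [CalibrationResult-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeCalibration <- function(cal, dir) {
  stopifnot(is(cal, "CalibrationResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "calibration.tsv")
  utils::write.table(cal@summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- tsv
  for (q in colnames(cal@overlapZ)) {
    z <- cal@overlapZ[, q]
    if (all(is.na(z))) next
    f <- file.path(dir, paste0("qq_", q, ".tsv"))
    utils::write.table(qqPoints(z), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
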