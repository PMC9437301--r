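#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. All remaining cells must be
#' numeric and finite.
#'
#' @param path Path to a TSV file.
#' @param unit Optional unit tag to attach (`"FPKM"`, `"TPM"` or
#'   `"log2TPM1"`). The tag is carried as the `"unit"` attribute and checked
#'   by downstream unit conversions.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, unit = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("expression file must have a gene column plus >=1 sample column")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric expression column(s): ", paste(names(vals)[!num], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  check_expression(m)
  if (!is.null(unit)) attr(m, "unit") <- match.arg(unit, c("FPKM", "TPM", "log2TPM1"))
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(matrix, path) {
  check_expression(matrix)
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated gene id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Convert FPKM to TPM
#'
#' Per sample, `TPM_g = FPKM_g / sum_g(FPKM_g) * 1e6`, so every column of the
#' result sums to one million.
#'
#' @param matrix Gene-by-sample matrix of FPKM values (non-negative).
#' @return Matrix of TPM values with unit tag `"TPM"`.
#' @export
fpkm_to_tpm <- function(matrix) {
  check_expression(matrix)
  u <- attr(matrix, "unit")
  if (!is.null(u) && u != "FPKM") stop("fpkm_to_tpm expects unit 'FPKM', got '", u, "'")
  cs <- colSums(matrix)
  bad <- colnames(matrix)[cs <= 0]
  if (length(bad)) stop("zero-sum sample(s): ", paste(bad, collapse = ", "))
  out <- sweep(matrix, 2L, cs, "/") * 1e6
  attr(out, "unit") <- "TPM"
  out
}

#' Log2(x + 1) transform
#'
#' Column sums are no longer 1e6 after this transform; downstream clustering,
#' differential expression and PCA in this package all operate on this scale.
#'
#' @param matrix Non-negative expression matrix (typically TPM).
#' @return `log2(matrix + 1)` with unit tag `"log2TPM1"`.
#' @export
log_transform <- function(matrix) {
  check_expression(matrix)
  if (any(matrix < 0)) stop("log_transform requires non-negative values")
  out <- log2(matrix + 1)
  attr(out, "unit") <- "log2TPM1"
  out
}

#' Merge expression cohorts on their common gene universe
#'
#' Genes are intersected across cohorts (exact string match), samples lacking
#' overall-survival time or event are dropped with a message, and each sample
#' receives a batch label equal to its cohort index. Sample identifiers must
#' be globally unique.
#'
#' @param cohorts List of `list(expr = matrix, clinical = data.frame)` pairs,
#'   at least two. Clinical tables need columns `sample`, `time`, `event`.
#' @return `list(expr, clinical)`; `clinical$batch` holds the cohort index.
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2L) stop("need at least 2 cohorts")
  units <- lapply(cohorts, function(co) attr(co$expr, "unit"))
  units <- unique(unlist(units[!vapply(units, is.null, logical(1L))]))
  if (length(units) > 1L) stop("cohorts have incompatible unit tags: ",
                               paste(units, collapse = ", "))
  genes <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$expr)))
  if (!length(genes)) stop("empty gene intersection across cohorts")
  all_samples <- unlist(lapply(cohorts, function(co) colnames(co$expr)))
  if (anyDuplicated(all_samples)) {
    stop("sample id collision across cohorts: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  exprs <- list(); clins <- list(); n_dropped <- 0L
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    cl <- co$clinical
    stopifnot(all(c("sample", "time", "event") %in% names(cl)))
    keep <- !is.na(cl$time) & !is.na(cl$event)
    n_dropped <- n_dropped + sum(!keep)
    cl <- cl[keep, , drop = FALSE]
    cl$batch <- i
    clins[[i]] <- cl
    exprs[[i]] <- co$expr[genes, cl$sample, drop = FALSE]
  }
  if (n_dropped > 0L) {
    message(n_dropped, " sample", if (n_dropped == 1L) "" else "s",
            " excluded (incomplete survival data)")
  }
  clinical <- do.call(rbind_fill, clins)
  expr <- do.call(cbind, exprs)
  if (length(units)) attr(expr, "unit") <- units
  check_clinical(clinical)
  list(expr = expr, clinical = clinical)
}

# rbind data.frames whose optional covariate columns may differ
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, c(dfs, list(make.row.names = FALSE)))
}

check_clinical <- function(cl) {
  stopifnot(is.data.frame(cl), all(c("sample", "time", "event") %in% names(cl)))
  if (anyDuplicated(cl$sample)) stop("duplicated sample ids in clinical table")
  if (any(cl$time <= 0, na.rm = TRUE)) stop("survival times must be > 0")
  if (!all(cl$event %in% c(0, 1) | is.na(cl$event))) stop("event flag must be 0/1")
  invisible(cl)
}

#' Baseline clinical summary (counts and percentages)
#'
#' For each requested covariate, counts every observed category and reports
#' the percentage of non-missing samples, rounded to one decimal — the usual
#' "N (%)" baseline table. Missing values are excluded from that covariate's
#' denominator.
#'
#' @param clinical Clinical data.frame.
#' @param covariates Character vector of column names to summarise.
#' @return data.frame with columns `covariate`, `level`, `n`, `pct`.
#' @export
summarize_clinical <- function(clinical, covariates) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov)) stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  out <- lapply(covariates, function(cv) {
    x <- clinical[[cv]]
    x <- x[!is.na(x)]
    tab <- table(x)
    data.frame(covariate = cv, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / sum(tab), 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read gene sets in GMT format
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated fields
#' `name`, `description`, then one or more gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids, with a
#'   `"description"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 3L
  if (any(short)) stop("GMT line(s) with fewer than 3 fields: line ",
                       paste(which(short), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene set name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), nm)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors; an optional `"description"`
#'   attribute supplies the second GMT field (default `"na"`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  if (any(vapply(sets, length, integer(1L)) == 0L)) stop("empty gene set")
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
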