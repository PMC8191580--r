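#' Expression matrix container
#'
#' Light-weight container for a genes x samples numeric matrix together
#' with the space the values live in. All functions in the package orient
#' expression as genes in rows and samples in columns.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene symbols) and colnames (sample identifiers).
#' @param space one of `"raw"` (non-negative linear scale, e.g. RSEM),
#'   `"log"` (already log-scale, e.g. microarray intensities) or
#'   `"zscore"` (per-gene standardized).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `space`.
#' @export
expression_matrix <- function(values, space = c("raw", "log", "zscore")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (genes) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (space == "zscore") {
    mu <- rowMeans(values)
    sdev <- apply(values, 1L, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sdev - 1) > 1e-6))
      stop("space = \"zscore\" but rows are not standardized")
  }
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), space = space),
    class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, space = %s\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' Read a gene x sample expression matrix from TSV or GCT
#'
#' The first column carries gene symbols; remaining columns are numeric,
#' one per sample. GCT files (version line + dimension line, `Name` and
#' `Description` columns) are detected by extension or by the `#1.2`
#' magic. Duplicate gene rows (e.g. multiple probes for one symbol) are
#' collapsed by their arithmetic mean, keeping first-occurrence order.
#'
#' @param path file path.
#' @param format `"auto"` (default, sniffed), `"tsv"` or `"gct"`.
#' @param space expression space of the stored values, default `"raw"`.
#' @return [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            space = "raw") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE) ||
                  startsWith(first, "#1.")) "gct" else "tsv"
  }
  skip <- 0L
  drop_desc <- FALSE
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !startsWith(hdr[[1L]], "#1."))
      stop("malformed GCT header in ", path)
    skip <- 2L
    drop_desc <- TRUE
  }
  df <- utils::read.delim(path, skip = skip, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("malformed header: need gene column plus samples")
  if (drop_desc && ncol(df) >= 2L) df[[2L]] <- NULL
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]  # before extraction: `[.data.frame` mangles dups
  df <- df[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (gene %s), column %s",
                   bad[[1L]], genes[bad[[1L]]], samples[[j]]))
    if (anyNA(v))
      stop(sprintf("missing value at row %d, column %s",
                   which(is.na(v))[[1L]], samples[[j]]))
    vals[, j] <- v
  }
  # collapse duplicated gene symbols by mean, first-occurrence order
  if (anyDuplicated(genes)) {
    keep <- !duplicated(genes)
    idx <- match(genes, genes[keep])
    coll <- matrix(0, nrow = sum(keep), ncol = ncol(vals))
    cnt <- tabulate(idx, nbins = sum(keep))
    for (j in seq_len(ncol(vals)))
      coll[, j] <- rowsum(vals[, j], idx, reorder = TRUE)[, 1L] / cnt
    vals <- coll
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  expression_matrix(vals, space = space)
}

#' Write an expression matrix as TSV (full precision)
#'
#' @param expr [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", expr$sample_ids), collapse = "\t"), con)
  body <- apply(expr$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(expr$gene_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' description is discarded, duplicate genes within a set are removed,
#' empty lines are skipped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(setNames(list(), character(0)),
                     class = "gene_set_collection"))
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                   i, length(f)))
    nms[[i]] <- f[[1L]]
    genes <- unique(f[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d: set %s is empty", i, f[[1L]]))
    sets[[i]] <- genes
  }
  structure(setNames(sets, nms), class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled), default `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[[i]], description,
            sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects a TSV with a `sample_id` column plus `time` (non-negative) and
#' `event` (0 = censored, 1 = event); optional covariate columns (age,
#' sex, stage, breslow, response, ...) are kept as-is.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  if (any(df$time < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(df$event %in% c(0, 1, NA)))
    stop("event must be 0 (censored) or 1 (event)")
  df
}
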