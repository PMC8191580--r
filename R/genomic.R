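#' Copy-number variation burden of one sample
#'
#' `sum_j |log2(c_j / 2)| * f_j / N` over aberrant fragments, where
#' `c_j` is the fragment copy number, `f_j` its length in bases and `N`
#' the genome size. A fully diploid profile has burden 0; fragments not
#' listed are treated as diploid and contribute nothing. Zero (or
#' negative) copy numbers are clamped to 0.5 before the log with a
#' warning, to avoid an infinite term for homozygous deletions.
#'
#' @param copy_number numeric vector of fragment copy numbers.
#' @param size numeric vector of fragment lengths in bases.
#' @param genome_size genome size N in bases, default 3.1e9 (human).
#' @return non-negative scalar burden.
#' @export
cnv_burden <- function(copy_number, size, genome_size = 3.1e9) {
  if (length(copy_number) != length(size))
    stop("copy_number and size must have equal length")
  if (!length(copy_number)) {
    message("empty fragment list; CNV burden is 0")
    return(0)
  }
  if (any(size <= 0)) stop("fragment sizes must be positive")
  if (sum(size) > genome_size)
    stop("total fragment size exceeds genome size")
  if (any(copy_number <= 0)) {
    warning("copy number <= 0 clamped to 0.5 before log2")
    copy_number <- pmax(copy_number, 0.5)
  }
  sum(abs(log2(copy_number / 2)) * size) / genome_size
}

#' CNV burden per sample from a segment table
#'
#' @param segments data.frame with columns `sample_id`, `start`, `end`
#'   (half-open, fragment length = end - start) and `copy_number`;
#'   alternatively a `size` column may be given directly.
#' @param genome_size genome size in bases.
#' @return named numeric vector, sample id -> burden.
#' @export
cnv_burden_table <- function(segments, genome_size = 3.1e9) {
  if (!"size" %in% colnames(segments)) {
    if (!all(c("start", "end") %in% colnames(segments)))
      stop("segment table needs `size` or `start`/`end` columns")
    segments$size <- segments$end - segments$start
  }
  need <- c("sample_id", "size", "copy_number")
  miss <- setdiff(need, colnames(segments))
  if (length(miss)) stop("segment table missing: ", paste(miss, collapse = ", "))
  vapply(split(segments, segments$sample_id), function(d)
    cnv_burden(d$copy_number, d$size, genome_size), 0)
}

# MAF variant classifications counted as non-silent
.nonsilent_default <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Site", "Frame_Shift_Ins", "Frame_Shift_Del",
  "In_Frame_Ins", "In_Frame_Del", "Translation_Start_Site")

.silent_default <- c(
  "Silent", "3'UTR", "5'UTR", "Intron", "RNA", "IGR", "3'Flank",
  "5'Flank", "Splice_Region", "lincRNA", "Targeted_Region")

#' Tumor mutation burden from a MAF-like table
#'
#' TMB is the count of non-silent somatic mutations per sample. Records
#' whose classification is recognized as silent are excluded quietly;
#' records with an unknown classification are excluded with a warning.
#'
#' @param maf data.frame with columns `Tumor_Sample_Barcode` (or
#'   `sample_id`) and `Variant_Classification`.
#' @param samples optional character vector of sample ids to report;
#'   samples absent from the table get count 0.
#' @param nonsilent character vector of classifications counted.
#' @return named integer vector, sample id -> non-silent count.
#' @export
tmb <- function(maf, samples = NULL, nonsilent = .nonsilent_default) {
  id_col <- intersect(c("Tumor_Sample_Barcode", "sample_id"), colnames(maf))
  if (!length(id_col)) stop("MAF table needs Tumor_Sample_Barcode or sample_id")
  if (!"Variant_Classification" %in% colnames(maf))
    stop("MAF table needs a Variant_Classification column")
  ids <- as.character(maf[[id_col[[1L]]]])
  cls <- as.character(maf$Variant_Classification)
  unknown <- setdiff(unique(cls), c(nonsilent, .silent_default))
  if (length(unknown))
    warning("unknown variant classification(s) excluded: ",
            paste(unknown, collapse = ", "))
  keep <- cls %in% nonsilent
  if (is.null(samples)) samples <- unique(ids)
  counts <- table(factor(ids[keep], levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Cytolytic activity (CYT) index
#'
#' Geometric mean of GZMA and PRF1 expression with a +1 pseudo-count,
#' per sample: `sqrt((GZMA + 1) * (PRF1 + 1))`.
#'
#' @param expr [expression_matrix()] in raw space with GZMA and PRF1
#'   rows present.
#' @return named numeric vector, sample id -> CYT index.
#' @export
cyt_index <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  for (g in c("GZMA", "PRF1"))
    if (!g %in% expr$gene_ids) stop("gene missing from matrix: ", g)
  sqrt((expr$values["GZMA", ] + 1) * (expr$values["PRF1", ] + 1))
}

#' Correlate a signature score with a per-sample feature
#'
#' Pairwise-complete rank (default) or product-moment correlation with
#' a two-sided p-value. Samples are matched by name when both vectors
#' are named.
#'
#' @param scores named (or plain) numeric vector.
#' @param feature numeric vector, same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `rho` and `p`.
#' @export
correlate_scores <- function(scores, feature,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(names(scores)) && !is.null(names(feature))) {
    shared <- intersect(names(scores), names(feature))
    scores <- scores[shared]
    feature <- feature[shared]
  }
  ok <- is.finite(scores) & is.finite(feature)
  scores <- scores[ok]; feature <- feature[ok]
  if (length(scores) < 3L) stop("need >= 3 paired samples")
  if (length(unique(scores)) < 2L || length(unique(feature)) < 2L)
    stop("constant vector; correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(scores, feature, method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
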