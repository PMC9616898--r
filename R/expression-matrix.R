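#' Expression matrix container
#'
#' Features-by-samples numeric matrix with a declared unit and an optional
#' feature-to-gene mapping. Units:
#' \describe{
#'   \item{count}{non-negative raw abundances;}
#'   \item{TPM}{transcripts per million — every sample column sums to 1e6
#'     (relative tolerance 1e-6; all-zero columns are tolerated);}
#'   \item{fraction}{per-gene isoform relative frequencies in \[0,1\] —
#'     features of one gene sum to 1 in every sample where the gene is
#'     expressed; samples where the gene is silent carry `NA`.}
#' }
#' `NA` values are only permitted for unit `"fraction"` (an unexpressed gene
#' has no defined isoform frequencies); they propagate as missing and are
#' never treated as zero.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param unit `"count"`, `"TPM"` or `"fraction"`.
#' @param gene_of named character vector mapping feature id -> gene id, or
#'   `NULL` for gene-level tables.
#' @param feature_level `"transcript"` or `"gene"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("count", "TPM", "fraction"),
                              gene_of = NULL,
                              feature_level = c("transcript", "gene")) {
  unit <- match.arg(unit)
  feature_level <- match.arg(feature_level)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (unit != "fraction" && anyNA(values))
    stop("missing values are not allowed in a ", unit, " matrix")
  if (any(values < 0, na.rm = TRUE))
    stop("negative expression values are not allowed")
  if (!is.null(gene_of)) {
    missing_map <- setdiff(rownames(values), names(gene_of))
    if (length(missing_map))
      stop("features without a gene mapping: ",
           paste(utils::head(missing_map, 5L), collapse = ", "))
    gene_of <- gene_of[rownames(values)]
  }
  if (unit == "TPM") {
    cs <- colSums(values)
    bad <- cs > 0 & abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad))
      stop("TPM columns must sum to 1e6; offending sample(s): ",
           paste(colnames(values)[bad], collapse = ", "))
  }
  if (unit == "fraction") {
    if (any(values > 1 + 1e-9, na.rm = TRUE))
      stop("fractions must lie in [0, 1]")
    if (is.null(gene_of))
      stop("a fraction matrix requires a feature-to-gene mapping")
  }
  structure(list(values = values, unit = unit, gene_of = gene_of,
                 feature_level = feature_level),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d %s(s) x %d sample(s), unit = %s\n",
              nrow(x$values), x$feature_level, ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids; the first column is the feature id
#' (`transcript_id` or `gene_id`) and, for transcript-level tables, the
#' second column is `gene_id`. Duplicate ids, ragged rows, negative values
#' and explicit missing values are all rejected.
#'
#' @param path TSV file path.
#' @param unit declared unit of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("count", "TPM", "fraction")) {
  unit <- match.arg(unit)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged TSV: rows have differing field counts (lines ",
         paste(utils::head(which(nf != nf[1L]), 3L), collapse = ", "), ")")
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  has_gene_col <- ncol(df) >= 2L && names(df)[2L] == "gene_id"
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  first_sample <- if (has_gene_col) 3L else 2L
  vals <- as.matrix(df[, first_sample:ncol(df), drop = FALSE])
  if (anyNA(vals))
    stop("missing values are not allowed in an expression TSV")
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", path)
  if (any(vals < 0))
    stop("negative expression values are not allowed")
  rownames(vals) <- ids
  gene_of <- NULL
  level <- "gene"
  if (has_gene_col) {
    gene_of <- stats::setNames(as.character(df[[2L]]), ids)
    level <- "transcript"
  }
  expression_matrix(vals, unit = unit, gene_of = gene_of,
                    feature_level = level)
}

#' Write an expression matrix to TSV
#'
#' Column order is fixed: feature id, gene id (transcript level only), then
#' samples in stored order. Deterministic for identical inputs.
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  id_col <- if (em$feature_level == "transcript") "transcript_id" else "gene_id"
  df <- data.frame(id = rownames(em$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- id_col
  if (!is.null(em$gene_of) && em$feature_level == "transcript")
    df$gene_id <- unname(em$gene_of)
  df <- cbind(df, as.data.frame(em$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
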