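#' TPM normalization of a count matrix
#'
#' Per sample, each feature's count is divided by its effective length in bp
#' and the length-normalized rates are rescaled to sum to one million:
#' \deqn{TPM_i = \frac{c_i/\ell_i}{\sum_j c_j/\ell_j} \times 10^6.}
#' An all-zero sample stays all-zero with a warning. TPM is invariant to
#' per-sample scaling of counts, so library size cancels.
#'
#' @param counts an [expression_matrix()] with unit `"count"`.
#' @param effective_lengths named numeric vector, feature id -> length in bp
#'   (>= 1). Every feature in `counts` must have a length.
#' @return an [expression_matrix()] with unit `"TPM"`.
#' @export
tpm_normalize <- function(counts, effective_lengths) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count")
    stop("tpm_normalize expects a count matrix, got unit '", counts$unit, "'")
  missing_len <- setdiff(rownames(counts$values), names(effective_lengths))
  if (length(missing_len))
    stop("missing effective length for feature(s): ",
         paste(utils::head(missing_len, 5L), collapse = ", "))
  len <- effective_lengths[rownames(counts$values)]
  if (any(len < 1)) stop("effective lengths must be >= 1 bp")
  rate <- counts$values / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample(s) left as zero columns: ",
            paste(colnames(counts$values)[zero], collapse = ", "))
    denom[zero] <- 1  # keeps 0/0 out; column stays zero
  }
  tpm <- sweep(rate, 2L, denom, "/") * 1e6
  expression_matrix(tpm, unit = "TPM", gene_of = counts$gene_of,
                    feature_level = counts$feature_level)
}

#' Per-gene isoform relative frequencies
#'
#' For each gene and sample, divides each transcript's TPM by the summed TPM
#' of the gene's transcripts. Samples where the gene sum is zero get `NA`
#' fractions (missing, excluded downstream) — never zero, which would invent
#' anti-correlation for silent genes.
#'
#' @param tpm transcript-level [expression_matrix()] with unit `"TPM"` (a
#'   count matrix is accepted too: fractions are scale-free within gene).
#' @return an [expression_matrix()] with unit `"fraction"`.
#' @export
isoform_fractions <- function(tpm) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (is.null(tpm$gene_of))
    stop("isoform_fractions requires a transcript-to-gene mapping")
  v <- tpm$values
  gene <- factor(tpm$gene_of, levels = unique(tpm$gene_of))
  gene_sum <- rowsum(v, gene)[as.integer(gene), , drop = FALSE]
  frac <- v / gene_sum
  frac[gene_sum == 0] <- NA_real_
  dimnames(frac) <- dimnames(v)
  expression_matrix(frac, unit = "fraction", gene_of = tpm$gene_of,
                    feature_level = "transcript")
}

#' Percent-spliced-in from junction counts
#'
#' Length-normalized PSI of one cassette event in one sample:
#' \deqn{\psi = \frac{I/L_I}{I/L_I + E/L_E}}
#' where `I` is the inclusion junction read count, `E` the exclusion
#' (skipping) count, and `L_I`, `L_E` the numbers of junctions supporting
#' each form. The defaults `L_I = 2`, `L_E = 1` reflect a cassette exon: two
#' flanking inclusion junctions versus one skipping junction. With equal
#' lengths the formula reduces to `I / (I + E)`. When both counts are zero
#' the event is unobserved and `psi` is `NA` (undefined), not 0.
#'
#' All arguments are vectorized; `event_id`/`sample_id` label the output.
#'
#' @param inclusion_count,exclusion_count non-negative integer counts.
#' @param inclusion_norm_len,exclusion_norm_len junction-count normalizers
#'   (>= 1).
#' @param event_id,sample_id optional labels.
#' @return data.frame of class `psi_record` with columns `event_id`,
#'   `sample_id`, `inclusion_count`, `exclusion_count`,
#'   `inclusion_norm_len`, `exclusion_norm_len`, `psi`.
#' @export
compute_psi <- function(inclusion_count, exclusion_count,
                        inclusion_norm_len = 2L, exclusion_norm_len = 1L,
                        event_id = NA_character_, sample_id = NA_character_) {
  if (any(inclusion_count < 0) || any(exclusion_count < 0))
    stop("junction counts must be non-negative")
  if (any(inclusion_norm_len < 1) || any(exclusion_norm_len < 1))
    stop("normalization lengths must be >= 1")
  inc <- inclusion_count / inclusion_norm_len
  exc <- exclusion_count / exclusion_norm_len
  psi <- ifelse(inc + exc == 0, NA_real_, inc / (inc + exc))
  out <- data.frame(event_id = event_id, sample_id = sample_id,
                    inclusion_count = inclusion_count,
                    exclusion_count = exclusion_count,
                    inclusion_norm_len = inclusion_norm_len,
                    exclusion_norm_len = exclusion_norm_len,
                    psi = psi, stringsAsFactors = FALSE)
  class(out) <- c("psi_record", class(out))
  out
}

#' PSI table from a junction-count table
#'
#' @param junctions data.frame with columns `event_id`, `sample_id`,
#'   `inclusion`, `exclusion`.
#' @inheritParams compute_psi
#' @return a `psi_record` data.frame, one row per (event, sample).
#' @export
psi_from_junctions <- function(junctions, inclusion_norm_len = 2L,
                               exclusion_norm_len = 1L) {
  need <- c("event_id", "sample_id", "inclusion", "exclusion")
  if (!all(need %in% names(junctions)))
    stop("junction table needs columns: ", paste(need, collapse = ", "))
  compute_psi(junctions$inclusion, junctions$exclusion,
              inclusion_norm_len, exclusion_norm_len,
              event_id = junctions$event_id, sample_id = junctions$sample_id)
}
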