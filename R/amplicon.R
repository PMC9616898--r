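#' In-silico RT-PCR amplicon prediction
#'
#' Predicts the product a primer pair would amplify from a sense-strand
#' cDNA sequence. The forward primer is matched directly on the sequence;
#' the reverse primer (given 5'->3') is matched as its reverse complement
#' downstream of the forward site. The leftmost forward site and the
#' nearest downstream reverse site are used; the product spans the first
#' base of the forward site through the last base of the reverse-complement
#' site inclusive (both primers counted, matching how gel sizes are
#' reported). Matching is case-insensitive and exact by default.
#'
#' @param transcript_seq cDNA sequence (A/C/G/T), sense strand.
#' @param forward,reverse primer sequences, each 5'->3', length >= 10,
#'   plain ACGT.
#' @param max_mismatches allowed mismatches per primer site (default 0,
#'   exact matching).
#' @param transcript_id optional label carried into the result.
#' @return data.frame of class `amplicon_prediction`: `transcript_id`,
#'   `product_length` (bp; `NA` when either site is absent), `forward_pos`,
#'   `reverse_pos` (0-based offsets of the matched sites), `mismatches`.
#' @export
predict_amplicon <- function(transcript_seq, forward, reverse,
                             max_mismatches = 0L,
                             transcript_id = NA_character_) {
  .check_primer <- function(p, what) {
    p <- toupper(p)
    if (nchar(p) < 10L) stop(what, " primer must be >= 10 nt")
    if (grepl("[^ACGT]", p)) stop(what, " primer contains non-ACGT characters")
    p
  }
  forward <- .check_primer(forward, "forward")
  reverse <- .check_primer(reverse, "reverse")
  seq <- Biostrings::DNAString(toupper(transcript_seq))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)))

  fwd_hits <- Biostrings::start(
    Biostrings::matchPattern(forward, seq, max.mismatch = max_mismatches))
  rev_hits <- Biostrings::start(
    Biostrings::matchPattern(rc, seq, max.mismatch = max_mismatches))

  empty <- data.frame(transcript_id = transcript_id,
                      product_length = NA_integer_,
                      forward_pos = NA_integer_, reverse_pos = NA_integer_,
                      mismatches = NA_integer_, stringsAsFactors = FALSE)
  class(empty) <- c("amplicon_prediction", class(empty))
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) return(empty)
  if (length(fwd_hits) > 1L)
    warning("multiple forward primer sites at 0-based offsets ",
            paste(fwd_hits - 1L, collapse = ", "), "; leftmost used")
  f <- min(fwd_hits)
  downstream <- rev_hits[rev_hits >= f + nchar(forward)]
  if (length(downstream) == 0L) return(empty)
  r <- min(downstream)
  out <- data.frame(transcript_id = transcript_id,
                    product_length = as.integer(r + nchar(rc) - f),
                    forward_pos = f - 1L, reverse_pos = r - 1L,
                    mismatches = 0L, stringsAsFactors = FALSE)
  class(out) <- c("amplicon_prediction", class(out))
  out
}

#' Predict amplicons across a set of transcript sequences
#'
#' @param seqs named character vector of cDNA sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams predict_amplicon
#' @return one `amplicon_prediction` row per transcript.
#' @export
predict_amplicons <- function(seqs, forward, reverse, max_mismatches = 0L) {
  stopifnot(length(seqs) == 0L || !is.null(names(seqs)))
  out <- do.call(rbind, lapply(names(seqs), function(id)
    predict_amplicon(seqs[[id]], forward, reverse, max_mismatches,
                     transcript_id = id)))
  if (is.null(out)) out <- predict_amplicon("A", "ACGTACGTAC",
                                            "ACGTACGTAC")[0L, ]
  out
}

# Isoform-discriminating primer pair used for the cassette-exon switch gene
# (given 5'->3'; the reverse primer anneals to the sense strand's complement).
#' Primer pair discriminating the two cassette-exon isoforms
#'
#' The forward/reverse RT-PCR primer pair that brackets the 72-nt cassette
#' exon of the studied switch gene, so the two isoforms yield products
#' differing by exactly the cassette length (222 vs 294 bp).
#' @return named list with elements `forward` and `reverse`.
#' @export
cassette_primer_pair <- function() {
  list(forward = "CCTCAGCAACAACCCCTCTA", reverse = "CCTGCTCTTCAATAACATCC")
}

#' Synthetic cassette-exon isoform pair for amplicon checks
#'
#' A constructed (synthetic, not downloaded) pair of cDNA sequences that
#' mimics the exon-7 switch geometry of the studied gene: the skipped-exon
#' isoform yields a 222-bp product with [cassette_primer_pair()], and the
#' inclusion isoform carries an additional 72-nt cassette strictly between
#' the primer sites, yielding 294 bp. The filler sequence is fixed and
#' verified to contain each primer site exactly once. The same sequences
#' ship as `inst/extdata/lrrfip2_synthetic.fa`.
#'
#' @return named character vector with elements `V2_skipped_synthetic` and
#'   `V3_inclusion_synthetic`, plus attribute `cassette` (the 72-nt insert).
#' @export
synthetic_isoform_pair <- function() {
  up  <- "CTGAATAAATCGTGTGAATACGTGAGTCGT"
  mid <- paste0("AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCA",
                "TATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCC",
                "CTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGC",
                "CTAGAAAGGTACCGCTGGCATATCACGCCTCC")
  cas <- paste0("CGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGC",
                "CGGAGTCTAGGCTTTGAAACAG")
  dn  <- "CGGAAAGCAGTTGAATATCTAACGACCCCT"
  pr <- cassette_primer_pair()
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(pr$reverse)))
  v2 <- paste0(up, pr$forward, mid, rc, dn)
  v3 <- paste0(up, pr$forward, substr(mid, 1L, 100L), cas,
               substr(mid, 101L, nchar(mid)), rc, dn)
  out <- c(V2_skipped_synthetic = v2, V3_inclusion_synthetic = v3)
  attr(out, "cassette") <- cas
  out
}
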