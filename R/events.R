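#' Classify the alternative-splicing event between two isoforms
#'
#' Compares the exon chains of two transcripts of the same gene and assigns
#' one of the seven canonical local event types, or a fallback:
#' \describe{
#'   \item{SE}{skipped (cassette) exon: one chain carries one extra internal
#'     exon, both flanking exons shared;}
#'   \item{RI}{retained intron: one chain's single exon spans two exons plus
#'     the intervening intron of the other;}
#'   \item{A3 / A5}{alternative 3' (acceptor) / 5' (donor) splice site:
#'     exactly one internal splice-site boundary differs;}
#'   \item{AF / AL}{alternative first / last exon: the transcription-first
#'     (or -last) exon differs, the remaining chain is shared;}
#'   \item{MX}{mutually exclusive exons: two disjoint exons, one per chain,
#'     between shared flanks;}
#'   \item{identical}{equal exon chains;}
#'   \item{complex}{any other difference (multi-exon or compound changes) —
#'     reported but not typed.}
#' }
#'
#' Labels are transcription-relative (strand-aware): on the minus strand the
#' donor of an internal exon sits at its genomic start, so a difference
#' there is A5, and the transcription-first exon is the genomically last
#' one. A difference confined to a transcript terminus boundary (TSS / 3'
#' end, not a splice site) is classed with the terminal-exon events AF/AL.
#' Ties between a terminal-exon skip reading as SE or AF/AL resolve by
#' position: terminal differences are AF/AL, internal ones SE.
#'
#' @param a,b [transcript_model()] objects sharing gene, chromosome and
#'   strand.
#' @return an object of class `splice_event`: list with `gene_id`,
#'   `isoform_a`, `isoform_b`, `event_type`, `event_coords` (matrix of
#'   0-based half-open distinguishing intervals; `NULL` for identical),
#'   `chrom`, `strand`.
#' @export
classify_event <- function(a, b) {
  stopifnot(inherits(a, "transcript_model"), inherits(b, "transcript_model"))
  if (a$gene_id != b$gene_id)
    stop("isoforms belong to different genes: ", a$gene_id, " vs ", b$gene_id)
  if (a$chrom != b$chrom || a$strand != b$strand)
    stop("isoforms on different chromosomes or strands cannot be compared")
  res <- .classify_chains(a$exons, b$exons, a$strand)
  structure(list(gene_id = a$gene_id,
                 isoform_a = a$transcript_id, isoform_b = b$transcript_id,
                 event_type = res$type, event_coords = res$coords,
                 chrom = a$chrom, strand = a$strand),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  coords <- if (is.null(x$event_coords)) "-" else
    paste(apply(x$event_coords, 1L, function(r)
      sprintf("%d-%d", r[1L] + 1, r[2L]), simplify = TRUE), collapse = ",")
  cat(sprintf("<splice_event> %s: %s vs %s -> %s [%s:%s %s]\n",
              x$gene_id, x$isoform_a, x$isoform_b, x$event_type,
              x$chrom, x$strand, coords))
  invisible(x)
}

.iv <- function(s, e) matrix(c(s, e), ncol = 2,
                             dimnames = list(NULL, c("start", "end")))

# Core chain comparison on sorted 0-based half-open exon matrices.
# Terminal labels are mapped through the strand at the end: the genomic-left
# terminus is the transcription start on '+' and the transcription end on '-'.
.classify_chains <- function(A, B, strand) {
  nA <- nrow(A); nB <- nrow(B)
  same_row <- function(x, y) x[1L] == y[1L] && x[2L] == y[2L]
  if (nA == nB && all(A == B)) return(list(type = "identical", coords = NULL))

  # longest common prefix / suffix of identical exons, non-overlapping
  np <- 0L
  while (np < min(nA, nB) && same_row(A[np + 1L, ], B[np + 1L, ])) np <- np + 1L
  ns <- 0L
  while (ns < min(nA, nB) - np && same_row(A[nA - ns, ], B[nB - ns, ])) ns <- ns + 1L
  mA <- if (np + ns >= nA) A[0L, , drop = FALSE] else
    A[(np + 1L):(nA - ns), , drop = FALSE]
  mB <- if (np + ns >= nB) B[0L, , drop = FALSE] else
    B[(np + 1L):(nB - ns), , drop = FALSE]
  kA <- nrow(mA); kB <- nrow(mB)
  left_flank <- np > 0L   # shared exon on the genomic left of the difference
  right_flank <- ns > 0L

  # terminal label helper: side is "left"/"right" in genomic orientation
  terminal <- function(side, coords) {
    first <- (side == "left") == (strand == "+")
    list(type = if (first) "AF" else "AL", coords = coords)
  }

  # one chain has extra exon(s)
  if (kA == 0L || kB == 0L) {
    m <- if (kA == 0L) mB else mA
    if (nrow(m) == 1L && left_flank && right_flank)
      return(list(type = "SE", coords = m))
    if (nrow(m) == 1L && !left_flank && right_flank)
      return(terminal("left", m))
    if (nrow(m) == 1L && left_flank && !right_flank)
      return(terminal("right", m))
    return(list(type = "complex", coords = rbind(mA, mB)))
  }

  # retained intron: two consecutive exons vs their exact span
  if ((kA == 2L && kB == 1L) || (kA == 1L && kB == 2L)) {
    two <- if (kA == 2L) mA else mB
    one <- if (kA == 2L) mB else mA
    if (one[1L, 1L] == two[1L, 1L] && one[1L, 2L] == two[2L, 2L])
      return(list(type = "RI", coords = .iv(two[1L, 2L], two[2L, 1L])))
    return(list(type = "complex", coords = rbind(mA, mB)))
  }

  if (kA == 1L && kB == 1L) {
    a <- mA[1L, ]; b <- mB[1L, ]
    share_left <- a[1L] == b[1L]; share_right <- a[2L] == b[2L]
    if (share_left && !share_right) {
      # differing boundary is a genomic-right edge: donor on '+', acceptor on '-'
      if (right_flank) {
        type <- if (strand == "+") "A5" else "A3"
        return(list(type = type,
                    coords = .iv(min(a[2L], b[2L]), max(a[2L], b[2L]))))
      }
      return(terminal("right", rbind(mA, mB)))
    }
    if (share_right && !share_left) {
      # genomic-left edge: acceptor on '+', donor on '-'
      if (left_flank) {
        type <- if (strand == "+") "A3" else "A5"
        return(list(type = type,
                    coords = .iv(min(a[1L], b[1L]), max(a[1L], b[1L]))))
      }
      return(terminal("left", rbind(mA, mB)))
    }
    # no shared endpoint
    if (!left_flank && right_flank) return(terminal("left", rbind(mA, mB)))
    if (left_flank && !right_flank) return(terminal("right", rbind(mA, mB)))
    disjoint <- a[2L] <= b[1L] || b[2L] <= a[1L]
    if (left_flank && right_flank && disjoint) {
      mx <- rbind(mA, mB)
      mx <- mx[order(mx[, 1L]), , drop = FALSE]
      return(list(type = "MX", coords = mx))
    }
    return(list(type = "complex", coords = rbind(mA, mB)))
  }

  list(type = "complex", coords = rbind(mA, mB))
}

#' Tabulate splice events for a list of isoform pairs
#'
#' @param models named list of [transcript_model()] (names = transcript ids).
#' @param pairs data.frame with columns `isoform_a`, `isoform_b`.
#' @return data.frame: gene, isoforms, event type, strand, and the
#'   distinguishing coordinates in 1-based inclusive genomic form
#'   (semicolon-separated for multi-interval events).
#' @export
classify_event_table <- function(models, pairs) {
  stopifnot(all(c("isoform_a", "isoform_b") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ev <- classify_event(models[[pairs$isoform_a[i]]],
                         models[[pairs$isoform_b[i]]])
    coords <- if (is.null(ev$event_coords)) "" else
      paste(sprintf("%d-%d", as.integer(ev$event_coords[, 1L] + 1),
                    as.integer(ev$event_coords[, 2L])), collapse = ";")
    data.frame(gene_id = ev$gene_id, isoform_a = ev$isoform_a,
               isoform_b = ev$isoform_b, event_type = ev$event_type,
               chrom = ev$chrom, strand = ev$strand, coords_1based = coords,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
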