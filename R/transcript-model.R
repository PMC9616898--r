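#' Transcript exon model
#'
#' A `transcript_model` holds the identity and exon chain of one transcript:
#' gene id, transcript id, chromosome, strand, and an ordered list of exon
#' intervals. Exon coordinates are stored 0-based half-open on the genome
#' axis; all GTF input/output converts at the boundary. Exons are always
#' sorted ascending by start, regardless of strand.
#'
#' @param gene_id,transcript_id character scalars.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (start, end), 0-based half-open.
#'   A data.frame or a list of length-2 vectors is accepted and coerced.
#' @return an object of class `transcript_model`.
#' @examples
#' tm <- transcript_model("g1", "t1", "chr1", "+",
#'                        rbind(c(99, 200), c(299, 400)))
#' exonic_length(tm)
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons) {
  if (is.data.frame(exons)) exons <- as.matrix(exons[, 1:2])
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(transcript_id), length(transcript_id) == 1L,
            length(chrom) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got: ", strand)
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "' has zero exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript '", transcript_id, "' has overlapping exons")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = as.character(chrom), strand = strand, exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s, %d exon(s), %d bp exonic\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), exonic_length(x)))
  invisible(x)
}

#' Total exonic length of a transcript model, in bp
#' @param model a [transcript_model()].
#' @return integer scalar.
#' @export
exonic_length <- function(model) {
  sum(model$exons[, 2L] - model$exons[, 1L])
}

.parse_gtf_attr <- function(attr, key, lineno) {
  m <- regmatches(attr, regexec(paste0(key, '\\s+"([^"]*)"'), attr))[[1L]]
  if (length(m) < 2L)
    stop("GTF line ", lineno, ": missing attribute '", key, "'")
  m[2L]
}

#' Read transcript models from a GTF file
#'
#' Consumes `exon` feature lines of a 9-column GTF (1-based inclusive
#' coordinates) and builds one [transcript_model()] per `transcript_id`.
#' Coordinates are converted to the internal 0-based half-open convention.
#' A `transcript` feature with no exon lines is excluded with a warning.
#'
#' @param path path to a GTF file.
#' @return list of [transcript_model()] objects, named by transcript id.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  exon_rows <- list()
  tx_declared <- character()
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L)
      stop("GTF line ", i, ": expected 9 tab-separated fields, found ",
           length(fields))
    feature <- fields[3L]
    start <- suppressWarnings(as.numeric(fields[4L]))
    end <- suppressWarnings(as.numeric(fields[5L]))
    if (is.na(start) || is.na(end))
      stop("GTF line ", i, ": non-numeric coordinates")
    if (feature == "transcript") {
      tx_declared <- c(tx_declared,
                       .parse_gtf_attr(fields[9L], "transcript_id", i))
      next
    }
    if (feature != "exon") next
    exon_rows[[length(exon_rows) + 1L]] <- list(
      chrom = fields[1L], start = start - 1, end = end,
      strand = fields[7L],
      gene_id = .parse_gtf_attr(fields[9L], "gene_id", i),
      transcript_id = .parse_gtf_attr(fields[9L], "transcript_id", i))
  }
  if (length(exon_rows) == 0L) {
    if (length(tx_declared))
      warning("transcript(s) with zero exons excluded: ",
              paste(tx_declared, collapse = ", "))
    else warning("no exon features found in ", path)
    return(list())
  }
  df <- do.call(rbind, lapply(exon_rows, as.data.frame))
  empty <- setdiff(tx_declared, df$transcript_id)
  if (length(empty))
    warning("transcript(s) with zero exons excluded: ",
            paste(empty, collapse = ", "))
  models <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L)
      stop("transcript '", d$transcript_id[1L],
           "' spans multiple chromosomes or strands")
    transcript_model(d$gene_id[1L], d$transcript_id[1L], d$chrom[1L],
                     d$strand[1L], cbind(d$start, d$end))
  })
  models[order(names(models))]
}

#' Write transcript models as GTF exon records
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exon intervals are
#' emitted as 1-based inclusive GTF coordinates. Round-trips exactly.
#'
#' @param models list of [transcript_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    sprintf('%s\tswitchscan\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            m$chrom, as.integer(m$exons[, 1L] + 1), as.integer(m$exons[, 2L]),
            m$strand, m$gene_id, m$transcript_id)
  }))
  writeLines(lines, path)
  invisible(path)
}
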