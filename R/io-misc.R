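#' Read a FASTA file into a named character vector
#'
#' Multi-line records are concatenated and case-folded to upper case.
#' Characters outside the IUPAC nucleotide alphabet are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector, one element per record (empty for an
#'   empty file).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(), character()))
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w)))
        stop("non-IUPAC nucleotide characters in ", path)
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write result tables and a run manifest
#'
#' Each table is written as TSV under `out_dir` with its list name as file
#' stem, in its given column order. A `manifest.json` records the parameters,
#' seed and package version, so a run is fully described by its output
#' directory. Writers are deterministic for identical inputs.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param params named list of run parameters recorded in the manifest.
#' @param seed integer seed recorded in the manifest.
#' @return paths of the written files, invisibly.
#' @export
write_results <- function(tables, out_dir, params = list(), seed = NA) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "switchscan",
    version = as.character(utils::packageVersion("switchscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    params = params,
    tables = names(tables))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
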