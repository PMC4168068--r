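#' Read a FASTA file into a tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `name` (full header line, `>` stripped) and
#'   `seq`. Errors on an empty file or duplicate IDs (first whitespace-
#'   delimited token of the header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  nm <- names(set)
  ids <- sub("\\s.*$", "", nm)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA IDs: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(name = nm, seq = as.character(unname(set)))
}

#' Write named sequences as FASTA
#'
#' @param records Tibble with columns `name` and `seq` (or a named character
#'   vector).
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records) && !is.null(names(records))) {
    records <- tibble(name = names(records), seq = unname(records))
  }
  set <- Biostrings::BStringSet(setNames(records$seq, records$name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
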