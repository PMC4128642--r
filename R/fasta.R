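#' Read and write aquaporin records as FASTA
#'
#' Thin wrappers around Biostrings keeping the round trip stable: record
#' order is preserved, gap characters are kept (records containing `-` are
#' marked as aligned), and lowercase input is uppercased with a message.
#'
#' @param path FASTA file path
#' @return `read_fasta`: a list of [aq_record()]; `write_fasta`: `path`,
#'   invisibly
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("lowercase residues uppercased on input")
    seqs <- toupper(seqs)
  }
  mapply(function(id, s) aq_record(id, s, aligned = grepl("-", s, fixed = TRUE)),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_fasta
#' @param records a list of [aq_record()] objects
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "aq_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "aq_record")))
  seqs <- vapply(records, `[[`, character(1), "sequence")
  ids <- vapply(records, `[[`, character(1), "id")
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
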