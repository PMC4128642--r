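AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' An aquaporin protein sequence record
#'
#' @param id record identifier (unique within a set)
#' @param sequence one-letter amino-acid string; the gap character `-` is
#'   permitted only when `aligned = TRUE`
#' @param aligned logical; is this row of an alignment?
#' @return an object of class `aq_record`
#' @export
aq_record <- function(id, sequence, aligned = FALSE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence for record '", id, "'")
  allowed <- if (aligned) c(AA20, "-") else AA20
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0)
    stop("record '", id, "' contains invalid characters: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, aligned = aligned),
            class = "aq_record")
}

#' @export
print.aq_record <- function(x, ...) {
  cat(sprintf(">%s (%d %s%s)\n", x$id, nchar(x$sequence),
              if (x$aligned) "columns" else "aa",
              if (x$aligned) ", aligned" else ""))
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(s, "\n")
  invisible(x)
}

seq_chars <- function(record) strsplit(record$sequence, "")[[1]]
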