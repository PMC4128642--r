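the_rules_cache <- new.env(parent = emptyenv())

#' Signature rules for atypical-substrate transport
#'
#' The allowed-residue sets at the nine diagnostic positions (ar/R filter
#' TMH2, TMH5, LE1, LE2 and P1-P5) for each of the five atypical
#' substrates: ammonia (NH3), boron, CO2, H2O2 and urea. Shipped as a JSON
#' data file; a custom rules file with the same schema can be supplied.
#'
#' @param path optional path to a rules JSON file; default is the built-in
#'   rule set
#' @return a named list; each element is a list with `substrate` and
#'   `allowed` (a list of 9 character vectors)
#' @export
signature_rules <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin) {
    if (!is.null(the_rules_cache$rules)) return(the_rules_cache$rules)
    path <- system.file("extdata", "signature_rules.json",
                        package = "aquaflux", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(names(raw$rules), function(nm) {
    allowed <- lapply(raw$rules[[nm]], function(x) toupper(unlist(x)))
    if (length(allowed) != 9 || any(vapply(allowed, length, integer(1)) == 0))
      stop("rule '", nm, "' must list 9 non-empty residue sets")
    list(substrate = nm, allowed = allowed)
  })
  names(rules) <- names(raw$rules)
  if (builtin) the_rules_cache$rules <- rules
  rules
}

#' Extract the nine selectivity residues of a sequence
#'
#' Reads the residues at the mapped ar/R filter and P1-P5 columns, in
#' canonical order (TMH2, TMH5, LE1, LE2; P1..P5).
#'
#' @param record an [aq_record()] (gaps permitted in the sequence, but not
#'   at mapped columns)
#' @param map an [position_map()] covering the record
#' @return an object of class `aq_selectivity_residues`: a list with
#'   `filter2` (4 named residues), `p_residues` (5 named residues) and
#'   `source`
#' @export
extract_selectivity_residues <- function(record, map) {
  stopifnot(inherits(record, "aq_record"), inherits(map, "aq_position_map"))
  chars <- seq_chars(record)
  pos <- c(map$filter2, map$p_positions)
  if (any(pos > length(chars)))
    stop("position map points past the end of '", record$id, "' (column ",
         max(pos), " > ", length(chars), ")")
  res <- chars[pos]
  if (any(res == "-")) {
    bad <- pos[res == "-"][1]
    stop("gap at mapped column ", bad, " of '", record$id, "'")
  }
  structure(list(filter2 = stats::setNames(res[1:4], names(map$filter2)),
                 p_residues = stats::setNames(res[5:9],
                                              names(map$p_positions)),
                 source = record$id),
            class = "aq_selectivity_residues")
}

#' @export
print.aq_selectivity_residues <- function(x, ...) {
  cat(sprintf("%s  ar/R: %s  P1-P5: %s\n", x$source,
              paste(x$filter2, collapse = "-"),
              paste(x$p_residues, collapse = "-")))
  invisible(x)
}

#' Build a selectivity-residue object from nine residues
#'
#' Convenience constructor for classifying residue tuples given directly
#' (e.g. transcribed from an alignment) rather than extracted from a
#' mapped sequence.
#'
#' @param residues character vector of 9 residues (TMH2, TMH5, LE1, LE2,
#'   P1-P5)
#' @param source identifier
#' @return an `aq_selectivity_residues` object
#' @export
selectivity_residues <- function(residues, source = "residues") {
  residues <- toupper(residues)
  stopifnot(length(residues) == 9, all(residues %in% AA20))
  structure(list(
    filter2 = stats::setNames(residues[1:4],
                              c("TMH2", "TMH5", "LE1", "LE2")),
    p_residues = stats::setNames(residues[5:9], paste0("P", 1:5)),
    source = source), class = "aq_selectivity_residues")
}

#' Predict atypical-substrate transport from selectivity residues
#'
#' Scores each substrate rule as the number of the nine diagnostic
#' positions whose residue falls in the rule's allowed set; a substrate is
#' assigned when the score reaches `threshold`. The default threshold of 7
#' reproduces the published assignments for the six cloned grapevine
#' aquaporins exactly (strict 9/9 matching would not: TIP P4 valine lies
#' outside the printed ammonia set).
#'
#' @param residues an `aq_selectivity_residues` object (or a 9-residue
#'   character vector)
#' @param rules a rule set from [signature_rules()]
#' @param threshold minimum match score (0-9) for assignment
#' @return an object of class `aq_selectivity_profile`: a data.frame with
#'   columns `substrate`, `score`, `assigned`, plus attributes `source`
#'   and `threshold`
#' @export
classify_substrates <- function(residues, rules = signature_rules(),
                                threshold = 7) {
  if (is.character(residues)) residues <- selectivity_residues(residues)
  stopifnot(inherits(residues, "aq_selectivity_residues"),
            threshold >= 0, threshold <= 9)
  res <- c(residues$filter2, residues$p_residues)
  out <- data.frame(
    substrate = names(rules),
    score = vapply(rules, function(r)
      sum(mapply(function(aa, allowed) aa %in% allowed, res, r$allowed)),
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$assigned <- out$score >= threshold
  attr(out, "source") <- residues$source
  attr(out, "threshold") <- threshold
  class(out) <- c("aq_selectivity_profile", "data.frame")
  out
}

#' @export
print.aq_selectivity_profile <- function(x, ...) {
  cat(sprintf("Selectivity profile for %s (threshold %d):\n",
              attr(x, "source"), attr(x, "threshold")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-6s score %d/9 %s\n", x$substrate[i], x$score[i],
                if (x$assigned[i]) "assigned" else ""))
  invisible(x)
}

#' Assigned substrates of a profile
#' @param profile a [classify_substrates()] result
#' @return character vector of assigned substrate names (sorted)
#' @export
assigned_substrates <- function(profile) {
  sort(profile$substrate[profile$assigned])
}
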