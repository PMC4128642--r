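#' Specification for one synthetic aquaporin-like sequence
#'
#' A sequence is derived from a subfamily template ([aq_template()]): the
#' nine selectivity residues are planted at the template's mapped columns,
#' then `n_substitutions` random substitutions are applied to non-reserved
#' columns (motif-bearing columns are never mutated).
#'
#' The planted residues can be given directly (`residues`, a 9-vector in
#' the order TMH2, TMH5, LE1, LE2, P1-P5), or indirectly as a set of
#' `substrates` the sequence should be predicted to transport, in which
#' case a residue satisfying every requested signature rule is chosen per
#' position (an error names the position if the rules conflict). With
#' neither, the subfamily default is used.
#'
#' @param id record identifier
#' @param subfamily `"PIP1"`, `"PIP2"` or `"TIP"`
#' @param residues optional character vector of 9 planted residues
#' @param substrates optional character vector of substrate names (see
#'   [signature_rules()])
#' @param n_substitutions number of random substitutions outside reserved
#'   columns
#' @param seed integer seed for the substitutions
#' @return an object of class `aq_seq_spec`
#' @export
seq_gen_spec <- function(id, subfamily = c("PIP1", "PIP2", "TIP"),
                         residues = NULL, substrates = NULL,
                         n_substitutions = 0, seed = NULL) {
  subfamily <- match.arg(subfamily)
  tpl <- aq_template(subfamily)
  if (n_substitutions < 0 || n_substitutions >= tpl$length)
    stop("'n_substitutions' must be in [0, sequence length)")
  if (!is.null(residues) && !is.null(substrates))
    stop("give 'residues' or 'substrates', not both")
  if (!is.null(substrates)) {
    residues <- residues_for_substrates(substrates)
  } else if (is.null(residues)) {
    residues <- default_selectivity_residues(subfamily)
  }
  residues <- toupper(residues)
  if (length(residues) != 9 || !all(residues %in% AA20))
    stop("'residues' must be 9 one-letter amino-acid codes")
  structure(list(id = id, subfamily = subfamily, residues = residues,
                 n_substitutions = as.integer(n_substitutions), seed = seed),
            class = "aq_seq_spec")
}

residues_for_substrates <- function(substrates) {
  rules <- signature_rules()
  unknown <- setdiff(substrates, names(rules))
  if (length(unknown) > 0)
    stop("unknown substrate(s): ", paste(unknown, collapse = ", "))
  slots <- c("TMH2", "TMH5", "LE1", "LE2", "P1", "P2", "P3", "P4", "P5")
  vapply(seq_along(slots), function(i) {
    allowed <- Reduce(intersect, lapply(substrates, function(s)
      rules[[s]]$allowed[[i]]))
    if (length(allowed) == 0)
      stop("no residue at position ", slots[i],
           " satisfies all of the rules: ",
           paste(substrates, collapse = ", "))
    allowed[1]
  }, character(1))
}

#' Generate a set of synthetic aquaporin sequences with known ground truth
#'
#' Builds each record from its subfamily template per [seq_gen_spec()].
#' Substitution positions are drawn without replacement, uniformly over
#' non-reserved columns; each substituted residue is replaced by a
#' uniformly chosen different amino acid. Identical spec + seed gives
#' bit-identical output.
#'
#' @param specs a list of [seq_gen_spec()] objects (a single spec is
#'   accepted)
#' @return a list with `records` (list of [aq_record()]) and `maps` (named
#'   list of position maps, one per record id)
#' @export
gen_aquaporin_set <- function(specs) {
  if (inherits(specs, "aq_seq_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "aq_seq_spec")))
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("record ids must be unique")
  records <- list()
  maps <- list()
  for (spec in specs) {
    tpl <- aq_template(spec$subfamily)
    s <- strsplit(tpl$sequence, "")[[1]]
    s[c(tpl$map$filter2, tpl$map$p_positions)] <- spec$residues
    if (spec$n_substitutions > 0) {
      if (!is.null(spec$seed)) set.seed(spec$seed)
      free <- setdiff(seq_along(s), tpl$reserved)
      pos <- sample(free, spec$n_substitutions)
      for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1)
    }
    records[[spec$id]] <- aq_record(spec$id, paste(s, collapse = ""))
    maps[[spec$id]] <- tpl$map
  }
  list(records = unname(records), maps = maps)
}
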