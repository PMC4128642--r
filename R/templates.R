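# Synthetic aquaporin templates.
#
# Three gap-free templates (PIP1-like 286 aa, PIP2-like 284 aa, TIP-like
# 251 aa) with the canonical MIP architecture: six hydrophobic
# transmembrane blocks (TMH1-TMH6) separated by hydrophilic loops (LA-LE),
# two NPA motifs (loop B, loop E), the water-specificity signature
# G-x(3)-NPA-R-S-x-G around the second NPA, the four ar/R filter columns
# (TMH2, TMH5, LE1, LE2), the five P1-P5 columns, and subfamily-specific
# regulatory sites (N-terminal methylation + diacidic motif and loop-D His
# for PIPs, a C-terminal K-x(3)-S-x-R phosphorylation consensus for PIP2,
# a TMH4 Cys mercury site for TIPs). Motif columns sit at plausible offsets
# but are fixture constants, not claims about any real protein.

TM_FILL <- c("I", "L", "V", "A", "F")
LOOP_FILL <- c("S", "G", "Q", "T", "D", "E", "R", "K")
TERM_FILL <- c("S", "G", "Q", "T", "A")

template_plan <- function(subfamily) {
  switch(subfamily,
    PIP1 = list(nterm = 28, TM1 = 23, LA = 12, TM2 = 23, LB = 18, TM3 = 23,
                LC = 20, TM4 = 23, LD = 18, TM5 = 23, LE = 26, TM6 = 23,
                cterm = 26),
    PIP2 = list(nterm = 20, TM1 = 23, LA = 12, TM2 = 23, LB = 18, TM3 = 23,
                LC = 20, TM4 = 23, LD = 18, TM5 = 23, LE = 26, TM6 = 23,
                cterm = 32),
    TIP  = list(nterm = 8, TM1 = 23, LA = 10, TM2 = 23, LB = 16, TM3 = 23,
                LC = 16, TM4 = 23, LD = 14, TM5 = 23, LE = 26, TM6 = 23,
                cterm = 23),
    stop("unknown subfamily '", subfamily, "'"))
}

#' Synthetic aquaporin template of a subfamily
#'
#' Returns the template sequence for one of the three built-in subfamilies
#' together with its position map and the set of reserved (motif-bearing)
#' columns that the sequence generator never mutates. Default selectivity
#' residues are F-H-T-R / Q-S-A-F-W for PIP templates and H-I-G-R /
#' T-S-A-V-W for the TIP template.
#'
#' @param subfamily one of `"PIP1"`, `"PIP2"`, `"TIP"`
#' @return a list with elements `id`, `subfamily`, `sequence` (character
#'   string), `length`, `map` (a position map, see [position_map()]) and
#'   `reserved` (integer vector of protected columns)
#' @export
aq_template <- function(subfamily = c("PIP1", "PIP2", "TIP")) {
  subfamily <- match.arg(subfamily)
  plan <- template_plan(subfamily)
  lens <- unlist(plan)
  starts <- stats::setNames(cumsum(c(1, lens[-length(lens)])), names(lens))
  ends <- starts + lens - 1
  total <- sum(lens)

  s <- character(total)
  for (seg in names(lens)) {
    idx <- starts[[seg]]:ends[[seg]]
    fill <- if (grepl("^TM", seg)) TM_FILL
            else if (seg %in% c("nterm", "cterm")) TERM_FILL
            else LOOP_FILL
    s[idx] <- rep_len(fill, length(idx))
  }

  plant <- function(pos, res) s[pos] <<- res
  reserved <- integer(0)
  reserve <- function(pos) reserved <<- c(reserved, pos)

  # N terminus
  if (subfamily %in% c("PIP1", "PIP2")) {
    plant(1:6, c("M", "G", "K", "D", "V", "E"))  # methylation K3/E6, diacidic D4-x-E6
  } else {
    plant(1:2, c("M", "A"))
  }
  reserve(1:6)

  # NPA1 in loop B
  npa1 <- starts[["LB"]] + 7
  plant(npa1:(npa1 + 2), c("N", "P", "A"))
  reserve(npa1:(npa1 + 2))

  # loop E: water signature G-AAA-NPA-R-S-A-G around NPA2, then LE1/LE2/P2/P3
  sig_start <- starts[["LE"]] + 3
  plant(sig_start:(sig_start + 10),
        c("G", "A", "A", "A", "N", "P", "A", "R", "S", "A", "G"))
  reserve(sig_start:(sig_start + 10))
  npa2 <- sig_start + 4

  le1 <- starts[["LE"]] + 15
  le2 <- starts[["LE"]] + 19
  p2 <- starts[["LE"]] + 20
  p3 <- starts[["LE"]] + 24

  tmh2 <- starts[["TM2"]] + 11
  tmh5 <- starts[["TM5"]] + 11
  p1 <- starts[["LC"]] + if (subfamily == "TIP") 7 else 9
  p4 <- starts[["TM6"]] + 15
  p5 <- p4 + 1

  residues <- default_selectivity_residues(subfamily)
  f2_pos <- c(TMH2 = unname(tmh2), TMH5 = unname(tmh5),
              LE1 = unname(le1), LE2 = unname(le2))
  p_pos <- c(P1 = unname(p1), P2 = unname(p2), P3 = unname(p3),
             P4 = unname(p4), P5 = unname(p5))
  plant(f2_pos, residues[1:4])
  plant(p_pos, residues[5:9])
  reserve(c(f2_pos, p_pos))

  extras <- list()
  if (subfamily %in% c("PIP1", "PIP2")) {
    his <- starts[["LD"]] + 8
    plant(his, "H"); reserve(his)
    extras$loop_d_his <- unname(his)
    extras$methylation <- c(k = 3, e = 6)
    extras$diacidic <- c(start = 4, end = 6)
  } else {
    his <- starts[["LD"]] + 6
    plant(his, "H"); reserve(his)
    extras$loop_d_his <- unname(his)
    cys <- starts[["TM4"]] + 11
    plant(cys, "C"); reserve(cys)
    extras$tmh4_cys <- unname(cys)
    thr <- starts[["LB"]] + 11
    plant(thr, "T"); reserve(thr)
    extras$loop_b_thr <- unname(thr)
  }
  if (subfamily == "PIP2") {
    ph <- ends[["cterm"]] - 10
    plant(ph:(ph + 6), c("K", "A", "A", "A", "S", "A", "R"))
    reserve(ph:(ph + 6))
    extras$cterm_phospho <- c(start = unname(ph), ser = unname(ph) + 4)
  }

  map <- position_map(npa1 = unname(npa1), npa2 = unname(npa2),
                      filter2 = f2_pos, p_positions = p_pos,
                      length = total, extras = extras)
  list(id = paste0(subfamily, "_template"), subfamily = subfamily,
       sequence = paste(s, collapse = ""), length = total,
       map = map, reserved = sort(unique(reserved)))
}

default_selectivity_residues <- function(subfamily) {
  if (subfamily == "TIP") c("H", "I", "G", "R", "T", "S", "A", "V", "W")
  else c("F", "H", "T", "R", "Q", "S", "A", "F", "W")
}

#' Position map of the diagnostic aquaporin columns
#'
#' 1-based residue indices of the two NPA motifs, the four ar/R filter
#' columns (TMH2, TMH5, LE1, LE2) and the five P1-P5 columns. For real
#' sequences the map must come from a structural alignment; the package
#' only derives maps for its own synthetic templates.
#'
#' @param npa1,npa2 start indices of the first and second NPA motif
#' @param filter2 named integer vector of length 4 (TMH2, TMH5, LE1, LE2),
#'   strictly increasing
#' @param p_positions named integer vector of length 5 (P1-P5), strictly
#'   increasing
#' @param length sequence length the map refers to (for bounds checks)
#' @param extras optional named list of additional annotated positions
#' @return an object of class `aq_position_map`
#' @export
position_map <- function(npa1, npa2, filter2, p_positions, length,
                         extras = list()) {
  stopifnot(length(filter2) == 4, length(p_positions) == 5)
  if (any(diff(filter2) <= 0)) stop("'filter2' must be strictly increasing")
  if (any(diff(p_positions) <= 0))
    stop("'p_positions' must be strictly increasing")
  all_pos <- c(npa1, npa2, filter2, p_positions)
  if (any(all_pos < 1) || any(all_pos > length))
    stop("position map indices out of range 1..", length)
  structure(list(npa1 = npa1, npa2 = npa2,
                 filter2 = filter2, p_positions = p_positions,
                 length = length, extras = extras),
            class = "aq_position_map")
}

#' @export
print.aq_position_map <- function(x, ...) {
  cat(sprintf("Position map (sequence length %d)\n", x$length))
  cat(sprintf("  NPA motifs at %d, %d\n", x$npa1, x$npa2))
  cat("  ar/R filter:", paste(names(x$filter2), x$filter2, sep = "=",
                              collapse = " "), "\n")
  cat("  P1-P5:", paste(x$p_positions, collapse = " "), "\n")
  invisible(x)
}
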