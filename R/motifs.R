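# Motif hits are returned as a data.frame with columns
# motif, start, end (1-based inclusive) and match (the sequence slice).

motif_hits <- function(motif = character(0), start = integer(0),
                       end = integer(0), match = character(0)) {
  data.frame(motif = motif, start = as.integer(start),
             end = as.integer(end), match = match,
             stringsAsFactors = FALSE)
}

regex_hits <- function(seq, pattern, motif, offset = 0L) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(motif_hits())
  start <- as.integer(m) + offset
  len <- attr(m, "match.length")
  motif_hits(motif = rep(motif, length(start)), start = start,
             end = start + len - 1L,
             match = regmatches(seq, list(m))[[1]])
}

check_ungapped <- function(record) {
  if (grepl("-", record$sequence, fixed = TRUE))
    stop("record '", record$id,
         "' contains gaps; strip them first (see strip_gaps)")
}

#' Remove gap characters from a record
#' @param record an [aq_record()]
#' @return an ungapped [aq_record()]
#' @export
strip_gaps <- function(record) {
  aq_record(record$id, gsub("-", "", record$sequence, fixed = TRUE))
}

#' Locate NPA motifs
#'
#' All occurrences of the conserved Asn-Pro-Ala tripeptide, in order of
#' position. Orthodox aquaporins carry two copies (loop B and loop E)
#' forming the central constriction of the pore.
#'
#' @param record an ungapped [aq_record()]
#' @return a motif-hit data.frame (columns `motif`, `start`, `end`, `match`)
#' @export
find_npa_motifs <- function(record) {
  check_ungapped(record)
  regex_hits(record$sequence, "NPA", "NPA")
}

#' Locate the water-specificity signature
#'
#' First match of `G-x(3)-N-P-A-R-[SD]-x-G`, the serine/aspartate signature
#' around the second NPA motif that marks water-transporting MIPs.
#'
#' @param record an ungapped [aq_record()]
#' @return a motif-hit data.frame with zero or one row
#' @export
find_water_signature <- function(record) {
  check_ungapped(record)
  hits <- regex_hits(record$sequence, "G...NPAR[SD].G", "water_signature")
  if (nrow(hits) > 1) hits[1, , drop = FALSE] else hits
}

#' Scan subfamily-specific regulatory motifs
#'
#' Reports, where present:
#' \itemize{
#'   \item N-terminal methylation site: Lys at position 3 or 4 together
#'     with Glu at position 6 (PIP subfamilies);
#'   \item diacidic ER-export motif `[DE]-x-[DE]` within the first 30
#'     residues;
#'   \item all His residues (candidate loop-D pH sensors);
#'   \item the C-terminal phosphorylation consensus `K-x(3)-S-x-R` within
#'     the last 40 residues (PIP2 only);
#'   \item all Cys residues (candidate mercury-sensitive sites, TIP only).
#' }
#'
#' @param record an ungapped [aq_record()]
#' @param subfamily `"PIP1"`, `"PIP2"` or `"TIP"`
#' @return a motif-hit data.frame
#' @export
scan_regulatory_motifs <- function(record, subfamily) {
  if (!subfamily %in% c("PIP1", "PIP2", "TIP"))
    stop("unknown subfamily '", subfamily, "'")
  check_ungapped(record)
  s <- record$sequence
  chars <- seq_chars(record)
  n <- length(chars)
  hits <- motif_hits()

  k_pos <- which(chars[3:4] == "K") + 2L
  if (length(k_pos) > 0 && n >= 6 && chars[6] == "E") {
    st <- k_pos[1]
    hits <- rbind(hits, motif_hits("methylation_K_E", st, 6L,
                                   substr(s, st, 6)))
  }
  head30 <- substr(s, 1, min(30, n))
  hits <- rbind(hits, regex_hits(head30, "[DE].[DE]", "diacidic"))
  his <- which(chars == "H")
  if (length(his) > 0)
    hits <- rbind(hits, motif_hits(rep("his_ph_sensor", length(his)),
                                   his, his, chars[his]))
  if (subfamily == "PIP2" && n > 7) {
    tail_start <- max(1L, n - 39L)
    tail_seq <- substr(s, tail_start, n)
    hits <- rbind(hits, regex_hits(tail_seq, "K...S.R", "cterm_phospho",
                                   offset = tail_start - 1L))
  }
  if (subfamily == "TIP") {
    cys <- which(chars == "C")
    if (length(cys) > 0)
      hits <- rbind(hits, motif_hits(rep("mercury_cys", length(cys)),
                                     cys, cys, chars[cys]))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Kyte-Doolittle hydropathy values
#' @keywords internal
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Mean Kyte-Doolittle hydropathy in a sliding window; maximal runs of
#' window centers above `threshold` are reported as segments, after merging
#' runs separated by fewer than 4 residues and discarding runs shorter than
#' 12 residues. A crude surrogate for dedicated topology predictors; on the
#' built-in templates it recovers the six TM helices.
#'
#' @param record an ungapped [aq_record()]
#' @param window odd window width, >= 7
#' @param threshold mean-hydropathy cutoff
#' @return a data.frame with columns `start` and `end` (center positions)
#' @export
hydropathy_tm_segments <- function(record, window = 19, threshold = 1.6) {
  stopifnot(window >= 7, window %% 2 == 1)
  check_ungapped(record)
  chars <- seq_chars(record)
  n <- length(chars)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  h <- unname(KYTE_DOOLITTLE[chars])
  half <- (window - 1) / 2
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (length(centers) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  breaks <- which(diff(centers) >= 5)       # gap = diff - 1; merge if gap < 4
  run_start <- centers[c(1, breaks + 1)]
  run_end <- centers[c(breaks, length(centers))]
  keep <- (run_end - run_start + 1) >= 12
  data.frame(start = run_start[keep], end = run_end[keep])
}
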