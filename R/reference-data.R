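#' Published water-transport measurements of grapevine aquaporins
#'
#' Reference measurements for six *Vitis vinifera* (cv. Touriga nacional)
#' aquaporins heterologously expressed in an aquaporin-null
#' *S. cerevisiae* strain, plus the empty-plasmid control (pUG35):
#' osmotic water permeability at 23 degC (mean +/- SD over replicate
#' stopped-flow traces), Arrhenius activation energy over 9-37 degC, and
#' the percent inhibition of Pf by 0.5 mM HgCl2 (15 min) for the
#' water-functional strains (NA otherwise). These serve as ground truths
#' for the synthetic recovery studies and as inputs for derived quantities
#' (e.g. percent Pf increase over the control).
#'
#' @return a data.frame with columns `strain`, `subfamily`, `pf_1e4`
#'   (Pf x 1e-4 cm/s), `pf_sd_1e4`, `ea` (kcal/mol), `ea_sd`,
#'   `functional`, `inhibition_pct`
#' @export
reference_permeability <- function() {
  data.frame(
    strain = c("pUG35", "VvTnPIP1;4", "VvTnPIP2;1", "VvTnPIP2;3",
               "VvTnTIP1;1", "VvTnTIP2;2", "VvTnTIP4;1"),
    subfamily = c(NA, "PIP1", "PIP2", "PIP2", "TIP", "TIP", "TIP"),
    pf_1e4 = c(4.30, 4.00, 7.43, 5.30, 8.06, 9.65, 3.31),
    pf_sd_1e4 = c(0.28, 0.35, 0.64, 0.63, 0.34, 0.03, 0.08),
    ea = c(14.05, 14.74, 10.84, 14.53, 8.79, 8.77, 14.86),
    ea_sd = c(0.01, 0.62, 0.83, 0.55, 0.77, 0.62, 0.22),
    functional = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    inhibition_pct = c(NA, NA, 24, NA, 38, 36, NA),
    stringsAsFactors = FALSE)
}

#' Published selectivity residues of the cloned grapevine aquaporins
#'
#' The nine diagnostic residues (ar/R filter TMH2, TMH5, LE1, LE2 and
#' P1-P5) of the six cloned aquaporins, together with their published
#' putative-substrate assignments (comma-separated, sorted on access via
#' [assigned_substrates()]-compatible names).
#'
#' @return a data.frame with columns `protein`, `subfamily`, `TMH2`,
#'   `TMH5`, `LE1`, `LE2`, `P1`..`P5`, `substrates`
#' @export
reference_selectivity_residues <- function() {
  pip_sub <- "boron,CO2,H2O2,urea"
  tip_sub <- "H2O2,NH3,urea"
  out <- data.frame(
    protein = c("VvTnPIP1;4", "VvTnPIP2;1", "VvTnPIP2;3",
                "VvTnTIP1;1", "VvTnTIP2;2", "VvTnTIP4;1"),
    subfamily = c("PIP1", "PIP2", "PIP2", "TIP", "TIP", "TIP"),
    stringsAsFactors = FALSE)
  res <- rbind(
    c("F", "H", "T", "R", "Q", "S", "A", "F", "W"),
    c("F", "H", "T", "R", "Q", "S", "A", "F", "W"),
    c("F", "H", "T", "R", "Q", "S", "A", "F", "W"),
    c("H", "I", "A", "V", "T", "S", "A", "V", "W"),
    c("H", "I", "G", "R", "T", "S", "A", "V", "W"),
    c("H", "V", "A", "R", "T", "S", "A", "V", "W"))
  colnames(res) <- c("TMH2", "TMH5", "LE1", "LE2", paste0("P", 1:5))
  out <- cbind(out, as.data.frame(res, stringsAsFactors = FALSE))
  out$substrates <- c(pip_sub, pip_sub, pip_sub, tip_sub, tip_sub, tip_sub)
  out
}
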