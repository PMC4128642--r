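#' Configuration of a synthetic kinetics study
#'
#' Describes a full synthetic stopped-flow study: the strains with their
#' ground-truth permeabilities, activation energies and (optionally)
#' mercurial inhibition, the temperature grid, replicate counts and noise
#' level. Defaults mirror the reference experimental design: ten traces
#' per strain at the 23 degC reference temperature, five per temperature
#' over 9-37 degC, five per inhibition arm, 2% amplitude noise.
#'
#' The acquisition window of each simulated trace scales with the expected
#' relaxation (6 / k_lin), as an operator would configure the instrument,
#' so slow relaxations at low temperature are still resolved.
#'
#' @param strains data.frame with columns `label`, `pf_true` (cm/s),
#'   `ea_true` (kcal/mol) and optionally `inhibition_true` (percent, NA
#'   for strains without an inhibition arm)
#' @param temperatures temperature grid (K) for the Arrhenius series
#' @param t_ref reference temperature (K) for Pf reporting
#' @param replicates_pf traces per strain at `t_ref`
#' @param replicates_temp traces per strain per temperature
#' @param replicates_inhibition traces per inhibition arm
#' @param noise_sd trace noise (fraction of amplitude)
#' @param model an [cell_model()]
#' @param dead_time fit dead time (s)
#' @param seed integer seed (required: reproducibility contract)
#' @return an object of class `aq_study_config`
#' @export
study_config <- function(strains,
                         temperatures = 273.15 + c(9, 16, 23, 30, 37),
                         t_ref = 296.15,
                         replicates_pf = 10,
                         replicates_temp = 5,
                         replicates_inhibition = 5,
                         noise_sd = 0.02,
                         model = cell_model(),
                         dead_time = 0.005,
                         seed = 1) {
  stopifnot(is.data.frame(strains),
            all(c("label", "pf_true", "ea_true") %in% names(strains)),
            replicates_pf >= 1, replicates_temp >= 1,
            replicates_inhibition >= 1, noise_sd >= 0,
            inherits(model, "aq_cell_model"))
  if (anyDuplicated(strains$label)) stop("strain labels must be unique")
  if (is.null(seed) || !is.finite(seed)) stop("a seed is required")
  if (!"inhibition_true" %in% names(strains))
    strains$inhibition_true <- NA_real_
  structure(list(strains = strains, temperatures = temperatures,
                 t_ref = t_ref, replicates_pf = replicates_pf,
                 replicates_temp = replicates_temp,
                 replicates_inhibition = replicates_inhibition,
                 noise_sd = noise_sd, model = model,
                 dead_time = dead_time, seed = as.integer(seed)),
            class = "aq_study_config")
}

#' Study configuration mirroring the published reference measurements
#'
#' Strain ground truths (Pf, Ea, inhibition) are taken from
#' [reference_permeability()].
#'
#' @param seed integer seed
#' @param ... further arguments to [study_config()]
#' @export
default_study_config <- function(seed = 1, ...) {
  ref <- reference_permeability()
  study_config(
    strains = data.frame(label = ref$strain,
                         pf_true = ref$pf_1e4 * 1e-4,
                         ea_true = ref$ea,
                         inhibition_true = ref$inhibition_pct,
                         stringsAsFactors = FALSE),
    seed = seed, ...)
}

strain_traces <- function(config, pf, temperature, n, label) {
  k <- linearized_rate(config$model, pf)
  spec <- trace_spec(pf_true = pf, temperature = temperature,
                     noise_sd = config$noise_sd, n_points = 400,
                     duration = 6 / k, dead_time = config$dead_time,
                     seed = NULL, label = label)
  lapply(seq_len(n), function(i) gen_trace(spec, config$model))
}

#' Run a full synthetic kinetics study
#'
#' For every configured strain: generates replicate traces at the
#' reference temperature and estimates Pf (mean +/- SD); generates traces
#' across the temperature grid (true Pf scaled by the Arrhenius law) and
#' estimates Ea; and, for strains with a configured inhibition, compares a
#' treated ensemble (Pf reduced by the true percentage) against an
#' untreated one with a pooled-variance t test. Fully deterministic given
#' the config seed. Per-strain failures are recorded; an error is raised
#' only if every strain fails.
#'
#' @param config an [study_config()]
#' @param out_dir optional output directory (written via
#'   [write_run_report()])
#' @param force overwrite an existing report in `out_dir`
#' @return an object of class `aq_run_report` with `pf_table`, `ea_table`,
#'   `inhibition_table`, `failures`, `config` and `seed`
#' @export
run_kinetics_study <- function(config, out_dir = NULL, force = FALSE) {
  stopifnot(inherits(config, "aq_study_config"))
  set.seed(config$seed)
  pf_rows <- list(); ea_rows <- list(); inh_rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(config$strains))) {
    st <- config$strains[i, ]
    res <- tryCatch({
      traces <- strain_traces(config, st$pf_true, config$t_ref,
                              config$replicates_pf, st$label)
      pf <- estimate_pf(traces, config$model, dead_time = config$dead_time)

      series <- lapply(config$temperatures, function(temp) {
        pf_t <- st$pf_true *
          exp(-(st$ea_true / R_KCAL) * (1 / temp - 1 / config$t_ref))
        tr <- strain_traces(config, pf_t, temp, config$replicates_temp,
                            paste0(st$label, "@", round(temp - 273.15)))
        estimate_pf(tr, config$model, dead_time = config$dead_time)
      })
      ea <- estimate_ea(series)

      inh <- NULL
      if (is.finite(st$inhibition_true)) {
        ctrl <- estimate_pf(
          strain_traces(config, st$pf_true, config$t_ref,
                        config$replicates_inhibition,
                        paste0(st$label, "-ctrl")),
          config$model, dead_time = config$dead_time)
        trt_pf <- st$pf_true * (1 - st$inhibition_true / 100)
        trt <- estimate_pf(
          strain_traces(config, trt_pf, config$t_ref,
                        config$replicates_inhibition,
                        paste0(st$label, "+Hg")),
          config$model, dead_time = config$dead_time)
        inh <- inhibition_percent(ctrl, trt)
      }
      list(pf = pf, ea = ea, inh = inh)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    paste0(st$label, ": ", conditionMessage(res)))
      next
    }
    pf_rows[[st$label]] <- data.frame(
      strain = st$label, pf_mean = res$pf$pf_mean, pf_sd = res$pf$pf_sd,
      n_traces = res$pf$n_traces, temperature = res$pf$temperature,
      pf_true = st$pf_true, stringsAsFactors = FALSE)
    ea_rows[[st$label]] <- data.frame(
      strain = st$label, ea = res$ea$ea, ea_se = res$ea$ea_se,
      r_squared = res$ea$r_squared, n_temps = res$ea$n_temps,
      ea_true = st$ea_true, stringsAsFactors = FALSE)
    if (!is.null(res$inh))
      inh_rows[[st$label]] <- data.frame(
        strain = st$label,
        percent_inhibition = res$inh$percent_inhibition,
        p_value = res$inh$p_value,
        stars = significance_stars(res$inh$p_value),
        concentration = res$inh$concentration,
        incubation_min = res$inh$incubation_min,
        inhibition_true = st$inhibition_true, stringsAsFactors = FALSE)
  }
  if (length(pf_rows) == 0)
    stop("all strains failed:\n", paste(failures, collapse = "\n"))
  report <- structure(list(
    pf_table = do.call(rbind, c(pf_rows, make.row.names = FALSE)),
    ea_table = do.call(rbind, c(ea_rows, make.row.names = FALSE)),
    inhibition_table = if (length(inh_rows) > 0)
      do.call(rbind, c(inh_rows, make.row.names = FALSE)) else NULL,
    failures = failures,
    config = config,
    seed = config$seed
  ), class = "aq_run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir, force = force)
  report
}

#' @export
print.aq_run_report <- function(x, ...) {
  cat("Kinetics study report (seed", x$seed, ")\n\n")
  tab <- x$pf_table
  tab$pf_mean <- round(tab$pf_mean * 1e4, 2)
  tab$pf_sd <- round(tab$pf_sd * 1e4, 2)
  names(tab)[names(tab) == "pf_mean"] <- "pf_x1e4"
  names(tab)[names(tab) == "pf_sd"] <- "sd_x1e4"
  tab$pf_true <- round(tab$pf_true * 1e4, 2)
  print(tab, row.names = FALSE)
  cat("\nActivation energies (kcal/mol):\n")
  ea <- x$ea_table
  ea$ea <- round(ea$ea, 2); ea$ea_se <- round(ea$ea_se, 2)
  ea$r_squared <- round(ea$r_squared, 4)
  print(ea, row.names = FALSE)
  if (!is.null(x$inhibition_table)) {
    cat("\nMercurial inhibition:\n")
    it <- x$inhibition_table
    it$percent_inhibition <- round(it$percent_inhibition, 1)
    it$p_value <- signif(it$p_value, 3)
    print(it, row.names = FALSE)
  }
  if (length(x$failures) > 0)
    cat("\nFailures:\n", paste(" ", x$failures, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a kinetics report to disk
#'
#' Creates `tables/pf.csv`, `tables/ea.csv`, `tables/inhibition.csv` and
#' `report.json` (config echo + all tables) under `out_dir`. Refuses to
#' overwrite an existing report unless `force = TRUE`.
#'
#' @param report an [run_kinetics_study()] result
#' @param out_dir output directory
#' @param force overwrite an existing report
#' @return `out_dir`, invisibly
#' @export
write_run_report <- function(report, out_dir, force = FALSE) {
  if (file.exists(file.path(out_dir, "report.json")) && !force)
    stop("'", out_dir, "' already holds a report; use force = TRUE")
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(report$pf_table,
                   file.path(out_dir, "tables", "pf.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ea_table,
                   file.path(out_dir, "tables", "ea.csv"),
                   row.names = FALSE)
  if (!is.null(report$inhibition_table))
    utils::write.csv(report$inhibition_table,
                     file.path(out_dir, "tables", "inhibition.csv"),
                     row.names = FALSE)
  cfg <- report$config
  echo <- list(
    strains = cfg$strains, temperatures = cfg$temperatures,
    t_ref = cfg$t_ref, replicates_pf = cfg$replicates_pf,
    replicates_temp = cfg$replicates_temp,
    replicates_inhibition = cfg$replicates_inhibition,
    noise_sd = cfg$noise_sd, dead_time = cfg$dead_time, seed = cfg$seed,
    model = cfg$model[c("v0", "area", "beta", "vw", "osm_in0", "osm_out")])
  jsonlite::write_json(
    list(config = echo, pf = report$pf_table, ea = report$ea_table,
         inhibition = report$inhibition_table, failures = report$failures),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

pad_records <- function(records) {
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  if (length(unique(lens)) == 1) return(records)
  message("records differ in length; padding with C-terminal gaps ",
          "(supply a real alignment for real data)")
  maxlen <- max(lens)
  lapply(records, function(r)
    aq_record(r$id,
              paste0(r$sequence, strrep("-", maxlen - nchar(r$sequence))),
              aligned = TRUE))
}

#' Run a sequence annotation study
#'
#' For each record: motif scan (NPA motifs, water signature and, when the
#' subfamily is known, the regulatory motifs) and, when a position map is
#' available, selectivity-residue extraction and substrate classification.
#' Across records: pairwise identity matrix and (for n >= 3) a
#' neighbor-joining tree from p-distances; records of unequal length are
#' padded with terminal gaps first.
#'
#' @param records list of [aq_record()] objects
#' @param maps named list of [position_map()]s (by record id); records
#'   without a map are skipped for classification, with a warning
#' @param subfamilies optional named character vector (by record id) for
#'   the regulatory-motif scan
#' @param rules signature rules, see [signature_rules()]; an empty list
#'   yields empty profiles with a warning
#' @param threshold classification threshold, see [classify_substrates()]
#' @param bootstrap NJ bootstrap replicates (0 = none)
#' @param seed integer seed for the bootstrap
#' @param out_dir optional output directory
#' @param force overwrite an existing report
#' @return an object of class `aq_seq_report` with `motifs`, `profiles`,
#'   `identity` (percent matrix), `tree` (Newick string or NULL) and
#'   `skipped`
#' @export
run_sequence_study <- function(records, maps = list(), subfamilies = NULL,
                               rules = signature_rules(), threshold = 7,
                               bootstrap = 0, seed = NULL,
                               out_dir = NULL, force = FALSE) {
  if (inherits(records, "aq_record")) records <- list(records)
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("record ids must be unique")

  motif_rows <- list()
  profile_rows <- list()
  skipped <- character(0)
  if (length(rules) == 0)
    warning("empty rule set: all selectivity profiles will be empty",
            call. = FALSE)
  for (r in records) {
    plain <- strip_gaps(r)
    hits <- rbind(find_npa_motifs(plain), find_water_signature(plain))
    sf <- if (!is.null(subfamilies)) subfamilies[[r$id]] else NULL
    if (!is.null(sf)) hits <- rbind(hits, scan_regulatory_motifs(plain, sf))
    if (nrow(hits) > 0)
      motif_rows[[r$id]] <- cbind(record = r$id, hits)
    map <- maps[[r$id]]
    if (is.null(map)) {
      skipped <- c(skipped, r$id)
    } else if (length(rules) > 0) {
      prof <- classify_substrates(extract_selectivity_residues(r, map),
                                  rules = rules, threshold = threshold)
      profile_rows[[r$id]] <- cbind(record = r$id,
                                    as.data.frame(prof))
    }
  }
  if (length(skipped) > 0)
    warning("no position map for: ", paste(skipped, collapse = ", "),
            "; classification skipped", call. = FALSE)

  aligned <- pad_records(records)
  n <- length(aligned)
  identity <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      identity[i, j] <- identity[j, i] <-
        percent_identity(aligned[[i]], aligned[[j]])
  tree <- NULL
  if (n >= 3) {
    tree <- tree_newick(nj_tree(p_distance_matrix(aligned),
                                records = aligned,
                                bootstrap = bootstrap, seed = seed))
  } else {
    warning("fewer than 3 records: no tree built", call. = FALSE)
  }

  report <- structure(list(
    motifs = if (length(motif_rows) > 0)
      do.call(rbind, c(motif_rows, make.row.names = FALSE)) else
        cbind(record = character(0), motif_hits()),
    profiles = if (length(profile_rows) > 0)
      do.call(rbind, c(profile_rows, make.row.names = FALSE)) else NULL,
    identity = identity,
    tree = tree,
    skipped = skipped
  ), class = "aq_seq_report")
  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "report.json")) && !force)
      stop("'", out_dir, "' already holds a report; use force = TRUE")
    dir.create(file.path(out_dir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(report$motifs,
                     file.path(out_dir, "tables", "motifs.csv"),
                     row.names = FALSE)
    if (!is.null(report$profiles))
      utils::write.csv(report$profiles,
                       file.path(out_dir, "tables", "selectivity.csv"),
                       row.names = FALSE)
    utils::write.csv(round(report$identity, 1),
                     file.path(out_dir, "tables", "identity.csv"))
    if (!is.null(report$tree))
      writeLines(report$tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(
      list(motifs = report$motifs, profiles = report$profiles,
           identity = report$identity, tree = report$tree,
           skipped = report$skipped),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.aq_seq_report <- function(x, ...) {
  cat("Sequence annotation report:", nrow(x$identity), "records\n")
  if (!is.null(x$profiles)) {
    ass <- x$profiles[x$profiles$assigned, ]
    for (id in unique(x$profiles$record))
      cat(sprintf("  %-14s %s\n", id,
                  paste(sort(ass$substrate[ass$record == id]),
                        collapse = ", ")))
  }
  if (!is.null(x$tree)) cat("  tree:", x$tree, "\n")
  invisible(x)
}
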