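small_config <- function(noise_sd, replicates = 1, seed = 1) {
  study_config(
    strains = data.frame(label = c("ctrl", "hi"),
                         pf_true = c(4.3e-4, 9.65e-4),
                         ea_true = c(14.05, 8.77),
                         inhibition_true = c(NA, 36)),
    temperatures = 273.15 + c(9, 23, 37),
    replicates_pf = replicates, replicates_temp = replicates,
    replicates_inhibition = max(replicates, 2),
    noise_sd = noise_sd, seed = seed)
}

test_that("a noiseless study recovers the ground truths to fit tolerance", {
  rep <- run_kinetics_study(small_config(noise_sd = 0))
  expect_equal(rep$pf_table$pf_mean, rep$pf_table$pf_true,
               tolerance = 1e-3)
  expect_equal(rep$ea_table$ea, rep$ea_table$ea_true, tolerance = 1e-3)
  expect_equal(rep$inhibition_table$percent_inhibition, 36,
               tolerance = 0.2)
})

test_that("a study is deterministic given config + seed", {
  r1 <- run_kinetics_study(small_config(noise_sd = 0.02, seed = 7))
  r2 <- run_kinetics_study(small_config(noise_sd = 0.02, seed = 7))
  expect_identical(r1$pf_table, r2$pf_table)
  expect_identical(r1$ea_table, r2$ea_table)
  expect_identical(r1$inhibition_table, r2$inhibition_table)
  r3 <- run_kinetics_study(small_config(noise_sd = 0.02, seed = 8))
  expect_false(identical(r1$pf_table$pf_mean, r3$pf_table$pf_mean))
})

test_that("reports are written once and protected from overwrites", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "run1")
  rep <- run_kinetics_study(small_config(noise_sd = 0), out_dir = out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "tables", "pf.csv")))
  expect_error(write_run_report(rep, out), "force")
  expect_silent(write_run_report(rep, out, force = TRUE))
  # config echo suffices to rebuild identical tables
  echo <- jsonlite::read_json(file.path(out, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(echo$config$seed, 1)
  expect_equal(echo$pf$pf_mean, rep$pf_table$pf_mean, tolerance = 1e-12)
})

test_that("strain labels must be unique and a seed is required", {
  strains <- data.frame(label = c("a", "a"), pf_true = c(1, 2) * 1e-4,
                        ea_true = c(10, 10))
  expect_error(study_config(strains), "unique")
  ok <- data.frame(label = "a", pf_true = 1e-4, ea_true = 10)
  expect_error(study_config(ok, seed = NULL), "seed")
})

test_that("sequence study composes motifs, profiles, identity and tree", {
  set <- gen_aquaporin_set(lapply(1:3, function(i)
    seq_gen_spec(paste0("t", i), "TIP", n_substitutions = 2 * i, seed = i)))
  rep <- run_sequence_study(set$records, set$maps,
                            subfamilies = setNames(rep("TIP", 3),
                                                   paste0("t", 1:3)))
  expect_setequal(unique(rep$profiles$record), paste0("t", 1:3))
  ass <- rep$profiles[rep$profiles$assigned, ]
  for (id in paste0("t", 1:3))
    expect_setequal(ass$substrate[ass$record == id],
                    c("NH3", "H2O2", "urea"))
  expect_true(all(c("NPA", "water_signature", "mercury_cys") %in%
                    rep$motifs$motif))
  expect_equal(dim(rep$identity), c(3, 3))
  expect_false(is.null(rep$tree))
})

test_that("degenerate sequence studies degrade gracefully", {
  set <- gen_aquaporin_set(seq_gen_spec("solo", "PIP2"))
  expect_warning(rep <- run_sequence_study(set$records, set$maps),
                 "fewer than 3")
  expect_equal(unname(rep$identity), matrix(100, 1, 1))
  expect_null(rep$tree)

  # empty rule set: warned, profiles empty
  warns <- character(0)
  rep2 <- withCallingHandlers(
    run_sequence_study(set$records, set$maps, rules = list()),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("empty rule set", warns)))
  expect_null(rep2$profiles)

  # records without a map are skipped with a warning
  set2 <- gen_aquaporin_set(lapply(1:3, function(i)
    seq_gen_spec(paste0("s", i), "TIP", seed = i)))
  maps <- set2$maps[1:2]
  expect_warning(rep3 <- run_sequence_study(set2$records, maps),
                 "no position map for: s3")
  expect_equal(rep3$skipped, "s3")
})
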