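test_that("selectivity residues are extracted in canonical order", {
  tpl <- aq_template("PIP2")
  res <- extract_selectivity_residues(aq_record("p", tpl$sequence), tpl$map)
  expect_equal(unname(res$filter2), c("F", "H", "T", "R"))
  expect_equal(unname(res$p_residues), c("Q", "S", "A", "F", "W"))
  expect_named(res$filter2, c("TMH2", "TMH5", "LE1", "LE2"))

  tip <- aq_template("TIP")
  res2 <- extract_selectivity_residues(aq_record("t", tip$sequence), tip$map)
  expect_equal(unname(c(res2$filter2, res2$p_residues)),
               c("H", "I", "G", "R", "T", "S", "A", "V", "W"))
})

test_that("bad maps and gapped columns are errors", {
  tpl <- aq_template("TIP")
  short <- aq_record("short", substr(tpl$sequence, 1, 100))
  expect_error(extract_selectivity_residues(short, tpl$map), "past the end")
  ch <- strsplit(tpl$sequence, "")[[1]]
  ch[tpl$map$filter2[["TMH5"]]] <- "-"
  gapped <- aq_record("gapped", paste(ch, collapse = ""), aligned = TRUE)
  expect_error(extract_selectivity_residues(gapped, tpl$map),
               paste0("gap at mapped column ", tpl$map$filter2[["TMH5"]]))
})

test_that("published residue tuples reproduce the published substrate sets", {
  # six proteins, threshold 7: 12 PIP + 9 TIP assignments, nothing else
  ref <- reference_selectivity_residues()
  total <- 0
  for (i in seq_len(nrow(ref))) {
    tuple <- unlist(ref[i, c("TMH2", "TMH5", "LE1", "LE2", paste0("P", 1:5))])
    prof <- classify_substrates(selectivity_residues(tuple, ref$protein[i]))
    got <- assigned_substrates(prof)
    expect_equal(got, sort(strsplit(ref$substrates[i], ",")[[1]]),
                 info = ref$protein[i])
    total <- total + length(got)
  }
  expect_equal(total, 21)
})

test_that("scores count per-position set membership", {
  # PIP tuple vs the ammonia rule matches at LE2, P2, P3, P5 only
  prof <- classify_substrates(c("F", "H", "T", "R", "Q", "S", "A", "F", "W"))
  expect_equal(prof$score[prof$substrate == "NH3"], 4)
  expect_false(prof$assigned[prof$substrate == "NH3"])
  # TIP2-type tuple scores 6 on boron: below threshold
  prof2 <- classify_substrates(c("H", "I", "G", "R", "T", "S", "A", "V", "W"))
  expect_equal(prof2$score[prof2$substrate == "boron"], 6)
  expect_false(prof2$assigned[prof2$substrate == "boron"])
})

test_that("an all-glycine tuple is assigned nothing", {
  prof <- classify_substrates(rep("G", 9))
  expect_false(any(prof$assigned))
  # brute-force oracle: max achievable score for poly-G over every rule
  rules <- signature_rules()
  max_score <- max(vapply(rules, function(r)
    sum(vapply(r$allowed, function(a) "G" %in% a, logical(1))), numeric(1)))
  expect_lt(max_score, 7)
  expect_equal(max(prof$score), max_score)
})

test_that("threshold is configurable and rules can be supplied externally", {
  tuple <- c("F", "H", "T", "R", "Q", "S", "A", "F", "W")
  strict <- classify_substrates(tuple, threshold = 9)
  expect_equal(assigned_substrates(strict),
               sort(c("boron", "CO2", "H2O2", "urea")))
  lax <- classify_substrates(tuple, threshold = 4)
  expect_true(lax$assigned[lax$substrate == "NH3"])

  path <- withr::local_tempfile(fileext = ".json")
  file.copy(system.file("extdata", "signature_rules.json",
                        package = "aquaflux"), path)
  rules <- signature_rules(path)
  expect_equal(sort(names(rules)),
               sort(c("NH3", "boron", "CO2", "H2O2", "urea")))
})
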