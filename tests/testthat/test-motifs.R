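test_that("NPA scan is exhaustive and position-exact", {
  expect_equal(nrow(find_npa_motifs(aq_record("none", "AAAA"))), 0)
  hits <- find_npa_motifs(aq_record("two", "NPANPA"))
  expect_equal(hits$start, c(1, 4))
  expect_equal(hits$match, c("NPA", "NPA"))

  tpl <- aq_template("PIP1")
  hits <- find_npa_motifs(aq_record("pip1", tpl$sequence))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(tpl$map$npa1, tpl$map$npa2))
})

test_that("water signature pattern G-x3-NPA-R-[SD]-x-G", {
  hit <- find_water_signature(aq_record("pos", "GAAANPARSAG"))
  expect_equal(c(hit$start, hit$end), c(1, 11))
  expect_equal(nrow(find_water_signature(aq_record("neg", "GAAANPARTAG"))),
               0)
  # aspartate variant also matches
  expect_equal(nrow(find_water_signature(aq_record("asp", "GAAANPARDAG"))),
               1)
  tpl <- aq_template("TIP")
  hit <- find_water_signature(aq_record("tip", tpl$sequence))
  expect_true(hit$start <= tpl$map$npa2 && tpl$map$npa2 <= hit$end)
})

test_that("every motif hit re-validates against its sequence slice", {
  for (sf in c("PIP1", "PIP2", "TIP")) {
    tpl <- aq_template(sf)
    rec <- aq_record(sf, tpl$sequence)
    hits <- rbind(find_npa_motifs(rec), find_water_signature(rec),
                  scan_regulatory_motifs(rec, sf))
    for (i in seq_len(nrow(hits)))
      expect_equal(substr(rec$sequence, hits$start[i], hits$end[i]),
                   hits$match[i])
  }
})

test_that("regulatory motifs are detected per subfamily", {
  pip2 <- aq_template("PIP2")
  hits <- scan_regulatory_motifs(aq_record("p", pip2$sequence), "PIP2")
  expect_true("methylation_K_E" %in% hits$motif)   # K3 + E6
  expect_true("diacidic" %in% hits$motif)
  expect_true(pip2$map$extras$loop_d_his %in%
                hits$start[hits$motif == "his_ph_sensor"])
  ph <- hits[hits$motif == "cterm_phospho", ]
  expect_equal(nrow(ph), 1)
  expect_equal(substr(ph$match, 5, 5), "S")        # Ser in the 5th slot

  # direct pattern instance at a C terminus
  toy <- aq_record("toy", paste0(strrep("A", 50), "KAAASAR"))
  toyhits <- scan_regulatory_motifs(toy, "PIP2")
  expect_equal(toyhits$match[toyhits$motif == "cterm_phospho"], "KAAASAR")

  tip <- aq_template("TIP")
  hits <- scan_regulatory_motifs(aq_record("t", tip$sequence), "TIP")
  expect_equal(hits$start[hits$motif == "mercury_cys"],
               tip$map$extras$tmh4_cys)
  # PIP scan must not report mercury Cys
  expect_false("mercury_cys" %in%
                 scan_regulatory_motifs(aq_record("p", pip2$sequence),
                                        "PIP1")$motif)
  expect_error(scan_regulatory_motifs(toy, "NIP"), "unknown subfamily")
})

test_that("hydropathy scan finds uniform extremes and the six TM helices", {
  expect_equal(nrow(hydropathy_tm_segments(aq_record("r", strrep("R", 30)))),
               0)
  seg <- hydropathy_tm_segments(aq_record("i", strrep("I", 30)))
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(10, 21))   # all valid centers
  expect_equal(nrow(hydropathy_tm_segments(aq_record("short", "IIII"))), 0)
  for (sf in c("PIP1", "PIP2", "TIP"))
    expect_equal(nrow(hydropathy_tm_segments(
      aq_record(sf, aq_template(sf)$sequence))), 6)
})
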