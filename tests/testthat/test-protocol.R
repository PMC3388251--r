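national <- protocol_config()

test_that("engine matches the hand-written truth table on the boundary
           grid", {
  states <- c("WILDTYPE", "PANEL_MUTATION", "NON_PANEL_MUTATION")
  grid <- expand.grid(irt = c(59, 60, 99, 100, 101),
                      pap = c(1.5, 1.6, 2.9, 3.0),
                      a1 = states, a2 = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    nb <- make_newborn(g$irt, g$pap, g$a1, g$a2)
    got <- screen_national(nb, national)$outcome
    want <- oracle_national_outcome(g$irt, g$pap, g$a1, g$a2)
    expect_identical(got, want,
                     label = sprintf("IRT=%g PAP=%g %s/%s: %s",
                                     g$irt, g$pap, g$a1, g$a2, got))
  }
})

test_that("worked single-newborn traces follow the four-step tree", {
  r <- screen_national(make_newborn(55, 9), national)
  expect_identical(r$outcome, "NEGATIVE")
  expect_identical(r$steps, "IRT")

  r <- screen_national(make_newborn(70, 2.9, "PANEL_MUTATION",
                                    "PANEL_MUTATION"), national)
  expect_identical(r$outcome, "NEGATIVE")
  expect_identical(r$steps, "IRT|PAP")

  # failsafe: no panel mutation, two rare disease alleles
  r <- screen_national(make_newborn(120, 1.7, "NON_PANEL_MUTATION",
                                    "NON_PANEL_MUTATION"), national)
  expect_identical(r$outcome, "CF_REFERRAL")
  expect_true(r$via_failsafe)
  expect_identical(r$steps, "IRT|PAP|PANEL|EGA")
  expect_identical(r$ega_found, 2L)

  r <- screen_national(make_newborn(80, 3.5, "PANEL_MUTATION", "WILDTYPE"),
                       national)
  expect_identical(r$outcome, "CARRIER_REPORT")
  expect_false(r$via_failsafe)

  # failsafe with nothing to find ends negative after sequencing
  r <- screen_national(make_newborn(120, 1.7), national)
  expect_identical(r$outcome, "NEGATIVE_AFTER_EGA")
  expect_true(r$via_failsafe)

  # two panel mutations refer at step 3 without sequencing
  r <- screen_national(make_newborn(120, 5, "PANEL_MUTATION",
                                    "PANEL_MUTATION"), national)
  expect_identical(r$steps, "IRT|PAP|PANEL")
  expect_identical(r$outcome, "CF_REFERRAL")
})

test_that("carrier reporting off relabels carrier findings", {
  cfg <- protocol_config(carrier_reporting = FALSE)
  r <- screen_national(make_newborn(80, 3.5, "PANEL_MUTATION", "WILDTYPE"),
                       cfg)
  expect_identical(r$outcome, "NEGATIVE_AFTER_EGA")
})

test_that("failsafe can be disabled and never touches panel-positives", {
  no_fs <- protocol_config(failsafe_enabled = FALSE)
  nb <- make_newborn(120, 1.7, "NON_PANEL_MUTATION", "NON_PANEL_MUTATION")
  expect_identical(screen_national(nb, no_fs)$outcome, "NEGATIVE")
  # outcomes of newborns with >= 1 panel allele are unchanged by the failsafe
  set.seed(31)
  m <- default_biomarker_model()
  co <- generate_cohort(single_stratum_config(20000, carrier_frequency = 0.2,
                                              panel_detectability = 0.6,
                                              seed = 31L), m)
  with_fs <- screen_cohort(co, national)
  without_fs <- screen_cohort(co, no_fs)
  has_panel <- co$allele1 == "PANEL_MUTATION" | co$allele2 == "PANEL_MUTATION"
  expect_identical(with_fs$outcome[has_panel], without_fs$outcome[has_panel])
  # and enabling it never loses a CF referral
  expect_true(all(without_fs$outcome != "CF_REFERRAL" |
                    with_fs$outcome == "CF_REFERRAL"))
})

test_that("PAP recalibration multiplies by exactly 5/3", {
  expect_identical(recalibrate_pap(3.0), 5.0)
  expect_identical(recalibrate_pap(0), 0)
  expect_equal(recalibrate_pap(1.8), 3.0)
  expect_error(recalibrate_pap(-0.1), "non-negative")
})

test_that("pilot strategy rules match their printed entry criteria", {
  # thresholds on the pilot scale, cohort on the pilot scale
  pap_pilot <- pilot_config("IRT_PAP", cohort_on_corrected_scale = FALSE)
  expect_identical(screen_pilot(make_newborn(55, 1.9), pap_pilot)$outcome,
                   "CF_REFERRAL")
  expect_identical(screen_pilot(make_newborn(102, 1.1), pap_pilot)$outcome,
                   "CF_REFERRAL")
  expect_identical(screen_pilot(make_newborn(102, 0.9), pap_pilot)$outcome,
                   "NEGATIVE")
  expect_identical(screen_pilot(make_newborn(55, 1.7), pap_pilot)$outcome,
                   "NEGATIVE")
  for (variant in c("IRT_PAP", "IRT_DNA_EGA", "COMBINED")) {
    cfg <- pilot_config(variant, cohort_on_corrected_scale = FALSE)
    r <- screen_pilot(make_newborn(49.9, 100, "PANEL_MUTATION",
                                   "PANEL_MUTATION"), cfg)
    expect_identical(r$outcome, "NEGATIVE")
  }
  # corrected-scale flag rescales thresholds by 5/3
  pap_corr <- pilot_config("IRT_PAP", cohort_on_corrected_scale = TRUE)
  expect_identical(screen_pilot(make_newborn(55, 2.9), pap_corr)$outcome,
                   "NEGATIVE")
  expect_identical(screen_pilot(make_newborn(55, 3.0), pap_corr)$outcome,
                   "CF_REFERRAL")

  dna <- pilot_config("IRT_DNA_EGA")
  r <- screen_pilot(make_newborn(55, 0.1, "PANEL_MUTATION", "WILDTYPE"), dna)
  expect_identical(r$outcome, "CARRIER_REPORT")
  expect_identical(r$steps, "IRT|PANEL|EGA")
  r <- screen_pilot(make_newborn(55, 0.1, "NON_PANEL_MUTATION",
                                 "NON_PANEL_MUTATION"), dna)
  expect_identical(r$outcome, "NEGATIVE") # no failsafe in the pilot

  comb <- pilot_config("COMBINED", cohort_on_corrected_scale = FALSE)
  r <- screen_pilot(make_newborn(55, 1.9, "PANEL_MUTATION",
                                 "NON_PANEL_MUTATION"), comb)
  expect_identical(r$outcome, "CF_REFERRAL")
  expect_identical(r$steps, "IRT|PAP|PANEL|EGA")
  r <- screen_pilot(make_newborn(55, 1.7, "PANEL_MUTATION",
                                 "NON_PANEL_MUTATION"), comb)
  expect_identical(r$outcome, "NEGATIVE") # PAP rule gates the DNA steps
})

test_that("raising the IRT cutoff never creates new positives", {
  m <- default_biomarker_model()
  co <- generate_cohort(single_stratum_config(20000, carrier_frequency = 0.1,
                                              seed = 77L), m)
  lo <- screen_cohort(co, protocol_config(irt_cutoff = 60))
  hi <- screen_cohort(co, protocol_config(irt_cutoff = 70))
  newly_positive <- hi$outcome != "NEGATIVE" & lo$outcome == "NEGATIVE"
  expect_false(any(newly_positive))
})

test_that("no newborn below the IRT cutoff consumes a DNA test", {
  m <- default_biomarker_model()
  co <- generate_cohort(single_stratum_config(30000, seed = 13L), m)
  for (strat in list(national, pilot_config("IRT_DNA_EGA"),
                     pilot_config("COMBINED"))) {
    res <- screen_cohort(co, strat)
    below <- co$irt_ugl < strat$irt_cutoff
    expect_false(any(grepl("PANEL", res$steps[below])))
  }
})

test_that("screening is order-invariant and deterministic", {
  m <- default_biomarker_model()
  co <- generate_cohort(single_stratum_config(5000, carrier_frequency = 0.1,
                                              seed = 21L), m)
  res <- screen_cohort(co, national)
  expect_identical(screen_cohort(co, national), res)
  perm <- sample(nrow(co))
  res_perm <- screen_cohort(co[perm, ], national)
  expect_identical(res_perm$outcome, res$outcome[perm])
  expect_identical(res_perm$newborn_id, res$newborn_id[perm])
  expect_identical(nrow(screen_cohort(co[0, ], national)), 0L)
})

test_that("invalid protocol configurations are rejected", {
  expect_error(protocol_config(irt_cutoff = 100, irt_high = 60),
               "irt_cutoff < irt_high")
  expect_error(protocol_config(pap_cutoff_mid = 1.0, pap_cutoff_high = 2.0),
               "pap_cutoff_high")
  expect_error(pilot_config("NOPE"))
  expect_error(screen_cohort(make_newborn(50, 1), list()), "strategy")
})
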