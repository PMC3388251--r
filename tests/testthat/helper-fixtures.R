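# Shared fixtures: hand-built newborns and an independent scalar oracle of
# the four-step decision tree, written as literal nested conditionals so it
# shares no code path with the vectorized engine.

make_newborn <- function(irt, pap, a1 = "WILDTYPE", a2 = "WILDTYPE",
                         id = 1L, stratum = "dutch_general",
                         meconium_ileus = FALSE, phenotype = NULL) {
  nd <- (a1 != "WILDTYPE") + (a2 != "WILDTYPE")
  if (is.null(phenotype)) {
    phenotype <- c("UNAFFECTED", "CARRIER", "CLASSICAL_CF")[nd + 1]
  }
  data.frame(id = as.integer(id), stratum = stratum,
             allele1 = a1, allele2 = a2, phenotype = phenotype,
             meconium_ileus = meconium_ileus,
             irt_ugl = irt, pap_ugl = pap, stringsAsFactors = FALSE)
}

single_stratum_config <- function(n, carrier_frequency = 1 / 30,
                                  panel_detectability = 0.95, seed = 1L,
                                  ...) {
  population_config(
    n,
    strata = list(ancestry_stratum("only", 1, carrier_frequency,
                                   panel_detectability)),
    seed = seed, ...
  )
}

# Independent oracle for the national protocol: IRT cutoff 60, high 100,
# PAP cutoffs 3.0 (mid band) / 1.6 (high band), failsafe on, carrier
# reporting on, perfect sequencing. Returns the outcome label.
oracle_national_outcome <- function(irt, pap, a1, a2) {
  n_dis <- (a1 != "WILDTYPE") + (a2 != "WILDTYPE")
  n_panel <- (a1 == "PANEL_MUTATION") + (a2 == "PANEL_MUTATION")
  if (irt < 60) return("NEGATIVE")
  if (irt < 100) {
    if (pap < 3.0) return("NEGATIVE")
  } else {
    if (pap < 1.6) return("NEGATIVE")
  }
  if (n_panel == 2) return("CF_REFERRAL")
  if (n_panel == 1) {
    if (n_dis == 2) return("CF_REFERRAL")
    return("CARRIER_REPORT")
  }
  # no panel mutation: sequencing only via the failsafe
  if (irt >= 100 && pap >= 1.6) {
    if (n_dis == 2) return("CF_REFERRAL")
    if (n_dis == 1) return("CARRIER_REPORT")
    return("NEGATIVE_AFTER_EGA")
  }
  "NEGATIVE"
}
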