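# cfscreen default configuration
#
# One root seed governs every stochastic stage; stage seeds are derived from
# it with fixed labels, so adding a stage never shifts another stage's
# random stream. Probabilities may be written as decimals or as fraction
# strings ("1/30").
seed: 1

population:
  # newborns per simulated cohort
  cohort_size: 200000
  # probability that a two-disease-allele genotype presents as the milder,
  # non-classical form (assumption; the literature gives no genotype rule)
  fraction_non_classical_given_cf: 0.28
  # probability a CF newborn is already diagnosed via meconium ileus before
  # screening (about four such infants per 25 screen-detected per year);
  # flagged newborns stay in the cohort but leave sensitivity denominators
  meconium_ileus_rate_given_cf: "4/29"
  # ancestry strata: birth shares must sum to 1. carrier_frequency is the
  # two-allele carrier rate; panel_detectability is the per-allele
  # probability that a disease allele is covered by the mutation panel
  # (0.95 for the general population is an assumption; 0.44 and 0.69 are the
  # published panel sensitivities for the two migrant strata)
  strata:
    - name: dutch_general
      fraction_of_births: 0.90
      carrier_frequency: "1/30"
      panel_detectability: 0.95
    - name: turkish
      fraction_of_births: 0.05
      carrier_frequency: "1/50"
      panel_detectability: 0.44
    - name: north_african
      fraction_of_births: 0.05
      carrier_frequency: "1/50"
      panel_detectability: 0.69

biomarkers:
  # unaffected IRT is log-normal, calibrated exactly to two published
  # population tail quantiles (ug/l, exceedance probability)
  irt_tail_constraints:
    - { threshold: 50.0, exceedance_probability: 0.0243 }
    - { threshold: 60.0, exceedance_probability: 0.0103 }
  # carriers run a mildly elevated IRT: median ratio vs unaffected
  carrier_irt_median_ratio: 1.15
  # log-scale IRT/PAP correlation within a phenotype class (0 = conditional
  # independence)
  rho: 0.0
  # medians (ug/l) and log-scale standard deviations for the remaining
  # class/marker pairs; PAP is on the corrected (post-recalibration) scale.
  # CF-class values are model assumptions calibrated analytically so the
  # four-step protocol lands at the programme's aggregate test properties
  # (see the methods vignette)
  medians_ugl:
    UNAFFECTED:       { PAP: 0.4 }
    CARRIER:          { PAP: 0.4 }
    CLASSICAL_CF:     { IRT: 130.0, PAP: 10.0 }
    NON_CLASSICAL_CF: { IRT: 115.0, PAP: 8.0 }
  sigmas:
    UNAFFECTED:       { PAP: 0.55 }
    CARRIER:          { PAP: 0.55 }
    CLASSICAL_CF:     { IRT: 0.40, PAP: 0.60 }
    NON_CLASSICAL_CF: { IRT: 0.45, PAP: 0.60 }

# national four-step protocol (ug/l, corrected PAP scale)
protocol:
  irt_cutoff: 60.0        # step 1: IRT below this is negative
  irt_high: 100.0         # boundary of the high-IRT branch (inclusive)
  pap_cutoff_mid: 3.0     # step 2 cutoff when 60 <= IRT < 100
  pap_cutoff_high: 1.6    # step 2 cutoff when IRT >= 100
  failsafe_enabled: true  # panel-negative, IRT>=100 & PAP>=1.6 -> sequencing
  carrier_reporting: true # parents have not opted out
  ega_sensitivity: 1.0    # per-allele detection probability of sequencing

# pilot-era strategies; PAP thresholds on the pilot (pre-correction) scale.
# cohort_on_corrected_scale multiplies them by 5/3 before comparison, since
# generated cohorts carry corrected-scale PAP values
pilot:
  irt_cutoff: 50.0
  irt_high: 100.0
  pap_cutoff_mid: 1.8
  pap_cutoff_high: 1.0
  cohort_on_corrected_scale: true
  carrier_reporting: true

risk:
  carrier_frequency: "1/30"
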