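#' Summarize screening results into test properties
#'
#' Cross-tabulates a cohort against its screening results and computes the
#' strategy's test properties. Conventions:
#' \itemize{
#'   \item An "abnormal result" is a `CF_REFERRAL`; carrier reports are
#'     tallied on their own row and are never counted as referrals or false
#'     positives.
#'   \item Disease-positive is `ANY_CF` (classical + non-classical, the
#'     default) or `CLASSICAL_ONLY`; both definitions are worth inspecting
#'     because published aggregate figures do not say which they use.
#'   \item Sensitivity excludes meconium-ileus newborns from the denominator
#'     (they are diagnosed clinically before screening results matter);
#'     specificity = TN / (TN + false-positive referrals) over non-diseased
#'     newborns; PPV = true-positive referrals / all referrals.
#'   \item Undefined ratios (empty denominators) are returned as `NA` with
#'     the matching `*_defined` flag set to `FALSE`.
#' }
#'
#' @param cohort cohort data.frame.
#' @param results results data.frame from [screen_cohort()], aligned 1:1
#'   with the cohort by `newborn_id`.
#' @param disease_definition `"ANY_CF"` or `"CLASSICAL_ONLY"`.
#' @param strategy label stored in the summary.
#' @return list of class `cohort_summary`: counts (`n_screened`,
#'   `abnormal_results`, `classical_cf_detected`, `non_classical_cf_detected`,
#'   `carriers_reported`, `false_positive_referrals`, `dna_tests_used`,
#'   `ega_tests_used`), proportions (`sensitivity`, `specificity`, `ppv`)
#'   and definedness flags.
#' @export
summarize_screening <- function(cohort, results,
                                disease_definition = c("ANY_CF",
                                                       "CLASSICAL_ONLY"),
                                strategy = "strategy") {
  disease_definition <- match.arg(disease_definition)
  if (nrow(cohort) != nrow(results) ||
      !identical(as.integer(cohort$id), as.integer(results$newborn_id))) {
    stop("results do not align with cohort ids", call. = FALSE)
  }
  diseased <- if (disease_definition == "ANY_CF") {
    cohort$phenotype %in% c("CLASSICAL_CF", "NON_CLASSICAL_CF")
  } else {
    cohort$phenotype == "CLASSICAL_CF"
  }
  referred <- results$outcome == "CF_REFERRAL"

  in_sens <- diseased & !cohort$meconium_ileus
  tp_sens <- sum(in_sens & referred)
  sens_def <- sum(in_sens) > 0
  sensitivity <- if (sens_def) tp_sens / sum(in_sens) else NA_real_

  tn <- sum(!diseased & !referred)
  fp <- sum(!diseased & referred)
  spec_def <- (tn + fp) > 0
  specificity <- if (spec_def) tn / (tn + fp) else NA_real_

  n_ref <- sum(referred)
  ppv_def <- n_ref > 0
  ppv <- if (ppv_def) sum(diseased & referred) / n_ref else NA_real_

  structure(list(
    strategy = strategy,
    disease_definition = disease_definition,
    n_screened = nrow(cohort),
    abnormal_results = n_ref,
    classical_cf_detected = sum(referred & cohort$phenotype == "CLASSICAL_CF"),
    non_classical_cf_detected =
      sum(referred & cohort$phenotype == "NON_CLASSICAL_CF"),
    carriers_reported = sum(results$outcome == "CARRIER_REPORT"),
    false_positive_referrals = fp,
    dna_tests_used = sum(grepl("PANEL", results$steps, fixed = TRUE)),
    ega_tests_used = sum(grepl("EGA", results$steps, fixed = TRUE)),
    sensitivity = sensitivity, sensitivity_defined = sens_def,
    specificity = specificity, specificity_defined = spec_def,
    ppv = ppv, ppv_defined = ppv_def
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Screening summary:", x$strategy,
      sprintf("(disease = %s)\n", x$disease_definition))
  cat(sprintf("  screened %d | referrals %d (false pos %d) | carriers %d\n",
              x$n_screened, x$abnormal_results, x$false_positive_referrals,
              x$carriers_reported))
  cat(sprintf("  classical CF detected %d | non-classical CF detected %d\n",
              x$classical_cf_detected, x$non_classical_cf_detected))
  pct <- function(v, def) if (def) sprintf("%.4f%%", 100 * v) else "undefined"
  cat(sprintf("  sensitivity %s | specificity %s | PPV %s\n",
              pct(x$sensitivity, x$sensitivity_defined),
              pct(x$specificity, x$specificity_defined),
              pct(x$ppv, x$ppv_defined)))
  cat(sprintf("  DNA panel tests %d | EGA tests %d\n",
              x$dna_tests_used, x$ega_tests_used))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(strategy = x$strategy,
             n_screened = x$n_screened,
             abnormal_results = x$abnormal_results,
             classical_cf = x$classical_cf_detected,
             non_classical_cf = x$non_classical_cf_detected,
             carriers = x$carriers_reported,
             false_positives = x$false_positive_referrals,
             sensitivity = x$sensitivity,
             specificity = x$specificity,
             ppv = x$ppv,
             dna_tests = x$dna_tests_used,
             ega_tests = x$ega_tests_used,
             stringsAsFactors = FALSE)
}

#' Compare screening strategies on one cohort
#'
#' Screens the same cohort under the two pilot strategies, their calculated
#' combination and the national four-step protocol, and returns the four
#' summaries side by side — the simulated analogue of the pilot's strategy
#' comparison table. Structural orderings that must hold by construction
#' (the combined referral set is the IRT/PAP-positive set filtered through
#' the DNA steps, so combined referrals and carriers can only be fewer) are
#' checked and returned in the `checks` attribute.
#'
#' @param cohort cohort data.frame.
#' @param strategies named list of strategy configs; defaults to pilot
#'   IRT/PAP, pilot IRT/DNA-EGA, combined, and the national protocol.
#' @param disease_definition passed to [summarize_screening()].
#' @return data.frame (one row per strategy) with attributes `summaries`
#'   (the `cohort_summary` objects) and `checks` (named logicals:
#'   `combined_subset_of_irt_pap`, `combined_referrals_le_irt_pap`,
#'   `combined_carriers_le_irt_dna`, `national_carriers_le_irt_dna`).
#' @export
compare_strategies <- function(cohort,
                               strategies = list(
                                 irt_pap = pilot_config("IRT_PAP"),
                                 irt_dna_ega = pilot_config("IRT_DNA_EGA"),
                                 combined = pilot_config("COMBINED"),
                                 national = protocol_config()
                               ),
                               disease_definition = "ANY_CF") {
  results <- lapply(strategies, function(s) screen_cohort(cohort, s))
  summaries <- Map(function(res, name) {
    summarize_screening(cohort, res, disease_definition, strategy = name)
  }, results, names(strategies))
  tab <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(tab) <- NULL

  checks <- logical(0)
  if (all(c("irt_pap", "irt_dna_ega", "combined") %in% names(results))) {
    ref_ids <- lapply(results, function(r) {
      r$newborn_id[r$outcome == "CF_REFERRAL"]
    })
    carriers <- vapply(results, function(r) {
      sum(r$outcome == "CARRIER_REPORT")
    }, 0L)
    checks <- c(
      combined_subset_of_irt_pap =
        all(ref_ids$combined %in% ref_ids$irt_pap),
      combined_referrals_le_irt_pap =
        length(ref_ids$combined) <= length(ref_ids$irt_pap),
      combined_carriers_le_irt_dna =
        carriers[["combined"]] <= carriers[["irt_dna_ega"]]
    )
    if ("national" %in% names(results)) {
      checks <- c(checks, national_carriers_le_irt_dna =
                    carriers[["national"]] <= carriers[["irt_dna_ega"]])
    }
  }
  attr(tab, "summaries") <- summaries
  attr(tab, "checks") <- checks
  tab
}
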