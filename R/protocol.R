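#' National four-step protocol configuration
#'
#' Cutoffs and rules of the tiered national screening strategy:
#' \enumerate{
#'   \item IRT below `irt_cutoff` (default 60 ug/l): negative.
#'   \item PAP below `pap_cutoff_mid` (default 3.0 ug/l) when
#'     `irt_cutoff <= IRT < irt_high`, or below `pap_cutoff_high` (default
#'     1.6 ug/l) when `IRT >= irt_high` (default 100 ug/l): negative. The
#'     IRT band is half-open, so IRT exactly at `irt_high` takes the
#'     high-IRT branch.
#'   \item Mutation panel: two panel mutations refer immediately; one
#'     proceeds to extended gene analysis (EGA); none is negative unless the
#'     failsafe fires (`failsafe_enabled` and `IRT >= irt_high` and
#'     `PAP >= pap_cutoff_high`), which sends panel-negative samples to EGA
#'     to catch rare non-panel mutations.
#'   \item EGA (full-gene sequencing): two disease alleles refer; one is a
#'     reportable carrier finding (suppressed when `carrier_reporting` is
#'     off, modelling parental opt-out); none is negative after EGA.
#' }
#' All positivity comparisons are inclusive (>=), negativity strict (<).
#' `ega_sensitivity` is the per-allele detection probability of EGA
#' (default 1: sequencing finds every disease allele).
#'
#' @param irt_cutoff,irt_high IRT thresholds in ug/l, `0 < irt_cutoff <
#'   irt_high`.
#' @param pap_cutoff_mid,pap_cutoff_high PAP thresholds in ug/l (corrected
#'   scale), `pap_cutoff_high <= pap_cutoff_mid`.
#' @param failsafe_enabled send panel-negative, high-IRT/high-PAP samples to
#'   EGA.
#' @param carrier_reporting report single-mutation (carrier) findings.
#' @param ega_sensitivity per-allele EGA detection probability in \[0, 1\].
#' @return list of class `protocol_config`.
#' @export
protocol_config <- function(irt_cutoff = 60, irt_high = 100,
                            pap_cutoff_mid = 3.0, pap_cutoff_high = 1.6,
                            failsafe_enabled = TRUE,
                            carrier_reporting = TRUE,
                            ega_sensitivity = 1.0) {
  stopifnot(is.numeric(irt_cutoff), is.numeric(irt_high),
            is.numeric(pap_cutoff_mid), is.numeric(pap_cutoff_high))
  if (!(irt_cutoff > 0 && irt_cutoff < irt_high)) {
    stop("need 0 < irt_cutoff < irt_high", call. = FALSE)
  }
  if (pap_cutoff_high > pap_cutoff_mid) {
    stop("pap_cutoff_high must not exceed pap_cutoff_mid", call. = FALSE)
  }
  if (pap_cutoff_mid < 0 || pap_cutoff_high < 0) {
    stop("PAP cutoffs must be non-negative", call. = FALSE)
  }
  stopifnot(isTRUE(failsafe_enabled) || isFALSE(failsafe_enabled),
            isTRUE(carrier_reporting) || isFALSE(carrier_reporting),
            is.numeric(ega_sensitivity), ega_sensitivity >= 0,
            ega_sensitivity <= 1)
  structure(list(strategy = "national",
                 irt_cutoff = irt_cutoff, irt_high = irt_high,
                 pap_cutoff_mid = pap_cutoff_mid,
                 pap_cutoff_high = pap_cutoff_high,
                 failsafe_enabled = failsafe_enabled,
                 carrier_reporting = carrier_reporting,
                 ega_sensitivity = ega_sensitivity),
            class = c("protocol_config", "screening_strategy"))
}

#' Pilot-era strategy configuration
#'
#' The two strategies compared in the regional pilot, plus their calculated
#' combination:
#' \itemize{
#'   \item `"IRT_PAP"`: positive (referred) iff `IRT >= irt_cutoff` and
#'     `PAP >= pap_cutoff_mid`, or `IRT >= irt_high` and
#'     `PAP >= pap_cutoff_high`. No DNA testing.
#'   \item `"IRT_DNA_EGA"`: `IRT >= irt_cutoff` triggers the mutation panel;
#'     two panel mutations refer, one proceeds to EGA with the same terminal
#'     rules as the national protocol. No PAP step, no failsafe.
#'   \item `"COMBINED"`: samples flagged by the full IRT/PAP rule are then
#'     processed through panel and EGA (the calculated third scenario:
#'     intersecting both strategies on the same individuals).
#' }
#' Default thresholds are the pilot's: IRT 50/100 ug/l and PAP 1.8/1.0 ug/l
#' on the pilot-era (pre-correction) PAP scale. When the cohort's PAP values
#' are on the corrected scale — as this package's generator emits — set
#' `cohort_on_corrected_scale = TRUE` (the default) and the PAP thresholds
#' are passed through [recalibrate_pap()] before comparison.
#'
#' @param variant `"IRT_PAP"`, `"IRT_DNA_EGA"` or `"COMBINED"`.
#' @param irt_cutoff,irt_high IRT thresholds in ug/l.
#' @param pap_cutoff_mid,pap_cutoff_high PAP thresholds in ug/l on the
#'   pilot-era scale.
#' @param cohort_on_corrected_scale rescale PAP thresholds by 5/3 to match a
#'   corrected-scale cohort.
#' @param carrier_reporting report single-mutation findings (DNA variants).
#' @param ega_sensitivity per-allele EGA detection probability.
#' @return list of class `pilot_config`.
#' @export
pilot_config <- function(variant = c("IRT_PAP", "IRT_DNA_EGA", "COMBINED"),
                         irt_cutoff = 50, irt_high = 100,
                         pap_cutoff_mid = 1.8, pap_cutoff_high = 1.0,
                         cohort_on_corrected_scale = TRUE,
                         carrier_reporting = TRUE,
                         ega_sensitivity = 1.0) {
  variant <- match.arg(variant)
  stopifnot(irt_cutoff > 0, irt_high > irt_cutoff,
            pap_cutoff_mid > 0, pap_cutoff_high > 0,
            isTRUE(cohort_on_corrected_scale) ||
              isFALSE(cohort_on_corrected_scale))
  pap_mid <- if (cohort_on_corrected_scale) recalibrate_pap(pap_cutoff_mid)
             else pap_cutoff_mid
  pap_high <- if (cohort_on_corrected_scale) recalibrate_pap(pap_cutoff_high)
              else pap_cutoff_high
  structure(list(strategy = paste0("pilot_", tolower(variant)),
                 variant = variant,
                 irt_cutoff = irt_cutoff, irt_high = irt_high,
                 pap_cutoff_mid = pap_mid, pap_cutoff_high = pap_high,
                 carrier_reporting = carrier_reporting,
                 ega_sensitivity = ega_sensitivity),
            class = c("pilot_config", "screening_strategy"))
}

#' Correct a pilot-era PAP concentration
#'
#' The PAP assay's calibrators assumed a 5 ul blood content of a 3 mm punch;
#' the true volume is 3 ul, so every pilot-era concentration must be
#' multiplied by exactly 5/3 to land on the corrected scale used by the
#' national protocol.
#'
#' @param raw PAP concentration(s) in ug/l, non-negative.
#' @return `raw * 5 / 3`.
#' @examples
#' recalibrate_pap(3.0) # 5.0
#' recalibrate_pap(1.8) # 3.0, the national mid cutoff
#' @export
recalibrate_pap <- function(raw) {
  if (!is.numeric(raw) || any(is.na(raw)) || any(raw < 0)) {
    stop("PAP concentrations must be non-negative numbers", call. = FALSE)
  }
  raw * 5 / 3
}

count_panel <- function(a1, a2) {
  (a1 == "PANEL_MUTATION") + (a2 == "PANEL_MUTATION")
}

# EGA allele detection: perfect at sensitivity 1, otherwise each disease
# allele is found independently with probability ega_sensitivity (consumes
# the current RNG stream).
ega_detect <- function(a1, a2, sens) {
  nd <- n_disease_alleles(a1, a2)
  if (sens >= 1) return(nd)
  found <- integer(length(nd))
  for (a in list(a1, a2)) {
    dis <- a %in% DISEASE_ALLELES
    found <- found + as.integer(dis & runif(length(nd)) < sens)
  }
  found
}

empty_results <- function() {
  data.frame(newborn_id = integer(), steps = character(),
             outcome = character(), panel_found = integer(),
             ega_found = integer(), via_failsafe = logical(),
             stringsAsFactors = FALSE)
}

screen_cohort_national <- function(cohort, cfg) {
  n <- nrow(cohort)
  irt <- cohort$irt_ugl
  pap <- cohort$pap_ugl
  outcome <- rep("NEGATIVE", n)
  steps <- rep("IRT", n)
  panel_found <- rep(NA_integer_, n)
  ega_found <- rep(NA_integer_, n)
  failsafe <- rep(FALSE, n)

  past1 <- irt >= cfg$irt_cutoff
  steps[past1] <- "IRT|PAP"
  high <- irt >= cfg$irt_high
  pap_pass <- past1 & ((high & pap >= cfg$pap_cutoff_high) |
                       (!high & pap >= cfg$pap_cutoff_mid))
  steps[pap_pass] <- "IRT|PAP|PANEL"
  panel_found[pap_pass] <- count_panel(cohort$allele1, cohort$allele2)[pap_pass]

  two_panel <- pap_pass & panel_found == 2
  outcome[two_panel] <- "CF_REFERRAL"

  to_ega <- pap_pass & panel_found == 1
  fs <- pap_pass & panel_found == 0 & cfg$failsafe_enabled &
    high & pap >= cfg$pap_cutoff_high
  failsafe[fs] <- TRUE
  to_ega <- to_ega | fs
  if (any(to_ega)) {
    steps[to_ega] <- "IRT|PAP|PANEL|EGA"
    found <- ega_detect(cohort$allele1[to_ega], cohort$allele2[to_ega],
                        cfg$ega_sensitivity)
    # panel hits are known mutations: EGA cannot report fewer
    found <- pmax(found, panel_found[to_ega])
    ega_found[to_ega] <- found
    out <- ifelse(found == 2, "CF_REFERRAL",
                  ifelse(found == 1,
                         if (cfg$carrier_reporting) "CARRIER_REPORT"
                         else "NEGATIVE_AFTER_EGA",
                         "NEGATIVE_AFTER_EGA"))
    outcome[to_ega] <- out
  }
  data.frame(newborn_id = cohort$id, steps = steps, outcome = outcome,
             panel_found = panel_found, ega_found = ega_found,
             via_failsafe = failsafe, stringsAsFactors = FALSE)
}

screen_cohort_pilot <- function(cohort, cfg) {
  n <- nrow(cohort)
  irt <- cohort$irt_ugl
  pap <- cohort$pap_ugl
  outcome <- rep("NEGATIVE", n)
  steps <- rep("IRT", n)
  panel_found <- rep(NA_integer_, n)
  ega_found <- rep(NA_integer_, n)

  past1 <- irt >= cfg$irt_cutoff
  pap_rule <- past1 & pap >= cfg$pap_cutoff_mid |
    (irt >= cfg$irt_high & pap >= cfg$pap_cutoff_high)

  if (cfg$variant == "IRT_PAP") {
    steps[past1] <- "IRT|PAP"
    outcome[pap_rule] <- "CF_REFERRAL"
  } else {
    to_panel <- if (cfg$variant == "IRT_DNA_EGA") past1 else {
      steps[past1] <- "IRT|PAP"
      pap_rule
    }
    prefix <- if (cfg$variant == "IRT_DNA_EGA") "IRT" else "IRT|PAP"
    steps[to_panel] <- paste0(prefix, "|PANEL")
    panel_found[to_panel] <-
      count_panel(cohort$allele1, cohort$allele2)[to_panel]
    outcome[to_panel & panel_found == 2] <- "CF_REFERRAL"
    to_ega <- to_panel & panel_found == 1
    if (any(to_ega)) {
      steps[to_ega] <- paste0(prefix, "|PANEL|EGA")
      found <- pmax(ega_detect(cohort$allele1[to_ega], cohort$allele2[to_ega],
                               cfg$ega_sensitivity), 1L)
      ega_found[to_ega] <- found
      outcome[to_ega] <- ifelse(found == 2, "CF_REFERRAL",
                                if (cfg$carrier_reporting) "CARRIER_REPORT"
                                else "NEGATIVE_AFTER_EGA")
    }
  }
  data.frame(newborn_id = cohort$id, steps = steps, outcome = outcome,
             panel_found = panel_found, ega_found = ega_found,
             via_failsafe = FALSE, stringsAsFactors = FALSE)
}

#' Screen a cohort under a strategy
#'
#' Applies a screening strategy to every newborn in the cohort, producing
#' one trace row per newborn in cohort order. Each row records the ordered
#' steps performed (`"IRT|PAP|PANEL|EGA"` prefixes), the terminal outcome
#' (`NEGATIVE`, `CF_REFERRAL`, `CARRIER_REPORT`, `NEGATIVE_AFTER_EGA`), the
#' mutation counts found by panel and EGA (NA where the step was not
#' reached) and whether EGA was entered via the failsafe. Results are
#' per-newborn independent: permuting the cohort permutes the rows.
#'
#' @param cohort cohort data.frame (see [generate_cohort()]).
#' @param strategy a [protocol_config()] or [pilot_config()].
#' @return results data.frame with columns `newborn_id`, `steps`, `outcome`,
#'   `panel_found`, `ega_found`, `via_failsafe`.
#' @export
screen_cohort <- function(cohort, strategy) {
  if (!inherits(strategy, "screening_strategy")) {
    stop("strategy must be a protocol_config() or pilot_config()",
         call. = FALSE)
  }
  if (nrow(cohort) == 0) return(empty_results())
  validate_cohort(cohort)
  if (inherits(strategy, "protocol_config")) {
    screen_cohort_national(cohort, strategy)
  } else {
    screen_cohort_pilot(cohort, strategy)
  }
}

#' Screen one newborn under the national four-step protocol
#'
#' Scalar convenience wrapper around [screen_cohort()]; see
#' [protocol_config()] for the decision tree.
#'
#' @param newborn one-row cohort data.frame.
#' @param cfg a [protocol_config()].
#' @return one-row results data.frame.
#' @export
screen_national <- function(newborn, cfg = protocol_config()) {
  stopifnot(is.data.frame(newborn), nrow(newborn) == 1L)
  if (any(!is.finite(newborn$irt_ugl)) || any(!is.finite(newborn$pap_ugl))) {
    stop("newborn has missing biomarker values", call. = FALSE)
  }
  screen_cohort(newborn, cfg)
}

#' Screen one newborn under a pilot strategy
#'
#' @param newborn one-row cohort data.frame.
#' @param cfg a [pilot_config()].
#' @return one-row results data.frame.
#' @export
screen_pilot <- function(newborn, cfg) {
  stopifnot(is.data.frame(newborn), nrow(newborn) == 1L,
            inherits(cfg, "pilot_config"))
  if (any(!is.finite(newborn$irt_ugl)) || any(!is.finite(newborn$pap_ugl))) {
    stop("newborn has missing biomarker values", call. = FALSE)
  }
  screen_cohort(newborn, cfg)
}
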