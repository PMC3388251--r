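#' Carrier-risk calculus for an autosomal recessive disorder
#'
#' After newborn screening reports a healthy carrier child, the parents'
#' recurrence risk for the disease rises well above the population birth
#' prevalence: one parent is an obligate carrier, and the counselling
#' arithmetic reduces to the population allele frequency. These operations
#' implement that calculus exactly. All functions accept [rational()] inputs
#' and then return exact rationals; plain numeric inputs return numerics.
#'
#' @name risk-calculus
NULL

#' Allele frequency from carrier frequency
#'
#' Under Hardy-Weinberg with a rare disease allele, a carrier frequency of
#' `c` corresponds to an allele frequency of `q = c / 2` (carriers hold one of
#' two alleles; homozygotes are negligible at counselling precision, and this
#' halving convention is the one used in screening-programme practice).
#'
#' @param carrier_freq carrier frequency in \[0, 1\] (numeric or [rational()]).
#' @return `carrier_freq / 2`, same arithmetic type as the input.
#' @examples
#' allele_frequency(rational(1, 30)) # 1/60
#' @export
allele_frequency <- function(carrier_freq) {
  as_prob(carrier_freq, "carrier frequency") / 2
}

#' Birth prevalence from allele frequency
#'
#' Hardy-Weinberg homozygote frequency `q^2`: with `q = 1/60` one in 3600
#' births is affected.
#'
#' @param q allele frequency in \[0, 1\] (numeric or [rational()]).
#' @return `q^2`.
#' @export
birth_prevalence <- function(q) {
  q <- as_prob(q, "allele frequency")
  q * q
}

#' Recurrence risk after a carrier child, programme convention
#'
#' The counselling figure used by the screening programme: the risk that the
#' next pregnancy is affected, given the newborn is a carrier, equals one
#' quarter of the allele frequency (`q / 4`; e.g. `1/4 * 1/60 = 1/240` at a
#' 1:30 carrier frequency). The convention fixes the known-carrier parent and
#' prices only the partner's single unknown allele at `q`.
#'
#' A stricter conditional derivation treats the partner as a potential
#' carrier with probability `2q(1 - q) ~ 2q`, giving approximately `q / 2` —
#' twice this figure; it is available as
#' [risk_given_carrier_child_conditional()] and is never substituted here.
#'
#' @param q allele frequency in \[0, 1\] (numeric or [rational()]).
#' @return `q / 4`.
#' @examples
#' risk_given_carrier_child(rational(1, 60)) # 1/240
#' @export
risk_given_carrier_child <- function(q) {
  as_prob(q, "allele frequency") / 4
}

#' Recurrence risk after a carrier child, conditional derivation
#'
#' Alternative to [risk_given_carrier_child()]: the partner of the obligate
#' carrier is an (undetected) carrier with probability `2q`, and a
#' carrier-by-carrier couple has a 1/4 affected-child risk, so the risk is
#' `2q * 1/4 = q / 2` — a factor 2 above the programme convention. Provided
#' for users who want the conditional treatment; the package's composite
#' report uses the programme convention.
#'
#' @inheritParams risk_given_carrier_child
#' @return `q / 2`.
#' @export
risk_given_carrier_child_conditional <- function(q) {
  as_prob(q, "allele frequency") / 2
}

#' Residual carrier probability after a negative mutation test
#'
#' Bayes update of a parent's carrier status after a negative test with
#' per-carrier detection sensitivity `s`:
#' `P(carrier | negative) = prior (1 - s) / (prior (1 - s) + 1 - prior)`.
#' A panel that misses rare alleles (`s < 1`) leaves a residual risk; full
#' gene sequencing (`s = 1`) removes it. The degenerate case
#' `prior = 1, s = 1` is defined as 0 by the limit convention (a perfect
#' negative test excludes carriership whatever the prior).
#'
#' @param prior pre-test carrier probability in \[0, 1\].
#' @param sensitivity probability the test detects a true carrier, in \[0, 1\].
#' @return posterior carrier probability; rational if both inputs are.
#' @examples
#' residual_carrier_probability(rational(1, 30), 1) # 0
#' residual_carrier_probability(1 / 30, 0.95)
#' @export
residual_carrier_probability <- function(prior, sensitivity) {
  prior <- as_prob(prior, "prior")
  sensitivity <- as_prob(sensitivity, "sensitivity")
  one <- if (is_rational(prior) && is_rational(sensitivity)) rational(1) else 1
  miss <- prior * (one - sensitivity)
  denom <- miss + one - prior
  if ((is_rational(denom) && denom$num == 0) ||
      (!is_rational(denom) && denom == 0)) {
    # prior = 1 and s = 1: negative result has probability 0; limit is 0
    return(if (is_rational(prior)) rational(0) else 0)
  }
  miss / denom
}

#' Full carrier-risk report
#'
#' Composes the risk operations into the complete counselling picture for the
#' parents of a screen-identified carrier child: population allele frequency
#' and birth prevalence, recurrence risk after the carrier child, and the
#' residual risk once the untested parent has had a negative panel or
#' sequencing test.
#'
#' `parent_test` describes the partner of the obligate-carrier parent:
#' `"NONE"` (no testing; residual risk equals the post-carrier-child risk),
#' `"PANEL_NEGATIVE"` (negative targeted mutation panel with sensitivity
#' `test_sensitivity`) or `"SEQUENCING_NEGATIVE"` (negative full-gene
#' sequencing, default sensitivity 1). The residual next-pregnancy risk is
#' the programme-convention risk evaluated at the Bayes-updated partner
#' carrier probability: `1/4 * (residual carrier probability / 2)`.
#'
#' @param carrier_freq population carrier frequency (numeric or [rational()]).
#' @param parent_test one of `"NONE"`, `"PANEL_NEGATIVE"`,
#'   `"SEQUENCING_NEGATIVE"`.
#' @param test_sensitivity per-carrier detection probability of the parental
#'   test; defaults to 1 for sequencing and is required for a panel test.
#' @return An object of class `cf_risk_report`: list with fields
#'   `carrier_frequency`, `allele_frequency`, `birth_prevalence`,
#'   `risk_given_carrier_child`, `residual_parent_carrier_prob`,
#'   `residual_risk_next_pregnancy`, `parent_test`, `test_sensitivity`.
#' @examples
#' full_risk_report(rational(1, 30))
#' full_risk_report(1 / 30, "PANEL_NEGATIVE", test_sensitivity = 0.95)
#' @export
full_risk_report <- function(carrier_freq,
                             parent_test = c("NONE", "PANEL_NEGATIVE",
                                             "SEQUENCING_NEGATIVE"),
                             test_sensitivity = NULL) {
  parent_test <- match.arg(parent_test)
  carrier_freq <- as_prob(carrier_freq, "carrier frequency")
  q <- allele_frequency(carrier_freq)

  s <- switch(parent_test,
    NONE = NULL,
    PANEL_NEGATIVE = {
      if (is.null(test_sensitivity)) {
        stop("test_sensitivity is required for PANEL_NEGATIVE", call. = FALSE)
      }
      test_sensitivity
    },
    SEQUENCING_NEGATIVE = {
      if (is.null(test_sensitivity)) {
        if (is_rational(carrier_freq)) rational(1) else 1
      } else {
        test_sensitivity
      }
    }
  )

  residual_carrier <- if (is.null(s)) {
    carrier_freq
  } else {
    residual_carrier_probability(carrier_freq, s)
  }
  residual_risk <- risk_given_carrier_child(allele_frequency(residual_carrier))

  structure(list(
    carrier_frequency = carrier_freq,
    allele_frequency = q,
    birth_prevalence = birth_prevalence(q),
    risk_given_carrier_child = risk_given_carrier_child(q),
    residual_parent_carrier_prob = residual_carrier,
    residual_risk_next_pregnancy = residual_risk,
    parent_test = parent_test,
    test_sensitivity = s
  ), class = "cf_risk_report")
}

#' @export
print.cf_risk_report <- function(x, ...) {
  fmt <- function(v) {
    if (is_rational(v)) paste0(format(v), " = ", signif(as.numeric(v), 6))
    else format(signif(v, 6))
  }
  cat("Autosomal-recessive carrier-risk report\n")
  cat("  carrier frequency:            ", fmt(x$carrier_frequency), "\n")
  cat("  allele frequency:             ", fmt(x$allele_frequency), "\n")
  cat("  birth prevalence:             ", fmt(x$birth_prevalence), "\n")
  cat("  risk after carrier child:     ", fmt(x$risk_given_carrier_child), "\n")
  cat("  parental test:                ", x$parent_test, "\n")
  cat("  residual partner carrier prob:", fmt(x$residual_parent_carrier_prob), "\n")
  cat("  residual next-pregnancy risk: ", fmt(x$residual_risk_next_pregnancy), "\n")
  invisible(x)
}

#' @export
as.list.cf_risk_report <- function(x, ...) {
  lapply(unclass(x), function(v) if (is_rational(v)) as.numeric(v) else v)
}
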