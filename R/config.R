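#' @importFrom utils packageVersion modifyList
NULL

# Deterministic per-stage seed derived from the root seed and a stage label,
# so adding a stage never shifts another stage's random stream. Plain
# polynomial hash folded into [1, 2^31 - 2]; all arithmetic stays below 2^53
# and therefore exact in doubles.
stage_seed <- function(root_seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483647
  as.integer((root_seed %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483647L
}

# Accept 0.0333, "1/30" or a numeric; fraction strings keep configs readable.
parse_fraction <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && grepl("^\\s*\\d+\\s*/\\s*\\d+\\s*$", x)) {
    parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
    return(parts[1] / parts[2])
  }
  stop("cannot parse '", x, "' as a probability", call. = FALSE)
}

#' Path of the shipped annotated default configuration
#'
#' @return file path of the package's default YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "cfscreen",
              mustWork = TRUE)
}

biomarker_model_from_config <- function(bm) {
  constraints <- lapply(bm$irt_tail_constraints, function(tc) {
    tail_constraint(tc$threshold, tc$exceedance_probability)
  })
  un <- calibrate_unaffected_irt(constraints[[1]], constraints[[2]])
  ratio <- bm$carrier_irt_median_ratio
  med <- bm$medians_ugl
  sig <- bm$sigmas
  params <- data.frame(
    class = rep(PHENOTYPES, each = 2),
    marker = rep(MARKERS, times = 4),
    mu = c(un[["mu"]], log(med$UNAFFECTED$PAP),
           un[["mu"]] + log(ratio), log(med$CARRIER$PAP),
           log(med$CLASSICAL_CF$IRT), log(med$CLASSICAL_CF$PAP),
           log(med$NON_CLASSICAL_CF$IRT), log(med$NON_CLASSICAL_CF$PAP)),
    sigma = c(un[["sigma"]], sig$UNAFFECTED$PAP,
              un[["sigma"]], sig$CARRIER$PAP,
              sig$CLASSICAL_CF$IRT, sig$CLASSICAL_CF$PAP,
              sig$NON_CLASSICAL_CF$IRT, sig$NON_CLASSICAL_CF$PAP),
    stringsAsFactors = FALSE
  )
  biomarker_model(params, rho = if (is.null(bm$rho)) 0 else bm$rho)
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration (see the annotated default at
#' [default_config_path()]), validates every section against the module
#' invariants, and materialises the configured objects. Validation problems
#' are aggregated: a broken config reports every offending field in one
#' error, before any simulation starts.
#'
#' @param path YAML file path; defaults to the shipped configuration.
#' @param overrides named list merged over the parsed YAML (nested lists are
#'   merged recursively), e.g. `list(seed = 7)`.
#' @return list of class `cfscreen_config` with elements `seed`, `raw` (the
#'   merged YAML list), `population` ([population_config()]), `biomarkers`
#'   ([biomarker_model()]), `national` ([protocol_config()]), `pilot` (named
#'   list of the three [pilot_config()] variants) and `carrier_frequency`
#'   (for the risk report).
#' @export
load_config <- function(path = default_config_path(), overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (length(overrides)) raw <- modifyList(raw, overrides)
  errors <- character(0)
  grab <- function(expr, where) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(where, ": ", conditionMessage(e)))
      NULL
    })
  }

  seed <- grab({
    s <- if (is.null(raw$seed)) 1L else raw$seed
    stopifnot(is.numeric(s), length(s) == 1L, s == trunc(s))
    as.integer(s)
  }, "seed")

  population <- grab({
    p <- raw$population
    strata <- lapply(p$strata, function(s) {
      ancestry_stratum(s$name, parse_fraction(s$fraction_of_births),
                       parse_fraction(s$carrier_frequency),
                       parse_fraction(s$panel_detectability))
    })
    population_config(
      cohort_size = p$cohort_size,
      strata = strata,
      fraction_non_classical_given_cf =
        parse_fraction(p$fraction_non_classical_given_cf),
      meconium_ileus_rate_given_cf =
        parse_fraction(p$meconium_ileus_rate_given_cf),
      seed = if (is.null(seed)) 1L else seed
    )
  }, "population")

  biomarkers <- grab(biomarker_model_from_config(raw$biomarkers), "biomarkers")

  national <- grab({
    pr <- raw$protocol
    protocol_config(irt_cutoff = pr$irt_cutoff, irt_high = pr$irt_high,
                    pap_cutoff_mid = pr$pap_cutoff_mid,
                    pap_cutoff_high = pr$pap_cutoff_high,
                    failsafe_enabled = pr$failsafe_enabled,
                    carrier_reporting = pr$carrier_reporting,
                    ega_sensitivity = pr$ega_sensitivity)
  }, "protocol")

  pilot <- grab({
    pl <- raw$pilot
    mk <- function(variant) {
      pilot_config(variant, irt_cutoff = pl$irt_cutoff,
                   irt_high = pl$irt_high,
                   pap_cutoff_mid = pl$pap_cutoff_mid,
                   pap_cutoff_high = pl$pap_cutoff_high,
                   cohort_on_corrected_scale = pl$cohort_on_corrected_scale,
                   carrier_reporting = pl$carrier_reporting)
    }
    list(irt_pap = mk("IRT_PAP"), irt_dna_ega = mk("IRT_DNA_EGA"),
         combined = mk("COMBINED"))
  }, "pilot")

  carrier_frequency <- grab({
    parse_fraction(raw$risk$carrier_frequency)
  }, "risk")

  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(seed = seed, raw = raw, population = population,
                 biomarkers = biomarkers, national = national,
                 pilot = pilot, carrier_frequency = carrier_frequency),
            class = "cfscreen_config")
}
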