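ALLELE_STATES <- c("WILDTYPE", "PANEL_MUTATION", "NON_PANEL_MUTATION")
DISEASE_ALLELES <- c("PANEL_MUTATION", "NON_PANEL_MUTATION")

#' Ancestry stratum of the birth cohort
#'
#' One sub-population with its own CF carrier frequency and its own
#' probability that a disease allele belongs to the targeted mutation panel
#' (panel detectability). Panel detectability is an allele-level property:
#' each disease allele is independently panel-detectable, so patient-level
#' panel sensitivity emerges from the genotype.
#'
#' @param name stratum label.
#' @param fraction_of_births share of births in this stratum.
#' @param carrier_frequency CF carrier frequency (two alleles, one mutant).
#' @param panel_detectability probability a disease allele is one of the
#'   panel mutations.
#' @return list of class `ancestry_stratum`.
#' @export
ancestry_stratum <- function(name, fraction_of_births, carrier_frequency,
                             panel_detectability) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (p in list(fraction_of_births, carrier_frequency, panel_detectability)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("stratum probabilities must be single values in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(name = name,
                 fraction_of_births = fraction_of_births,
                 carrier_frequency = carrier_frequency,
                 panel_detectability = panel_detectability),
            class = "ancestry_stratum")
}

#' Default ancestry strata of the Dutch birth cohort
#'
#' Three strata: the general population (90% of births, carrier frequency
#' 1:30, panel detectability 0.95 — an assumption for a panel covering all
#' common local mutations) and two migrant strata with carrier frequency
#' about 1:50 and the published panel sensitivities (Turkish ancestry 44%,
#' North African ancestry 69%). The 5%/5% birth shares are assumptions; all
#' values are configurable.
#'
#' @return list of [ancestry_stratum()] objects.
#' @export
default_strata <- function() {
  list(
    ancestry_stratum("dutch_general", 0.90, 1 / 30, 0.95),
    ancestry_stratum("turkish", 0.05, 1 / 50, 0.44),
    ancestry_stratum("north_african", 0.05, 1 / 50, 0.69)
  )
}

#' Synthetic-cohort configuration
#'
#' @param cohort_size number of newborns to generate (>= 1).
#' @param strata list of [ancestry_stratum()]; birth fractions must sum to 1
#'   (tolerance 1e-12).
#' @param fraction_non_classical_given_cf probability that a two-disease-
#'   allele genotype presents as non-classical (milder) CF. Default 0.28.
#' @param meconium_ileus_rate_given_cf probability a CF newborn is already
#'   diagnosed via meconium ileus before screening. Default 4/29 (four such
#'   infants per 25 screen-detected patients per year).
#' @param seed root RNG seed, integer.
#' @return list of class `population_config`.
#' @export
population_config <- function(cohort_size,
                              strata = default_strata(),
                              fraction_non_classical_given_cf = 0.28,
                              meconium_ileus_rate_given_cf = 4 / 29,
                              seed = 1L) {
  stopifnot(is.numeric(cohort_size), length(cohort_size) == 1L,
            cohort_size == trunc(cohort_size))
  if (cohort_size < 1) stop("cohort_size must be >= 1", call. = FALSE)
  stopifnot(is.list(strata), length(strata) >= 1L)
  if (!all(vapply(strata, inherits, TRUE, "ancestry_stratum"))) {
    stop("strata must be ancestry_stratum objects", call. = FALSE)
  }
  fr <- vapply(strata, `[[`, 0, "fraction_of_births")
  if (abs(sum(fr) - 1) > 1e-12) {
    stop("stratum birth fractions must sum to 1 (got ", sum(fr), ")",
         call. = FALSE)
  }
  nm <- vapply(strata, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate stratum names", call. = FALSE)
  for (p in list(fraction_non_classical_given_cf,
                 meconium_ileus_rate_given_cf)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("rates must be single values in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == trunc(seed))
  structure(list(cohort_size = as.integer(cohort_size),
                 strata = stats::setNames(strata, nm),
                 fraction_non_classical_given_cf =
                   fraction_non_classical_given_cf,
                 meconium_ileus_rate_given_cf = meconium_ileus_rate_given_cf,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Sample a CFTR genotype for one stratum
#'
#' Hardy-Weinberg sampling: each of the two alleles is independently a
#' disease allele with probability `q = carrier_frequency / 2`, and each
#' disease allele is independently a panel mutation with probability
#' `panel_detectability` (otherwise a rare, non-panel mutation).
#'
#' @param stratum an [ancestry_stratum()].
#' @param n number of genotypes to draw.
#' @return data.frame with character columns `allele1`, `allele2` taking
#'   values `"WILDTYPE"`, `"PANEL_MUTATION"`, `"NON_PANEL_MUTATION"`.
#' @export
sample_genotype <- function(stratum, n = 1) {
  stopifnot(inherits(stratum, "ancestry_stratum"), n >= 0)
  q <- stratum$carrier_frequency / 2
  draw <- function() {
    mutant <- runif(n) < q
    state <- rep("WILDTYPE", n)
    k <- sum(mutant)
    if (k > 0) {
      state[mutant] <- ifelse(runif(k) < stratum$panel_detectability,
                              "PANEL_MUTATION", "NON_PANEL_MUTATION")
    }
    state
  }
  data.frame(allele1 = draw(), allele2 = draw(), stringsAsFactors = FALSE)
}

n_disease_alleles <- function(a1, a2) {
  (a1 %in% DISEASE_ALLELES) + (a2 %in% DISEASE_ALLELES)
}

assign_phenotype <- function(a1, a2, fraction_non_classical) {
  nd <- n_disease_alleles(a1, a2)
  ph <- rep("UNAFFECTED", length(nd))
  ph[nd == 1] <- "CARRIER"
  cf <- which(nd == 2)
  if (length(cf)) {
    nc <- runif(length(cf)) < fraction_non_classical
    ph[cf] <- ifelse(nc, "NON_CLASSICAL_CF", "CLASSICAL_CF")
  }
  ph
}

build_cohort <- function(id, stratum, geno, config, model) {
  phenotype <- assign_phenotype(geno$allele1, geno$allele2,
                                config$fraction_non_classical_given_cf)
  mi <- rep(FALSE, length(id))
  is_cf <- phenotype %in% c("CLASSICAL_CF", "NON_CLASSICAL_CF")
  if (any(is_cf)) {
    mi[is_cf] <- runif(sum(is_cf)) < config$meconium_ileus_rate_given_cf
  }
  irt <- numeric(length(id))
  pap <- numeric(length(id))
  for (ph in PHENOTYPES) { # fixed class order keeps the draw order stable
    idx <- which(phenotype == ph)
    if (length(idx)) {
      bm <- sample_biomarkers(ph, model, length(idx))
      irt[idx] <- bm$irt_ugl
      pap[idx] <- bm$pap_ugl
    }
  }
  data.frame(id = as.integer(id), stratum = stratum,
             allele1 = geno$allele1, allele2 = geno$allele2,
             phenotype = phenotype, meconium_ileus = mi,
             irt_ugl = irt, pap_ugl = pap, stringsAsFactors = FALSE)
}

#' Generate a synthetic newborn cohort
#'
#' Draws `config$cohort_size` newborns: stratum membership multinomially by
#' birth fraction, Hardy-Weinberg genotypes per stratum, phenotype class from
#' the genotype, a meconium-ileus flag for CF newborns, and genotype-
#' conditional IRT and PAP concentrations from the biomarker model. The whole
#' cohort is drawn from a single stream seeded with `config$seed` in a fixed
#' field order, so an identical configuration reproduces a bit-identical
#' table.
#'
#' @param config a [population_config()].
#' @param model a calibrated [biomarker_model()].
#' @return data.frame with columns `id`, `stratum`, `allele1`, `allele2`,
#'   `phenotype`, `meconium_ileus`, `irt_ugl`, `pap_ugl`.
#' @export
generate_cohort <- function(config, model = default_biomarker_model()) {
  stopifnot(inherits(config, "population_config"))
  check_calibrated(model)
  n <- config$cohort_size
  set.seed(config$seed)
  fr <- vapply(config$strata, `[[`, 0, "fraction_of_births")
  stratum_idx <- sample.int(length(fr), n, replace = TRUE, prob = fr)
  stratum <- names(config$strata)[stratum_idx]
  geno <- data.frame(allele1 = rep("WILDTYPE", n),
                     allele2 = rep("WILDTYPE", n), stringsAsFactors = FALSE)
  for (k in seq_along(config$strata)) { # fixed stratum order for determinism
    idx <- which(stratum_idx == k)
    if (length(idx)) {
      g <- sample_genotype(config$strata[[k]], length(idx))
      geno$allele1[idx] <- g$allele1
      geno$allele2[idx] <- g$allele2
    }
  }
  build_cohort(seq_len(n), stratum, geno, config, model)
}

#' Generate a CF-enriched cohort by conditional oversampling
#'
#' Draws newborns conditional on carrying two disease alleles, i.e. an
#' importance sample of the CF sub-population. Stratum membership is drawn
#' with probability proportional to `fraction_of_births * q^2` (the births-
#' weighted CF prevalence of each stratum), both alleles are disease alleles,
#' and each is a panel mutation with the stratum's detectability. Every row
#' represents `birth_prevalence` of probability mass in the full cohort; for
#' CF-conditional quantities such as screening sensitivity the weights cancel
#' and the rows can be used directly.
#'
#' @param n_cf number of CF-genotype newborns to draw.
#' @param config a [population_config()] (its `cohort_size` is ignored).
#' @param model a calibrated [biomarker_model()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return cohort data.frame as [generate_cohort()], all rows CF genotypes.
#' @export
generate_cf_cohort <- function(n_cf, config, model = default_biomarker_model(),
                               seed = config$seed) {
  stopifnot(inherits(config, "population_config"),
            is.numeric(n_cf), length(n_cf) == 1L, n_cf >= 1)
  check_calibrated(model)
  n_cf <- as.integer(n_cf)
  set.seed(seed)
  fr <- vapply(config$strata, `[[`, 0, "fraction_of_births")
  q <- vapply(config$strata, `[[`, 0, "carrier_frequency") / 2
  w <- fr * q^2
  if (sum(w) == 0) {
    stop("no stratum has a positive carrier frequency; CF-conditional ",
         "sampling is undefined", call. = FALSE)
  }
  stratum_idx <- sample.int(length(w), n_cf, replace = TRUE, prob = w)
  stratum <- names(config$strata)[stratum_idx]
  det <- vapply(config$strata, `[[`, 0, "panel_detectability")[stratum_idx]
  allele_state <- function() {
    ifelse(runif(n_cf) < det, "PANEL_MUTATION", "NON_PANEL_MUTATION")
  }
  geno <- data.frame(allele1 = allele_state(), allele2 = allele_state(),
                     stringsAsFactors = FALSE)
  build_cohort(seq_len(n_cf), stratum, geno, config, model)
}

#' Validate a cohort table
#'
#' Checks the invariants every cohort row must satisfy: known allele states
#' and phenotype labels, phenotype consistent with the allele count, strictly
#' positive IRT, non-negative PAP, and meconium ileus confined to CF
#' phenotypes. Errors name the first offending row.
#'
#' @param cohort cohort data.frame.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  cols <- c("id", "stratum", "allele1", "allele2", "phenotype",
            "meconium_ileus", "irt_ugl", "pap_ugl")
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rows, msg) {
    if (any(rows)) {
      stop("cohort row ", which(rows)[1L], ": ", msg, call. = FALSE)
    }
  }
  fail(!(cohort$allele1 %in% ALLELE_STATES) |
         !(cohort$allele2 %in% ALLELE_STATES), "unknown allele state")
  fail(!(cohort$phenotype %in% PHENOTYPES), "unknown phenotype label")
  nd <- n_disease_alleles(cohort$allele1, cohort$allele2)
  expected <- ifelse(nd == 0, "UNAFFECTED",
                     ifelse(nd == 1, "CARRIER", "CF"))
  got <- ifelse(cohort$phenotype %in% c("CLASSICAL_CF", "NON_CLASSICAL_CF"),
                "CF", cohort$phenotype)
  fail(expected != got, "phenotype inconsistent with allele count")
  fail(!is.finite(cohort$irt_ugl) | cohort$irt_ugl <= 0,
       "IRT must be strictly positive")
  fail(!is.finite(cohort$pap_ugl) | cohort$pap_ugl < 0,
       "PAP must be non-negative")
  fail(cohort$meconium_ileus & got != "CF",
       "meconium ileus flagged on a non-CF phenotype")
  invisible(cohort)
}
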