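COHORT_COLS <- c("id", "stratum", "allele1", "allele2", "phenotype",
                 "meconium_ileus", "irt_ugl", "pap_ugl")

#' Write a cohort to a tab-separated file
#'
#' UTF-8 TSV with a header row and exactly the columns `id`, `stratum`,
#' `allele1`, `allele2`, `phenotype`, `meconium_ileus`, `irt_ugl`,
#' `pap_ugl`. Booleans are serialized as 0/1 and concentrations with 12
#' significant digits, so [read_cohort()] round-trips a cohort
#' field-for-field (floats to better than 9 significant digits).
#'
#' @param cohort cohort data.frame (validated before writing).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) > 0) validate_cohort(cohort)
  out <- cohort[, COHORT_COLS, drop = FALSE]
  out$meconium_ileus <- as.integer(out$meconium_ileus)
  out$irt_ugl <- sprintf("%.12g", out$irt_ugl)
  out$pap_ugl <- sprintf("%.12g", out$pap_ugl)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from a tab-separated file
#'
#' Counterpart of [write_cohort()]. Malformed input — missing columns,
#' unknown phenotype or allele labels, non-numeric or negative
#' concentrations, booleans outside 0/1 — fails with an error naming the
#' offending (1-based, header excluded) row.
#'
#' @param path TSV file produced by [write_cohort()] or following the same
#'   contract.
#' @return cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(COHORT_COLS, names(raw))
  if (length(miss)) {
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(data.frame(id = integer(), stratum = character(),
                      allele1 = character(), allele2 = character(),
                      phenotype = character(), meconium_ileus = logical(),
                      irt_ugl = numeric(), pap_ugl = numeric(),
                      stringsAsFactors = FALSE))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v)
    if (any(bad)) {
      stop("cohort file row ", which(bad)[1L], ": non-numeric ", what,
           call. = FALSE)
    }
    v
  }
  mi <- num("meconium_ileus", "meconium_ileus")
  bad <- !(mi %in% c(0, 1))
  if (any(bad)) {
    stop("cohort file row ", which(bad)[1L],
         ": meconium_ileus must be 0 or 1", call. = FALSE)
  }
  cohort <- data.frame(
    id = as.integer(num("id", "id")),
    stratum = raw$stratum,
    allele1 = raw$allele1,
    allele2 = raw$allele2,
    phenotype = raw$phenotype,
    meconium_ileus = mi == 1,
    irt_ugl = num("irt_ugl", "IRT concentration"),
    pap_ugl = num("pap_ugl", "PAP concentration"),
    stringsAsFactors = FALSE
  )
  tryCatch(validate_cohort(cohort), error = function(e) {
    stop("cohort file ", conditionMessage(e), call. = FALSE)
  })
  cohort
}
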