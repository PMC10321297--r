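# Patient registry: reading, validation, eligibility filtering, dose groups.

MANIFESTATIONS <- c(DM = "onset_dm", OA = "onset_oa",
                    DI = "onset_di", HL = "onset_hl")

REQUIRED_COLUMNS <- c("patient_id", "sex", "allele1", "allele2",
                      unname(MANIFESTATIONS))

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  out
}

.parse_age <- function(x, column, ids) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- nzchar(raw) & !is.na(raw) & is.na(out)
  if (any(bad))
    warning(sprintf(
      "%s: non-numerical age of onset for patient(s) %s; treated as absent",
      column, paste(ids[bad], collapse = ", ")), call. = FALSE)
  neg <- !is.na(out) & (out < 0 | !is.finite(out))
  if (any(neg)) {
    warning(sprintf(
      "%s: negative or non-finite age for patient(s) %s; treated as absent",
      column, paste(ids[neg], collapse = ", ")), call. = FALSE)
    out[neg] <- NA_real_
  }
  out
}

#' Read a patient registry file
#'
#' Reads a delimited registry (one row per patient) with required columns
#' `patient_id`, `sex`, `allele1`, `allele2`, `onset_dm`, `onset_oa`,
#' `onset_di`, `onset_hl`; an optional `source` column is carried through.
#' The delimiter is auto-detected from the extension (`.csv` comma,
#' everything else tab). Empty cells mean absent. Non-numeric onset entries
#' (e.g. `"childhood"`) are kept as absent with a warning — such records are
#' later excluded from the affected manifestation only, mirroring the
#' numerical-age-of-onset eligibility rule.
#'
#' @param path Path to a UTF-8 TSV/CSV registry file.
#' @return A `data.frame` of class `wfs_registry` with character allele
#'   columns, normalised `sex` (`male`/`female`/`unknown`) and numeric onset
#'   columns in years.
#' @seealso [filter_eligible()]
#' @export
read_registry <- function(path) {
  if (!file.exists(path))
    stop(sprintf("registry file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(tab))
  if (length(missing_cols))
    stop(sprintf("registry %s is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  ids <- trimws(tab$patient_id)
  if (anyDuplicated(ids))
    stop(sprintf("registry %s has duplicate patient_id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  out <- data.frame(
    patient_id = ids,
    sex = .normalize_sex(tab$sex),
    allele1 = trimws(tab$allele1),
    allele2 = trimws(tab$allele2),
    stringsAsFactors = FALSE)
  for (m in names(MANIFESTATIONS))
    out[[MANIFESTATIONS[[m]]]] <- .parse_age(tab[[MANIFESTATIONS[[m]]]],
                                             MANIFESTATIONS[[m]], ids)
  out$source <- if ("source" %in% names(tab)) trimws(tab$source)
                else NA_character_
  class(out) <- c("wfs_registry", "data.frame")
  out
}

# Parse both alleles of every row once; returns a per-patient annotation
# data.frame plus the list of parsed variants.
.annotate_genotypes <- function(registry, domains = NULL) {
  n <- nrow(registry)
  cls1 <- cls2 <- character(n)
  nsfs <- n_inframe <- rep(NA_integer_, n)
  tm <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    a1 <- registry$allele1[i]; a2 <- registry$allele2[i]
    if (is.na(a1) || is.na(a2) || !nzchar(a1) || !nzchar(a2)) {
      reason[i] <- "missing_allele"
      next
    }
    v1 <- withCallingHandlers(parse_protein_descriptor(a1),
                              warning = function(w) invokeRestart("muffleWarning"))
    v2 <- withCallingHandlers(parse_protein_descriptor(a2),
                              warning = function(w) invokeRestart("muffleWarning"))
    cls1[i] <- broad_class(v1); cls2[i] <- broad_class(v2)
    if (cls1[i] == "OTHER" || cls2[i] == "OTHER") {
      reason[i] <- "unparseable_allele"
      next
    }
    nsfs[i] <- count_nsfs_alleles(v1, v2)
    n_inframe[i] <- 2L - nsfs[i]
    if (!is.null(domains) && n_inframe[i] >= 1L)
      tm[i] <- count_tm_inframe(v1, v2, domains)
  }
  data.frame(patient_id = registry$patient_id, genotype_exclusion = reason,
             nsfs_dose = nsfs, n_inframe = n_inframe, tm_dose = tm,
             stringsAsFactors = FALSE)
}

#' Classify every genotype in a registry
#'
#' Per-patient allele classification table: NSFS dose (number of
#' nonsense/frameshift alleles, 0-2), number of in-frame alleles, and — when
#' a domain table is supplied — the TM dose (number of in-frame alleles
#' overlapping a transmembrane range). Patients with a missing or
#' unclassifiable allele get an exclusion reason instead of doses.
#'
#' @param registry A `wfs_registry` from [read_registry()].
#' @param domains Optional [domain_table()]; without it `tm_dose` is `NA`.
#' @return A `data.frame` with columns `patient_id`, `genotype_exclusion`,
#'   `nsfs_dose`, `n_inframe`, `tm_dose`.
#' @export
classify_registry <- function(registry, domains = NULL) {
  stopifnot(is.data.frame(registry))
  .annotate_genotypes(registry, domains)
}

#' Filter a cohort to patients eligible for one manifestation
#'
#' Applies the eligibility rules for a per-manifestation onset analysis:
#' a patient is retained iff (i) both allele descriptors are present and
#' classify as NSFS or in-frame (not OTHER), and (ii) a numerical age of
#' onset is recorded for the requested manifestation. Eligibility is
#' per-manifestation: the same patient may be eligible for DM and ineligible
#' for HL. Excluded patients are reported, each with a machine-readable
#' reason (`missing_allele`, `unparseable_allele`, `missing_onset`), in the
#' `"exclusions"` attribute of the result.
#'
#' @param registry A `wfs_registry` (or compatible `data.frame`).
#' @param manifestation One of `"DM"`, `"OA"`, `"DI"`, `"HL"`.
#' @param domains Optional [domain_table()] used to attach `tm_dose` to
#'   genotypes with at least one in-frame allele.
#' @return A `data.frame` of class `wfs_grouped` with one row per eligible
#'   patient: `patient_id`, `sex`, `onset` (years), `nsfs_dose`,
#'   `n_inframe`, `tm_dose` (NA when undefined). Attributes: `manifestation`
#'   and `exclusions`.
#' @export
filter_eligible <- function(registry, manifestation, domains = NULL) {
  manifestation <- match.arg(manifestation, names(MANIFESTATIONS))
  geno <- .annotate_genotypes(registry, domains)
  onset <- registry[[MANIFESTATIONS[[manifestation]]]]
  reason <- geno$genotype_exclusion
  reason[is.na(reason) & is.na(onset)] <- "missing_onset"
  keep <- is.na(reason)
  out <- data.frame(
    patient_id = registry$patient_id[keep],
    sex = registry$sex[keep],
    onset = onset[keep],
    nsfs_dose = geno$nsfs_dose[keep],
    n_inframe = geno$n_inframe[keep],
    tm_dose = geno$tm_dose[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "manifestation") <- manifestation
  attr(out, "exclusions") <- data.frame(
    patient_id = registry$patient_id[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  class(out) <- c("wfs_grouped", "data.frame")
  out
}
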