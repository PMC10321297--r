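# Synthetic patient-registry generator.
#
# Emulates the statistical structure the analysis assumes: a biallelic
# recessive cohort with a mixture of truncating (NSFS) and in-frame alleles,
# log-normal onset ages with allele-dose shifts, a male shift for diabetes
# mellitus, and per-manifestation missingness. A fictitious protein
# ("SYNP01") with synthetic transmembrane ranges stands in for a real
# annotation snapshot so no external database is needed.

# run expr with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Synthetic transmembrane-domain table
#'
#' Nine 21-residue membrane-spanning ranges on a fictitious 890-residue
#' protein, laid out like a polytopic ER membrane protein. Purely synthetic:
#' suitable for tests and simulations, not for analysing real variants.
#'
#' @return A [domain_table()] with `protein_id = "SYNP01"`.
#' @export
synthetic_domain_table <- function() {
  starts <- c(311L, 342L, 383L, 418L, 446L, 494L, 529L, 561L, 627L)
  domain_table(starts, starts + 20L,
               protein_id = "SYNP01",
               provenance = "synthetic fixture bundled with wfsdose; not a real annotation")
}

#' Simulation parameters for the synthetic registry
#'
#' Defaults describe the registry the generator emulates: ~350 enrolled
#' biallelic patients, onset medians of 8/12/13/14 years (DM/OA/DI/HL) in
#' the zero-dose group, a 1.5-year-per-allele NSFS shift, a 2-year-per-allele
#' transmembrane shift, a 1.5-year male shift for DM only, and
#' per-manifestation missingness chosen so eligible sample sizes fall in the
#' 100-330 range typical of pooled rare-disease registries.
#'
#' @param n_patients Number of registry rows (ignored if `dose_group_n` is
#'   given).
#' @param nsfs_allele_freq Probability an allele is NSFS (truncating).
#' @param tm_fraction Probability an in-frame allele falls in a
#'   transmembrane range.
#' @param baseline_onset Named list per manifestation: `c(median, sdlog)` —
#'   zero-dose onset median in years and log-scale SD of the log-normal
#'   onset distribution.
#' @param nsfs_shift Years subtracted from the onset median per NSFS allele.
#' @param tm_shift Years subtracted per transmembrane in-frame allele.
#' @param male_dm_shift Years subtracted for males, DM only.
#' @param missing_rate Named per-manifestation probability the onset is
#'   absent.
#' @param missing_allele_rate Probability a row lacks one allele descriptor.
#' @param shift_mode `"multiplicative"` (shifts move the log-normal location;
#'   ages stay positive by construction) or `"additive"` (shifts subtracted
#'   from sampled ages, truncated at 0).
#' @param dose_group_n Optional integer vector `c(n0, n1, n2)` fixing exact
#'   NSFS dose-group sizes instead of the binomial allele mixture.
#' @param protein_length Length of the fictitious protein.
#' @param seed RNG seed; the same seed reproduces the cohort byte-for-byte.
#' @return Validated list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 350L,
                       nsfs_allele_freq = 0.55,
                       tm_fraction = 0.5,
                       baseline_onset = list(DM = c(median = 8, sdlog = 0.45),
                                             OA = c(median = 12, sdlog = 0.35),
                                             DI = c(median = 13, sdlog = 0.30),
                                             HL = c(median = 14, sdlog = 0.40)),
                       nsfs_shift = 1.5,
                       tm_shift = 2.0,
                       male_dm_shift = 1.5,
                       missing_rate = c(DM = 0.06, OA = 0.11,
                                        DI = 0.56, HL = 0.43),
                       missing_allele_rate = 0.04,
                       shift_mode = c("multiplicative", "additive"),
                       dose_group_n = NULL,
                       protein_length = 890L,
                       seed = 1L) {
  shift_mode <- match.arg(shift_mode)
  if (!is.null(dose_group_n)) {
    stopifnot(length(dose_group_n) == 3L, all(dose_group_n >= 0))
    n_patients <- sum(dose_group_n)
  }
  probs <- c(nsfs_allele_freq, tm_fraction, missing_allele_rate,
             unlist(missing_rate))
  if (any(probs < 0 | probs > 1))
    stop("sim_params: probabilities must lie in [0, 1]", call. = FALSE)
  if (n_patients < 1) stop("sim_params: n_patients must be >= 1",
                           call. = FALSE)
  stopifnot(setequal(names(baseline_onset), names(MANIFESTATIONS)),
            setequal(names(missing_rate), names(MANIFESTATIONS)))
  for (m in names(baseline_onset)) {
    b <- baseline_onset[[m]]
    if (b[["median"]] <= 0 || b[["sdlog"]] <= 0)
      stop(sprintf("sim_params: baseline_onset for %s must be positive", m),
           call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 nsfs_allele_freq = nsfs_allele_freq,
                 tm_fraction = tm_fraction,
                 baseline_onset = baseline_onset,
                 nsfs_shift = nsfs_shift, tm_shift = tm_shift,
                 male_dm_shift = male_dm_shift,
                 missing_rate = missing_rate,
                 missing_allele_rate = missing_allele_rate,
                 shift_mode = shift_mode,
                 dose_group_n = if (is.null(dose_group_n)) NULL
                                else as.integer(dose_group_n),
                 protein_length = as.integer(protein_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Write / read simulation parameters as a YAML config
#' @param params A [sim_params()] object.
#' @param path File path.
#' @return `path` (write) or a `sim_params` object (read).
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  out <- unclass(params)
  # named atomic vectors must become mappings, or YAML drops the names
  out$baseline_onset <- lapply(out$baseline_onset, as.list)
  out$missing_rate <- as.list(out$missing_rate)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$baseline_onset <- lapply(raw$baseline_onset, function(b)
    c(median = b[["median"]], sdlog = b[["sdlog"]]))
  raw$missing_rate <- unlist(raw$missing_rate)
  do.call(sim_params, raw)
}

AA3_NAMES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
               "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
               "Tyr", "Val")

# gap intervals (non-TM) of the protein, positions 2..len (1 avoided so a
# sampled missense can never be a start-loss)
.nontm_gaps <- function(t, len) {
  r <- t$ranges
  if (!nrow(r)) return(data.frame(start = 2L, end = len))
  gaps <- data.frame(start = c(2L, r$end + 1L), end = c(r$start - 1L, len))
  gaps[gaps$start <= gaps$end, , drop = FALSE]
}

# sample an interval of length L fully inside (tm = FALSE) the gaps, or
# starting inside a TM range (tm = TRUE: guarantees overlap)
.sample_interval <- function(tm, L, t, gaps) {
  if (tm) {
    r <- t$ranges[sample.int(nrow(t$ranges), 1L), ]
    s <- sample(r$start:r$end, 1L)
  } else {
    ok <- gaps[gaps$end - gaps$start + 1L >= L, , drop = FALSE]
    g <- ok[sample.int(nrow(ok), 1L), ]
    s <- sample(g$start:(g$end - L + 1L), 1L)
  }
  c(s, s + L - 1L)
}

.random_aa <- function(n = 1L, exclude = NULL) {
  pool <- setdiff(AA3_NAMES, exclude)
  pool[sample.int(length(pool), n, replace = TRUE)]
}

# one synthetic allele descriptor; returns list(text, class, tm)
.sample_allele <- function(is_nsfs, tm, t, gaps, len) {
  if (is_nsfs) {
    pos <- sample(2:(len - 30L), 1L)
    ref <- .random_aa()
    if (stats::runif(1) < 0.5) {
      txt <- sprintf("p.%s%dTer", ref, pos)
    } else {
      txt <- sprintf("p.%s%d%sfs*%d", ref, pos, .random_aa(exclude = ref),
                     sample(2:60, 1L))
    }
    return(list(text = txt, tm = NA))
  }
  kind <- sample(c("mis", "del", "ins", "delins"), 1L,
                 prob = c(0.80, 0.10, 0.05, 0.05))
  if (kind == "mis") {
    iv <- .sample_interval(tm, 1L, t, gaps)
    ref <- .random_aa()
    txt <- sprintf("p.%s%d%s", ref, iv[1], .random_aa(exclude = c(ref, "Met")))
  } else if (kind == "ins") {
    iv <- .sample_interval(tm, 2L, t, gaps)   # two flanking residues
    txt <- sprintf("p.%s%d_%s%dins%s", .random_aa(), iv[1], .random_aa(),
                   iv[2], paste(.random_aa(sample(1:2, 1L)), collapse = ""))
  } else {
    L <- sample(1:3, 1L)
    iv <- .sample_interval(tm, L, t, gaps)
    lhs <- if (L == 1L) sprintf("p.%s%d", .random_aa(), iv[1])
           else sprintf("p.%s%d_%s%d", .random_aa(), iv[1], .random_aa(),
                        iv[2])
    txt <- if (kind == "del") paste0(lhs, "del")
           else paste0(lhs, "delins",
                       paste(.random_aa(sample(1:2, 1L)), collapse = ""))
  }
  list(text = txt, tm = tm)
}

#' Generate a synthetic patient registry
#'
#' Draws a cohort under the given [sim_params()]: per-patient NSFS allele
#' dose (binomial allele mixture, or fixed group sizes), syntactically valid
#' protein-level descriptors whose positions fall inside or outside the
#' bundled synthetic transmembrane table according to `tm_fraction`,
#' log-normal onset ages shifted per NSFS allele, per TM in-frame allele and
#' (DM only) for males, and per-manifestation missingness. The ground truth
#' of every patient (true doses and noiseless group assignment) is returned
#' alongside, so classification can be audited end to end.
#'
#' @param params A [sim_params()] object.
#' @param domains A [domain_table()]; default [synthetic_domain_table()].
#' @return Object of class `wfs_cohort_sim`: list with `registry` (a
#'   `wfs_registry` data frame in the standard schema), `truth` (data frame
#'   with `patient_id`, `nsfs_dose`, `tm_dose`, `n_inframe`, `sex`),
#'   `domains` and `params`. Fully reproducible from `params$seed`.
#' @seealso [write_cohort()], [run_power_study()]
#' @export
generate_cohort <- function(params = sim_params(),
                            domains = synthetic_domain_table()) {
  stopifnot(inherits(params, "sim_params"), inherits(domains, "domain_table"))
  .with_seed(params$seed, {
    n <- params$n_patients
    len <- params$protein_length
    gaps <- .nontm_gaps(domains, len)
    doses <- if (!is.null(params$dose_group_n))
               rep(0:2, times = params$dose_group_n)
             else stats::rbinom(n, 2L, params$nsfs_allele_freq)
    sex <- sample(c("male", "female", "unknown"), n, replace = TRUE,
                  prob = c(0.49, 0.49, 0.02))
    allele1 <- allele2 <- character(n)
    tm_dose <- rep(NA_integer_, n)
    n_inframe <- 2L - doses
    for (i in seq_len(n)) {
      homozygous <- doses[i] != 1L && stats::runif(1) < 0.15
      mk <- function(is_nsfs) {
        tm <- !is_nsfs && stats::runif(1) < params$tm_fraction
        .sample_allele(is_nsfs, tm, domains, gaps, len)
      }
      al1 <- mk(doses[i] >= 1L)
      al2 <- if (homozygous) al1 else mk(doses[i] == 2L)
      allele1[i] <- al1$text; allele2[i] <- al2$text
      if (n_inframe[i] >= 1L)
        tm_dose[i] <- sum(c(al1$tm, al2$tm), na.rm = TRUE)
    }
    # onset ages
    onset <- matrix(NA_real_, n, length(MANIFESTATIONS),
                    dimnames = list(NULL, names(MANIFESTATIONS)))
    tm_eff <- ifelse(is.na(tm_dose), 0L, tm_dose)
    for (m in names(MANIFESTATIONS)) {
      b <- params$baseline_onset[[m]]
      shift <- doses * params$nsfs_shift + tm_eff * params$tm_shift +
        (m == "DM") * (sex == "male") * params$male_dm_shift
      if (params$shift_mode == "multiplicative") {
        med <- pmax(0.5, b[["median"]] - shift)
        ages <- stats::rlnorm(n, meanlog = log(med), sdlog = b[["sdlog"]])
      } else {
        ages <- pmax(0, stats::rlnorm(n, meanlog = log(b[["median"]]),
                                      sdlog = b[["sdlog"]]) - shift)
      }
      ages[stats::runif(n) < params$missing_rate[[m]]] <- NA_real_
      onset[, m] <- round(ages, 2)
    }
    # allele missingness
    drop1 <- stats::runif(n) < params$missing_allele_rate
    which_allele <- stats::runif(n) < 0.5
    allele1[drop1 & which_allele] <- ""
    allele2[drop1 & !which_allele] <- ""

    registry <- data.frame(
      patient_id = sprintf("SYN%04d", seq_len(n)),
      sex = sex, allele1 = allele1, allele2 = allele2,
      onset_dm = onset[, "DM"], onset_oa = onset[, "OA"],
      onset_di = onset[, "DI"], onset_hl = onset[, "HL"],
      source = "synthetic", stringsAsFactors = FALSE)
    class(registry) <- c("wfs_registry", "data.frame")
    truth <- data.frame(
      patient_id = registry$patient_id, sex = sex,
      nsfs_dose = doses, n_inframe = n_inframe, tm_dose = tm_dose,
      stringsAsFactors = FALSE)
    structure(list(registry = registry, truth = truth, domains = domains,
                   params = params),
              class = "wfs_cohort_sim")
  })
}

#' @export
print.wfs_cohort_sim <- function(x, ...) {
  cat(sprintf("<wfs_cohort_sim> %d patients (seed %d)\n",
              nrow(x$registry), x$params$seed))
  cat("NSFS dose:", paste(sprintf("%d:%d", 0:2, tabulate(x$truth$nsfs_dose + 1L, 3L)),
                          collapse = "  "), "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `registry.tsv` (standard registry schema, empty cells for missing
#' values), `domains.tsv`, `truth.tsv` and `params.yaml` into a directory.
#' Output is byte-identical across runs with the same seed.
#'
#' @param sim A `wfs_cohort_sim` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "wfs_cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- sim$registry
  for (col in unname(MANIFESTATIONS))
    reg[[col]] <- ifelse(is.na(reg[[col]]), "",
                         formatC(reg[[col]], format = "f", digits = 2))
  utils::write.table(reg, file.path(dir, "registry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_domain_table(sim$domains, file.path(dir, "domains.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sim_params(sim$params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Monte-Carlo power / type-I-error study of the dose analysis
#'
#' Repeatedly generates cohorts under `params`, runs the full pipeline
#' (descriptor parsing, classification, eligibility filtering, dose-group
#' comparison with Bonferroni adjustment) and estimates, per pairwise
#' comparison, the probability of declaring adjusted significance at
#' `alpha`. Under a null `params` (all shifts zero) this estimates type-I
#' error; under a dose shift it estimates power. Also reports the recovered
#' median onset gap between the two groups of `gap_pair`, for parameter
#' recovery checks.
#'
#' @param params [sim_params()] describing one replicate cohort.
#' @param n_replicates Number of Monte-Carlo replicates (>= 100 recommended).
#' @param alpha Significance threshold applied to adjusted p-values.
#' @param manifestation Manifestation analysed (default `"DM"`).
#' @param grouping Grouping passed to [compare_dose_groups()].
#' @param gap_pair Character vector `c(a, b)` of two group labels; the
#'   recovered gap reported is `median(b) - median(a)` per replicate. The
#'   default `c("NSFS2", "NSFS0")` reports how much later onset is in the
#'   zero-dose group than in the two-dose group.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return Object of class `power_study`: `rates` (data frame with
#'   `group_a`, `group_b`, `reject_rate`, `se`), `mean_gap`, `gap_se`,
#'   `alpha`, `n_replicates`, `n_tested`.
#' @export
run_power_study <- function(params, n_replicates = 200L, alpha = 0.05,
                            manifestation = "DM", grouping = "nsfs",
                            gap_pair = c("NSFS2", "NSFS0"),
                            seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), n_replicates >= 1L)
  domains <- synthetic_domain_table()
  rej <- list()
  gaps <- rep(NA_real_, n_replicates)
  n_tested <- 0L
  for (i in seq_len(n_replicates)) {
    p_i <- params
    p_i$seed <- as.integer((seed + 7919 * i) %% 2147483647)
    sim <- generate_cohort(p_i, domains = domains)
    elig <- filter_eligible(sim$registry, manifestation, domains = domains)
    cmp <- compare_dose_groups(elig, grouping = grouping)
    if (!cmp$testable) next
    n_tested <- n_tested + 1L
    pw <- cmp$pairwise
    for (j in seq_len(nrow(pw))) {
      key <- paste(pw$group_a[j], pw$group_b[j], sep = " vs ")
      rej[[key]] <- c(rej[[key]], pw$p_adj[j] < alpha)
    }
    if (all(gap_pair %in% names(cmp$per_group)))
      gaps[i] <- cmp$per_group[[gap_pair[2]]]$median -
        cmp$per_group[[gap_pair[1]]]$median
  }
  rates <- do.call(rbind, lapply(names(rej), function(k) {
    r <- mean(rej[[k]])
    data.frame(comparison = k, reject_rate = r,
               se = sqrt(r * (1 - r) / length(rej[[k]])),
               n = length(rej[[k]]), stringsAsFactors = FALSE)
  }))
  gaps <- gaps[!is.na(gaps)]
  structure(list(rates = rates,
                 mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
                 gap_se = if (length(gaps) > 1)
                            stats::sd(gaps) / sqrt(length(gaps))
                          else NA_real_,
                 alpha = alpha, n_replicates = n_replicates,
                 n_tested = n_tested, manifestation = manifestation,
                 grouping = grouping, gap_pair = gap_pair),
            class = "power_study")
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf("<power_study> %s by %s, %d replicates (alpha = %g)\n",
              x$manifestation, x$grouping, x$n_replicates, x$alpha))
  if (!is.null(x$rates)) {
    r <- x$rates
    r$reject_rate <- signif(r$reject_rate, 4); r$se <- signif(r$se, 3)
    print(r, row.names = FALSE)
  }
  if (!is.na(x$mean_gap))
    cat(sprintf("recovered median gap (%s minus %s): %.3f years (SE %.3f)\n",
                x$gap_pair[2], x$gap_pair[1], x$mean_gap, x$gap_se))
  invisible(x)
}
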