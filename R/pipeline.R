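# End-to-end analysis: read -> classify -> annotate -> group -> test -> report.

#' Analysis run configuration
#'
#' @param registry_path Path to the patient registry TSV/CSV.
#' @param domain_table_path Path to the transmembrane-domain TSV.
#' @param output_dir Directory for report tables, figures and the manifest.
#' @param quartile_method Quartile interpolation for all summaries.
#' @param alpha Significance threshold (reported, not used to drop results).
#' @param figures Emit box-plot PNGs.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters only if resampling modes are added).
#' @param mode Wilcoxon mode, see [wilcoxon_rank_sum()].
#' @return List of class `run_config`.
#' @export
run_config <- function(registry_path, domain_table_path, output_dir,
                       quartile_method = c("linear", "lower", "midpoint"),
                       alpha = 0.05, figures = FALSE, seed = 1L,
                       mode = "auto") {
  quartile_method <- match.arg(quartile_method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("run_config: alpha must lie in (0, 1)", call. = FALSE)
  structure(list(registry_path = registry_path,
                 domain_table_path = domain_table_path,
                 output_dir = output_dir,
                 quartile_method = quartile_method, alpha = alpha,
                 figures = isTRUE(figures), seed = as.integer(seed),
                 mode = mode, sidedness = "two_sided"),
            class = "run_config")
}

.fmt4 <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = 4))
}

.write_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) if (is.double(out[[col]]))  # counts stay integer
    out[[col]] <- .fmt4(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.pairwise_df <- function(cmp) {
  if (!cmp$testable || !nrow(cmp$pairwise))
    return(data.frame(manifestation = cmp$manifestation,
                      group_a = NA_character_, group_b = NA_character_,
                      U = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                      note = "not testable", stringsAsFactors = FALSE))
  cbind(data.frame(manifestation = cmp$manifestation,
                   stringsAsFactors = FALSE),
        cmp$pairwise, note = "")
}

#' Run the full genotype-phenotype onset analysis
#'
#' Reads a registry and a transmembrane-domain table, then for each clinical
#' manifestation (DM, OA, DI, HL):
#' cohort-level onset summary; NSFS allele-dose comparison (0/1/2);
#' transmembrane-dose comparisons in the two-in-frame and one-in-frame
#' subsets; and sex-stratified comparisons (whole cohort and per NSFS
#' stratum). Writes TSV tables (floating point at 4 decimals), optional
#' box-plot figures, and a JSON run manifest recording configuration, input
#' checksums and every excluded patient with its machine-readable reason.
#' Identical inputs and configuration yield byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Object of class `wfs_report` (invisibly): all comparison objects
#'   plus the manifest, and the paths written.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  registry <- read_registry(config$registry_path)
  domains <- load_domain_table(config$domain_table_path)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  manifests <- names(MANIFESTATIONS)
  cohort_rows <- list(); nsfs_groups <- list(); nsfs_pw <- list()
  tm2_groups <- list(); tm2_pw <- list(); tm1_groups <- list()
  tm1_pw <- list(); sex_groups <- list(); sex_pw <- list()
  comparisons <- list(); exclusions <- list()
  for (m in manifests) {
    elig <- filter_eligible(registry, m, domains = domains)
    exclusions[[m]] <- attr(elig, "exclusions")
    comparisons[[m]] <- list()
    if (nrow(elig)) {
      s <- five_number_summary(elig$onset, method = config$quartile_method)
      cohort_rows[[m]] <- data.frame(
        manifestation = m, n = s$n, median = s$median,
        lower_quartile = s$q1, upper_quartile = s$q3,
        whisker_low = s$whisker_low, whisker_high = s$whisker_high,
        n_outliers = length(s$outliers), stringsAsFactors = FALSE)
    } else {
      cohort_rows[[m]] <- data.frame(
        manifestation = m, n = 0L, median = NA_real_,
        lower_quartile = NA_real_, upper_quartile = NA_real_,
        whisker_low = NA_real_, whisker_high = NA_real_, n_outliers = 0L,
        stringsAsFactors = FALSE)
    }
    run_cmp <- function(grouping) {
      cmp <- compare_dose_groups(elig, grouping = grouping,
                                 quartile_method = config$quartile_method,
                                 mode = config$mode)
      comparisons[[m]][[grouping]] <<- cmp
      cmp
    }
    if (nrow(elig)) {
      cn <- run_cmp("nsfs")
      nsfs_groups[[m]] <- summary(cn); nsfs_pw[[m]] <- .pairwise_df(cn)
      c2 <- run_cmp("tm_two_inframe")
      tm2_groups[[m]] <- summary(c2); tm2_pw[[m]] <- .pairwise_df(c2)
      c1 <- run_cmp("tm_one_inframe")
      tm1_groups[[m]] <- summary(c1); tm1_pw[[m]] <- .pairwise_df(c1)
      cs <- sex_stratified_comparison(elig,
                                      quartile_method = config$quartile_method,
                                      mode = config$mode)
      comparisons[[m]][["sex"]] <- cs
      sg <- summary(cs)
      if (!is.null(sg)) sg$stratum <- "all"
      spw <- .pairwise_df(cs); spw$stratum <- "all"
      sex_groups[[m]] <- list(sg); sex_pw[[m]] <- list(spw)
      for (d in 0:2) {
        csd <- sex_stratified_comparison(elig, within_dose = d,
                                         quartile_method = config$quartile_method,
                                         mode = config$mode)
        comparisons[[m]][[paste0("sex_nsfs", d)]] <- csd
        sgd <- summary(csd)
        if (!is.null(sgd)) {
          sgd$stratum <- paste0("NSFS", d)
          sex_groups[[m]] <- c(sex_groups[[m]], list(sgd))
        }
        spwd <- .pairwise_df(csd); spwd$stratum <- paste0("NSFS", d)
        sex_pw[[m]] <- c(sex_pw[[m]], list(spwd))
      }
      sex_groups[[m]] <- do.call(rbind, sex_groups[[m]])
      sex_pw[[m]] <- do.call(rbind, sex_pw[[m]])
    }
  }

  paths <- character(0)
  bind <- function(lst) do.call(rbind, unname(lst))
  emit <- function(lst, file) {
    if (!length(lst)) return(invisible(NULL))
    p <- .write_tsv(bind(lst), file.path(config$output_dir, file))
    paths <<- c(paths, p)
  }
  emit(cohort_rows, "cohort_summary.tsv")
  emit(nsfs_groups, "nsfs_dose_groups.tsv")
  emit(nsfs_pw, "nsfs_dose_pairwise.tsv")
  emit(tm2_groups, "tm_dose_two_inframe_groups.tsv")
  emit(tm2_pw, "tm_dose_two_inframe_pairwise.tsv")
  emit(tm1_groups, "tm_dose_one_inframe_groups.tsv")
  emit(tm1_pw, "tm_dose_one_inframe_pairwise.tsv")
  emit(sex_groups, "sex_groups.tsv")
  emit(sex_pw, "sex_pairwise.tsv")

  if (config$figures) {
    for (m in manifests) {
      for (g in c("nsfs", "tm_two_inframe", "tm_one_inframe", "sex")) {
        cmp <- comparisons[[m]][[g]]
        if (is.null(cmp) || !length(cmp$per_group)) next
        fp <- file.path(config$output_dir, sprintf("box_%s_%s.png", m, g))
        grDevices::png(fp, width = 700, height = 500)
        plot(cmp)
        grDevices::dev.off()
        paths <- c(paths, fp)
      }
    }
  }

  excl_all <- do.call(rbind, lapply(manifests, function(m) {
    e <- exclusions[[m]]
    if (!nrow(e)) return(NULL)
    cbind(data.frame(manifestation = m, stringsAsFactors = FALSE), e)
  }))
  manifest <- list(
    config = unclass(config),
    inputs = list(
      registry = list(path = config$registry_path,
                      md5 = unname(tools::md5sum(config$registry_path)),
                      n_rows = nrow(registry)),
      domain_table = list(path = config$domain_table_path,
                          md5 = unname(tools::md5sum(config$domain_table_path)))),
    eligible_n = lapply(manifests, function(m)
      nrow(registry) - nrow(exclusions[[m]])),
    exclusion_counts = lapply(manifests, function(m)
      as.list(table(exclusions[[m]]$reason))),
    exclusions = if (is.null(excl_all)) list() else excl_all)
  names(manifest$eligible_n) <- manifests
  names(manifest$exclusion_counts) <- manifests
  mpath <- file.path(config$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mpath)

  structure(list(config = config, comparisons = comparisons,
                 cohort_summary = bind(cohort_rows),
                 manifest = manifest, paths = paths),
            class = "wfs_report")
}

#' @export
print.wfs_report <- function(x, ...) {
  cat("<wfs_report>\n")
  cat("cohort onset summaries:\n")
  cs <- x$cohort_summary
  for (col in c("median", "lower_quartile", "upper_quartile"))
    cs[[col]] <- signif(cs[[col]], 4)
  print(cs[, c("manifestation", "n", "median", "lower_quartile",
               "upper_quartile")], row.names = FALSE)
  cat("eligible n:", paste(names(x$manifest$eligible_n),
                           unlist(x$manifest$eligible_n), sep = "=",
                           collapse = "  "), "\n")
  cat(length(x$paths), "file(s) written to", x$config$output_dir, "\n")
  invisible(x)
}
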