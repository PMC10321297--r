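# Independent oracles used across the suite.

# Brute-force exact two-sided rank-sum p: enumerate every assignment of the
# pooled observations to the two samples and count assignments whose
# Mann-Whitney pair-count statistic is at least as far from its null
# expectation as the observed one. Independent of the package's rank-sum
# enumeration (different statistic, recomputed per split from raw values).
oracle_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- nx * (n - nx) / 2
  obs <- abs(u_stat(x, y) - mu)
  splits <- utils::combn(n, nx)
  hits <- apply(splits, 2, function(idx) {
    abs(u_stat(pooled[idx], pooled[-idx]) - mu) >= obs - 1e-9
  })
  mean(hits)
}

# Per-residue brute-force transmembrane membership: a variant is TM iff any
# residue of its affected interval is listed in any range, checked by
# expanding every range to its residue set.
oracle_is_tm <- function(v, t) {
  iv <- affected_interval(v)
  residues <- seq(iv[1], iv[2])
  tm_residues <- unlist(mapply(seq, t$ranges$start, t$ranges$end,
                               SIMPLIFY = FALSE))
  any(residues %in% tm_residues)
}

# Random valid domain table on a protein of given length.
random_domain_table <- function(len = 500L, max_ranges = 6L) {
  k <- sample(0:max_ranges, 1L)
  if (k == 0L)
    return(domain_table(integer(0), integer(0), provenance = "random test table"))
  cuts <- sort(sample(seq_len(len), 2L * k))
  domain_table(cuts[seq(1, 2 * k, 2)], cuts[seq(2, 2 * k, 2)],
               provenance = "random test table")
}

# Random in-frame variant (missense / deletion / insertion / delins) with
# positions in [2, len - 5].
random_inframe_variant <- function(len = 500L) {
  kind <- sample(c("mis", "del", "ins", "delins"), 1L)
  p <- sample(2:(len - 5L), 1L)
  aa <- function(exclude = "Met")
    sample(setdiff(names(wfsdose:::AA3), exclude), 1L)
  txt <- switch(kind,
    mis = {
      ref <- aa()
      sprintf("p.%s%d%s", ref, p, aa(exclude = c("Met", ref)))
    },
    del = sprintf("p.%s%d_%s%ddel", aa(), p, aa(), p + sample(0:4, 1L)),
    ins = sprintf("p.%s%d_%s%dins%s", aa(), p, aa(), p + 1L, aa()),
    delins = sprintf("p.%s%d_%s%ddelins%s", aa(), p, aa(),
                     p + sample(0:4, 1L), aa()))
  suppressWarnings(parse_protein_descriptor(txt))
}

# Registry data.frame -> temporary TSV file path.
write_registry_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  sep <- if (ext == ".csv") "," else "\t"
  df2 <- df
  for (col in names(df2))
    if (is.numeric(df2[[col]])) df2[[col]] <- ifelse(is.na(df2[[col]]), "",
                                                     as.character(df2[[col]]))
  utils::write.table(df2, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

toy_registry_path <- function() {
  system.file("extdata", "toy_registry.tsv", package = "wfsdose")
}

synthetic_domains_path <- function() {
  system.file("extdata", "wfs1_tm_domains_synthetic.tsv", package = "wfsdose")
}

# Null simulation parameters: fixed group sizes, no shifts, no missingness.
null_params <- function(group_n, seed = 1L, ...) {
  sim_params(dose_group_n = rep(group_n, 3L),
             nsfs_shift = 0, tm_shift = 0, male_dm_shift = 0,
             missing_rate = c(DM = 0, OA = 0, DI = 0, HL = 0),
             missing_allele_rate = 0, seed = seed, ...)
}
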