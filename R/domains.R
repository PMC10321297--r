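# Transmembrane-domain interval tables and overlap classification.
# Residue coordinates are 1-based, closed intervals throughout (protein
# convention).

#' Construct a transmembrane-domain table
#'
#' A `domain_table` holds the ordered, non-overlapping residue intervals
#' (1-based, inclusive at both ends) annotated as membrane-spanning for one
#' protein, plus provenance text recording where the annotation snapshot came
#' from (database entry and retrieval date). An empty table is valid: every
#' variant is then classified non-transmembrane.
#'
#' @param start,end Integer vectors of equal length; `start[i] <= end[i]`,
#'   all `>= 1`, intervals pairwise non-overlapping.
#' @param label Optional character vector of interval labels (e.g. `"TM3"`).
#' @param protein_id Identifier of the annotated protein.
#' @param provenance Non-empty free-text source note.
#' @return An object of class `domain_table`.
#' @seealso [load_domain_table()], [is_transmembrane()]
#' @export
domain_table <- function(start, end, label = NULL,
                         protein_id = "unknown", provenance) {
  if (missing(provenance) || !nzchar(trimws(provenance)))
    stop("domain_table: provenance must be a non-empty source note",
         call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end))
    stop("domain_table: start and end differ in length", call. = FALSE)
  if (is.null(label)) label <- if (length(start)) paste0("TM", seq_along(start))
                               else character(0)
  rng <- data.frame(start = start, end = end,
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  if (nrow(rng)) {
    bad <- which(is.na(rng$start) | is.na(rng$end) | rng$start < 1L |
                 rng$end < rng$start)
    if (length(bad))
      stop(sprintf("domain_table: invalid range in row %d (start=%s, end=%s)",
                   bad[1], rng$start[bad[1]], rng$end[bad[1]]), call. = FALSE)
    rng <- rng[order(rng$start), , drop = FALSE]
    rownames(rng) <- NULL
    if (nrow(rng) > 1L) {
      ov <- which(rng$start[-1L] <= rng$end[-nrow(rng)])
      if (length(ov))
        stop(sprintf(
          "domain_table: ranges overlap at row %d ('%s' %d-%d vs '%s' %d-%d)",
          ov[1] + 1L, rng$label[ov[1]], rng$start[ov[1]], rng$end[ov[1]],
          rng$label[ov[1] + 1L], rng$start[ov[1] + 1L], rng$end[ov[1] + 1L]),
          call. = FALSE)
    }
  }
  structure(list(protein_id = protein_id, ranges = rng,
                 provenance = provenance),
            class = "domain_table")
}

#' Read a transmembrane-domain table from a TSV file
#'
#' Expects `#`-prefixed header lines carrying `protein_id:` and
#' `provenance:`, followed by a tab-separated table with columns
#' `start`, `end`, `label`. Rows are sorted and validated (1-based, closed,
#' non-overlapping intervals); a missing provenance line is an error so that
#' annotation snapshots always record their source.
#'
#' @param path Path to the domain TSV.
#' @return A [domain_table()].
#' @export
load_domain_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("domain table file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(hit)) return("")
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  pid <- field("protein_id")
  prov <- field("provenance")
  if (!nzchar(prov))
    stop(sprintf("domain table %s lacks a '# provenance:' header line", path),
         call. = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) <= 1L)        # header row only, or nothing
    return(domain_table(integer(0), integer(0),
                        protein_id = if (nzchar(pid)) pid else "unknown",
                        provenance = prov))
  tab <- utils::read.delim(text = body, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("start", "end")
  if (!all(need %in% names(tab)))
    stop(sprintf("domain table %s must have columns start, end (and label)",
                 path), call. = FALSE)
  domain_table(tab$start, tab$end,
               label = if ("label" %in% names(tab)) tab$label else NULL,
               protein_id = if (nzchar(pid)) pid else "unknown",
               provenance = prov)
}

#' Write a domain table to TSV
#' @param t A [domain_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(t, path) {
  stopifnot(inherits(t, "domain_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# protein_id: ", t$protein_id),
               paste0("# provenance: ", t$provenance),
               "# coordinates: 1-based residue positions, closed intervals",
               "start\tend\tlabel"), con)
  if (nrow(t$ranges))
    utils::write.table(t$ranges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.domain_table <- function(x, ...) {
  cat(sprintf("<domain_table> %s: %d transmembrane range(s)\n",
              x$protein_id, nrow(x$ranges)))
  if (nrow(x$ranges)) print(x$ranges)
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Residue interval affected by an in-frame variant
#'
#' Missense variants affect their single substituted residue; in-frame
#' deletions and delins affect the deleted span; a pure in-frame insertion
#' has no reference residue of its own and is attributed to its two flanking
#' residues. Only in-frame variants have an affected interval — truncating
#' (NSFS) and OTHER alleles are contract violations here.
#'
#' @param v A `protein_variant` with `broad_class(v) == "INFRAME"`.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
affected_interval <- function(v) {
  if (broad_class(v) != "INFRAME")
    stop(sprintf("affected_interval is defined for in-frame variants only (got %s)",
                 v$kind), call. = FALSE)
  c(v$start_pos, v$end_pos)
}

#' Is an in-frame variant transmembrane?
#'
#' `TRUE` iff the variant's affected residue interval overlaps any
#' transmembrane range in the table (closed-interval overlap: sharing a
#' single residue counts). Multi-residue variants therefore count as
#' transmembrane if *any* affected residue is membrane-spanning.
#'
#' @param v A `protein_variant` with `broad_class(v) == "INFRAME"`.
#' @param t A [domain_table()].
#' @return Logical scalar.
#' @export
is_transmembrane <- function(v, t) {
  stopifnot(inherits(t, "domain_table"))
  iv <- affected_interval(v)
  if (!nrow(t$ranges)) return(FALSE)
  any(t$ranges$start <= iv[2] & t$ranges$end >= iv[1])
}

#' Count transmembrane in-frame alleles in a genotype
#'
#' Among a patient's in-frame alleles (there must be at least one), counts
#' how many overlap a transmembrane range: the TM allele dose. NSFS alleles
#' never contribute.
#'
#' @param allele1,allele2 `protein_variant` objects.
#' @param t A [domain_table()].
#' @return Integer 0, 1 or 2.
#' @export
count_tm_inframe <- function(allele1, allele2, t) {
  alleles <- list(allele1, allele2)
  inframe <- vapply(alleles, function(a) broad_class(a) == "INFRAME",
                    logical(1))
  if (!any(inframe))
    stop("count_tm_inframe: genotype has no in-frame allele", call. = FALSE)
  sum(vapply(alleles[inframe], is_transmembrane, logical(1), t = t))
}
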