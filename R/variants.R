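# Protein-level variant descriptors: parsing, classification, allele dose.

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
AA1 <- names(AA3)
names(AA1) <- unname(AA3)

VARIANT_KINDS <- c("MISSENSE", "NONSENSE", "FRAMESHIFT", "INFRAME_DELETION",
                   "INFRAME_INSERTION", "INFRAME_DELINS", "OTHER")

# descriptor grammar (compiled once; the parser is on the hot path of the
# simulation harness)
.AA_RE <- "([A-Z][a-z]{2}|[ACDEFGHIKLMNPQRSTVWY])"
.POS_RE <- "([0-9]+)"
.AASEQ_RE <- "((?:[A-Z][a-z]{2})+|[ACDEFGHIKLMNPQRSTVWY]+)"
.RE_FS <- paste0("^", .AA_RE, .POS_RE, .AA_RE, "?fs(?:(?:Ter|\\*)([0-9]+)?)?$")
.RE_DELINS <- paste0("^", .AA_RE, .POS_RE, "(?:_", .AA_RE, .POS_RE,
                     ")?delins", .AASEQ_RE, "$")
.RE_DELDUP <- paste0("^", .AA_RE, .POS_RE, "(?:_", .AA_RE, .POS_RE,
                     ")?(del|dup)$")
.RE_INS <- paste0("^", .AA_RE, .POS_RE, "_", .AA_RE, .POS_RE, "ins",
                  .AASEQ_RE, "$")
.RE_SUB <- paste0("^", .AA_RE, .POS_RE, "(", .AA_RE, "|Ter|\\*|=|\\?)$")

# One residue token ("Arg", "R", "Ter", "*", "X") -> single-letter code, or NA.
.aa_to_one <- function(tok) {
  if (is.na(tok) || !nzchar(tok)) return(NA_character_)
  if (tok %in% c("Ter", "*", "X", "Xaa")) return("*")
  if (nchar(tok) == 3) {
    hit <- AA3[tok]
    return(unname(hit))            # NA for unknown 3-letter codes
  }
  if (nchar(tok) == 1 && tok %in% unname(AA3)) return(tok)
  NA_character_
}

# A run of residues ("SerLysVal" or "SKV") -> one-letter string, or NA.
.aaseq_to_one <- function(s) {
  if (is.na(s) || !nzchar(s)) return("")
  if (grepl("^[A-Z][a-z]{2}([A-Z][a-z]{2})*$", s)) {
    toks <- regmatches(s, gregexpr("[A-Z][a-z]{2}", s))[[1]]
    out <- vapply(toks, .aa_to_one, character(1))
    if (anyNA(out)) return(NA_character_)
    return(paste0(out, collapse = ""))
  }
  if (grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", s)) return(s)
  NA_character_
}

.one_to_aa3 <- function(s) {
  if (!nzchar(s)) return("")
  if (s == "*") return("Ter")
  paste0(AA1[strsplit(s, "")[[1]]], collapse = "")
}

.new_variant <- function(raw_text, start_pos, end_pos, ref, alt, kind,
                         fs_term = NA_integer_) {
  stopifnot(kind %in% VARIANT_KINDS)
  structure(
    list(raw_text = raw_text, start_pos = as.integer(start_pos),
         end_pos = as.integer(end_pos), ref_residues = ref,
         alt_residues = alt, kind = kind, fs_term = as.integer(fs_term)),
    class = "protein_variant")
}

.other_variant <- function(raw_text, why) {
  warning(sprintf("descriptor '%s' not classifiable (%s); kind set to OTHER",
                  raw_text, why), call. = FALSE)
  .new_variant(raw_text, 1L, 1L, "", "", "OTHER")
}

#' Parse a protein-level variant descriptor
#'
#' Parses HGVS-style protein descriptors such as `"p.Arg558Cys"` (missense),
#' `"p.Trp613*"` (nonsense), `"p.Val412Serfs*29"` (frameshift),
#' `"p.Phe883del"` / `"p.Leu330_Ala340del"` (in-frame deletion),
#' `"p.Lys400_Leu401insAla"` (in-frame insertion) and
#' `"p.His313_Gln315delinsSer"` (in-frame deletion-insertion). Both 1- and
#' 3-letter residue codes are accepted and normalised internally to 1-letter;
#' `Ter` and `*` are synonymous. Descriptors outside this grammar (start-loss,
#' stop-loss/extension, synonymous, splice and other unrecognised forms) are
#' preserved with `kind = "OTHER"` and a warning, never an error, except for
#' clearly malformed input (empty string, residue position < 1) and
#' DNA-level descriptors (`c.`/`g.`/`n.`/`m.`), which are errors: this parser
#' operates on amino-acid coordinates only.
#'
#' @param text A single descriptor string, with or without the `"p."` prefix.
#' @return An object of class `protein_variant`: a list with fields
#'   `raw_text`, `start_pos`, `end_pos`, `ref_residues`, `alt_residues`
#'   (1-letter; `"*"` for a stop), `kind` (one of `MISSENSE`, `NONSENSE`,
#'   `FRAMESHIFT`, `INFRAME_DELETION`, `INFRAME_INSERTION`, `INFRAME_DELINS`,
#'   `OTHER`) and `fs_term` (frameshift termination offset, or `NA`).
#' @examples
#' parse_protein_descriptor("p.Arg558Cys")
#' parse_protein_descriptor("p.Val412Serfs*29")
#' @seealso [broad_class()], [format.protein_variant()]
#' @export
parse_protein_descriptor <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("variant descriptor must be a non-empty string", call. = FALSE)
  raw <- trimws(text)
  if (grepl("^[cgnm]\\.", raw))
    stop(sprintf(paste("descriptor '%s' uses DNA-level coordinates;",
                       "only protein-level (p.) descriptors are supported"),
                 raw), call. = FALSE)
  body <- sub("^p\\.", "", raw)
  body <- sub("^\\((.*)\\)$", "\\1", body)   # tolerate p.(Arg558Cys)
  body <- gsub("[[:space:]]+", "", body)

  .pos_check <- function(p) {
    p <- as.integer(p)
    if (is.na(p) || p < 1L)
      stop(sprintf("residue position must be >= 1 in '%s'", raw),
           call. = FALSE)
    p
  }

  # frameshift: Ref Pos [Alt] fs [Ter|*] [N]
  m <- regmatches(body, regexec(.RE_FS, body))[[1]]
  if (length(m)) {
    ref <- .aa_to_one(m[2]); p <- .pos_check(m[3]); alt <- .aa_to_one(m[4])
    if (is.na(ref) || ref == "*")
      return(.other_variant(raw, "unrecognised reference residue"))
    term <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
    return(.new_variant(raw, p, p, ref,
                        if (is.na(alt)) "" else alt, "FRAMESHIFT", term))
  }

  # delins on a single residue or a range
  m <- regmatches(body, regexec(.RE_DELINS, body))[[1]]
  if (length(m)) {
    r1 <- .aa_to_one(m[2]); p1 <- .pos_check(m[3])
    has_range <- nzchar(m[4])
    r2 <- if (has_range) .aa_to_one(m[4]) else r1
    p2 <- if (has_range) .pos_check(m[5]) else p1
    ins <- .aaseq_to_one(m[6])
    if (is.na(r1) || is.na(r2) || r1 == "*" || r2 == "*" || is.na(ins) ||
        p2 < p1)
      return(.other_variant(raw, "malformed delins"))
    ref <- if (has_range) paste0(r1, strrep(".", max(0, p2 - p1 - 1)), r2)
           else r1
    return(.new_variant(raw, p1, p2, ref, ins, "INFRAME_DELINS"))
  }

  # deletion / duplication on a single residue or a range
  m <- regmatches(body, regexec(.RE_DELDUP, body))[[1]]
  if (length(m)) {
    r1 <- .aa_to_one(m[2]); p1 <- .pos_check(m[3])
    has_range <- nzchar(m[4])
    r2 <- if (has_range) .aa_to_one(m[4]) else r1
    p2 <- if (has_range) .pos_check(m[5]) else p1
    if (is.na(r1) || is.na(r2) || r1 == "*" || r2 == "*" || p2 < p1)
      return(.other_variant(raw, "malformed deletion/duplication"))
    ref <- if (has_range) paste0(r1, strrep(".", max(0, p2 - p1 - 1)), r2)
           else r1
    # a duplication is an in-frame insertion after its last duplicated residue
    if (m[6] == "dup")
      return(.new_variant(raw, p2, p2 + 1L, r2, ref, "INFRAME_INSERTION"))
    return(.new_variant(raw, p1, p2, ref, "", "INFRAME_DELETION"))
  }

  # insertion between two flanking residues
  m <- regmatches(body, regexec(.RE_INS, body))[[1]]
  if (length(m)) {
    r1 <- .aa_to_one(m[2]); p1 <- .pos_check(m[3])
    r2 <- .aa_to_one(m[4]); p2 <- .pos_check(m[5])
    ins <- .aaseq_to_one(m[6])
    if (is.na(r1) || is.na(r2) || r1 == "*" || r2 == "*" || is.na(ins) ||
        p2 != p1 + 1L)
      return(.other_variant(raw, "malformed insertion"))
    return(.new_variant(raw, p1, p2, paste0(r1, r2), ins,
                        "INFRAME_INSERTION"))
  }

  # substitution: missense, nonsense, synonymous, start-loss, unknown effect
  m <- regmatches(body, regexec(.RE_SUB, body))[[1]]
  if (length(m)) {
    ref <- .aa_to_one(m[2]); p <- .pos_check(m[3]); alt_tok <- m[4]
    if (is.na(ref))
      return(.other_variant(raw, "unrecognised reference residue"))
    if (alt_tok %in% c("=", "?"))
      return(.other_variant(raw, if (alt_tok == "=") "synonymous"
                                 else "unknown consequence"))
    if (ref == "*")
      return(.other_variant(raw, "stop-loss"))
    alt <- .aa_to_one(alt_tok)
    if (is.na(alt))
      return(.other_variant(raw, "unrecognised alternate residue"))
    if (alt == "*")
      return(.new_variant(raw, p, p, ref, "*", "NONSENSE"))
    if (ref == "M" && p == 1L)
      return(.other_variant(raw, "start-loss"))
    if (alt == ref)
      return(.other_variant(raw, "synonymous"))
    return(.new_variant(raw, p, p, ref, alt, "MISSENSE"))
  }

  .other_variant(raw, "does not match the protein descriptor grammar")
}

#' @export
format.protein_variant <- function(x, ...) {
  r3 <- function(s) .one_to_aa3(s)
  first <- function(s) .one_to_aa3(substr(s, 1, 1))
  last <- function(s) .one_to_aa3(substr(s, nchar(s), nchar(s)))
  switch(x$kind,
    MISSENSE = sprintf("p.%s%d%s", r3(x$ref_residues), x$start_pos,
                       r3(x$alt_residues)),
    NONSENSE = sprintf("p.%s%dTer", r3(x$ref_residues), x$start_pos),
    FRAMESHIFT = sprintf("p.%s%d%sfs%s", r3(x$ref_residues), x$start_pos,
                         r3(x$alt_residues),
                         if (is.na(x$fs_term)) ""
                         else sprintf("Ter%d", x$fs_term)),
    INFRAME_DELETION =
      if (x$start_pos == x$end_pos)
        sprintf("p.%s%ddel", r3(x$ref_residues), x$start_pos)
      else sprintf("p.%s%d_%s%ddel", first(x$ref_residues), x$start_pos,
                   last(x$ref_residues), x$end_pos),
    INFRAME_INSERTION =
      # duplications record only the left flanking residue, and a range dup's
      # inserted sequence has gaps: both serialize as originally written
      if (grepl("\\.", x$alt_residues) || nchar(x$ref_residues) < 2L)
        x$raw_text
      else sprintf("p.%s%d_%s%dins%s", first(x$ref_residues), x$start_pos,
                   last(x$ref_residues), x$end_pos, r3(x$alt_residues)),
    INFRAME_DELINS =
      if (x$start_pos == x$end_pos)
        sprintf("p.%s%ddelins%s", r3(x$ref_residues), x$start_pos,
                r3(x$alt_residues))
      else sprintf("p.%s%d_%s%ddelins%s", first(x$ref_residues), x$start_pos,
                   last(x$ref_residues), x$end_pos, r3(x$alt_residues)),
    OTHER = x$raw_text)
}

#' @export
print.protein_variant <- function(x, ...) {
  cat(sprintf("<protein_variant> %s  [%s, residues %d-%d]\n",
              format(x), x$kind, x$start_pos, x$end_pos))
  invisible(x)
}

#' Broad consequence class of a parsed variant
#'
#' Collapses the variant kind into the two analysis bins used for allele-dose
#' grouping: `"NSFS"` (nonsense or frameshift; predicted truncating) versus
#' `"INFRAME"` (missense or in-frame insertion/deletion/delins; reading frame
#' preserved). Kinds outside either bin return `"OTHER"`; such alleles are
#' excluded from dose analyses upstream rather than guessed into a bin.
#'
#' @param v A `protein_variant` from [parse_protein_descriptor()].
#' @return `"NSFS"`, `"INFRAME"` or `"OTHER"`.
#' @export
broad_class <- function(v) {
  stopifnot(inherits(v, "protein_variant"))
  if (v$kind %in% c("NONSENSE", "FRAMESHIFT")) return("NSFS")
  if (v$kind %in% c("MISSENSE", "INFRAME_DELETION", "INFRAME_INSERTION",
                    "INFRAME_DELINS")) return("INFRAME")
  "OTHER"
}

#' Count truncating alleles in a biallelic genotype
#'
#' Number of a patient's two alleles whose broad class is NSFS
#' (nonsense/frameshift): the NSFS allele dose, 0, 1 or 2. Homozygous
#' genotypes are written as the same descriptor twice and each allele counts
#' independently. An allele of class OTHER is a contract violation here —
#' such patients must be excluded before dose assignment.
#'
#' @param allele1,allele2 `protein_variant` objects.
#' @return Integer 0, 1 or 2.
#' @export
count_nsfs_alleles <- function(allele1, allele2) {
  cls <- c(broad_class(allele1), broad_class(allele2))
  if (any(cls == "OTHER"))
    stop("count_nsfs_alleles: allele of class OTHER; patient should have been excluded",
         call. = FALSE)
  sum(cls == "NSFS")
}
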