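# Variant descriptor parsing and broad classification.

test_that("canonical descriptor forms parse to the right kind and coordinates", {
  cases <- list(
    list("p.Arg558Cys", "MISSENSE", 558L, 558L, "R", "C"),
    list("R558C", "MISSENSE", 558L, 558L, "R", "C"),
    list("p.Trp613*", "NONSENSE", 613L, 613L, "W", "*"),
    list("p.Trp613Ter", "NONSENSE", 613L, 613L, "W", "*"),
    list("W613*", "NONSENSE", 613L, 613L, "W", "*"),
    list("p.Val412Serfs*29", "FRAMESHIFT", 412L, 412L, "V", "S"),
    list("p.Val412SerfsTer29", "FRAMESHIFT", 412L, 412L, "V", "S"),
    list("p.Val412fs", "FRAMESHIFT", 412L, 412L, "V", ""),
    list("p.Phe883del", "INFRAME_DELETION", 883L, 883L, "F", ""),
    list("p.Leu330_Ala340del", "INFRAME_DELETION", 330L, 340L, NULL, ""),
    list("p.Lys400_Leu401insAla", "INFRAME_INSERTION", 400L, 401L, "KL", "A"),
    list("p.His313_Gln315delinsSer", "INFRAME_DELINS", 313L, 315L, NULL, "S"))
  for (cs in cases) {
    v <- parse_protein_descriptor(cs[[1]])
    expect_s3_class(v, "protein_variant")
    expect_identical(v$kind, cs[[2]], label = cs[[1]])
    expect_identical(v$start_pos, cs[[3]], label = cs[[1]])
    expect_identical(v$end_pos, cs[[4]], label = cs[[1]])
    if (!is.null(cs[[5]])) expect_identical(v$ref_residues, cs[[5]],
                                            label = cs[[1]])
    expect_identical(v$alt_residues, cs[[6]], label = cs[[1]])
  }
})

test_that("descriptors outside the two analysis bins become OTHER with a warning", {
  for (txt in c("p.Met1?",          # start-loss
                "p.Met1Leu",        # start-loss via substitution
                "p.Ter891Leu",      # stop-loss
                "p.Leu100=",        # synonymous
                "p.Leu100Leu",      # synonymous spelled out
                "p.Leu100?",        # unknown consequence
                "not_a_variant")) {
    expect_warning(v <- parse_protein_descriptor(txt), "OTHER")
    expect_identical(v$kind, "OTHER")
    expect_identical(v$raw_text, txt)
    expect_identical(broad_class(v), "OTHER")
  }
})

test_that("malformed and DNA-level input are rejected as errors", {
  expect_error(parse_protein_descriptor(""), "non-empty")
  expect_error(parse_protein_descriptor("  "), "non-empty")
  expect_error(parse_protein_descriptor("c.1672C>T"), "protein-level")
  expect_error(parse_protein_descriptor("g.100A>G"), "protein-level")
  expect_error(parse_protein_descriptor("p.Arg0Cys"), ">= 1")
})

test_that("parsed descriptors re-serialize and re-parse to the same variant", {
  texts <- c("p.Arg558Cys", "R558C", "p.Trp613*", "p.Val412Serfs*29",
             "p.Val412fs", "p.Phe883del", "p.Leu330_Ala340del",
             "p.Lys400_Leu401insAla", "p.His313_Gln315delinsSer",
             "p.Ala100dup")
  for (txt in texts) {
    v1 <- parse_protein_descriptor(txt)
    v2 <- parse_protein_descriptor(format(v1))
    v1$raw_text <- v2$raw_text <- NULL
    expect_identical(v2, v1, label = txt)
  }
})

test_that("broad classification maps each kind to exactly one bin", {
  expect_identical(broad_class(parse_protein_descriptor("p.Trp613*")), "NSFS")
  expect_identical(broad_class(parse_protein_descriptor("p.Val412fs")), "NSFS")
  for (txt in c("p.Arg558Cys", "p.Phe883del", "p.Lys400_Leu401insAla",
                "p.His313delinsSer"))
    expect_identical(broad_class(parse_protein_descriptor(txt)), "INFRAME",
                     label = txt)
})

test_that("NSFS allele dose counts alleles independently and symmetrically", {
  mis <- parse_protein_descriptor("p.Arg558Cys")
  fs <- parse_protein_descriptor("p.Val412fs")
  non <- parse_protein_descriptor("p.Trp613*")
  expect_identical(count_nsfs_alleles(mis, mis), 0L)
  expect_identical(count_nsfs_alleles(fs, mis), 1L)
  expect_identical(count_nsfs_alleles(mis, fs), 1L)
  expect_identical(count_nsfs_alleles(non, fs), 2L)
  # homozygous: same descriptor twice counts both alleles
  expect_identical(count_nsfs_alleles(non, non), 2L)
  oth <- suppressWarnings(parse_protein_descriptor("p.Met1?"))
  expect_error(count_nsfs_alleles(oth, mis), "OTHER")
})

test_that("generator-emitted descriptors are recovered with their true class", {
  set.seed(402)
  dom <- synthetic_domain_table()
  gaps <- wfsdose:::.nontm_gaps(dom, 890L)
  n_ok <- 0L
  for (i in 1:1000) {
    is_nsfs <- runif(1) < 0.5
    tm <- !is_nsfs && runif(1) < 0.5
    al <- wfsdose:::.sample_allele(is_nsfs, tm, dom, gaps, 890L)
    v <- parse_protein_descriptor(al$text)
    cls <- broad_class(v)
    expect_false(cls == "OTHER", label = al$text)
    n_ok <- n_ok + identical(cls == "NSFS", is_nsfs)
  }
  expect_identical(n_ok, 1000L)
})
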