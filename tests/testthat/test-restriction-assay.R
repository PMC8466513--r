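test_that("recognition-site scanning matches hand-derived positions", {
  expect_identical(find_recognition_sites("", mlucI()), integer(0))
  expect_identical(find_recognition_sites("GAATTC", mlucI()), 1L)
  # forced primer + TT allele completes an AATT site at the junction
  expect_identical(
    find_recognition_sites(paste0(cry1_forced_primer(), "TT"), mlucI()),
    25L)
  expect_error(find_recognition_sites("ACGTX", mlucI()), "position 5")
})

test_that("scanning expands IUPAC degeneracy in the motif, not the sequence", {
  ecoRI <- enzyme("EcoRI", "GAATTC", 1L)
  hinfI <- enzyme("HinfI", "GANTC", 2L)
  expect_identical(find_recognition_sites("GACTCA", hinfI), 0L)
  expect_identical(find_recognition_sites("GATTCGAGTC", hinfI), c(0L, 5L))
  # degenerate letter in the subject does not match a literal motif letter
  expect_identical(find_recognition_sites("GANTTC", ecoRI), integer(0))
})

test_that("scanning agrees with a naive IUPAC scan on random sequences", {
  set.seed(11)
  enzymes <- list(mlucI(), enzyme("HinfI", "GANTC", 2L),
                  enzyme("DdeI", "CTNAG", 1L))
  for (k in 1:1000) {
    seq <- random_dna(sample(0:500, 1))
    enz <- enzymes[[sample(3, 1)]]
    expect_identical(find_recognition_sites(seq, enz),
                     as.integer(naive_motif_scan(seq, enz$recognition)))
  }
})

test_that("digestion reproduces the published fragment sizes", {
  asy <- cry1_assay()
  expect_identical(digest(assay_amplicon(asy, "TT"), mlucI()), c(25L, 151L))
  expect_identical(digest(assay_amplicon(asy, "AG"), mlucI()), 176L)
  # cut flush with the amplicon start yields no observable band
  expect_identical(digest("AATTGAATT", mlucI()), c(4L, 5L))
})

test_that("digestion conserves sequence length and drops zero fragments", {
  set.seed(7)
  for (k in 1:200) {
    seq <- random_dna(sample(1:400, 1))
    fr <- digest(seq, mlucI())
    expect_identical(sum(fr), nchar(seq))
    expect_true(all(fr > 0L))
  }
})

test_that("forced-primer design recreates the published A-for-G modification", {
  # natural template context ends ...GTTGA; the penultimate G must become A
  fp <- design_forced_primer("AGAAACATTGGTTACTCTTATAGTTGA", "AG", "TT",
                             mlucI(), max_mismatches = 1)
  expect_identical(fp$primer, cry1_forced_primer())
  expect_identical(fp$discriminating_allele, "TT")
  expect_identical(fp$n_mismatches, 1L)
  expect_identical(fp$mismatch_positions, 26L)  # penultimate, never terminal
})

test_that("forced-primer design handles zero-mismatch and impossible cases", {
  # context already ending AA: TT allele completes the site unforced
  fp0 <- design_forced_primer("GGGGGGGGGGGGGGAA", "AG", "TT", mlucI(),
                              max_mismatches = 0)
  expect_identical(fp0$n_mismatches, 0L)
  expect_identical(fp0$discriminating_allele, "TT")
  # all-C context: no single-base change can complete a junction AATT
  expect_null(design_forced_primer(strrep("C", 20), "AG", "TT", mlucI(),
                                   max_mismatches = 1))
  expect_error(design_forced_primer("ACGTACGT", "AG", "TT", mlucI(),
                                    max_mismatches = -1))
})

test_that("designed primers verify by digestion of both allelic amplicons", {
  set.seed(3)
  found <- 0
  for (k in 1:50) {
    ctx <- random_dna(24)
    fp <- design_forced_primer(ctx, "AG", "TT", mlucI(), max_mismatches = 1)
    if (is.null(fp)) next
    found <- found + 1
    asy <- snp_assay(fp$primer, 120L)
    alt_pat <- digest(assay_amplicon(asy, "TT"), mlucI())
    ref_pat <- digest(assay_amplicon(asy, "AG"), mlucI())
    if (fp$discriminating_allele == "TT") {
      expect_gte(length(alt_pat), 2L)
    } else {
      expect_gte(length(ref_pat), 2L)
    }
    expect_false(identical(ref_pat, alt_pat))
    # the terminal base is never modified
    expect_false(nchar(ctx) %in% fp$mismatch_positions)
  }
  expect_gt(found, 5)
})

test_that("genotype calls map fragment patterns to the three genotypes", {
  asy <- cry1_assay()
  expect_identical(call_genotype(c(176, 151, 25), asy), "AG/TT")
  expect_identical(call_genotype(c(151, 25), asy), "TT/TT")
  expect_identical(call_genotype(176, asy), "AG/AG")
  expect_warning(res <- call_genotype(c(100, 76), asy), "uncallable")
  expect_true(is.na(res))
  # near-miss band sizes resolve under a gel-reading tolerance
  expect_identical(call_genotype(c(150, 26), asy, tolerance_bp = 2), "TT/TT")
})

test_that("digest/call round trip recovers each genotype", {
  set.seed(21)
  for (k in 1:20) {
    ctx <- random_dna(22)
    fp <- design_forced_primer(ctx, "AG", "TT", mlucI())
    if (is.null(fp)) next
    asy <- snp_assay(fp$primer, nchar(fp$primer) + 2L + sample(30:120, 1))
    ref <- digest(assay_amplicon(asy, asy$allele_ref), asy$enzyme)
    alt <- digest(assay_amplicon(asy, asy$allele_alt), asy$enzyme)
    expect_identical(call_genotype(ref, asy), "AG/AG")
    expect_identical(call_genotype(alt, asy), "TT/TT")
    expect_identical(call_genotype(union(ref, alt), asy), "AG/TT")
  }
})

test_that("enzyme constructor enforces its invariants", {
  expect_error(enzyme("X", "", 0), "non-empty")
  expect_error(enzyme("X", "AAQT", 0), "non-IUPAC")
  expect_error(enzyme("X", "AATT", 5), "cut_offset")
  expect_silent(enzyme("X", "RAATTY", 6))
})
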