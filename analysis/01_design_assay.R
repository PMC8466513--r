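#!/usr/bin/env Rscript
# Step 1: recreate the forced PCR-RFLP assay for the CRY1 intron-7 AG/TT
# dinucleotide variant and tabulate the diagnostic fragment patterns.

suppressMessages(library(pigeonrace))
dir.create("results", showWarnings = FALSE)

# natural template context ending immediately 5' of the variant; the last
# two bases are ...GA, so no MluCI site can form without forcing
context <- "AGAAACATTGGTTACTCTTATAGTTGA"

fp <- design_forced_primer(context, "AG", "TT", mlucI(), max_mismatches = 1)
cat("Forced primer design:\n")
cat(sprintf("  natural 3' context : ...%s\n", substr(context, 18, 27)))
cat(sprintf("  forced primer      : ...%s\n", substr(fp$primer, 18, 27)))
cat(sprintf("  mismatch at primer position %d (%s -> %s), discriminates %s\n",
            fp$mismatch_positions,
            substr(context, fp$mismatch_positions, fp$mismatch_positions),
            substr(fp$primer, fp$mismatch_positions, fp$mismatch_positions),
            fp$discriminating_allele))

assay <- snp_assay(fp$primer, 176L)
print(assay)
rep <- write_assay_report(assay, "results/assay_report.csv")
cat("\nAssay report written to results/assay_report.csv:\n")
print(rep)

stopifnot(identical(fp$primer, cry1_forced_primer()))
cat("\nThe designed primer matches the package's built-in assay.\n")
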