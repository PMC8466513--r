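#' Genotype labels used throughout the pipeline
#'
#' The diagnostic locus is a biallelic dinucleotide substitution with
#' reference allele `AG` and alternative allele `TT`; the three genotype
#' strings are fixed as `"AG/AG"`, `"AG/TT"` and `"TT/TT"`.
#'
#' @return Character vector of the three genotype labels.
#' @export
genotype_levels <- function() c("AG/AG", "AG/TT", "TT/TT")

#' Design a forced (mismatch) primer that creates an allele-specific site
#'
#' Forced PCR-RFLP (dCAPS) introduces deliberate mismatches near the 3' end
#' of a primer so that, after amplification, a restriction site spanning the
#' primer/variant junction is present for one allele and absent for the
#' other. The candidate site must lie entirely within primer + allele (bases
#' beyond the variant are unknown at design time), and the primer's
#' 3'-terminal base is never modified because a terminal mismatch would
#' block extension.
#'
#' @param template_context Template sequence ending at the base immediately
#'   5' of the variant; the primer is this sequence (its 3' end) with up to
#'   `max_mismatches` substitutions.
#' @param allele_ref,allele_alt The two alleles of the dinucleotide variant.
#' @param enzyme An [enzyme()] object whose site should discriminate alleles.
#' @param max_mismatches Maximum number of substitutions allowed (default 1).
#' @return A list of class `"forced_primer"` with elements `primer`,
#'   `discriminating_allele`, `n_mismatches` and `mismatch_positions`
#'   (1-based, from the primer 5' end), or `NULL` if no modification of at
#'   most `max_mismatches` bases discriminates the alleles.
#' @examples
#' design_forced_primer("AGAAACATTGGTTACTCTTATAGTTGA", "AG", "TT", mlucI())
#' @export
design_forced_primer <- function(template_context, allele_ref, allele_alt,
                                 enzyme, max_mismatches = 1L) {
  stopifnot(inherits(enzyme, "enzyme"))
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer", call. = FALSE)
  ctx <- .check_sequence(template_context, "template_context")
  allele_ref <- .check_sequence(allele_ref, "allele_ref")
  allele_alt <- .check_sequence(allele_alt, "allele_alt")
  L <- nchar(ctx)
  m <- nchar(enzyme$recognition)
  if (L < m) stop("template_context shorter than the recognition motif",
                  call. = FALSE)

  # only bases inside a junction-spanning site window can matter; the
  # 3'-terminal base (position L) is off-limits
  editable <- seq.int(max(1L, L - m + 2L), L - 1L)
  bases <- c("A", "C", "G", "T")

  candidates <- list(integer(0))
  if (max_mismatches >= 1L)
    candidates <- c(candidates, as.list(rev(editable)))  # 3'-most first
  if (max_mismatches >= 2L && length(editable) >= 2L) {
    pairs <- utils::combn(rev(editable), 2L, simplify = FALSE)
    candidates <- c(candidates, pairs)
  }

  for (pos_set in candidates) {
    subs <- .enumerate_substitutions(ctx, pos_set, bases)
    for (primer in subs) {
      disc <- .discriminating_allele(primer, allele_ref, allele_alt, enzyme)
      if (!is.na(disc)) {
        mism <- which(strsplit(primer, "")[[1L]] != strsplit(ctx, "")[[1L]])
        return(structure(list(primer = primer,
                              discriminating_allele = disc,
                              n_mismatches = length(mism),
                              mismatch_positions = mism),
                         class = "forced_primer"))
      }
    }
  }
  NULL
}

# all primers obtained by substituting the given positions with other bases
.enumerate_substitutions <- function(ctx, pos_set, bases) {
  if (!length(pos_set)) return(ctx)
  chars <- strsplit(ctx, "")[[1L]]
  grids <- lapply(pos_set, function(p) setdiff(bases, chars[p]))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  apply(combos, 1L, function(repl) {
    ch <- chars
    ch[pos_set] <- repl
    paste(ch, collapse = "")
  })
}

# which allele (if exactly one) gains a site spanning the primer/allele
# junction; NA if none or both
.discriminating_allele <- function(primer, allele_ref, allele_alt, enzyme) {
  L <- nchar(primer)
  m <- nchar(enzyme$recognition)
  spans <- function(allele) {
    sites <- find_recognition_sites(paste0(primer, allele), enzyme)
    # a junction site covers the last primer base(s) and at least one allele
    # base; sites are 0-based starts
    any(sites >= L - m + 1L & sites <= L - 1L)
  }
  ref_cut <- spans(allele_ref)
  alt_cut <- spans(allele_alt)
  if (xor(ref_cut, alt_cut)) {
    if (alt_cut) allele_alt else allele_ref
  } else NA_character_
}

#' Define a forced PCR-RFLP genotyping assay
#'
#' Bundles the forced forward primer, the amplicon size, the two alleles and
#' the discriminating enzyme. The variant sits immediately 3' of the forward
#' primer, so its 0-based offset in the amplicon equals the primer length.
#' Sequence downstream of the variant is represented by a neutral filler
#' chosen to contain no recognition site (the reverse primer enters only
#' through `amplicon_length`).
#'
#' @param forward_primer The forced forward primer sequence.
#' @param amplicon_length Total amplicon length in bp.
#' @param allele_ref,allele_alt The two dinucleotide alleles
#'   (defaults `"AG"` / `"TT"`).
#' @param enzyme An [enzyme()] object (default [mlucI()]).
#' @return An object of class `"snp_assay"`.
#' @seealso [assay_amplicon()], [expected_fragments()], [call_genotype()]
#' @export
snp_assay <- function(forward_primer, amplicon_length,
                      allele_ref = "AG", allele_alt = "TT",
                      enzyme = mlucI()) {
  stopifnot(inherits(enzyme, "enzyme"))
  forward_primer <- .check_sequence(forward_primer, "forward_primer")
  allele_ref <- .check_sequence(allele_ref, "allele_ref")
  allele_alt <- .check_sequence(allele_alt, "allele_alt")
  if (nchar(allele_ref) != 2L || nchar(allele_alt) != 2L)
    stop("both alleles must be dinucleotides", call. = FALSE)
  amplicon_length <- as.integer(amplicon_length)
  variant_offset <- nchar(forward_primer)
  if (variant_offset + 2L > amplicon_length)
    stop("amplicon too short to hold primer plus the variant dinucleotide",
         call. = FALSE)
  assay <- structure(list(forward_primer = forward_primer,
                          amplicon_length = amplicon_length,
                          variant_offset = variant_offset,
                          allele_ref = allele_ref,
                          allele_alt = allele_alt,
                          enzyme = enzyme,
                          filler = NA_character_),
                     class = "snp_assay")
  assay$filler <- .neutral_filler(assay)
  assay
}

# filler for the sequence downstream of the variant that introduces no
# recognition site on its own or at the allele/filler junction
.neutral_filler <- function(assay) {
  n_fill <- assay$amplicon_length - assay$variant_offset - 2L
  if (n_fill == 0L) return("")
  for (unit in c("C", "G", "GC", "CA")) {
    fill <- substr(strrep(unit, n_fill), 1L, n_fill)
    ok <- vapply(c(assay$allele_ref, assay$allele_alt), function(al) {
      tail_sites <- find_recognition_sites(paste0(al, fill), assay$enzyme)
      length(tail_sites) == 0L
    }, logical(1L))
    if (all(ok)) return(fill)
  }
  stop("could not construct a filler free of recognition sites", call. = FALSE)
}

#' Amplicon sequence of an assay for a given allele
#'
#' @param assay An [snp_assay()] object.
#' @param allele One of the assay's two alleles.
#' @return The amplicon sequence `forward_primer + allele + filler`.
#' @export
assay_amplicon <- function(assay, allele) {
  stopifnot(inherits(assay, "snp_assay"))
  allele <- toupper(allele)
  if (!allele %in% c(assay$allele_ref, assay$allele_alt))
    stop(sprintf("unknown allele '%s' for this assay", allele), call. = FALSE)
  paste0(assay$forward_primer, allele, assay$filler)
}

#' Expected restriction fragment patterns of an assay
#'
#' Digests the two allelic amplicons in silico. The heterozygote pattern is
#' the union of band sizes from both homozygotes, as seen on a gel.
#'
#' @param assay An [snp_assay()] object.
#' @return Named list with integer vectors `ref`, `alt` and `het` of band
#'   lengths (bp, sorted ascending).
#' @export
expected_fragments <- function(assay) {
  stopifnot(inherits(assay, "snp_assay"))
  ref <- digest(assay_amplicon(assay, assay$allele_ref), assay$enzyme)
  alt <- digest(assay_amplicon(assay, assay$allele_alt), assay$enzyme)
  list(ref = ref, alt = alt, het = sort(union(ref, alt)))
}

#' Call a genotype from an observed fragment pattern
#'
#' Matches the observed band sizes against the three expected patterns
#' (reference homozygote, alternative homozygote, and their union for the
#' heterozygote), each band within `tolerance_bp`.
#'
#' @param observed Integer vector of observed band lengths (bp).
#' @param assay An [snp_assay()] object.
#' @param tolerance_bp Per-band matching tolerance in bp (default 0, exact).
#' @return One of `"AG/AG"`, `"AG/TT"`, `"TT/TT"` (rendered with the assay's
#'   alleles), or `NA_character_` with a warning when the pattern matches no
#'   expectation (uncallable sample).
#' @examples
#' asy <- snp_assay(strrep("G", 25), 176)
#' call_genotype(c(176, 151, 25), asy)
#' @export
call_genotype <- function(observed, assay, tolerance_bp = 0L) {
  stopifnot(inherits(assay, "snp_assay"))
  observed <- as.integer(observed)
  if (any(is.na(observed)) || any(observed <= 0L))
    stop("observed fragment lengths must be positive integers", call. = FALSE)
  exp <- expected_fragments(assay)
  pat <- list(exp$ref, exp$het, exp$alt)
  names(pat) <- c(paste(assay$allele_ref, assay$allele_ref, sep = "/"),
                  paste(assay$allele_ref, assay$allele_alt, sep = "/"),
                  paste(assay$allele_alt, assay$allele_alt, sep = "/"))
  obs <- sort(unique(observed))
  for (g in names(pat)) {
    e <- pat[[g]]
    if (length(obs) == length(e) && all(abs(obs - e) <= tolerance_bp))
      return(g)
  }
  warning("fragment pattern matches no expected genotype; sample uncallable",
          call. = FALSE)
  NA_character_
}

#' The published CRY1 intron-7 forced PCR-RFLP assay
#'
#' The forced forward primer for the CRY1 intron-7 AG/TT dinucleotide
#' variant carries a single A-for-G substitution at its penultimate base so
#' that, together with the TT allele, it completes an `AATT` MluCI site at
#' the primer/variant junction. The diagnostic amplicon is 176 bp; MluCI
#' digestion yields 151 + 25 bp for the TT allele and leaves the AG allele
#' uncut.
#'
#' @return `cry1_forced_primer()` returns the 27-nt forced primer string;
#'   `cry1_assay()` returns the corresponding [snp_assay()].
#' @export
cry1_forced_primer <- function() "AGAAACATTGGTTACTCTTATAGTTAA"

#' @rdname cry1_forced_primer
#' @export
cry1_assay <- function() snp_assay(cry1_forced_primer(), 176L)

#' @export
print.snp_assay <- function(x, ...) {
  pat <- expected_fragments(x)
  cat(sprintf("<snp_assay> %d bp amplicon, %s/%s variant at offset %d, enzyme %s\n",
              x$amplicon_length, x$allele_ref, x$allele_alt,
              x$variant_offset, x$enzyme$name))
  cat(sprintf("  %s/%s: %s bp\n", x$allele_ref, x$allele_ref,
              paste(rev(pat$ref), collapse = " + ")))
  cat(sprintf("  %s/%s: %s bp\n", x$allele_ref, x$allele_alt,
              paste(rev(pat$het), collapse = " + ")))
  cat(sprintf("  %s/%s: %s bp\n", x$allele_alt, x$allele_alt,
              paste(rev(pat$alt), collapse = " + ")))
  invisible(x)
}
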