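#' Restriction enzyme definition
#'
#' A restriction enzyme is described by its recognition motif (IUPAC codes
#' allowed) and the 0-based offset of the top-strand cut relative to the
#' motif start. An offset of 0 means the enzyme cuts immediately 5' of the
#' motif; an offset equal to the motif length cuts immediately 3' of it.
#'
#' @param name Enzyme name, e.g. `"MluCI"`.
#' @param recognition Recognition motif as an IUPAC nucleotide string.
#' @param cut_offset Integer in `[0, nchar(recognition)]`: 0-based top-strand
#'   cut position relative to the motif start.
#' @return An object of class `"enzyme"`.
#' @examples
#' enzyme("EcoRI", "GAATTC", 1)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(as.character(recognition))
  if (length(recognition) != 1L || !nzchar(recognition))
    stop("recognition motif must be a non-empty string", call. = FALSE)
  bad <- .non_iupac_positions(recognition)
  if (length(bad))
    stop(sprintf("recognition motif contains non-IUPAC character at position %d",
                 bad[1L]), call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie in [0, motif length]", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' MluCI restriction enzyme
#'
#' MluCI recognises `AATT` and cuts immediately 5' of the motif (blunt on
#' the top strand at the motif start). The motif is its own reverse
#' complement, so top-strand scanning finds every genomic site.
#'
#' @return An `enzyme` object.
#' @export
mlucI <- function() enzyme("MluCI", "AATT", 0L)

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s: %s, top-strand cut at +%d\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

# 1-based positions of characters that are not IUPAC nucleotide codes
.non_iupac_positions <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  which(!chars %in% names(Biostrings::IUPAC_CODE_MAP))
}

.check_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq))
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  seq <- toupper(seq)
  bad <- .non_iupac_positions(seq)
  if (length(bad))
    stop(sprintf("%s contains non-IUPAC character '%s' at position %d",
                 what, substr(seq, bad[1L], bad[1L]), bad[1L]), call. = FALSE)
  seq
}

#' Locate recognition sites of an enzyme in a sequence
#'
#' Scans the top strand for matches to the enzyme's recognition motif. IUPAC
#' degeneracy is expanded in the motif only: degenerate letters in `seq`
#' are treated as literal characters and do not match.
#'
#' @param seq Nucleotide sequence (single string, IUPAC letters).
#' @param enzyme An [enzyme()] object.
#' @param both_strands If `TRUE`, also scan the reverse complement and report
#'   the corresponding top-strand motif start positions. Off by default:
#'   palindromic motifs (such as MluCI's `AATT`) make it redundant.
#' @return Integer vector of 0-based motif start positions, sorted ascending.
#' @examples
#' find_recognition_sites("GAATTC", mlucI())  # 1
#' @export
find_recognition_sites <- function(seq, enzyme, both_strands = FALSE) {
  stopifnot(inherits(enzyme, "enzyme"))
  seq <- .check_sequence(seq)
  if (nchar(seq) < nchar(enzyme$recognition)) return(integer(0))
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(enzyme$recognition, subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  pos <- Biostrings::start(hits) - 1L
  if (both_strands) {
    rc <- Biostrings::reverseComplement(subj)
    rhits <- Biostrings::matchPattern(enzyme$recognition, rc,
                                      fixed = c(pattern = FALSE, subject = TRUE))
    # convert a motif start on the reverse strand to top-strand coordinates
    rpos <- nchar(seq) - (Biostrings::start(rhits) - 1L) -
      nchar(enzyme$recognition)
    pos <- union(pos, rpos)
  }
  sort(as.integer(pos))
}

#' In-silico restriction digestion
#'
#' Cuts `seq` at `site + cut_offset` for every recognition site and returns
#' the multiset of fragment lengths. Zero-length fragments (a cut flush with
#' a sequence end) are dropped, as they yield no observable band on a gel.
#'
#' @inheritParams find_recognition_sites
#' @return Integer vector of fragment lengths, sorted ascending; lengths sum
#'   to `nchar(seq)`.
#' @examples
#' digest("AATTGAATT", mlucI())  # 4 5
#' @export
digest <- function(seq, enzyme, both_strands = FALSE) {
  seq <- .check_sequence(seq)
  n <- nchar(seq)
  if (n == 0L) return(integer(0))
  sites <- find_recognition_sites(seq, enzyme, both_strands = both_strands)
  cuts <- sites + enzyme$cut_offset
  bounds <- sort(unique(c(0L, cuts[cuts > 0L & cuts < n], n)))
  sort(as.integer(diff(bounds)))
}
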