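#' Read a pedigree CSV
#'
#' Expects a header row with columns `id`, `sire`, `dam` and optionally
#' `sex`; empty fields are unknown parents. Validation errors carry the
#' offending row number of the data portion of the file.
#'
#' @param path Path to a CSV file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "sire", "dam")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  pedigree(df)
}

#' Write a pedigree CSV
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[, intersect(c("id", "sire", "dam", "sex"),
                                        names(ped)), drop = FALSE]
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype CSV
#'
#' Expects columns `pigeon_id` and `genotype`; genotype strings must be one
#' of [genotype_levels()] and pigeon ids unique.
#'
#' @param path Path to a CSV file.
#' @return Data frame `pigeon_id`, `genotype`.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(c("pigeon_id", "genotype"), names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- which(!df$genotype %in% genotype_levels())
  if (length(bad))
    stop(sprintf("%s: invalid genotype '%s' at row %d", path,
                 df$genotype[bad[1L]], bad[1L]), call. = FALSE)
  dup <- which(duplicated(df$pigeon_id))
  if (length(dup))
    stop(sprintf("%s: duplicate pigeon_id '%s' at row %d", path,
                 df$pigeon_id[dup[1L]], dup[1L]), call. = FALSE)
  df[, c("pigeon_id", "genotype")]
}

#' Read a race-record CSV
#'
#' Expects columns `pigeon_id`, `race_id`, `distance_km`, `n_starters`,
#' `position` (empty = did not finish), `weather_start`, `weather_end`,
#' `breeder`, `sex`. Positions exceeding the number of starters and
#' covariate levels outside [model_factor_levels()] are errors naming the
#' row.
#'
#' @param path Path to a CSV file.
#' @return Data frame of validated race records (unscored; see
#'   [score_races()]).
#' @export
read_races <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pigeon_id", "race_id", "distance_km", "n_starters", "position",
            "weather_start", "weather_end", "breeder", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$pigeon_id <- as.character(df$pigeon_id)
  df$race_id <- as.character(df$race_id)
  df$distance_km <- as.numeric(df$distance_km)
  df$n_starters <- as.integer(df$n_starters)
  df$position <- suppressWarnings(as.integer(df$position))
  if (any(df$distance_km <= 0, na.rm = TRUE) || anyNA(df$distance_km))
    stop(sprintf("%s: non-positive or missing distance_km", path),
         call. = FALSE)
  bad <- which(!is.na(df$position) & df$position > df$n_starters)
  if (length(bad))
    stop(sprintf("%s: position %d exceeds n_starters %d at row %d", path,
                 df$position[bad[1L]], df$n_starters[bad[1L]], bad[1L]),
         call. = FALSE)
  lv <- model_factor_levels()
  for (f in c("weather_start", "weather_end", "breeder", "sex")) {
    bad <- which(!df[[f]] %in% lv[[f]])
    if (length(bad))
      stop(sprintf("%s: invalid %s '%s' at row %d", path, f,
                   df[[f]][bad[1L]], bad[1L]), call. = FALSE)
  }
  df
}

#' Read an enzyme table
#'
#' Flat CSV with columns `name`, `recognition`, `cut_offset`.
#'
#' @param path Path to a CSV file.
#' @return Named list of [enzyme()] objects.
#' @examples
#' enz <- read_enzyme_table(system.file("extdata", "enzymes.csv",
#'                                      package = "pigeonrace"))
#' enz$MluCI
#' @export
read_enzyme_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "recognition", "cut_offset"), names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    enzyme(df$name[i], df$recognition[i], df$cut_offset[i]))
  stats::setNames(out, df$name)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers around Biostrings returning plain character vectors.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' In-silico PCR against a template
#'
#' Locates the forward primer on the top strand and the reverse primer as a
#' reverse complement downstream of it, and returns the unique product the
#' pair delimits (primers included). Zero or multiple products are errors.
#'
#' @param template Template sequence (single string).
#' @param fwd,rev Primer sequences, at least 15 nt; `rev` is given 5'->3' on
#'   the opposite strand, as primers are ordered.
#' @param max_mismatches Mismatches tolerated per primer site (default 0).
#' @return The amplicon sequence.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatches = 0L) {
  template <- .check_sequence(template, "template")
  fwd <- .check_sequence(fwd, "fwd")
  rev <- .check_sequence(rev, "rev")
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  subj <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(fwd, subj, max.mismatch = max_mismatches)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  rhits <- Biostrings::matchPattern(rc, subj, max.mismatch = max_mismatches)
  fs <- Biostrings::start(fhits)
  re <- Biostrings::end(rhits)
  prods <- expand.grid(fs = fs, re = re)
  prods <- prods[prods$re > prods$fs + nchar(fwd) - 1L, , drop = FALSE]
  if (nrow(prods) == 0L)
    stop("no PCR product: primer pair does not delimit a region", call. = FALSE)
  if (nrow(prods) > 1L)
    stop(sprintf("multiple PCR products (%d primer-pair placements)",
                 nrow(prods)), call. = FALSE)
  substr(template, prods$fs[1L], prods$re[1L])
}

#' Write an assay report CSV
#'
#' One row per allele with the expected fragment lengths and a flag marking
#' the allele whose amplicon is cut at the primer/variant junction.
#'
#' @param assay An [snp_assay()] object.
#' @param path Output path.
#' @return The report data frame, invisibly.
#' @export
write_assay_report <- function(assay, path) {
  pat <- expected_fragments(assay)
  rep <- data.frame(allele = c(assay$allele_ref, assay$allele_alt),
                    fragments_bp = c(paste(pat$ref, collapse = "+"),
                                     paste(pat$alt, collapse = "+")),
                    discriminating = c(length(pat$ref) > 1L,
                                       length(pat$alt) > 1L),
                    stringsAsFactors = FALSE)
  utils::write.csv(rep, path, row.names = FALSE, quote = FALSE)
  invisible(rep)
}
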