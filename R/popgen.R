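#' Genotype counts at a biallelic locus
#'
#' @param n_refref,n_refalt,n_altalt Non-negative integer counts of the
#'   reference homozygote, heterozygote and alternative homozygote.
#' @return An object of class `"genotype_counts"`.
#' @examples
#' genotype_counts(107, 14, 2)
#' @export
genotype_counts <- function(n_refref, n_refalt, n_altalt) {
  n <- c(n_refref = n_refref, n_refalt = n_refalt, n_altalt = n_altalt)
  n <- vapply(n, as.integer, integer(1L))
  if (any(is.na(n)) || any(n < 0L))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  if (sum(n) == 0L)
    stop("total count must be positive", call. = FALSE)
  structure(as.list(n), class = "genotype_counts")
}

#' Tabulate genotype counts from genotype strings
#'
#' @param genotypes Character vector of genotype strings as in
#'   [genotype_levels()].
#' @return A [genotype_counts()] object.
#' @export
count_genotypes <- function(genotypes) {
  lv <- genotype_levels()
  bad <- setdiff(unique(genotypes), lv)
  if (length(bad))
    stop(sprintf("unknown genotype value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  tab <- table(factor(genotypes, levels = lv))
  genotype_counts(tab[[1L]], tab[[2L]], tab[[3L]])
}

.as_counts <- function(counts) {
  if (inherits(counts, "genotype_counts")) return(counts)
  if (is.numeric(counts) && length(counts) == 3L)
    return(genotype_counts(counts[1L], counts[2L], counts[3L]))
  stop("counts must be a genotype_counts object or a numeric triple",
       call. = FALSE)
}

#' Genotype frequencies
#'
#' @param counts A [genotype_counts()] object or numeric triple
#'   (ref/ref, ref/alt, alt/alt).
#' @return Named numeric vector of the three genotype frequencies (sums to 1).
#' @examples
#' genotype_frequencies(genotype_counts(107, 14, 2))
#' @export
genotype_frequencies <- function(counts) {
  counts <- .as_counts(counts)
  n <- unlist(counts)
  structure(n / sum(n), names = c("ref/ref", "ref/alt", "alt/alt"))
}

#' Allele frequencies
#'
#' @inheritParams genotype_frequencies
#' @return Named numeric vector `c(p_ref, q_alt)`; `p_ref` counts two
#'   reference alleles per ref/ref individual and one per heterozygote.
#' @examples
#' allele_frequencies(genotype_counts(107, 14, 2))  # 0.9268 / 0.0732
#' @export
allele_frequencies <- function(counts) {
  counts <- .as_counts(counts)
  n <- sum(unlist(counts))
  p <- (2 * counts$n_refref + counts$n_refalt) / (2 * n)
  c(p_ref = p, q_alt = 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts with Hardy-Weinberg expectations
#' `n*p^2, 2npq, n*q^2` computed from the sample allele frequencies. The
#' statistic is the uncorrected Pearson chi-square on 1 degree of freedom
#' (three genotype classes minus one, minus one estimated allele frequency).
#' No continuity correction is applied by default; `correct = TRUE` applies
#' the Yates correction. When one allele is absent the observed counts equal
#' the expectations by construction and the statistic is 0.
#'
#' A warning flag is set when any expected class count falls below 5, where
#' the chi-square approximation is unreliable.
#'
#' @inheritParams genotype_frequencies
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list of class `"hwe_test"` with elements `chi2`, `df`,
#'   `p_value`, `expected` (length-3 numeric summing to n) and
#'   `low_expected_warning`.
#' @examples
#' hwe_chi_square(genotype_counts(107, 14, 2))  # chi2 = 3.1811
#' @export
hwe_chi_square <- function(counts, correct = FALSE) {
  counts <- .as_counts(counts)
  obs <- unlist(counts)
  n <- sum(obs)
  p <- allele_frequencies(counts)[["p_ref"]]
  q <- 1 - p
  expected <- c(n * p^2, 2 * n * p * q, n * q^2)
  if (p == 0 || q == 0) {
    chi2 <- 0
  } else {
    dev <- abs(obs - expected)
    if (correct) dev <- pmax(dev - 0.5, 0)
    chi2 <- sum(dev^2 / expected)
  }
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 expected = unname(expected),
                 low_expected_warning = any(expected < 5)),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg chi-square test: chi2 = %.4f, df = %d, p = %.4f\n",
              x$chi2, x$df, x$p_value))
  cat(sprintf("expected counts: %s\n",
              paste(sprintf("%.2f", x$expected), collapse = ", ")))
  if (x$low_expected_warning)
    cat("note: at least one expected count < 5; chi-square approximation unreliable\n")
  invisible(x)
}
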