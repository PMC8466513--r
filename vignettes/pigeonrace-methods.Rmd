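---
title: "Methods: forced PCR-RFLP genotyping and the ace-points animal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forced PCR-RFLP genotyping and the ace-points animal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigeonrace)
```

`pigeonrace` implements a complete candidate-gene association pipeline for
homing-pigeon racing performance, from the molecular assay that produces the
genotypes to the mixed model that links them to race results. This vignette
explains each stage's model and assumptions, the tunable parameters, the
numerical choices, and what the simulation-based validation does and does not
demonstrate.

## 1. In-silico forced PCR-RFLP (dCAPS)

The diagnostic locus is a biallelic dinucleotide substitution (reference
allele `AG`, alternative allele `TT`) in an intron of the cryptochrome-1
gene, a candidate for the avian magnetoreceptor. Neither allele creates a
natural restriction site, so genotyping uses the forced PCR-RFLP (dCAPS)
trick: the forward primer carries a deliberate mismatch near its 3' end such
that primer-derived sequence plus one allele — and only one — completes a
restriction site at the primer/variant junction.

`design_forced_primer()` searches the substitution space. Only positions
inside the junction window (the last `motif length - 1` bases of the primer)
can participate in a junction-spanning site, so the enumeration is restricted
to them; the 3'-terminal base is never modified because a terminal mismatch
would block polymerase extension. Candidates are ranked by mismatch count
(fewest first), then by position (3'-most first), so a zero-mismatch solution
is always preferred and the returned design is deterministic. A candidate
site must lie entirely within primer + allele: bases downstream of the
variant are unknown at design time and may not be relied on. For the shipped
assay (`cry1_assay()`), a single A-for-G substitution at the penultimate
primer base, together with the `TT` allele, completes the `AATT` site of
MluCI at the junction; with `AG` the amplicon is refractory.

Digestion model: `digest()` scans the top strand for the recognition motif
(IUPAC degeneracy is expanded in the motif only — a degenerate letter in the
*sequence* is data, not a wildcard), cuts at `site + cut_offset`, and reports
fragment *lengths*, matching gel-reading practice. Coordinates are 0-based
and intervals half-open. Zero-length fragments (a cut flush with an amplicon
end) are dropped, since they produce no band. MluCI's `AATT` is its own
reverse complement, so top-strand scanning is lossless for this assay; a
`both_strands` flag exists for non-palindromic enzymes. The 176 bp amplicon
yields 151 + 25 bp for `TT`, an uncut 176 bp product for `AG`, and the union
of both band sets for the heterozygote. The reverse primer is represented
only through the amplicon length, and sequence downstream of the variant by
a filler chosen to contain no recognition site: fragment sizes depend only on
the junction cut, so this loses nothing. `call_genotype()` matches observed
band sets against the three expectations with a per-band tolerance
(`tolerance_bp`, default 0; a 3% agarose gel justifies 1-3 bp); a pattern
matching none of the three returns `NA` with a warning rather than an error,
since uncallable lanes are routine.

## 2. Population genetics

`hwe_chi_square()` compares observed genotype counts with Hardy-Weinberg
expectations $(np^2, 2npq, nq^2)$ computed from the sample allele
frequencies, using the uncorrected Pearson statistic on 1 degree of freedom
(three classes, minus one, minus one estimated frequency). No continuity
correction is applied by default; with the published counts (107/14/2) the
uncorrected statistic is 3.1811, and a Yates-corrected variant is available
as a flag. The p-value is always recomputed from the statistic. Published
tables of this kind sometimes print, in the p-value slot, a number that is
actually the major-allele frequency (here 228/246 = 0.9268); the recomputed
tail probability of 3.1811 on 1 df is 0.0745. The implementation reports the
recomputed value only. A `low_expected_warning` flags expected class counts
below 5 (with a minor-allele frequency of 0.07 and n = 123 the expected
alternative-homozygote count is 0.66), where the chi-square approximation is
unreliable and an exact test would be preferred.

## 3. Ace-points scoring

Race results are scored on the federation ace-points scale: with `a` the
prize-list size (20% of starters) and `b` the finishing position,

$$AP = \frac{a - b + 1}{a} \times 100, \qquad b \le a,$$

so the winner always scores 100, points decline linearly over the prize
list, and everyone else — including birds that did not finish — scores 0.
Rounding of the 20% rule is `floor` with a minimum of one prize slot;
federations differ, so `round` and `ceiling` are options. Ties in position
are rejected (the formula is undefined for ties), and positions must not
exceed the number of starters. Distances classify races as short
($\le 400$ km) or long ($\ge 500$ km); the scheme leaves (400, 500) km
undefined, which is an error by default and a nearest-boundary warning in
lenient mode. Did-not-finish records are retained at AP = 0 rather than
excluded, so repeated-records counts stay complete; both behaviours are
available downstream because exclusion simply filters the table.

## 4. Pedigree and the additive relationship matrix

The additive (numerator) relationship matrix **A** is built by the tabular
method over a parent-first ordered pedigree:
$a_{ii} = 1 + a_{s_i d_i}/2$ and $a_{ij} = (a_{j s_i} + a_{j d_i})/2$ for
earlier $j$, missing-parent terms contributing zero. Unknown parents are
unrelated, non-inbred founders — the standard convention — and one known
parent is allowed. `truncate_pedigree()` counts meioses back from the
phenotyped (focal) birds, so "three generations of known pedigree" means
ancestors up to three meioses deep, with the cut-off generation converted to
founders. The matrix is validated in two independent ways: against a
memoised coancestry (path-counting) recursion on random pedigrees, and by
positive semidefiniteness of its spectrum. The matrix spans all study birds
jointly; per-breeder blocks would discard the (rare but real) cross-loft
relationships.

## 5. The repeated-measures animal model

Ace points are analysed with

$$y = \mu + g + s + h + ps + pp + k + i + a + e,$$

fixed effects of genotype ($g$), sex ($s$), breeder ($h$), weather at
release ($ps$) and arrival ($pp$), and race category ($k$); a random
permanent-environment effect $i \sim N(0, \sigma^2_i I)$ per bird carrying
the repeated records, a polygenic effect $a \sim N(0, \sigma^2_a A)$, and
residual $e \sim N(0, \sigma^2_e I)$. Race category appears once: listing it
with both the distance term and the weather terms would double-count a
single classification.

**Fitting.** REML, with the residual variance profiled out analytically and
the optimisation run over the two log variance ratios
$\log(\sigma^2_i/\sigma^2_e)$ and $\log(\sigma^2_a/\sigma^2_e)$ — the log
scale imposes non-negativity by construction. Writing
$V = \sigma^2_e (I + Z W Z')$ with $W = \lambda_i I + \lambda_a A$ over the
$q$ phenotyped birds and $Z$ the record-to-bird incidence, the Woodbury
identity and the determinant lemma reduce every likelihood evaluation to
$q \times q$ Cholesky algebra on sufficient statistics computed once
($Z'X$, $Z'y$, diagonal $Z'Z$), so a 2 000-record fit takes well under a
second. Two default starts (equal split, residual-dominant) guard against
local optima; Nelder-Mead exploration is polished by L-BFGS-B (golden-section
search when only one ratio is free), and ratios driven to the numerical
floor ($10^{-8}$) are reported as structural zeros. Tolerance is $10^{-8}$
on the relative change of $-2\,\mathrm{logRL}$. With the identity matrix for
**A** and the polygenic term fixed at zero, the fit coincides with a
standard one-random-intercept model (verified against `lme4` to $10^{-4}$,
and against closed-form balanced ANOVA estimators); with both random
components fixed at zero it reduces to ordinary least squares.

**Inference.** Fixed effects come from generalised least squares at the
optimum, with covariance $\sigma^2_e (X' H^{-1} X)^{-1}$. Genotype
least-squares means average the prediction over a balanced grid of the other
observed factor levels; pairwise contrasts are Wald tests with the
large-sample normal reference (the study's ~1 700 records make a
Satterthwaite-style denominator-df correction a refinement rather than a
necessity, and it is deliberately out of scope). Raw per-genotype ace-point
means with standard errors are reported alongside (`summarize_by_genotype()`),
but the significance claim belongs to the model-based contrast, which
adjusts for covariates and relatedness. Factors observed at a single level
are dropped with a warning. A rank-deficient fixed design is an error by
default; `on_singular = "drop"` removes aliased columns as `lm()` does,
which matters for simulated short seasons where race-level covariates can be
aliased by chance (in one generated season, every long race happened to end
in rain).

## 6. The synthetic-data generator

The generator emulates the study design the pipeline targets: 123 raced
birds (the final generation of a 3-generation, two-loft pedigree), a
14-race season spanning 100-800 km, Mendelian genotypes at a founder
alternative-allele frequency of 0.07, and latent genotype shifts of
0 / +7 / +4 ace points (reference homozygote / heterozygote / alternative
homozygote) — the heterozygote-advantage ordering and magnitude of the
association the pipeline is meant to detect. Variance-component defaults are
$\sigma^2_a = 100$, $\sigma^2_i = 50$, $\sigma^2_e = 400$ squared ace
points: a repeatability of 0.27 and heritability of 0.18, in the range
reported for racing-pigeon performance traits. Sex, breeder, weather and
category effects default to a few ace points each; weather is drawn once per
race and shared by all of its records (a race has one sky). Each loft breeds
from a limited team (15 pairs by default, a male heading up to two pairs),
giving the full-sib and paternal half-sib families a racing loft actually
produces; youngsters are allocated round-robin so family sizes are balanced
(~6-7). All draws come from one seeded stream, so a run is byte-identical
given its seed.

Breeding values are dropped down the pedigree by Mendelian sampling —
founders $N(0, \sigma^2_a)$, offspring receiving the parent average plus a
deviation with variance $\sigma^2_a(0.5 - (F_s + F_d)/4)$ — which realises
exactly the covariance $\sigma^2_a A$ (checked empirically over replicates
against the tabular matrix). Finishing positions are the within-race ranks
of latent performance after embedding the cohort in a larger club field
(drawn from the cohort's race-specific latent distribution, field size
uniform on 50-500); ace points then emerge through the actual prize-list
formula rather than being drawn directly. This is the minimal generative
model consistent with a rank-based scoring system.

**What the validation shows, and on which scale.** Rank-derived ace points
are a bounded, zero-inflated, nonlinear transform of latent performance: the
top 20% of a 50-500-bird field score on a 0-100 scale and everyone else
scores 0. No estimator can recover latent variance components (e.g.
$\sigma^2_e = 400$) from that transform, so parameter-recovery experiments
fit the latent performance retained in the generator's truth ledger — they
validate the REML machinery on the scale where the truth is defined. The
rank-to-AP path is validated separately: scoring arithmetic exactly, effect
*direction* in raw AP means, and total dominance of rankings under an
extreme injected effect. Consequently, passing tests demonstrate correct
estimation for a linear mixed model and correct scoring mechanics; they do
not demonstrate that fitting a linear model to real (rank-derived) ace
points recovers effects on any latent scale — there, as in the field study,
the model estimates genotype differences in *expected ace points*.

**Experiment sizes.** The recovery and power experiments use 200 birds by
10 races over 20 seeds, and null (type-I error) simulations use 200
replicates of 60 birds by 6 races — sizes at which one replicate fits in
under a second, chosen so the whole validation suite runs comfortably on a
laptop. The power and null experiments set the alternative-allele frequency
to 0.3 rather than the field value 0.07: with ~26 carriers out of 200 the
analytic power of a +7-point contrast is only ~0.65, so a power assertion at
the field frequency would measure allele-frequency starvation, not detection
ability. The field frequency is kept wherever frequency itself is the
quantity under test. At the field frequency the demo cohort
(`analysis/`, seed 2021) in fact shows a *negative* heterozygote contrast —
nine carrier birds from a handful of families can easily be collectively
unlucky in their polygenic draw — which is exactly the fragility that makes
kinship adjustment and power calculations indispensable at rare-variant
frequencies.

**Known limitations.** The generator does not model attrition or selection
across the season (every bird flies every race; the field study's 1209
records from 123 birds imply missed races), loft geography, weather
correlation across races, or realistic field-size distributions; its field
birds are exchangeable with the cohort. None of these affect the estimand
of the validation experiments, but all of them matter for transferring
conclusions to real race data.

## 7. Numerical and interface conventions

Sequence coordinates 0-based half-open; fragment multisets sorted ascending.
Genotype strings are exactly `AG/AG`, `AG/TT`, `TT/TT`; CSV dialects use a
header row, comma delimiter, empty field for unknown parent, and readers
report the offending row on validation failure. `in_silico_pcr()` demands
unique placement of both primers and errors on zero or multiple products.
Internal frequencies and statistics are kept at full precision, rounding
happens only in presentation. The REML fit is deterministic given data and
start; simulation functions reseed from their config by default but share
one stream inside `simulate_study()`.
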