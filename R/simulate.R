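#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: a multi-
#' generation pedigree from two breeders' lofts, Mendelian transmission of a
#' biallelic dinucleotide variant, and a full racing season in which
#' finishing positions arise from ranking a latent performance built from
#' genotype, sex, breeder, weather, race-category, polygenic,
#' permanent-environment and residual effects.
#'
#' Defaults mirror the field study the pipeline targets: 123 phenotyped
#' birds bred over 3 generations by 2 breeders, an alternative-allele
#' frequency of 0.07, 14 races spanning 100-800 km, and latent genotype
#' shifts of 0 / +7 / +4 ace points for the reference homozygote,
#' heterozygote and alternative homozygote. Variance components default to
#' a polygenic variance of 100, permanent-environment variance of 50 and
#' residual variance of 400 (squared ace-point units).
#'
#' @param n_founders Number of founder birds (split over the two lofts).
#' @param n_breeding_pairs Breeding pairs mated per loft and generation;
#'   lofts breed from a limited team, so a season's youngsters form
#'   full-sib and paternal half-sib families.
#' @param n_generations Number of bred generations after the founders.
#' @param n_birds_phenotyped Size of the final (raced) generation.
#' @param n_races Races flown by the cohort (one season).
#' @param allele_freq_alt Founder frequency of the alternative (TT) allele.
#' @param genotype_effects Named latent shifts per genotype (ace points).
#' @param sex_effects,breeder_effects,weather_start_effects,
#'   weather_end_effects,category_effects Named latent shifts per level.
#' @param sigma2_a,sigma2_i,sigma2_e Polygenic, permanent-environment and
#'   residual variances.
#' @param mu Latent grand mean (ace points).
#' @param distances_km Race distances; lengths other than `n_races` recycle.
#' @param n_starters_range Range the per-race field size is drawn from
#'   (the club field is larger than the focal cohort).
#' @param seed Integer seed driving the single pseudo-random stream.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 40L,
                       n_breeding_pairs = 15L,
                       n_generations = 3L,
                       n_birds_phenotyped = 123L,
                       n_races = 14L,
                       allele_freq_alt = 0.07,
                       genotype_effects = c("AG/AG" = 0, "AG/TT" = 7,
                                            "TT/TT" = 4),
                       sex_effects = c(male = 0, female = -2),
                       breeder_effects = c(A = 0, B = 3),
                       weather_start_effects = c(sunny = 0, changeable = -3),
                       weather_end_effects = c(sunny = 0, changeable = -2,
                                               rainy = -5, windy = -4,
                                               cloudy = -1),
                       category_effects = c(short = 0, long = -2),
                       sigma2_a = 100, sigma2_i = 50, sigma2_e = 400,
                       mu = 30,
                       distances_km = c(150, 200, 250, 300, 320, 350, 380,
                                        400, 500, 550, 600, 650, 700, 800),
                       n_starters_range = c(50L, 500L),
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_breeding_pairs = as.integer(n_breeding_pairs),
              n_generations = as.integer(n_generations),
              n_birds_phenotyped = as.integer(n_birds_phenotyped),
              n_races = as.integer(n_races),
              allele_freq_alt = allele_freq_alt,
              genotype_effects = genotype_effects,
              sex_effects = sex_effects,
              breeder_effects = breeder_effects,
              weather_start_effects = weather_start_effects,
              weather_end_effects = weather_end_effects,
              category_effects = category_effects,
              sigma2_a = sigma2_a, sigma2_i = sigma2_i, sigma2_e = sigma2_e,
              mu = mu,
              distances_km = rep_len(distances_km, n_races),
              n_starters_range = as.integer(n_starters_range),
              seed = as.integer(seed))
  if (cfg$n_founders < 2L) stop("need at least 2 founders", call. = FALSE)
  if (cfg$allele_freq_alt <= 0 || cfg$allele_freq_alt >= 1)
    stop("allele_freq_alt must lie in (0, 1)", call. = FALSE)
  if (any(c(cfg$sigma2_a, cfg$sigma2_i, cfg$sigma2_e) < 0))
    stop("variance components must be non-negative", call. = FALSE)
  if (cfg$n_races < 1L) stop("n_races must be >= 1", call. = FALSE)
  stopifnot(identical(names(cfg$genotype_effects), genotype_levels()))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation racing-pigeon pedigree
#'
#' Founders are split evenly between two lofts (breeders A and B) with
#' alternating sexes. Each generation, mated pairs are formed within a loft
#' (a male may head up to two pairs, giving half-sib as well as full-sib
#' structure) and offspring are assigned to random pairs, so the final
#' generation carries informative sibship structure. Offspring sexes
#' alternate within the generation to keep both sexes represented.
#'
#' @param config A [sim_config()].
#' @param reseed Set the stream from `config$seed` before drawing (default
#'   `TRUE`; [simulate_study()] manages one stream itself).
#' @return A topologically sorted [pedigree()] with extra columns
#'   `generation` and `breeder`; attribute `"phenotyped"` holds the ids of
#'   the final generation.
#' @export
simulate_pedigree <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  nf <- config$n_founders
  founders <- data.frame(id = sprintf("F%03d", seq_len(nf)),
                         sire = NA_character_, dam = NA_character_,
                         sex = rep_len(c("male", "female"), nf),
                         generation = 0L,
                         breeder = rep_len(c("A", "A", "B", "B"), nf),
                         stringsAsFactors = FALSE)
  gens <- list(founders)
  sizes <- rep(config$n_birds_phenotyped, config$n_generations)
  for (g in seq_len(config$n_generations)) {
    prev <- gens[[g]]
    loft_n <- c(A = ceiling(sizes[g] / 2), B = floor(sizes[g] / 2))
    kids <- lapply(c("A", "B"), function(br) {
      males <- prev$id[prev$sex == "male" & prev$breeder == br]
      females <- prev$id[prev$sex == "female" & prev$breeder == br]
      if (!length(males) || !length(females))
        stop(sprintf("generation %d of loft %s has a single sex; cannot mate",
                     g - 1L, br), call. = FALSE)
      n_kids <- loft_n[[br]]
      # limited breeding team: each male may head up to two pairs, each
      # with a distinct female, capped at n_breeding_pairs per loft
      sires <- rep(sample(males), each = 2L)
      dams <- sample(rep_len(sample(females), length(sires)))
      ok <- !duplicated(paste(sires, dams))
      pairs <- data.frame(sire = sires[ok], dam = dams[ok],
                          stringsAsFactors = FALSE)
      pairs <- pairs[seq_len(min(nrow(pairs), config$n_breeding_pairs)), ,
                     drop = FALSE]
      # youngsters spread evenly over the team (round-robin), so family
      # sizes are balanced
      take <- rep_len(sample(nrow(pairs)), n_kids)
      data.frame(id = NA_character_,
                 sire = pairs$sire[take], dam = pairs$dam[take],
                 sex = NA_character_, generation = g, breeder = br,
                 stringsAsFactors = FALSE)
    })
    kids <- do.call(rbind, kids)
    kids$id <- sprintf("G%d_%03d", g, seq_len(nrow(kids)))
    kids$sex <- rep_len(c("male", "female"), nrow(kids))
    gens[[g + 1L]] <- kids
  }
  ped <- do.call(rbind, gens)
  out <- topological_sort(pedigree(ped))
  out$generation <- ped$generation[match(out$id, ped$id)]
  out$breeder <- ped$breeder[match(out$id, ped$id)]
  attr(out, "phenotyped") <- ped$id[ped$generation == config$n_generations]
  out
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders draw genotypes from Hardy-Weinberg proportions at the given
#' alternative-allele frequency; each offspring receives one uniformly
#' random allele from each parent (Mendelian segregation).
#'
#' @param ped A topologically sorted [pedigree()].
#' @param allele_freq_alt Founder frequency of the alternative (TT) allele.
#' @param seed Optional seed; `NULL` continues the current stream.
#' @return Data frame `pigeon_id`, `genotype` in pedigree order.
#' @export
simulate_genotypes <- function(ped, allele_freq_alt = 0.07, seed = NULL) {
  if (!.is_sorted_pedigree(ped))
    stop("pedigree is not parent-first ordered; call topological_sort() first",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- allele_freq_alt
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  # allele codes: 0 = AG (reference), 1 = TT (alternative)
  al <- matrix(NA_integer_, n, 2L)
  for (i in seq_len(n)) {
    s <- pos[ped$sire[i]]; d <- pos[ped$dam[i]]
    al[i, 1L] <- if (is.na(s)) stats::rbinom(1L, 1L, q)
                 else al[s, sample.int(2L, 1L)]
    al[i, 2L] <- if (is.na(d)) stats::rbinom(1L, 1L, q)
                 else al[d, sample.int(2L, 1L)]
  }
  g <- rowSums(al)
  data.frame(pigeon_id = ped$id,
             genotype = genotype_levels()[g + 1L],
             stringsAsFactors = FALSE)
}

#' Drop breeding values down a pedigree
#'
#' Mendelian-sampling recursion: founders draw `N(0, sigma2_a)`; an
#' offspring's breeding value is the parent average plus a Mendelian
#' deviation with variance `sigma2_a * (0.5 - (F_s + F_d) / 4)` (missing
#' parents contribute a 0 mean and a correspondingly larger deviation).
#' Over replicates the simulated values have covariance `sigma2_a * A`.
#'
#' @param ped A topologically sorted [pedigree()].
#' @param sigma2_a Additive genetic variance.
#' @param seed Optional seed; `NULL` continues the current stream.
#' @return Named numeric vector of breeding values in pedigree order.
#' @export
simulate_breeding_values <- function(ped, sigma2_a, seed = NULL) {
  if (!.is_sorted_pedigree(ped))
    stop("pedigree is not parent-first ordered; call topological_sort() first",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  if (sigma2_a == 0) return(stats::setNames(rep(0, n), ped$id))
  Fcoef <- inbreeding(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  bv <- numeric(n)
  for (i in seq_len(n)) {
    s <- pos[ped$sire[i]]; d <- pos[ped$dam[i]]
    mean_par <- 0
    var_mend <- 1          # fraction of sigma2_a left for the deviation
    if (!is.na(s)) {
      mean_par <- mean_par + bv[s] / 2
      var_mend <- var_mend - 0.25 * (1 + Fcoef[s])
    }
    if (!is.na(d)) {
      mean_par <- mean_par + bv[d] / 2
      var_mend <- var_mend - 0.25 * (1 + Fcoef[d])
    }
    bv[i] <- mean_par + stats::rnorm(1L, 0, sqrt(sigma2_a * var_mend))
  }
  stats::setNames(bv, ped$id)
}

#' Simulate a season of races for the phenotyped cohort
#'
#' Builds, per race, a latent performance for every phenotyped bird (grand
#' mean + genotype, sex, breeder, weather, category shifts + breeding value
#' + permanent-environment effect + residual), embeds the cohort in a wider
#' club field of `n_starters` birds whose latent values are drawn from the
#' cohort's race-specific distribution, converts latent performance to
#' finishing positions by ranking (best latent value wins), and scores ace
#' points through [score_races()]. Weather is drawn once per race and shared
#' by all its records. When all variance components and effects are zero the
#' ranking falls back to a seeded random tie-break and the result is flagged
#' `degenerate`.
#'
#' @param ped Pedigree from [simulate_pedigree()] (needs `breeder` column
#'   and the `"phenotyped"` attribute).
#' @param genotypes Data frame from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param reseed Set the stream from `config$seed` (default `TRUE`).
#' @return A list of class `"sim_races"`: `records` (scored race records
#'   with the latent performance in `latent_ap`), `truth` (per-bird breeding
#'   values, permanent-environment effects, genotypes and the config) and
#'   `degenerate` flag.
#' @export
simulate_races <- function(ped, genotypes, config, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  birds <- attr(ped, "phenotyped")
  if (is.null(birds)) birds <- ped$id
  gmap <- stats::setNames(genotypes$genotype, genotypes$pigeon_id)
  if (anyNA(gmap[birds]))
    stop("genotypes missing for at least one phenotyped bird", call. = FALSE)
  nb <- length(birds)
  info <- data.frame(pigeon_id = birds,
                     sex = ped$sex[match(birds, ped$id)],
                     breeder = ped$breeder[match(birds, ped$id)],
                     genotype = unname(gmap[birds]),
                     stringsAsFactors = FALSE)
  bv <- simulate_breeding_values(ped, config$sigma2_a, seed = NULL)[birds]
  pe <- stats::rnorm(nb, 0, sqrt(config$sigma2_i))
  base <- config$mu +
    config$genotype_effects[info$genotype] +
    config$sex_effects[info$sex] +
    config$breeder_effects[info$breeder] +
    bv + pe

  degenerate <- config$sigma2_a == 0 && config$sigma2_i == 0 &&
    config$sigma2_e == 0 && all(config$genotype_effects == 0) &&
    all(config$sex_effects == 0) && all(config$breeder_effects == 0)
  if (degenerate)
    warning("all variances and effects are zero; rankings are random tie-breaks",
            call. = FALSE)

  races <- lapply(seq_len(config$n_races), function(r) {
    dist <- config$distances_km[r]
    ws <- sample(names(config$weather_start_effects), 1L)
    we <- sample(names(config$weather_end_effects), 1L)
    cat_r <- as.character(categorize_race(dist))
    lat <- base +
      config$weather_start_effects[ws] +
      config$weather_end_effects[we] +
      config$category_effects[cat_r] +
      stats::rnorm(nb, 0, sqrt(config$sigma2_e))
    n_starters <- max(nb, sample(seq(config$n_starters_range[1L],
                                     config$n_starters_range[2L]), 1L))
    # the rest of the club field, resampled from the cohort's distribution
    n_field <- n_starters - nb
    field <- stats::rnorm(n_field, mean(lat), max(stats::sd(lat), 1e-12))
    all_lat <- c(lat, field)
    pos_all <- rank(-all_lat, ties.method = "random")
    data.frame(pigeon_id = birds,
               race_id = sprintf("R%02d", r),
               distance_km = dist,
               n_starters = n_starters,
               position = as.integer(pos_all[seq_len(nb)]),
               weather_start = ws, weather_end = we,
               breeder = info$breeder, sex = info$sex,
               latent_ap = as.numeric(lat),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, races)
  rownames(records) <- NULL
  records <- score_races(records)
  structure(list(records = records,
                 truth = list(breeding_values = bv,
                              permanent_env = stats::setNames(pe, birds),
                              genotypes = info,
                              config = config),
                 degenerate = degenerate),
            class = "sim_races")
}

#' Run the full simulation: pedigree, genotypes and races
#'
#' Draws everything from a single pseudo-random stream seeded once from
#' `config$seed`, so repeated runs are byte-identical.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_study"` with `pedigree`, `genotypes`,
#'   `records` (scored), `truth` and `A` (additive relationship matrix over
#'   the whole pedigree).
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  ped <- simulate_pedigree(config, reseed = FALSE)
  gen <- simulate_genotypes(ped, config$allele_freq_alt, seed = NULL)
  sim <- simulate_races(ped, gen, config, reseed = FALSE)
  structure(list(pedigree = ped,
                 genotypes = gen,
                 records = sim$records,
                 truth = sim$truth,
                 degenerate = sim$degenerate,
                 A = additive_relationship_matrix(ped)),
            class = "sim_study")
}
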