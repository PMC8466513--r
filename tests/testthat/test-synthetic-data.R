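test_that("simulation is deterministic per seed", {
  cfg <- sim_config(n_founders = 8, n_birds_phenotyped = 20, n_races = 4,
                    seed = 7)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$pedigree, st2$pedigree)
  expect_identical(st1$genotypes, st2$genotypes)
  expect_identical(st1$records, st2$records)

  cfg2 <- sim_config(n_founders = 4, n_generations = 1,
                     n_birds_phenotyped = 6, seed = 1)
  expect_identical(simulate_pedigree(cfg2), simulate_pedigree(cfg2))
})

test_that("pedigree structure: generations, parents, both sexes", {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    n_birds_phenotyped = 40, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_true(pigeonrace:::.is_sorted_pedigree(ped))
  for (g in 1:3) {
    gen <- ped[ped$generation == g, ]
    prev <- ped$id[ped$generation == g - 1L]
    expect_true(all(gen$sire %in% prev))
    expect_true(all(gen$dam %in% prev))
    expect_true(all(c("male", "female") %in% gen$sex))
  }
  expect_identical(length(attr(ped, "phenotyped")), 40L)
  # zero generations: founders only
  ped0 <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 0,
                                       n_birds_phenotyped = 10, seed = 2))
  expect_true(all(is.na(ped0$sire)))
})

test_that("gene dropping is Mendelian and matches founder frequencies", {
  # fixed reference allele: everyone homozygous reference
  cfg <- sim_config(n_founders = 10, n_birds_phenotyped = 30, seed = 5)
  ped <- simulate_pedigree(cfg)
  g0 <- simulate_genotypes(ped, allele_freq_alt = 0, seed = 5)
  expect_true(all(g0$genotype == "AG/AG"))

  # two reference homozygote parents never produce a carrier
  set.seed(6)
  g <- simulate_genotypes(ped, allele_freq_alt = 0.4, seed = 6)
  gm <- setNames(g$genotype, g$pigeon_id)
  kids <- ped[!is.na(ped$sire), ]
  both_ref <- gm[kids$sire] == "AG/AG" & gm[kids$dam] == "AG/AG"
  expect_true(all(gm[kids$id[both_ref]] == "AG/AG"))
  # and an alt-homozygote parent always transmits an alt allele
  alt_par <- gm[kids$sire] == "TT/TT"
  expect_true(all(gm[kids$id[alt_par]] != "AG/AG"))

  # founder draw stays within binomial error of the target frequency
  big <- pedigree(data.frame(id = sprintf("f%04d", 1:2000),
                             sire = NA, dam = NA, sex = "male"))
  gb <- simulate_genotypes(topological_sort(big), 0.07, seed = 11)
  qhat <- allele_frequencies(count_genotypes(gb$genotype))[["q_alt"]]
  expect_lt(abs(qhat - 0.07), 3 * sqrt(0.07 * 0.93 / (2 * 2000)))
})

test_that("gene dropping preserves allele frequency across generations", {
  cfg <- sim_config(n_founders = 60, n_generations = 3,
                    n_birds_phenotyped = 60, allele_freq_alt = 0.2, seed = 13)
  ped <- simulate_pedigree(cfg)
  set.seed(13)
  qs <- replicate(60, {
    g <- simulate_genotypes(ped, 0.2)
    gm <- setNames(g$genotype, g$pigeon_id)
    last <- gm[ped$id[ped$generation == 3L]]
    cnt <- count_genotypes(unname(last))
    allele_frequencies(cnt)[["q_alt"]]
  })
  # mean over replicates close to the founder frequency (drift averages out)
  expect_lt(abs(mean(qs) - 0.2), 3 * sd(qs) / sqrt(length(qs)))
})

test_that("dropped breeding values realise the pedigree covariance", {
  # 6-animal pedigree with sibs and an inbred individual
  ped <- topological_sort(pedigree(data.frame(
    id = c("s", "d", "k1", "k2", "d2", "x"),
    sire = c(NA, NA, "s", "s", NA, "k1"),
    dam = c(NA, NA, "d", "d", NA, "d2"),
    sex = c("male", "female", "male", "male", "female", "male"))))
  A <- additive_relationship_matrix(ped)
  s2a <- 4
  set.seed(99)
  bvs <- t(replicate(500, simulate_breeding_values(ped, s2a)[colnames(A)]))
  emp <- cov(bvs)
  # entrywise agreement within Monte-Carlo error (~ 3 SE of a covariance)
  mc_tol <- 3 * s2a * 2 / sqrt(500)
  expect_lt(max(abs(emp - s2a * A)), mc_tol)
})

test_that("an extreme genotype effect dominates every race ranking", {
  cfg <- sim_config(n_founders = 16, n_birds_phenotyped = 40, n_races = 4,
                    allele_freq_alt = 0.4,
                    genotype_effects = c("AG/AG" = 0, "AG/TT" = 1000,
                                         "TT/TT" = 1000),
                    seed = 19)
  st <- simulate_study(cfg)
  gm <- setNames(st$genotypes$genotype, st$genotypes$pigeon_id)
  rec <- st$records
  rec$gt <- gm[rec$pigeon_id]
  for (r in unique(rec$race_id)) {
    sub <- rec[rec$race_id == r, ]
    carriers <- sub$position[sub$gt != "AG/AG"]
    refs <- sub$position[sub$gt == "AG/AG"]
    if (length(carriers) && length(refs))
      expect_lt(max(carriers), min(refs))
  }
})

test_that("degenerate all-zero simulations are flagged and still rank", {
  cfg <- sim_config(n_founders = 8, n_birds_phenotyped = 12, n_races = 2,
                    genotype_effects = c("AG/AG" = 0, "AG/TT" = 0, "TT/TT" = 0),
                    sex_effects = c(male = 0, female = 0),
                    breeder_effects = c(A = 0, B = 0),
                    weather_start_effects = c(sunny = 0, changeable = 0),
                    weather_end_effects = c(sunny = 0, changeable = 0,
                                            rainy = 0, windy = 0, cloudy = 0),
                    category_effects = c(short = 0, long = 0),
                    sigma2_a = 0, sigma2_i = 0, sigma2_e = 0, seed = 4)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg$allele_freq_alt, seed = 4)
  expect_warning(sim <- simulate_races(ped, gen, cfg), "tie-breaks")
  expect_true(sim$degenerate)
  expect_false(anyNA(sim$records$position))
})

test_that("simulated records carry consistent scoring and truth ledger", {
  cfg <- sim_config(n_founders = 12, n_birds_phenotyped = 24, n_races = 5,
                    seed = 31)
  st <- simulate_study(cfg)
  expect_identical(nrow(st$records), 24L * 5L)
  expect_true(all(st$records$position <= st$records$n_starters))
  expect_equal(st$records$ap,
               ace_points(st$records$prize_list, st$records$position))
  expect_setequal(names(st$truth$breeding_values),
                  unique(st$records$pigeon_id))
  expect_true(all(rownames(st$A) == st$pedigree$id))
})
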