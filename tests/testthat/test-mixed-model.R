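test_that("design bookkeeping: dimensions, single-level drops, level checks", {
  dat <- balanced_records(4, 2, seed = 1,
                          genotype = c("AG/AG", "AG/TT", "AG/AG", "AG/TT"))
  w <- capture_warnings(des <- build_design(dat$records, NULL, dat$A))
  expect_true(all(grepl("single observed level", w)))
  expect_identical(ncol(des$X), 2L)            # intercept + genotype contrast
  expect_identical(length(des$y), 8L)
  expect_identical(nlevels(des$bird), 4L)
  expect_true(all(c("sex", "breeder") %in% des$dropped))

  bad <- dat$records; bad$weather_end[1] <- "hail"
  expect_error(suppressWarnings(build_design(bad, NULL, dat$A)), "hail")

  g <- data.frame(pigeon_id = dat$ids[-1], genotype = "AG/AG")
  expect_error(suppressWarnings(build_design(dat$records, g, dat$A)),
               "genotype missing")

  small_A <- dat$A[1:3, 1:3]
  expect_error(suppressWarnings(build_design(dat$records, NULL, small_A)),
               "missing from the relationship matrix")
})

test_that("with all variances fixed at zero the fit reduces to least squares", {
  set.seed(23)
  dat <- balanced_records(30, 4, bird_effect_sd = 2, resid_sd = 3, seed = 23)
  des <- suppressWarnings(build_design(dat$records, NULL, dat$A))
  fit <- fit_reml(des, fix = list(sigma2_i = 0, sigma2_a = 0))
  ols <- lm.fit(des$X, des$y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-8)
  expect_equal(fit$sigma2[["e"]],
               sum(ols$residuals^2) / (length(des$y) - ncol(des$X)),
               tolerance = 1e-8)
})

test_that("balanced one-way REML equals the closed-form ANOVA estimators", {
  set.seed(77)
  nb <- 20L; m <- 5L
  dat <- balanced_records(nb, m, bird_effect_sd = 3, resid_sd = 2, seed = 77,
                          genotype = rep("AG/AG", nb))
  des <- suppressWarnings(build_design(dat$records, NULL, dat$A,
                                       fixed = character(0)))
  fit <- fit_reml(des, fix = list(sigma2_a = 0))
  av <- anova(lm(ap ~ pigeon_id, dat$records))
  ms_between <- av$`Mean Sq`[1]; ms_within <- av$`Mean Sq`[2]
  expect_equal(fit$sigma2[["e"]], ms_within, tolerance = 1e-4)
  expect_equal(fit$sigma2[["i"]], (ms_between - ms_within) / m,
               tolerance = 1e-4)
})

test_that("identity-A fits match lme4's one-random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(99)
  for (k in 1:10) {
    nb <- sample(20:40, 1); m <- sample(3:6, 1)
    dat <- balanced_records(nb, m, bird_effect_sd = runif(1, 0.5, 3),
                            resid_sd = runif(1, 1, 4))
    dat$records$sex <- sample(c("male", "female"), nb * m, replace = TRUE)
    des <- suppressWarnings(build_design(dat$records, NULL, dat$A))
    fit <- fit_reml(des, fix = list(sigma2_a = 0))
    rec <- dat$records
    rec$sex <- factor(rec$sex, levels = c("male", "female"))
    rec$genotype <- factor(rec$genotype, levels = genotype_levels())
    lmod <- lme4::lmer(ap ~ genotype + sex + (1 | pigeon_id), data = rec,
                       REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lmod))
    expect_equal(fit$sigma2[["i"]], vc$vcov[1], tolerance = 1e-4)
    expect_equal(fit$sigma2[["e"]], vc$vcov[2], tolerance = 1e-4)
    expect_equal(unname(fit$beta), unname(lme4::fixef(lmod)),
                 tolerance = 1e-4)
    expect_equal(-2 * fit$loglik_reml, lme4::REMLcrit(lmod),
                 tolerance = 1e-6)
  }
})

test_that("record order does not change the fit", {
  set.seed(55)
  cfg <- sim_config(n_founders = 16, n_birds_phenotyped = 30, n_races = 6,
                    allele_freq_alt = 0.3, seed = 55)
  st <- simulate_study(cfg)
  des1 <- suppressWarnings(build_design(st$records, st$genotypes, st$A,
                                        response = "latent_ap",
                                        on_singular = "drop"))
  fit1 <- fit_reml(des1)
  shuf <- sample(nrow(st$records))
  des2 <- suppressWarnings(build_design(st$records[shuf, ], st$genotypes,
                                        st$A, response = "latent_ap",
                                        on_singular = "drop"))
  fit2 <- fit_reml(des2)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-4)
  expect_equal(fit1$beta[sort(names(fit1$beta))],
               fit2$beta[sort(names(fit2$beta))], tolerance = 1e-5)
  expect_equal(fit1$loglik_reml, fit2$loglik_reml, tolerance = 1e-8)
})

test_that("the optimum dominates the default starts with a small gradient", {
  set.seed(12)
  cfg <- sim_config(n_founders = 16, n_birds_phenotyped = 40, n_races = 6,
                    allele_freq_alt = 0.3, seed = 12)
  st <- simulate_study(cfg)
  des <- suppressWarnings(build_design(st$records, st$genotypes, st$A,
                                       response = "latent_ap",
                                       on_singular = "drop"))
  fit <- fit_reml(des)
  expect_true(fit$converged)
  suf <- pigeonrace:::.design_sufficient(des)
  m2ll <- function(li, la) pigeonrace:::.reml_eval(li, la, suf, des$A)$value
  opt <- -2 * fit$loglik_reml
  expect_lte(opt, m2ll(0.5, 0.5) + 1e-6)
  expect_lte(opt, m2ll(0.05, 0.05) + 1e-6)
  # finite-difference gradient on the log-ratio scale is ~0 at the optimum
  lam <- fit$sigma2[c("i", "a")] / fit$sigma2[["e"]]
  if (all(lam > 1e-6)) {
    h <- 1e-4
    g1 <- (m2ll(lam[1] * exp(h), lam[2]) - m2ll(lam[1] * exp(-h), lam[2])) / (2 * h)
    g2 <- (m2ll(lam[1], lam[2] * exp(h)) - m2ll(lam[1], lam[2] * exp(-h))) / (2 * h)
    expect_lt(max(abs(c(g1, g2))), 0.05)
  }
})

test_that("genotype contrasts: self-contrast is null, pairs are reported", {
  set.seed(65)
  dat <- balanced_records(45, 4, bird_effect_sd = 1, resid_sd = 2, seed = 65)
  des <- suppressWarnings(build_design(dat$records, NULL, dat$A))
  fit <- fit_reml(des, fix = list(sigma2_a = 0))
  ct <- genotype_contrasts(fit)
  expect_identical(nrow(ct), 3L)
  expect_true(all(ct$se > 0))
  expect_equal(ct$p_value, 2 * pnorm(-abs(ct$z)))
  # a level contrasted with itself: zero estimate, p = 1
  L <- fit$lsmeans$L
  l <- L[1, ] - L[1, ]
  expect_equal(sum(l * fit$beta), 0)
  expect_error(genotype_contrasts(fit, alpha = 1.5), "alpha")
  no_gt <- fit_reml(suppressWarnings(
    build_design(dat$records, NULL, dat$A, fixed = "sex")),
    fix = list(sigma2_a = 0))
  expect_error(genotype_contrasts(no_gt), "genotype")
})

test_that("raw genotype summaries compute group means, SEs and counts", {
  rec <- data.frame(pigeon_id = c("a", "a", "b"), race_id = c("r1", "r2", "r1"),
                    ap = c(40, 60, 10), category = factor(c("short", "long", "short"),
                                                          levels = c("short", "long")))
  g <- data.frame(pigeon_id = c("a", "b"), genotype = c("AG/TT", "AG/AG"))
  s <- summarize_by_genotype(rec, g)
  row <- s[s$genotype == "AG/TT" & s$scope == "all", ]
  expect_equal(row$mean_ap, 50)
  expect_equal(row$se, 10)
  expect_identical(row$n_records, 2L)
  # empty groups are absent, not zero rows
  expect_false(any(s$genotype == "TT/TT"))
  expect_false(any(s$genotype == "AG/TT" & s$scope == "long" & s$n_records == 0))
  g2 <- data.frame(pigeon_id = "a", genotype = "AG/TT")
  expect_warning(s2 <- summarize_by_genotype(rec, g2), "without a genotype")
  expect_true(all(s2$genotype == "AG/TT"))
})
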