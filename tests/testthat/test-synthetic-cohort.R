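test_that("constructors validate their invariants", {
  expect_error(ancestry_panel("one"), "at least 2")
  expect_error(ancestry_panel(c("A", "A")), "unique")
  expect_error(group_profile("g", c(0.6, 0.5), 10), "sum to 1")
  expect_error(group_profile("g", c(1.2, -0.2), 10), "0, 1")
  expect_error(causal_spec(1, c(0.5, 1.5)), "0, 1")
  expect_error(variance_spec(kinship = -1), "non-negative")
})

test_that("degenerate admixture proportions give a single-ancestry cohort", {
  la <- simulate_local_ancestry(
    ancestry_panel(), list(group_profile("pure", c(1, 0, 0), 30)),
    n_intervals = 15, seed = 3)
  expect_true(all(la$counts$European == 2))
  expect_true(all(la$counts$African == 0))
  expect_true(all(la$counts$Amerindian == 0))
})

test_that("ancestry counts sum to two and coordinates are half-open", {
  la <- tiny_cohort(seed = 5)$la
  total <- Reduce(`+`, la$counts)
  expect_true(all(total == 2))
  expect_equal(la$intervals$start[-1], la$intervals$end[-la$n_intervals])
  expect_true(all(la$intervals$end > la$intervals$start))
})

test_that("switch-point counts follow the Poisson tract process", {
  pan <- two_anc_panel()
  la <- simulate_local_ancestry(
    pan, list(group_profile("G", c(0.5, 0.5), 5000)),
    chrom_length = 1, generations = 8, n_intervals = 10, seed = 11)
  # 10,000 haplotypes; mean switch count has expectation 8 (rate x length)
  mc_se <- sd(la$n_switch) / sqrt(length(la$n_switch))
  expect_lt(abs(mean(la$n_switch) - 8), 3 * mc_se)
})

test_that("genome-wide ancestry fractions match the group profile", {
  la <- simulate_local_ancestry(
    ancestry_panel(), list(group_profile("G", c(0.45, 0.08, 0.47), 2000)),
    n_intervals = 50, seed = 13)
  frac1 <- rowMeans(la$counts$European) / 2
  se <- sd(frac1) / sqrt(length(frac1))
  expect_lt(abs(mean(frac1) - 0.45), 3 * se)
  frac3 <- rowMeans(la$counts$Amerindian) / 2
  expect_lt(abs(mean(frac3) - 0.47), 3 * sd(frac3) / sqrt(length(frac3)))
})

test_that("identical seeds give bit-identical cohorts", {
  a <- tiny_cohort(seed = 99, variants = list(causal_spec(5e7, c(0.3, 0.5, 0.8))))
  b <- tiny_cohort(seed = 99, variants = list(causal_spec(5e7, c(0.3, 0.5, 0.8))))
  expect_identical(a$la$hap_ancestry, b$la$hap_ancestry)
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$pheno, b$pheno)
})

test_that("fixed allele frequencies give deterministic dosages", {
  la <- tiny_cohort(seed = 2)$la
  gm0 <- simulate_genotypes(la, list(causal_spec(1e7, c(0, 0, 0))), seed = 1)
  expect_true(all(gm0$dosage == 0))
  gm2 <- simulate_genotypes(la, list(causal_spec(1e7, c(1, 1, 1))), seed = 1)
  expect_true(all(gm2$dosage == 2))
  expect_error(simulate_genotypes(la, list(causal_spec(9e99, c(0, 0, 0)))),
               "outside")
})

test_that("dosage regressed on ancestry count recovers the frequency difference", {
  pan <- two_anc_panel()
  la <- simulate_local_ancestry(
    pan, list(group_profile("G", c(0.5, 0.5), 4000)),
    n_intervals = 20, seed = 17)
  gm <- simulate_genotypes(la, list(causal_spec(2.5e7, c(0.5, 0.1))),
                           seed = 18)
  iv <- gm$variants$interval[1]
  fit <- lm(gm$dosage[, 1] ~ la$counts$European[, iv])
  est <- coef(summary(fit))[2, ]
  # per-chromosome enumeration gives slope p1 - p2 = 0.4
  expect_lt(abs(est["Estimate"] - 0.4), 3 * est["Std. Error"])
})

test_that("genotype-ancestry joint law matches the product law", {
  pan <- two_anc_panel()
  la <- simulate_local_ancestry(
    pan, list(group_profile("G", c(0.5, 0.5), 3000)),
    n_intervals = 10, seed = 23)
  gm <- simulate_genotypes(la, list(causal_spec(5e7, c(0.7, 0.2))),
                           seed = 24)
  iv <- gm$variants$interval[1]
  anc <- la$hap_ancestry[, iv]
  allele <- gm$hap_alleles[, 1]
  obs <- table(anc, allele)
  q <- c(0.5, 0.5)
  p <- c(0.7, 0.2)
  expected <- rbind(q[1] * c(1 - p[1], p[1]), q[2] * c(1 - p[2], p[2]))
  gof <- chisq.test(as.vector(obs), p = as.vector(expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero variances and zero effects give a constant latent SBP", {
  la <- tiny_cohort(seed = 31)$la
  ph <- simulate_phenotypes(
    NULL, la, vs = variance_spec(0, 0, 0, 0),
    covariate_effects = list(sbp = c(age = 0, sexM = 0),
                             dbp = c(age = 0, sexM = 0)),
    med_model = list(threshold = 1e6, scale = 1),
    inconsistency_rate = 0, missing_rate = 0, seed = 32)
  expect_equal(ph$sbp_mean, rep(120, nrow(ph)))
  expect_equal(ph$dbp_mean, rep(75, nrow(ph)))
})

test_that("between-household variance of household means matches the ANOVA decomposition", {
  la <- simulate_local_ancestry(
    ancestry_panel(), list(group_profile("G", c(0.4, 0.2, 0.4), 4000)),
    n_intervals = 10, seed = 41)
  ph <- simulate_phenotypes(
    NULL, la, vs = variance_spec(0, 9, 0, 4),
    covariate_effects = list(sbp = c(age = 0, sexM = 0),
                             dbp = c(age = 0, sexM = 0)),
    med_model = list(threshold = 1e6, scale = 1),
    inconsistency_rate = 0, missing_rate = 0,
    household_size = 2, seed = 42)
  hm <- tapply(ph$sbp_mean, ph$household, mean)
  # var of household means = sigma2_hh + sigma2_resid / 2 = 11
  v <- var(hm)
  H <- length(hm)
  se_v <- v * sqrt(2 / (H - 1))
  expect_lt(abs(v - 11), 3 * se_v)
})

test_that("treated individuals' measured pressures sit below the latent scale", {
  co <- tiny_cohort(seed = 51, n = 400)
  truth <- attr(co$pheno, "truth")
  on <- !is.na(co$pheno$on_meds) & co$pheno$on_meds
  expect_equal(co$pheno$sbp_mean[on], truth$latent_sbp[on] - 10)
  expect_equal(co$pheno$dbp_mean[on], truth$latent_dbp[on] - 5)
})
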