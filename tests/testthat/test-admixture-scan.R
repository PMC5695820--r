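# shared null cohort for several scan tests (no causal variant)
scan_fixture <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      co <<- simulate_cohort(groups = default_groups(400, 400),
                             vs = variance_spec(10, 8, 2, 60),
                             n_intervals = 60, seed = 211)
    }
    co
  }
})

fit_sbp_null <- function(co, tt) {
  X <- model.matrix(~ age + sex + center + weight + PC1 + PC2 + PC3 +
                      PC4 + PC5, tt$traits)
  kin <- co$kinship[match(tt$traits$id, co$la$ids),
                    match(tt$traits$id, co$la$ids)]
  fit_null_model(tt$traits$SBP, X, kin, tt$traits$household,
                 tt$traits$block,
                 options = null_model_options(compute_se = FALSE))
}

test_that("ancestry frequency uses a two-chromosomes-per-individual denominator", {
  co <- scan_fixture()
  f <- ancestry_freq(co$la, "Amerindian")
  expect_equal(attr(f, "n_chromosomes"), 2 * co$la$n)
  expect_equal(as.numeric(f),
               colSums(co$la$counts$Amerindian) / (2 * co$la$n))
  expect_equal(n_chromosomes(12116), 24232)
})

test_that("a scan emits one row per interval with sensible frequencies", {
  co <- scan_fixture()
  tt <- prepare_traits(co$pheno)
  null <- fit_sbp_null(co, tt)
  la_r <- subset_individuals(co$la, tt$traits$id)
  sc <- scan_ancestry(la_r, null, "Amerindian", trait = "SBP")
  expect_equal(nrow(sc), la_r$n_intervals)
  expect_true(all(sc$ancestry_freq >= 0 & sc$ancestry_freq <= 1))
  expect_true(all(is.na(sc$p) | (sc$p > 0 & sc$p <= 1)))
  expect_equal(sc$stat[!is.na(sc$stat)],
               (sc$effect[!is.na(sc$stat)] / sc$se[!is.na(sc$stat)])^2)
})

test_that("monomorphic intervals are flagged, not dropped", {
  set.seed(31)
  hap <- matrix(sample(1:2, 40 * 10, TRUE), 40, 10)
  hap[, 3] <- 1L   # every chromosome ancestry 1 at interval 3
  la <- manual_la(hap, c("A", "B"))
  y <- rnorm(20)
  fit <- fit_null_model(y, cbind(1, rnorm(20) * 0 + seq_len(20)),
                        options = null_model_options(compute_se = FALSE))
  sc <- scan_ancestry(la, fit, "B")
  expect_equal(nrow(sc), 10)
  expect_true(is.na(sc$p[3]))
  expect_equal(sc$note[3], "monomorphic")
  expect_equal(sc$ancestry_freq[3], 0)
})

test_that("the planted frequency-differentiated variant is recovered at the causal interval", {
  pan <- two_anc_panel()
  co <- simulate_cohort(
    panel = pan, groups = list(group_profile("G", c(0.5, 0.5), 2500)),
    variants = list(causal_spec(1e8, c(0.5, 0.1), c(1, 1), traits = "sbp")),
    vs = variance_spec(0, 0, 0, 1), n_intervals = 40, seed = 223)
  tt <- prepare_traits(co$pheno)
  null <- fit_sbp_null(co, tt)
  la_r <- subset_individuals(co$la, tt$traits$id)
  sc <- scan_ancestry(la_r, null, "European", trait = "SBP")
  iv <- which(co$la$intervals$start <= 1e8 & co$la$intervals$end > 1e8)
  # enumeration closed form: slope = beta * (p1 - p2) = 0.4, positive for
  # the ancestry carrying the higher frequency
  expect_lt(abs(sc$effect[iv] - 0.4), 3 * sc$se[iv])
  expect_gt(sc$effect[iv], 0)
  # testing the other ancestry flips the sign
  sc2 <- scan_ancestry(la_r, null, "Amerindian", trait = "SBP")
  expect_lt(abs(sc2$effect[iv] + 0.4), 3 * sc2$se[iv])
})

test_that("null scans rarely cross the genome-wide admixture threshold", {
  co <- scan_fixture()
  tt <- prepare_traits(co$pheno)
  null <- fit_sbp_null(co, tt)
  la_r <- subset_individuals(co$la, tt$traits$id)
  cnt <- la_r$counts$Amerindian
  set.seed(41)
  n_rep <- 25
  exceed <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    perm <- sample.int(la_r$n)
    la_p <- la_r
    la_p$counts <- lapply(la_r$counts, function(m) m[perm, , drop = FALSE])
    sc <- scan_ancestry(la_p, null, "Amerindian")
    exceed[r] <- min(sc$p, na.rm = TRUE) < genomewide_threshold()
  }
  expect_gte(mean(!exceed), 0.94)
})

test_that("the joint 2-df test behaves like two focal columns", {
  co <- scan_fixture()
  tt <- prepare_traits(co$pheno)
  null <- fit_sbp_null(co, tt)
  la_r <- subset_individuals(co$la, tt$traits$id)
  sj <- scan_joint(la_r, null, c("Amerindian", "African"), trait = "SBP")
  expect_equal(nrow(sj), la_r$n_intervals)
  expect_true(all(sj$df == 2))
  j <- which(!is.na(sj$p))[1]
  direct <- test_fixed_effect(null, cbind(la_r$counts$Amerindian[, j],
                                          la_r$counts$African[, j]))
  expect_equal(sj$stat[j], direct$stat, tolerance = 1e-10)
  # all three count columns sum to 2: collinear with the intercept
  expect_error(test_fixed_effect(null, cbind(
    a = la_r$counts$European[, j], b = la_r$counts$African[, j],
    c = la_r$counts$Amerindian[, j])), "collinear")
})

test_that("when only one ancestry is causal its 1-df scan beats the joint test", {
  pan <- ancestry_panel(c("E", "Af", "Am"))
  co <- simulate_cohort(
    panel = pan,
    groups = list(group_profile("G", c(0.4, 0.2, 0.4), 1500)),
    variants = list(causal_spec(1e8, c(0.1, 0.1, 0.9), c(2, 2, 2),
                                traits = "sbp")),
    vs = variance_spec(0, 0, 0, 4), n_intervals = 30, seed = 307)
  tt <- prepare_traits(co$pheno)
  null <- fit_sbp_null(co, tt)
  la_r <- subset_individuals(co$la, tt$traits$id)
  iv <- which(co$la$intervals$start <= 1e8 & co$la$intervals$end > 1e8)
  s1 <- scan_ancestry(la_r, null, "Am", trait = "SBP")
  sj <- scan_joint(la_r, null, c("Am", "Af"), trait = "SBP")
  expect_lt(s1$p[iv], sj$p[iv])
})

test_that("significant intervals merge into contiguous, disjoint regions", {
  p <- rep(0.5, 12)
  expect_equal(nrow(significant_regions(manual_scan(p))), 0)
  p[c(4, 5, 6, 10)] <- c(1e-6, 1e-8, 2e-6, 1e-7)
  reg <- significant_regions(manual_scan(p), threshold = 5.68e-5)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$n_lai, c(3L, 1L))
  expect_equal(reg$lead_interval, c(5L, 10L))
  expect_equal(reg$start, c(3e6, 9e6))
  expect_equal(reg$end, c(6e6, 10e6))
  # default threshold is the genome-wide admixture mapping level
  expect_equal(eval(formals(significant_regions)$threshold), 5.68e-5)
  # ties go to the leftmost interval
  p2 <- rep(0.5, 6); p2[2:3] <- 1e-6
  expect_equal(significant_regions(manual_scan(p2))$lead_interval, 2L)
})

test_that("simpleM counts independent traits from the eigenvalue spectrum", {
  expect_equal(effective_num_tests(diag(4)), 4L)
  expect_equal(effective_num_tests(matrix(1, 3, 3)), 1L)
  r <- 0.8
  C <- matrix(r, 4, 4); diag(C) <- 1
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  oracle <- which(cumsum(ev) / sum(ev) >= 0.995)[1]
  expect_equal(effective_num_tests(C), as.integer(oracle))
  expect_error(effective_num_tests(matrix(c(1, 2, 2, 1), 2)), "positive")
  expect_error(effective_num_tests(matrix(c(1, 0, 0.2, 1), 2)), "symmetric")
})
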