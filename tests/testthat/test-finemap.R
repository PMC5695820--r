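# genotype_matrix built directly from a dosage matrix
manual_gm <- function(dosage, positions = NULL) {
  m <- ncol(dosage)
  if (is.null(positions)) positions <- seq_len(m) * 1e5
  ids <- sprintf("i%03d", seq_len(nrow(dosage)))
  vid <- colnames(dosage) %||% sprintf("v%02d", seq_len(m))
  colnames(dosage) <- vid
  rownames(dosage) <- ids
  structure(list(
    dosage = dosage,
    variants = data.frame(id = vid, chrom = "1", position = positions,
                          a1 = "A", a2 = "G", type = "g", info = 1,
                          interval = NA_integer_, stringsAsFactors = FALSE),
    hap_alleles = NULL, specs = NULL, ids = ids),
    class = "genotype_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group EAFs are mean dosage over two chromosomes", {
  dos <- cbind(v1 = c(2, 2, 2, 0, 1, 1), v2 = c(0, 1, 2, 1, 1, 1))
  gm <- manual_gm(dos)
  g <- c("hi", "hi", "hi", "lo", "lo", "lo")
  tab <- group_eaf(gm, g)
  expect_equal(tab$eaf[tab$group == "hi" & tab$variant == "v1"], 1)
  expect_equal(tab$eaf[tab$group == "lo" & tab$variant == "v1"], 1 / 3)
  d <- eaf_difference(tab, "hi", "lo")
  expect_equal(d$delta[d$variant == "v1"], 2 / 3)
  # frequencies like the strongly differentiated variant: 0.57 vs 0.35
  tab2 <- data.frame(variant = "rs_x", group = c("hi", "lo"),
                     eaf = c(0.57, 0.35))
  expect_equal(eaf_difference(tab2, "hi", "lo")$delta, 0.22)
  # allele flip changes the sign, not the magnitude
  tab3 <- tab2; tab3$eaf <- 1 - tab3$eaf
  expect_equal(eaf_difference(tab3, "hi", "lo")$delta, -0.22)
})

test_that("ladder admits low-p variants regardless of EAF difference", {
  assoc <- data.frame(variant = c("a", "b"),
                      p_overall = c(5e-7, 0.5))
  eafs <- data.frame(variant = c("a", "b"), eaf_high = c(0.5, 0.7),
                     eaf_low = c(0.5, 0.2), delta = c(0, 0.5))
  cand <- candidate_ladder(assoc, eafs)
  expect_equal(cand$variant, "a")
  expect_equal(cand$rung_p, 1e-6)
  expect_true(is.na(cand$rung_delta))
})

test_that("lenient rungs require the EAF-difference filter", {
  assoc <- data.frame(variant = c("big", "small"),
                      p_overall = c(2e-3, 2e-3))
  eafs <- data.frame(variant = c("big", "small"),
                     eaf_high = c(0.52, 0.35), eaf_low = c(0.30, 0.30),
                     delta = c(0.22, 0.05))
  cand <- candidate_ladder(assoc, eafs)
  expect_equal(cand$variant, "big")
  expect_equal(cand$rung_delta, 0.2)
  # accumulate = TRUE keeps walking and eventually admits both
  cand2 <- candidate_ladder(assoc, eafs, accumulate = TRUE)
  expect_setequal(cand2$variant, c("big", "small"))
  expect_equal(cand2$rung_delta[cand2$variant == "small"], 0.05)
})

test_that("a region with no qualifying variant returns an empty list", {
  assoc <- data.frame(variant = c("a", "b"),
                      p_overall = c(0.02, 0.3))
  eafs <- data.frame(variant = c("a", "b"), eaf_high = c(0.5, 0.5),
                     eaf_low = c(0.48, 0.47), delta = c(0.02, 0.03))
  expect_warning(cand <- candidate_ladder(assoc, eafs), "no candidate")
  expect_equal(nrow(cand), 0)
  expect_warning(candidate_ladder(assoc[0, ], eafs), "no variants")
})

test_that("any of the three analysis strata can admit a variant", {
  assoc <- data.frame(variant = "m", p_overall = 0.2,
                      p_mainland = 3e-5, p_caribbean = 0.4)
  eafs <- data.frame(variant = "m", eaf_high = 0.5, eaf_low = 0.5,
                     delta = 0)
  cand <- candidate_ladder(assoc, eafs)
  expect_equal(cand$analysis, "p_mainland")
  expect_equal(cand$p_min, 3e-5)
})

test_that("tightening a rung never adds candidates (ladder monotonicity)", {
  set.seed(61)
  assoc <- data.frame(variant = sprintf("v%02d", 1:20),
                      p_overall = 10^runif(20, -7, -1))
  eafs <- data.frame(variant = assoc$variant, eaf_high = runif(20),
                     eaf_low = runif(20))
  eafs$delta <- eafs$eaf_high - eafs$eaf_low
  base <- suppressWarnings(candidate_ladder(assoc, eafs, accumulate = TRUE))
  tight <- suppressWarnings(candidate_ladder(
    assoc, eafs, spec = ladder_spec(eaf_deltas = c(0.3, 0.25, 0.2, 0.15)),
    accumulate = TRUE))
  expect_true(all(tight$variant %in% base$variant))
  tight2 <- suppressWarnings(candidate_ladder(
    assoc, eafs, spec = ladder_spec(p_rungs = c(1e-6, 1e-5, 1e-4, 1e-3),
                                    eaf_rungs = c(1e-3)),
    accumulate = TRUE))
  expect_true(all(tight2$variant %in% base$variant))
})

test_that("correlation pruning keeps the most significant variant per component", {
  set.seed(71)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  A <- base
  B <- ifelse(runif(n) < 0.85, base, rbinom(n, 2, 0.4))   # r(A,B) high
  C <- ifelse(runif(n) < 0.85, B, rbinom(n, 2, 0.4))      # r(B,C) high
  D <- rbinom(n, 2, 0.3)                                  # unlinked
  gm <- manual_gm(cbind(A = A, B = B, C = C, D = D))
  expect_gt(abs(cor(A, B)), 0.4)
  expect_gt(abs(cor(B, C)), 0.4)
  cand <- data.frame(variant = c("A", "B", "C", "D"),
                     p_min = c(1e-4, 1e-5, 1e-3, 1e-2))
  pruned <- prune_by_correlation(cand, gm, r_max = 0.4)
  # chain A-B-C is one component even if r(A,C) is below the threshold
  expect_equal(length(unique(pruned$component[1:3])), 1L)
  expect_equal(pruned$variant[pruned$lead], c("B", "D"))
  # input order does not change the selected leads
  shuf <- c(3, 1, 4, 2)
  pruned2 <- prune_by_correlation(cand[shuf, ], gm, r_max = 0.4)
  expect_setequal(pruned2$variant[pruned2$lead],
                  pruned$variant[pruned$lead])
})

test_that("perfectly correlated pair keeps the smaller p; uncorrelated pair keeps both", {
  set.seed(73)
  x <- rbinom(200, 2, 0.5)
  gm <- manual_gm(cbind(a = x, b = x, c = rbinom(200, 2, 0.5)))
  cand <- data.frame(variant = c("a", "b", "c"),
                     p_min = c(1e-4, 1e-5, 1e-3))
  pruned <- prune_by_correlation(cand, gm)
  expect_setequal(pruned$variant[pruned$lead], c("b", "c"))
  # zero-variance dosage is treated as unlinked
  gm0 <- manual_gm(cbind(a = x, z = rep(0L, 200)))
  cand0 <- data.frame(variant = c("a", "z"), p_min = c(1e-4, 1e-3))
  pruned0 <- prune_by_correlation(cand0, gm0)
  expect_true(all(pruned0$lead))
})

test_that("conditioning on an all-zero dosage leaves the scan unchanged", {
  co <- tiny_cohort(seed = 81, n = 300)
  tt <- prepare_traits(co$pheno)
  X <- model.matrix(~ age + sex + center + weight + PC1 + PC2 + PC3 +
                      PC4 + PC5, tt$traits)
  null <- fit_null_model(tt$traits$SBP, X, household = tt$traits$household,
                         block = tt$traits$block,
                         options = null_model_options(compute_se = FALSE))
  la_r <- subset_individuals(co$la, tt$traits$id)
  base <- scan_ancestry(la_r, null, "Amerindian", trait = "SBP")
  expect_warning(
    cond <- conditional_scan(la_r, null,
                             matrix(0, nrow(tt$traits), 1,
                                    dimnames = list(NULL, "zero")),
                             "Amerindian", trait = "SBP"),
    "collinear")
  expect_equal(cond$dropped, "zero")
  expect_equal(cond$scan$p, base$p, tolerance = 1e-12)
  att <- attenuation(base, cond$scan)
  expect_equal(att$p_primary, att$p_conditional, tolerance = 1e-12)
})

test_that("explained-signal classification follows the two cutpoints", {
  expect_equal(classify_explained(2.29e-5, 0.003), "partial")
  expect_equal(classify_explained(4.67e-5, 0.002), "partial")
  expect_equal(classify_explained(1e-6, 0.5), "full")
  expect_equal(classify_explained(1e-6, 1e-6), "none")
  expect_equal(classify_explained(c(1e-6, 1e-6), c(0.02, 0.004)),
               c("full", "partial"))
  expect_error(classify_explained(1e-3, 0.5), "genome-wide")
})
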