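# Monte-Carlo draw of one dataset under the two-ancestry model; returns
# two-sided z-test rejections for both predictors
mc_reject <- function(m, n_rep, seed) {
  set.seed(seed)
  rej_adm <- rej_assoc <- logical(n_rep)
  zc <- qnorm(1 - m$alpha / 2)
  for (r in seq_len(n_rep)) {
    a1 <- rbinom(m$n, 1, m$q); a2 <- rbinom(m$n, 1, m$q)
    g1 <- rbinom(m$n, 1, ifelse(a1 == 1, m$p1, m$p2))
    g2 <- rbinom(m$n, 1, ifelse(a2 == 1, m$p1, m$p2))
    yv <- ifelse(a1 == 1, m$beta1, m$beta2) * g1 +
      ifelse(a2 == 1, m$beta1, m$beta2) * g2 +
      rnorm(m$n, 0, sqrt(m$sigma2))
    test1 <- function(x) {
      rr <- cor(yv, x)
      z <- rr * sqrt((m$n - 2) / (1 - rr^2))
      abs(z) > zc
    }
    rej_adm[r] <- test1(a1 + a2)
    rej_assoc[r] <- test1(g1 + g2)
  }
  c(adm = mean(rej_adm), assoc = mean(rej_assoc))
}

test_that("the admixture estimand equals the closed form over a parameter grid", {
  set.seed(5)
  for (i in 1:100) {
    m <- two_ancestry_model(runif(1, 0.05, 0.95), runif(1), runif(1),
                            runif(1, -2, 2), runif(1, -2, 2))
    expect_equal(admixture_effect(m), m$beta1 * m$p1 - m$beta2 * m$p2,
                 tolerance = 1e-12)
  }
})

test_that("estimand special cases behave as the theory says", {
  # no frequency or effect contrast: no admixture signal
  expect_equal(admixture_effect(two_ancestry_model(0.3, 0.4, 0.4, 1, 1)), 0)
  # shared effect: causal effect down-weighted by the frequency difference
  expect_equal(admixture_effect(two_ancestry_model(0.5, 0.5, 0.1, 1, 1)),
               0.4)
  # equal frequencies but ancestry-specific effect still yields signal
  expect_equal(admixture_effect(two_ancestry_model(0.5, 0.5, 0.5, 1, 0)),
               0.5)
  # swapping ancestries flips the sign
  m <- two_ancestry_model(0.3, 0.7, 0.2, 1.5, 0.5)
  m_swap <- two_ancestry_model(1 - 0.3, 0.2, 0.7, 0.5, 1.5)
  expect_equal(admixture_effect(m), -admixture_effect(m_swap),
               tolerance = 1e-12)
  # degenerate ancestry composition carries no information
  expect_true(is.na(admixture_effect(two_ancestry_model(1, 0.5, 0.1, 1, 1))))
  # association slope reduces to the per-allele effect at equal frequencies
  expect_equal(association_effect(two_ancestry_model(0.4, 0.3, 0.3, 1.2, 1.2)),
               1.2, tolerance = 1e-12)
})

test_that("a null configuration rejects at the nominal level", {
  m <- two_ancestry_model(0.5, 0.3, 0.3, 1, 1, sigma2 = 1, n = 500,
                          alpha = 0.05)
  pw <- power_compare(m)
  expect_equal(unname(pw["power_admixture"]), 0.05, tolerance = 1e-10)
})

test_that("analytic power matches Monte-Carlo rejection rates", {
  n_rep <- 1000
  grid <- list(
    two_ancestry_model(0.5, 0.6, 0.2, 0.25, 0.25, sigma2 = 1, n = 400),
    two_ancestry_model(0.3, 0.8, 0.3, 0.2, 0.2, sigma2 = 1, n = 600),
    two_ancestry_model(0.5, 0.5, 0.5, 0.3, 0, sigma2 = 1, n = 500))
  for (i in seq_along(grid)) {
    m <- grid[[i]]
    emp <- mc_reject(m, n_rep, seed = 400 + i)
    ana <- power_compare(m)
    se_adm <- sqrt(emp["adm"] * (1 - emp["adm"]) / n_rep)
    se_assoc <- sqrt(emp["assoc"] * (1 - emp["assoc"]) / n_rep)
    expect_lt(abs(ana["power_admixture"] - emp["adm"]),
              2 * se_adm + 0.01)
    expect_lt(abs(ana["power_association"] - emp["assoc"]),
              2 * se_assoc + 0.01)
  }
})

test_that("admixture beats association when the causal variant is untyped", {
  m <- two_ancestry_model(0.5, 0.9, 0.1, 0.5, 0.5, sigma2 = 1, n = 500)
  pw <- power_compare(m, causal_typed = FALSE)
  expect_equal(unname(pw["power_association"]), 0)
  expect_gt(pw["power_admixture"], pw["power_association"])
  # with the variant typed at these frequencies, association testing at
  # the same level is at least as powerful (it sees the allele directly)
  pw_t <- power_compare(m, causal_typed = TRUE)
  expect_gt(pw_t["power_association"], 0)
})

test_that("power is monotone in sample size and effect magnitude", {
  pows_n <- sapply(c(100, 400, 1600), function(n)
    power_compare(two_ancestry_model(0.5, 0.6, 0.2, 0.3, 0.3,
                                     n = n))["power_admixture"])
  expect_true(all(diff(pows_n) > 0))
  pows_b <- sapply(c(0.1, 0.3, 0.6), function(b)
    power_compare(two_ancestry_model(0.5, 0.6, 0.2, b, b,
                                     n = 400))["power_admixture"])
  expect_true(all(diff(pows_b) > 0))
})

test_that("the multiple-testing advantage is expressible through the levels", {
  m <- two_ancestry_model(0.5, 0.7, 0.2, 0.25, 0.25, sigma2 = 1, n = 2000)
  pw <- power_compare(m, alpha_admixture = 5.68e-5,
                      alpha_association = 5e-8)
  expect_gt(pw["power_admixture"], 0)
  # the coarser admixture threshold partially offsets its smaller slope
  pw_same <- power_compare(m, alpha_admixture = 5e-8,
                           alpha_association = 5e-8)
  expect_gt(pw["power_admixture"], pw_same["power_admixture"])
})

test_that("power_table sweeps a grid", {
  tab <- power_table(expand.grid(p1 = c(0.3, 0.9), p2 = 0.1),
                     q = 0.5, beta1 = 0.3, beta2 = 0.3, n = 500)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("power_admixture", "power_association") %in% names(tab)))
  expect_gt(tab$power_admixture[2], tab$power_admixture[1])
})
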