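#' Two-ancestry single-variant model
#'
#' The simplest setting for comparing admixture and association mapping:
#' each of an individual's two chromosomes is of ancestry 1 with
#' probability `q` (else ancestry 2), carries the effect allele with the
#' frequency of its ancestry (`p1` or `p2`), and contributes the
#' ancestry-specific per-allele effect (`beta1` or `beta2`) to the trait,
#' on top of residual variance `sigma2`.
#'
#' @param q Proportion of ancestry 1 chromosomes.
#' @param p1,p2 Effect-allele frequencies by ancestry.
#' @param beta1,beta2 Per-allele effects (trait units) by ancestry.
#' @param sigma2 Residual trait variance.
#' @param n Sample size for power computations.
#' @param alpha Test level.
#' @return An object of class `two_ancestry_model`.
#' @export
two_ancestry_model <- function(q, p1, p2, beta1, beta2, sigma2 = 1,
                               n = 1000, alpha = 0.05) {
  stopifnot(q >= 0, q <= 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            sigma2 > 0, n >= 1, alpha > 0, alpha < 1)
  structure(list(q = q, p1 = p1, p2 = p2, beta1 = beta1, beta2 = beta2,
                 sigma2 = sigma2, n = n, alpha = alpha),
            class = "two_ancestry_model")
}

## exact joint law of the per-chromosome (ancestry indicator, allele)
## pair and the moments of the two-chromosome summaries used by both the
## estimand and the power computation
.chrom_law <- function(m) {
  states <- expand.grid(anc = 1:2, allele = 0:1)
  pa <- ifelse(states$anc == 1, m$q, 1 - m$q)
  pf <- ifelse(states$anc == 1, m$p1, m$p2)
  prob <- pa * ifelse(states$allele == 1, pf, 1 - pf)
  beta <- ifelse(states$anc == 1, m$beta1, m$beta2)
  g <- beta * states$allele          # genetic contribution of the chromosome
  a <- as.numeric(states$anc == 1)   # ancestry-1 indicator
  d <- states$allele                 # allele count of the chromosome
  mom <- function(x) sum(prob * x)
  list(
    E_a = mom(a), V_a = mom(a^2) - mom(a)^2,
    E_d = mom(d), V_d = mom(d^2) - mom(d)^2,
    E_g = mom(g), V_g = mom(g^2) - mom(g)^2,
    C_ga = mom(g * a) - mom(g) * mom(a),
    C_gd = mom(g * d) - mom(g) * mom(d))
}

#' Admixture-mapping estimand
#'
#' The population regression slope of the trait on the ancestry-1
#' chromosome count, computed by exact enumeration of the per-chromosome
#' joint law of (ancestry, allele) under independent chromosomes. It
#' equals the causal effect down-weighted by the ancestral allele
#' frequency difference, `beta1 * p1 - beta2 * p2` (reducing to
#' `beta * (p1 - p2)` for a shared effect size): admixture signal arises
#' from frequency differentiation, from effect-size differences between
#' ancestries, or both.
#'
#' @param m A [two_ancestry_model()].
#' @return Slope in trait units per ancestry-1 chromosome (`NA` when `q`
#'   is 0 or 1, where the ancestry count does not vary).
#' @examples
#' admixture_effect(two_ancestry_model(0.5, 0.5, 0.1, 1, 1))  # 0.4
#' @export
admixture_effect <- function(m) {
  stopifnot(inherits(m, "two_ancestry_model"))
  law <- .chrom_law(m)
  if (law$V_a <= 0) return(NA_real_)
  ## chromosomes are iid, so two-chromosome covariances/variances double
  law$C_ga / law$V_a
}

#' Association-mapping estimand
#'
#' The population regression slope of the trait on the causal variant's
#' dosage, from the same enumeration as [admixture_effect()].
#'
#' @param m A [two_ancestry_model()].
#' @return Slope in trait units per effect allele.
#' @export
association_effect <- function(m) {
  stopifnot(inherits(m, "two_ancestry_model"))
  law <- .chrom_law(m)
  if (law$V_d <= 0) return(NA_real_)
  law$C_gd / law$V_d
}

#' Analytic power of admixture versus association testing
#'
#' For each test, the noncentrality is `n * slope^2 * Var(predictor) /
#' Var(trait | predictor)` with all moments from the exact enumeration of
#' the two-ancestry model; power is the two-sided normal rejection
#' probability at the respective level. Admixture mapping is tested at a
#' coarser (genome-wide admixture) level than single-variant association,
#' reflecting its smaller multiple-testing burden; both levels are
#' exposed. When the causal variant is untyped (and no proxy is modeled),
#' association mapping cannot test it and its power is zero.
#'
#' @param m A [two_ancestry_model()].
#' @param causal_typed Is the causal variant available to association
#'   testing?
#' @param alpha_admixture,alpha_association Test levels (default the
#'   model's `alpha` for both).
#' @return Named numeric vector `power_admixture`, `power_association`.
#' @export
power_compare <- function(m, causal_typed = TRUE,
                          alpha_admixture = m$alpha,
                          alpha_association = m$alpha) {
  stopifnot(inherits(m, "two_ancestry_model"))
  law <- .chrom_law(m)
  var_y <- 2 * law$V_g + m$sigma2
  pw <- function(slope, v_pred, alpha) {
    if (!is.finite(slope) || v_pred <= 0) return(alpha)
    resid <- var_y - slope^2 * v_pred
    ncp <- m$n * slope^2 * v_pred / resid
    z <- stats::qnorm(1 - alpha / 2)
    s <- sqrt(ncp)
    (1 - stats::pnorm(z - s)) + stats::pnorm(-z - s)
  }
  p_adm <- pw(if (law$V_a > 0) law$C_ga / law$V_a else NA_real_,
              2 * law$V_a, alpha_admixture)
  p_assoc <- if (!causal_typed) 0
  else pw(if (law$V_d > 0) law$C_gd / law$V_d else NA_real_,
          2 * law$V_d, alpha_association)
  c(power_admixture = p_adm, power_association = p_assoc)
}

#' Tabulate power over a parameter grid
#'
#' @param grid Data frame with columns among the [two_ancestry_model()]
#'   arguments; missing columns take the given defaults.
#' @param causal_typed Passed to [power_compare()].
#' @param ... Defaults for model parameters absent from `grid`.
#' @return `grid` with added `power_admixture` and `power_association`.
#' @export
power_table <- function(grid, causal_typed = TRUE, ...) {
  defaults <- list(...)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    args <- utils::modifyList(defaults, as.list(grid[i, , drop = FALSE]))
    pc <- power_compare(do.call(two_ancestry_model, args),
                        causal_typed = causal_typed)
    cbind(grid[i, , drop = FALSE], t(pc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
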