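#' One-sided replication p-value
#'
#' Replication testing with the side fixed by the direction of association
#' in the discovery cohort: for a positive discovery effect the upper
#' normal tail of the replication z-statistic, otherwise the lower tail.
#' The two directional p-values of a statistic are exact complements.
#'
#' @param rep_effect,rep_se Replication effect estimate and its standard
#'   error (`rep_se > 0`).
#' @param discovery_sign Sign of the discovery effect (any positive number
#'   means positive direction; the discovery effect itself can be passed).
#' @return One-sided p-value(s) in (0, 1).
#' @examples
#' one_sided_p(0, 1, +1)  # 0.5
#' @export
one_sided_p <- function(rep_effect, rep_se, discovery_sign) {
  if (any(rep_se <= 0)) stop("rep_se must be positive")
  if (any(discovery_sign == 0)) stop("discovery direction must be nonzero")
  z <- rep_effect / rep_se
  k <- max(length(z), length(discovery_sign))
  z <- rep_len(z, k)
  pos <- rep_len(discovery_sign > 0, k)
  out <- stats::pnorm(z, lower.tail = TRUE)
  out[pos] <- stats::pnorm(z[pos], lower.tail = FALSE)
  out
}

#' Bonferroni threshold for a replication family
#'
#' @param m_tests Number of tests in the family (>= 1).
#' @param family_alpha Family-wise level.
#' @return `family_alpha / m_tests`.
#' @examples
#' bonferroni_threshold(6)  # 0.008333...
#' @export
bonferroni_threshold <- function(m_tests, family_alpha = 0.05) {
  m_tests <- as.integer(m_tests)
  if (is.na(m_tests) || m_tests < 1L) stop("m_tests must be >= 1")
  family_alpha / m_tests
}

#' Assemble a replication record table
#'
#' One row per variant x trait: discovery direction, replication summary
#' statistics, the direction-fixed one-sided p-value, and the significance
#' flag at the Bonferroni threshold over the family of tests.
#'
#' @param records Data frame with columns `variant`, `trait`,
#'   `discovery_effect`, `rep_effect`, `rep_se` (and optionally
#'   `rep_freq`).
#' @param family_alpha Family-wise level.
#' @param m_tests Family size (default: number of rows).
#' @return `records` with added `discovery_sign`, `p_one_sided`,
#'   `threshold`, `significant`.
#' @export
replication_test <- function(records, family_alpha = 0.05,
                             m_tests = nrow(records)) {
  needed <- c("variant", "trait", "discovery_effect", "rep_effect",
              "rep_se")
  if (!all(needed %in% names(records)))
    stop("records must carry ", paste(needed, collapse = ", "))
  thr <- bonferroni_threshold(m_tests, family_alpha)
  records$discovery_sign <- sign(records$discovery_effect)
  records$p_one_sided <- one_sided_p(records$rep_effect, records$rep_se,
                                     records$discovery_sign)
  records$threshold <- thr
  records$significant <- records$p_one_sided < thr
  records
}
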