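#' Genome-wide admixture mapping significance threshold
#'
#' The default local-ancestry scan threshold for three-way admixed
#' Hispanic/Latino cohorts, derived externally from the autocorrelation of
#' local ancestry (a configured constant here, not recomputed).
#'
#' @return `5.68e-5`.
#' @export
genomewide_threshold <- function() 5.68e-5

#' Number of chromosomes in a cohort of n individuals
#'
#' The denominator of the tested-ancestry frequency at a local ancestry
#' interval: two chromosomes per (diploid, autosomal) individual.
#'
#' @param n_individuals Cohort size.
#' @return `2 * n_individuals` as an integer-valued numeric.
#' @examples
#' n_chromosomes(12116)  # 24232
#' @export
n_chromosomes <- function(n_individuals) 2 * as.numeric(n_individuals)

#' Tested-ancestry frequency per local ancestry interval
#'
#' @param la A `local_ancestry` object.
#' @param ancestry Ancestry label or index.
#' @return Numeric vector of per-interval frequencies (sum of counts over
#'   `2n` chromosomes), with the denominator in attribute
#'   `"n_chromosomes"`.
#' @export
ancestry_freq <- function(la, ancestry) {
  cnt <- .ancestry_counts(la, ancestry)
  structure(colSums(cnt) / n_chromosomes(la$n),
            n_chromosomes = n_chromosomes(la$n))
}

.ancestry_counts <- function(la, ancestry) {
  if (is.character(ancestry)) {
    if (!ancestry %in% la$ancestries)
      stop("unknown ancestry '", ancestry, "'")
    la$counts[[ancestry]]
  } else la$counts[[as.integer(ancestry)]]
}

#' Local ancestry interval scan for one ancestry
#'
#' Tests, at every local ancestry interval, the association of the count of
#' chromosomes inherited from the given ancestry (0/1/2; baseline = the
#' other ancestries pooled) with the trait of the null model fit, via a
#' 1-df Wald test with variance components held at the null REML
#' estimates. A positive effect means the trait increases with the count
#' of the tested ancestry. Monomorphic intervals (ancestry frequency 0 or
#' 1) are emitted with `NA` statistics and a note, never dropped.
#'
#' @param la A `local_ancestry` object covering the fitted individuals (in
#'   the same order).
#' @param null A [fit_null_model()] result for the trait.
#' @param ancestry Ancestry label (or index) to test.
#' @param trait Trait label carried into the output.
#' @return A data frame of class `admix_scan`: one row per interval with
#'   `chrom`, `start`, `end`, `interval`, `trait`, `ancestry`,
#'   `ancestry_freq`, `effect`, `se`, `stat`, `df`, `p`, `note`; the
#'   frequency denominator is in attribute `"n_chromosomes"`.
#' @export
scan_ancestry <- function(la, null, ancestry, trait = "trait") {
  stopifnot(inherits(la, "local_ancestry"),
            inherits(null, "null_model_fit"))
  if (la$n != null$n)
    stop("local ancestry and null model cover different numbers of individuals")
  G <- .ancestry_counts(la, ancestry)
  anc_lab <- if (is.character(ancestry)) ancestry else la$ancestries[ancestry]
  m <- ncol(G)
  freq <- colSums(G) / n_chromosomes(la$n)
  mono <- freq <= 0 | freq >= 1

  effect <- se <- stat <- p <- rep(NA_real_, m)
  note <- rep(NA_character_, m)
  note[mono] <- "monomorphic"
  testable <- which(!mono)
  if (length(testable)) {
    Gm <- G[, testable, drop = FALSE]
    ## all intervals solved against the null factorization at once
    ViG <- as.matrix(Matrix::solve(null$ch, Gm))
    a <- colSums(Gm * ViG)
    B <- crossprod(Gm, null$ViX)             # m x p
    s <- a - rowSums((B %*% null$XtViX_inv) * B)
    u <- as.numeric(crossprod(Gm, null$Py))
    bad <- s <= pmax(a, 1) * 1e-10
    s[bad] <- NA
    eff <- u / s
    effect[testable] <- eff
    se[testable] <- sqrt(1 / s)
    stat[testable] <- u^2 / s
    p[testable] <- stats::pchisq(u^2 / s, df = 1, lower.tail = FALSE)
    note[testable][bad] <- "collinear"
  }
  out <- data.frame(chrom = la$intervals$chrom, start = la$intervals$start,
                    end = la$intervals$end, interval = seq_len(m),
                    trait = trait, ancestry = anc_lab,
                    ancestry_freq = freq, effect = effect, se = se,
                    stat = stat, df = 1L, p = p, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("admix_scan", "data.frame")
  attr(out, "n_chromosomes") <- n_chromosomes(la$n)
  out
}

#' Joint two-ancestry local ancestry scan (2-df test)
#'
#' Models the counts of two ancestries simultaneously (baseline: the
#' remaining ancestry) and tests the 2-df null hypothesis that both
#' ancestry effects are zero. Supplying all ancestries of the panel is a
#' collinearity error, since the counts sum to two.
#'
#' @inheritParams scan_ancestry
#' @param ancestries Two ancestry labels (or indices).
#' @return An `admix_scan` data frame with `df = 2`; `effect`/`se` report
#'   the first listed ancestry, `effect2`/`se2` the second, and
#'   `ancestry_freq` the first listed ancestry's frequency.
#' @export
scan_joint <- function(la, null, ancestries, trait = "trait") {
  stopifnot(length(ancestries) == 2L)
  G1 <- .ancestry_counts(la, ancestries[1])
  G2 <- .ancestry_counts(la, ancestries[2])
  labs <- vapply(ancestries, function(a)
    if (is.character(a)) a else la$ancestries[a], character(1))
  m <- ncol(G1)
  freq1 <- colSums(G1) / n_chromosomes(la$n)
  freq2 <- colSums(G2) / n_chromosomes(la$n)
  mono <- (freq1 <= 0 | freq1 >= 1) & (freq2 <= 0 | freq2 >= 1)

  effect <- se <- effect2 <- se2 <- stat <- p <- rep(NA_real_, m)
  note <- rep(NA_character_, m)
  note[mono] <- "monomorphic"
  for (j in which(!mono)) {
    tst <- test_fixed_effect(null, cbind(G1[, j], G2[, j]), names = labs)
    effect[j] <- tst$coefficients$effect[1]
    se[j] <- tst$coefficients$se[1]
    effect2[j] <- tst$coefficients$effect[2]
    se2[j] <- tst$coefficients$se[2]
    stat[j] <- tst$stat
    p[j] <- tst$p
  }
  out <- data.frame(chrom = la$intervals$chrom, start = la$intervals$start,
                    end = la$intervals$end, interval = seq_len(m),
                    trait = trait, ancestry = paste(labs, collapse = "+"),
                    ancestry_freq = freq1, effect = effect, se = se,
                    effect2 = effect2, se2 = se2,
                    stat = stat, df = 2L, p = p, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("admix_scan", "data.frame")
  attr(out, "n_chromosomes") <- n_chromosomes(la$n)
  out
}

#' Merge significant local ancestry intervals into association regions
#'
#' Intervals with `p` below the threshold are merged when adjacent (no gap
#' of non-significant intervals is tolerated) on the same chromosome; the
#' lead interval of a region is its most significant one (ties broken by
#' leftmost start).
#'
#' @param scan An `admix_scan` data frame.
#' @param threshold Significance threshold (default the genome-wide
#'   admixture mapping level, [genomewide_threshold()]).
#' @return Data frame with one row per region: `trait`, `ancestry`,
#'   `chrom`, `start`, `end`, `n_lai`, `lead_interval`, `lead_start`,
#'   `lead_end`, `lead_p`. Zero rows when nothing is significant.
#' @export
significant_regions <- function(scan, threshold = genomewide_threshold()) {
  sig <- which(!is.na(scan$p) & scan$p < threshold)
  if (!length(sig))
    return(data.frame(trait = character(), ancestry = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), n_lai = integer(),
                      lead_interval = integer(), lead_start = numeric(),
                      lead_end = numeric(), lead_p = numeric(),
                      stringsAsFactors = FALSE))
  sig <- sig[order(scan$chrom[sig], scan$interval[sig])]
  new_run <- c(TRUE, diff(scan$interval[sig]) != 1L |
                 scan$chrom[sig][-1] != scan$chrom[sig][-length(sig)])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(sig, run), function(idx) {
    lead <- idx[order(scan$p[idx], scan$start[idx])][1]
    data.frame(trait = scan$trait[idx[1]], ancestry = scan$ancestry[idx[1]],
               chrom = scan$chrom[idx[1]], start = min(scan$start[idx]),
               end = max(scan$end[idx]), n_lai = length(idx),
               lead_interval = scan$interval[lead],
               lead_start = scan$start[lead], lead_end = scan$end[lead],
               lead_p = scan$p[lead], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Effective number of independent traits (simpleM)
#'
#' The smallest number of top eigenvalues of the trait correlation matrix
#' capturing at least the given fraction (default 99.5%) of the total
#' variance.
#'
#' @param trait_corr Symmetric correlation matrix with unit diagonal.
#' @param var_fraction Variance fraction to capture.
#' @return Integer effective number of tests.
#' @examples
#' effective_num_tests(diag(4))  # 4
#' @export
effective_num_tests <- function(trait_corr, var_fraction = 0.995) {
  trait_corr <- as.matrix(trait_corr)
  if (!isSymmetric(trait_corr, tol = 1e-8))
    stop("trait correlation matrix must be symmetric")
  if (any(abs(diag(trait_corr) - 1) > 1e-8))
    stop("trait correlation matrix must have unit diagonal")
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev))
    stop("trait correlation matrix is not positive semi-definite")
  ev <- pmax(ev, 0)
  as.integer(which(cumsum(ev) / sum(ev) >= var_fraction)[1])
}

#' Write a scan result as TSV
#'
#' @param scan An `admix_scan` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
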