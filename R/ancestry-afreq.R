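#' Ancestry-specific effect-allele frequency via EM
#'
#' Estimates the effect-allele frequency within each ancestral population
#' at one variant, from unphased dosages and the (known, point-estimate)
#' ancestry diplotype at the covering local ancestry interval. Each of an
#' individual's two chromosome copies carries the effect allele with the
#' probability of its ancestry; the observed genotype is the unphased sum,
#' so for heterozygous-ancestry individuals with genotype 1 the carrying
#' copy is latent. The E-step distributes such alleles across the two
#' ancestral copies in proportion to the current frequency odds, and the
#' M-step sets each frequency to the expected allele count over that
#' ancestry's chromosomes. The log-likelihood ascends monotonically and is
#' checked at every iteration.
#'
#' @param dosage Integer dosages in {0, 1, 2}. Non-integer (imputed)
#'   dosages are rounded to the nearest integer when `round_dosage` is
#'   `TRUE` (the default), otherwise excluded.
#' @param ancestry_counts Matrix (individuals x K ancestries) of local
#'   ancestry counts at the covering interval; rows sum to 2.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param round_dosage See `dosage`.
#' @return An object of class `ancestry_eaf`: list with `p` (named K-vector
#'   of frequencies; `NA` for ancestries with zero chromosomes),
#'   `loglik`, `loglik_trace`, `iterations`, `converged` and `n_chrom`.
#' @export
estimate_ancestry_eaf <- function(dosage, ancestry_counts, tol = 1e-8,
                                  max_iter = 1000, round_dosage = TRUE) {
  ancestry_counts <- as.matrix(ancestry_counts)
  K <- ncol(ancestry_counts)
  labels <- colnames(ancestry_counts) %||% paste0("anc", seq_len(K))
  if (length(dosage) != nrow(ancestry_counts))
    stop("dosage and ancestry_counts have different lengths")
  if (any(rowSums(ancestry_counts) != 2))
    stop("ancestry counts must sum to 2 for every individual")
  keep <- !is.na(dosage)
  if (round_dosage) dosage <- round(dosage)
  else keep <- keep & dosage == round(dosage)
  dosage <- dosage[keep]
  ancestry_counts <- ancestry_counts[keep, , drop = FALSE]
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]")
  n <- length(dosage)
  if (n == 0L) stop("no usable dosages")

  ## collapse individuals into (ancestry configuration, genotype) classes
  hom_k <- apply(ancestry_counts == 2, 1, function(z) which(z)[1])
  is_hom <- !is.na(hom_k)
  het_pair <- t(apply(ancestry_counts[!is_hom, , drop = FALSE], 1,
                      function(z) which(z == 1)))
  n_chrom <- colSums(ancestry_counts)

  ## class tables: hom classes by (k, g); het classes by (k, l, g), k < l
  hom_tab <- if (any(is_hom))
    as.data.frame(table(k = hom_k[is_hom], g = dosage[is_hom]),
                  stringsAsFactors = FALSE) else NULL
  het_tab <- if (any(!is_hom))
    as.data.frame(table(k = het_pair[, 1], l = het_pair[, 2],
                        g = dosage[!is_hom]), stringsAsFactors = FALSE)
  else NULL
  num <- function(x) as.numeric(as.character(x))
  if (!is.null(hom_tab)) {
    hom_tab <- hom_tab[hom_tab$Freq > 0, ]
    hom_tab$k <- num(hom_tab$k); hom_tab$g <- num(hom_tab$g)
  }
  if (!is.null(het_tab)) {
    het_tab <- het_tab[het_tab$Freq > 0, ]
    het_tab$k <- num(het_tab$k); het_tab$l <- num(het_tab$l)
    het_tab$g <- num(het_tab$g)
  }

  loglik_at <- function(p) {
    ll <- 0
    if (!is.null(hom_tab) && nrow(hom_tab))
      ll <- ll + sum(hom_tab$Freq *
                       stats::dbinom(hom_tab$g, 2, p[hom_tab$k], log = TRUE))
    if (!is.null(het_tab) && nrow(het_tab)) {
      pk <- p[het_tab$k]; pl <- p[het_tab$l]
      pr <- ifelse(het_tab$g == 0, (1 - pk) * (1 - pl),
                   ifelse(het_tab$g == 2, pk * pl,
                          pk * (1 - pl) + pl * (1 - pk)))
      ll <- ll + sum(het_tab$Freq * log(pmax(pr, 1e-300)))
    }
    ll
  }

  active <- n_chrom > 0
  p <- rep(sum(dosage) / (2 * n), K)
  p[!active] <- NA_real_
  p[active] <- pmin(pmax(p[active], 1e-6), 1 - 1e-6)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## E-step: expected effect alleles per ancestry
    ea <- numeric(K)
    if (!is.null(hom_tab) && nrow(hom_tab))
      for (r in seq_len(nrow(hom_tab)))
        ea[hom_tab$k[r]] <- ea[hom_tab$k[r]] + hom_tab$Freq[r] * hom_tab$g[r]
    if (!is.null(het_tab) && nrow(het_tab)) {
      for (r in seq_len(nrow(het_tab))) {
        k <- het_tab$k[r]; l <- het_tab$l[r]; g <- het_tab$g[r]
        w <- het_tab$Freq[r]
        if (g == 2) {
          ea[k] <- ea[k] + w; ea[l] <- ea[l] + w
        } else if (g == 1) {
          num_k <- p[k] * (1 - p[l])
          num_l <- p[l] * (1 - p[k])
          denom <- num_k + num_l
          wk <- if (denom > 0) num_k / denom else 0.5
          ea[k] <- ea[k] + w * wk
          ea[l] <- ea[l] + w * (1 - wk)
        }
      }
    }
    ## M-step
    p_new <- p
    p_new[active] <- ea[active] / n_chrom[active]
    ll <- loglik_at(p_new)
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    p <- p_new
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  names(p) <- labels
  names(n_chrom) <- labels
  structure(list(p = p, loglik = ll_old, loglik_trace = trace,
                 iterations = iter, converged = converged,
                 n_chrom = n_chrom),
            class = "ancestry_eaf")
}

#' @export
print.ancestry_eaf <- function(x, ...) {
  cat("Ancestry-specific EAF (EM,", x$iterations, "iterations):\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Batch ancestry-specific EAF estimation over a variant list
#'
#' Runs [estimate_ancestry_eaf()] for each listed variant, pulling the
#' ancestry diplotype from the local ancestry interval covering the
#' variant's position.
#'
#' @param gm A `genotype_matrix`.
#' @param la The matching `local_ancestry` object.
#' @param variant_ids Variants to process (default: all in `gm`).
#' @param ... Passed to [estimate_ancestry_eaf()].
#' @return Data frame with one row per variant x ancestry: `variant`,
#'   `ancestry`, `eaf`, `n_chrom`, `iterations`.
#' @export
estimate_ancestry_eaf_batch <- function(gm, la, variant_ids = NULL, ...) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(la, "local_ancestry"))
  if (is.null(variant_ids)) variant_ids <- gm$variants$id
  rows <- lapply(variant_ids, function(v) {
    j <- match(v, gm$variants$id)
    if (is.na(j)) stop("unknown variant '", v, "'")
    iv <- gm$variants$interval[j]
    if (is.na(iv)) iv <- .interval_of(la, gm$variants$position[j])
    ac <- vapply(la$ancestries, function(k) la$counts[[k]][, iv],
                 numeric(la$n))
    fit <- estimate_ancestry_eaf(gm$dosage[, j], ac, ...)
    data.frame(variant = v, ancestry = la$ancestries,
               eaf = unname(fit$p), n_chrom = unname(fit$n_chrom),
               iterations = fit$iterations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
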