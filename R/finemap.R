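#' Candidate-variant ladder specification
#'
#' The step-wise search used to nominate candidate variants inside a
#' significant admixture-mapping region: the association p-value threshold
#' is relaxed by factors of 10, and at the two most lenient p rungs a
#' variant is additionally required to show a minimum effect-allele
#' frequency difference between the analysis groups with the highest and
#' lowest proportion of the tested ancestry; that minimum is itself relaxed
#' through a decreasing sequence.
#'
#' @param p_rungs Increasing p-value rungs.
#' @param eaf_deltas Decreasing EAF-difference requirements, in (0, 1).
#' @param eaf_rungs Subset of `p_rungs` at which the EAF filter applies
#'   (the most lenient rungs).
#' @param high_group,low_group Names of the analysis groups with high/low
#'   proportion of the tested ancestry (e.g. Mexican and Cuban for
#'   Amerindian ancestry).
#' @return An object of class `ladder_spec`.
#' @export
ladder_spec <- function(p_rungs = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                        eaf_deltas = c(0.2, 0.15, 0.1, 0.05),
                        eaf_rungs = c(1e-3, 1e-2),
                        high_group = "Mainland", low_group = "Caribbean") {
  if (is.unsorted(p_rungs, strictly = TRUE))
    stop("p_rungs must be strictly increasing")
  if (is.unsorted(rev(eaf_deltas), strictly = TRUE))
    stop("eaf_deltas must be strictly decreasing")
  if (any(eaf_deltas <= 0 | eaf_deltas >= 1))
    stop("eaf_deltas must lie in (0, 1)")
  if (!all(eaf_rungs %in% p_rungs))
    stop("eaf_rungs must be a subset of p_rungs")
  structure(list(p_rungs = p_rungs, eaf_deltas = eaf_deltas,
                 eaf_rungs = eaf_rungs, high_group = high_group,
                 low_group = low_group),
            class = "ladder_spec")
}

#' Per-group effect-allele frequencies
#'
#' EAF = mean dosage / 2 within each analysis group; the cheap proxy for
#' ancestral-population frequency differentiation used by the candidate
#' ladder.
#'
#' @param gm A `genotype_matrix`.
#' @param groups Group label per individual (aligned with `gm`).
#' @param variant_ids Variants to include (default all).
#' @return Data frame: `variant`, `group`, `eaf`, `n` (NA frequency for an
#'   empty group).
#' @export
group_eaf <- function(gm, groups, variant_ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  groups <- factor(groups)
  if (length(groups) != nrow(gm$dosage))
    stop("group labels do not match the genotype matrix")
  if (is.null(variant_ids)) variant_ids <- gm$variants$id
  j <- match(variant_ids, gm$variants$id)
  if (anyNA(j)) stop("unknown variant id(s)")
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    eaf <- if (length(idx))
      colMeans(gm$dosage[idx, j, drop = FALSE], na.rm = TRUE) / 2
    else rep(NA_real_, length(j))
    data.frame(variant = variant_ids, group = g, eaf = unname(eaf),
               n = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' EAF difference between the designated high/low ancestry groups
#'
#' @param eafs A [group_eaf()] table.
#' @param high_group,low_group Group names.
#' @return Data frame: `variant`, `eaf_high`, `eaf_low`, `delta`
#'   (signed high - low).
#' @export
eaf_difference <- function(eafs, high_group, low_group) {
  hi <- eafs[eafs$group == high_group, ]
  lo <- eafs[eafs$group == low_group, ]
  if (!nrow(hi) || !nrow(lo))
    stop("high/low group not present in the EAF table")
  m <- match(hi$variant, lo$variant)
  data.frame(variant = hi$variant, eaf_high = hi$eaf,
             eaf_low = lo$eaf[m], delta = hi$eaf - lo$eaf[m],
             stringsAsFactors = FALSE)
}

#' Candidate-variant ladder search within an association region
#'
#' Walks the rungs of the [ladder_spec()] from most to least stringent.
#' A variant qualifies at a p-only rung when its association p-value in
#' any of the supplied analyses (overall / Mainland-only / Caribbean-only)
#' is below the rung; at the lenient rungs it must additionally show an
#' absolute EAF difference of at least the current relaxation value
#' between the designated group pair. Steps are evaluated cumulatively
#' (anything admitted at a stricter step stays admitted); by default the
#' search stops at the first step that admits at least one candidate
#' (`accumulate = TRUE` walks all steps instead).
#'
#' @param assoc Data frame with column `variant` and one or more p-value
#'   columns among `p_overall`, `p_mainland`, `p_caribbean`, restricted to
#'   the region's variants.
#' @param eafs An [eaf_difference()] table (or [group_eaf()] long table,
#'   in which case the spec's group pair is used).
#' @param spec A [ladder_spec()].
#' @param accumulate Walk all rungs instead of stopping at the first
#'   non-empty one.
#' @return Data frame of admitted candidates: `variant`, `p_min`,
#'   `analysis` (which analysis attained `p_min`), `delta`, `rung_p`,
#'   `rung_delta` (NA at p-only rungs); zero rows (with a warning) when
#'   nothing qualifies.
#' @export
candidate_ladder <- function(assoc, eafs, spec = ladder_spec(),
                             accumulate = FALSE) {
  stopifnot(inherits(spec, "ladder_spec"))
  if (!nrow(assoc)) {
    warning("no variants in the region")
    return(data.frame(variant = character(), p_min = numeric(),
                      analysis = character(), delta = numeric(),
                      rung_p = numeric(), rung_delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  pcols <- intersect(c("p_overall", "p_mainland", "p_caribbean"),
                     names(assoc))
  if (!length(pcols)) stop("assoc must carry at least one p-value column")
  pm <- as.matrix(assoc[, pcols, drop = FALSE])
  p_min <- suppressWarnings(apply(pm, 1, min, na.rm = TRUE))
  p_min[!is.finite(p_min)] <- NA_real_
  analysis <- pcols[max.col(-replace(pm, is.na(pm), Inf),
                            ties.method = "first")]
  if ("group" %in% names(eafs))
    eafs <- eaf_difference(eafs, spec$high_group, spec$low_group)
  delta <- abs(eafs$delta[match(assoc$variant, eafs$variant)])

  p_only <- setdiff(spec$p_rungs, spec$eaf_rungs)
  steps <- data.frame(p = p_only, d = NA_real_)
  for (dd in spec$eaf_deltas)
    steps <- rbind(steps, data.frame(p = spec$eaf_rungs, d = dd))

  admitted <- rep(FALSE, nrow(assoc))
  rung_p <- rung_d <- rep(NA_real_, nrow(assoc))
  stopped_at <- NA_integer_
  for (s in seq_len(nrow(steps))) {
    ok <- !is.na(p_min) & p_min < steps$p[s] &
      (is.na(steps$d[s]) | (!is.na(delta) & delta >= steps$d[s]))
    newly <- ok & !admitted
    rung_p[newly] <- steps$p[s]
    rung_d[newly] <- steps$d[s]
    admitted <- admitted | ok
    if (any(admitted) && !accumulate) {
      stopped_at <- s
      break
    }
  }
  if (!any(admitted)) {
    warning("no candidate variant met any ladder rung")
    return(data.frame(variant = character(), p_min = numeric(),
                      analysis = character(), delta = numeric(),
                      rung_p = numeric(), rung_delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(variant = assoc$variant[admitted],
                    p_min = p_min[admitted],
                    analysis = analysis[admitted],
                    delta = delta[admitted],
                    rung_p = rung_p[admitted],
                    rung_delta = rung_d[admitted],
                    stringsAsFactors = FALSE)
  attr(out, "stopped_at_step") <- stopped_at
  out[order(out$p_min), , drop = FALSE]
}

#' Prune candidates to lead variants by dosage correlation
#'
#' Builds a graph over candidates with an edge wherever the absolute
#' Pearson correlation of dosages exceeds `r_max`, and keeps, within each
#' connected component, the variant with the smallest association p-value
#' (ties broken by smallest position). The retained leads are pairwise
#' uncorrelated at the `r_max` level across components by construction.
#' A zero-variance dosage vector yields an undefined correlation and is
#' treated as unlinked.
#'
#' @param candidates A [candidate_ladder()] table (needs `variant` and
#'   `p_min`).
#' @param gm A `genotype_matrix` holding the candidates' dosages.
#' @param r_max Correlation threshold.
#' @return `candidates` with added columns `component` and `lead`.
#' @export
prune_by_correlation <- function(candidates, gm, r_max = 0.4) {
  if (!nrow(candidates)) stop("no candidates to prune")
  j <- match(candidates$variant, gm$variants$id)
  if (anyNA(j)) stop("candidate variant(s) missing from the genotype matrix")
  D <- gm$dosage[, j, drop = FALSE]
  m <- ncol(D)
  cc <- suppressWarnings(stats::cor(D))
  cc[is.na(cc)] <- 0
  ## union-find over |r| > r_max edges
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (m > 1) {
    for (a in seq_len(m - 1)) for (b in (a + 1):m)
      if (abs(cc[a, b]) > r_max) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  comp <- match(comp, unique(comp))
  pos <- gm$variants$position[j]
  lead <- logical(m)
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    lead[idx[order(candidates$p_min[idx], pos[idx])][1]] <- TRUE
  }
  candidates$component <- comp
  candidates$lead <- lead
  candidates
}

#' Conditional admixture scan
#'
#' Re-runs the local ancestry scan with the lead variants' dosages added
#' to the fixed-effect design (variance components held at the null fit).
#' Attenuation of the interval signal indicates that the conditioned
#' variants explain the admixture-mapping association. Leads collinear
#' with the existing design (including all-zero dosages) are dropped with
#' a warning and reported.
#'
#' @param la A `local_ancestry` object.
#' @param null The primary-trait `null_model_fit`.
#' @param lead_dosages Numeric matrix (individuals x leads) of dosages, or
#'   a vector for a single lead.
#' @param ancestry Ancestry to scan.
#' @param trait Trait label.
#' @return List with `scan` (the conditional `admix_scan`) and `dropped`
#'   (names of leads excluded as collinear).
#' @export
conditional_scan <- function(la, null, lead_dosages, ancestry,
                             trait = "trait") {
  null_c <- update_fixed_effects(null, lead_dosages)
  list(scan = scan_ancestry(la, null_c, ancestry, trait = trait),
       dropped = attr(null_c, "dropped"))
}

#' Pair primary and conditional scan p-values
#'
#' @param primary,conditional `admix_scan` data frames over the same
#'   intervals.
#' @return Data frame: `chrom`, `start`, `end`, `interval`, `p_primary`,
#'   `p_conditional`.
#' @export
attenuation <- function(primary, conditional) {
  if (nrow(primary) != nrow(conditional) ||
      any(primary$interval != conditional$interval))
    stop("primary and conditional scans are not aligned")
  data.frame(chrom = primary$chrom, start = primary$start,
             end = primary$end, interval = primary$interval,
             p_primary = primary$p, p_conditional = conditional$p,
             stringsAsFactors = FALSE)
}

#' Classify how completely conditioning explains an admixture signal
#'
#' A genome-wide significant interval is classified from its conditional
#' p-value: `full` when the conditional p is no longer even nominally
#' significant (at `full_cut`), `partial` when it is attenuated above the
#' genome-wide level but still below `full_cut`, and `none` when it
#' remains genome-wide significant.
#'
#' @param p_primary,p_conditional Primary and conditional p-values of the
#'   lead interval. `p_primary` must be below `genomewide`.
#' @param genomewide Genome-wide admixture-mapping threshold.
#' @param full_cut Nominal-significance cutpoint for "fully explained".
#' @return Character vector in `{"full", "partial", "none"}`.
#' @examples
#' classify_explained(2.29e-5, 0.003)  # "partial"
#' @export
classify_explained <- function(p_primary, p_conditional,
                               genomewide = genomewide_threshold(),
                               full_cut = 0.01) {
  if (any(p_primary >= genomewide))
    stop("classification applies to genome-wide significant signals only")
  ifelse(p_conditional >= full_cut, "full",
         ifelse(p_conditional >= genomewide, "partial", "none"))
}
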