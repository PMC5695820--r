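#' Ancestry panel
#'
#' Defines the ordered set of ancestral populations contributing to the
#' admixed cohort. Hispanic/Latino cohorts are typically modeled as a
#' three-way admixture of European, African and Amerindian ancestry.
#'
#' @param labels Character vector of at least two unique ancestry names.
#' @return An object of class `ancestry_panel`.
#' @examples
#' ancestry_panel()
#' ancestry_panel(c("CEU", "YRI"))
#' @export
ancestry_panel <- function(labels = c("European", "African", "Amerindian")) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("an ancestry panel needs at least 2 ancestries")
  if (anyDuplicated(labels)) stop("ancestry labels must be unique")
  structure(list(labels = labels, K = length(labels)), class = "ancestry_panel")
}

#' Genetic analysis group profile
#'
#' A cohort subgroup (e.g. "Mainland" vs "Caribbean") characterized by its
#' expected admixture proportions. Individual admixture proportions are drawn
#' from a Dirichlet distribution centered at these proportions.
#'
#' @param name Group label.
#' @param admixture_props Numeric vector of expected ancestry proportions,
#'   one per panel ancestry; must sum to 1.
#' @param n_individuals Number of individuals to simulate for the group.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name, admixture_props, n_individuals) {
  admixture_props <- as.numeric(admixture_props)
  if (any(!is.finite(admixture_props)) || any(admixture_props < 0) ||
      any(admixture_props > 1))
    stop("admixture proportions must be finite and in [0, 1]")
  if (abs(sum(admixture_props) - 1) > 1e-9)
    stop("admixture proportions must sum to 1 (tolerance 1e-9)")
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    stop("n_individuals must be a positive integer")
  structure(list(name = as.character(name), admixture_props = admixture_props,
                 n_individuals = n_individuals),
            class = "group_profile")
}

#' Causal (or neutral) variant specification
#'
#' Describes a biallelic variant by its position, its effect-allele frequency
#' within each ancestral population, and its per-allele trait effect within
#' each ancestral population. Ancestry-specific frequencies generate
#' admixture-mapping signal through frequency differentiation; ancestry-
#' specific effects generate signal even at equal frequencies.
#'
#' @param position 0-based genomic coordinate (base pairs).
#' @param ancestry_afs Numeric vector of effect-allele frequencies per panel
#'   ancestry, each in \[0, 1\].
#' @param ancestry_effects Numeric vector of per-allele effects (trait units)
#'   per panel ancestry. Defaults to all zero (a neutral variant).
#' @param typed Whether the variant is emitted in the genotype matrix.
#' @param id Variant identifier; autogenerated from position if `NULL`.
#' @param traits Which simulated traits receive the effect ("sbp", "dbp").
#' @return An object of class `causal_spec`.
#' @export
causal_spec <- function(position, ancestry_afs, ancestry_effects = NULL,
                        typed = TRUE, id = NULL, traits = c("sbp", "dbp")) {
  ancestry_afs <- as.numeric(ancestry_afs)
  if (any(!is.finite(ancestry_afs)) || any(ancestry_afs < 0) ||
      any(ancestry_afs > 1))
    stop("ancestry_afs must be finite frequencies in [0, 1]")
  if (is.null(ancestry_effects)) ancestry_effects <- rep(0, length(ancestry_afs))
  ancestry_effects <- as.numeric(ancestry_effects)
  if (length(ancestry_effects) != length(ancestry_afs))
    stop("ancestry_effects and ancestry_afs must have equal length")
  if (any(!is.finite(ancestry_effects))) stop("ancestry_effects must be finite")
  traits <- match.arg(traits, c("sbp", "dbp"), several.ok = TRUE)
  if (is.null(id)) id <- paste0("var_", format(position, scientific = FALSE,
                                               trim = TRUE))
  structure(list(id = as.character(id), position = as.numeric(position),
                 ancestry_afs = ancestry_afs,
                 ancestry_effects = ancestry_effects,
                 typed = isTRUE(typed), traits = traits),
            class = "causal_spec")
}

#' Variance components of the phenotype model
#'
#' Variances (trait units squared) of the kinship (polygenic), shared
#' household, shared census-block and residual random effects used when
#' simulating phenotypes and recovered by the mixed model.
#'
#' @param kinship,household,block,resid Non-negative variances.
#' @return An object of class `variance_spec`.
#' @export
variance_spec <- function(kinship = 30, household = 16, block = 4,
                          resid = 130) {
  v <- c(kinship = kinship, household = household, block = block,
         resid = resid)
  if (any(!is.finite(v)) || any(v < 0))
    stop("variance components must be finite and non-negative")
  structure(as.list(v), class = "variance_spec")
}

## map genetic distance (Morgans) to emitted base-pair coordinates at a
## uniform 1 cM/Mb, i.e. 1 Morgan = 1e8 bp
.BP_PER_MORGAN <- 1e8

#' Simulate local ancestry intervals for an admixed cohort
#'
#' Ancestry switch-points along each haplotype are drawn as a Poisson process
#' with rate `generations` per Morgan (the expected tract structure after
#' `generations` generations of random mating); the ancestry of each tract is
#' drawn independently from the individual's admixture proportions, which are
#' themselves Dirichlet-distributed around the group profile. The chromosome
#' is then summarized over `n_intervals` equal-width (in genetic distance)
#' intervals by the ancestry at each interval midpoint, mimicking the
#' interval-level output of local ancestry inference software.
#'
#' @param panel An [ancestry_panel()].
#' @param groups List of [group_profile()] objects.
#' @param chrom_length Chromosome length in Morgans.
#' @param generations Number of generations since admixture (switch-point
#'   rate per Morgan).
#' @param n_intervals Number of local ancestry intervals to emit.
#' @param seed Integer seed; if not `NULL`, `set.seed()` is called.
#' @param concentration Dirichlet concentration of individual admixture
#'   proportions around the group profile (larger = tighter).
#' @param chrom Chromosome label for emitted coordinates.
#' @return An object of class `local_ancestry` with per-ancestry count
#'   matrices (individuals x intervals, entries 0/1/2 summing to 2 across
#'   ancestries), haplotype-level ancestry assignments, 0-based half-open
#'   interval coordinates, group labels and individual admixture proportions.
#' @export
simulate_local_ancestry <- function(panel, groups, chrom_length = 2,
                                    generations = 8, n_intervals = 120,
                                    seed = NULL, concentration = 30,
                                    chrom = "1") {
  stopifnot(inherits(panel, "ancestry_panel"))
  if (inherits(groups, "group_profile")) groups <- list(groups)
  if (length(groups) == 0L) stop("at least one group profile is required")
  ok <- vapply(groups, inherits, logical(1), what = "group_profile")
  if (!all(ok)) stop("groups must be a list of group_profile objects")
  if (!is.finite(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be a positive, finite number of Morgans")
  if (!is.finite(generations) || generations < 1)
    stop("generations must be >= 1")
  n_intervals <- as.integer(n_intervals)
  if (is.na(n_intervals) || n_intervals < 1L) stop("n_intervals must be >= 1")
  K <- panel$K
  for (g in groups)
    if (length(g$admixture_props) != K)
      stop("group '", g$name, "' has ", length(g$admixture_props),
           " proportions but the panel has ", K, " ancestries")
  if (!is.null(seed)) set.seed(seed)

  n <- sum(vapply(groups, function(g) g$n_individuals, integer(1)))
  group <- factor(rep(vapply(groups, function(g) g$name, character(1)),
                      vapply(groups, function(g) g$n_individuals, integer(1))),
                  levels = vapply(groups, function(g) g$name, character(1)))
  ids <- sprintf("ind_%05d", seq_len(n))

  ## individual admixture proportions: Dirichlet via gamma draws; a zero
  ## group proportion stays exactly zero
  admix <- matrix(0, n, K, dimnames = list(ids, panel$labels))
  row0 <- 0L
  for (g in groups) {
    alpha <- concentration * g$admixture_props
    gam <- matrix(0, g$n_individuals, K)
    for (k in seq_len(K))
      if (alpha[k] > 0) gam[, k] <- stats::rgamma(g$n_individuals, alpha[k])
    rs <- rowSums(gam)
    if (any(rs == 0)) stop("degenerate Dirichlet draw; increase concentration")
    admix[row0 + seq_len(g$n_individuals), ] <- gam / rs
    row0 <- row0 + g$n_individuals
  }

  mids <- (seq_len(n_intervals) - 0.5) * chrom_length / n_intervals
  hap_anc <- matrix(0L, 2L * n, n_intervals)
  n_switch <- integer(2L * n)
  for (i in seq_len(n)) {
    pr <- admix[i, ]
    for (h in 1:2) {
      r <- 2L * (i - 1L) + h
      ns <- stats::rpois(1L, generations * chrom_length)
      n_switch[r] <- ns
      if (ns == 0L) {
        hap_anc[r, ] <- sample.int(K, 1L, prob = pr)
      } else {
        breaks <- sort(stats::runif(ns, 0, chrom_length))
        tract <- sample.int(K, ns + 1L, replace = TRUE, prob = pr)
        hap_anc[r, ] <- tract[findInterval(mids, breaks) + 1L]
      }
    }
  }

  counts <- vector("list", K)
  names(counts) <- panel$labels
  odd <- seq(1L, 2L * n, by = 2L)
  for (k in seq_len(K))
    counts[[k]] <- (hap_anc[odd, , drop = FALSE] == k) +
      (hap_anc[odd + 1L, , drop = FALSE] == k)
  for (k in seq_len(K)) dimnames(counts[[k]]) <- list(ids, NULL)

  start <- floor((seq_len(n_intervals) - 1L) * chrom_length / n_intervals *
                   .BP_PER_MORGAN)
  end <- floor(seq_len(n_intervals) * chrom_length / n_intervals *
                 .BP_PER_MORGAN)
  intervals <- data.frame(chrom = chrom, start = start, end = end,
                          stringsAsFactors = FALSE)

  structure(list(counts = counts, hap_ancestry = hap_anc,
                 intervals = intervals, ancestries = panel$labels,
                 ids = ids, group = group, admixture = admix,
                 n = n, n_intervals = n_intervals,
                 chrom_length = chrom_length, generations = generations,
                 n_switch = n_switch),
            class = "local_ancestry")
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat("Local ancestry matrix:", x$n, "individuals x", x$n_intervals,
      "intervals,", length(x$ancestries), "ancestries (",
      paste(x$ancestries, collapse = ", "), ")\n")
  cat("Groups:", paste(levels(x$group), table(x$group), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

## interval index covering a base-pair position (0-based half-open)
.interval_of <- function(la, position) {
  idx <- findInterval(position, la$intervals$start)
  bad <- idx < 1L | position >= la$intervals$end[pmax(idx, 1L)]
  if (any(bad))
    stop("position(s) ", paste(position[bad], collapse = ", "),
         " outside the simulated intervals")
  idx
}

#' Simulate genotype dosages conditional on local ancestry
#'
#' Each haplotype's allele at a variant is Bernoulli with the effect-allele
#' frequency of that haplotype's ancestry at the covering local ancestry
#' interval; the emitted dosage is the sum over the two haplotypes.
#'
#' @param la A [simulate_local_ancestry()] result.
#' @param variants List of [causal_spec()] objects (causal and/or neutral).
#' @param seed Integer seed; if not `NULL`, `set.seed()` is called.
#' @return An object of class `genotype_matrix` with a dosage matrix
#'   (individuals x variants), variant metadata, and haplotype-level alleles
#'   (used internally when planting ancestry-specific effects).
#' @export
simulate_genotypes <- function(la, variants, seed = NULL) {
  stopifnot(inherits(la, "local_ancestry"))
  if (inherits(variants, "causal_spec")) variants <- list(variants)
  ok <- vapply(variants, inherits, logical(1), what = "causal_spec")
  if (length(variants) == 0L || !all(ok))
    stop("variants must be a non-empty list of causal_spec objects")
  K <- length(la$ancestries)
  for (v in variants)
    if (length(v$ancestry_afs) != K)
      stop("variant '", v$id, "' has ", length(v$ancestry_afs),
           " ancestry frequencies but the panel has ", K)
  if (!is.null(seed)) set.seed(seed)

  m <- length(variants)
  n <- la$n
  pos <- vapply(variants, function(v) v$position, numeric(1))
  iv <- .interval_of(la, pos)
  hap_alleles <- matrix(0L, 2L * n, m)
  for (j in seq_len(m)) {
    anc <- la$hap_ancestry[, iv[j]]
    p <- variants[[j]]$ancestry_afs[anc]
    hap_alleles[, j] <- stats::rbinom(2L * n, 1L, p)
  }
  odd <- seq(1L, 2L * n, by = 2L)
  dosage <- hap_alleles[odd, , drop = FALSE] +
    hap_alleles[odd + 1L, , drop = FALSE]
  vid <- vapply(variants, function(v) v$id, character(1))
  dimnames(dosage) <- list(la$ids, vid)
  meta <- data.frame(
    id = vid, chrom = la$intervals$chrom[iv], position = pos,
    a1 = "A", a2 = "G",
    type = ifelse(vapply(variants, function(v) v$typed, logical(1)), "g", "i"),
    info = 1, interval = iv, stringsAsFactors = FALSE)
  structure(list(dosage = dosage, variants = meta, hap_alleles = hap_alleles,
                 specs = variants, ids = la$ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "variants\n")
  invisible(x)
}

## per-individual trait contribution of planted variants; the per-allele
## effect depends on the ancestry of the carrying haplotype
.genetic_value <- function(la, gm, trait) {
  n <- la$n
  val <- numeric(n)
  odd <- seq(1L, 2L * n, by = 2L)
  for (j in seq_along(gm$specs)) {
    sp <- gm$specs[[j]]
    if (!(trait %in% sp$traits) || all(sp$ancestry_effects == 0)) next
    iv <- .interval_of(la, sp$position)
    beta_h <- sp$ancestry_effects[la$hap_ancestry[, iv]]
    contrib <- beta_h * gm$hap_alleles[, j]
    val <- val + contrib[odd] + contrib[odd + 1L]
  }
  val
}

#' Simulate blood-pressure phenotypes with clustered random effects
#'
#' Generates latent systolic and diastolic blood pressure as the sum of an
#' intercept, covariate effects, planted variant effects (ancestry-specific
#' per-allele effects from the haplotype data), a polygenic (kinship) effect
#' realized through sibling pairs, shared household and census-block effects,
#' and an individual residual. Anti-hypertensive medication use is drawn from
#' a logistic model in latent SBP, and treated individuals' measured
#' pressures are lowered by the standard 10/5 mmHg, so that the downstream
#' medication adjustment recovers the latent scale. Device-summary and
#' raw-measure means are both emitted (with occasional planted
#' inconsistencies) to exercise the measurement-consistency filter.
#'
#' @param gm A [simulate_genotypes()] result (or `NULL` for no variants).
#' @param la The matching [simulate_local_ancestry()] result.
#' @param vs A [variance_spec()].
#' @param covariate_effects Named list with numeric elements `sbp` and `dbp`,
#'   each with entries `age` and `sexM` (mmHg per year / for male sex).
#' @param household_size Individuals per household (last household may be
#'   smaller).
#' @param sib_prob Probability that a multi-person household's first two
#'   members are full siblings (kinship correlation 0.5).
#' @param households_per_block Households per census block unit.
#' @param med_model Named list `threshold` and `scale` (mmHg) of the logistic
#'   medication model in latent SBP.
#' @param inconsistency_rate Fraction of individuals given a device/raw
#'   discrepancy of at least 5 mmHg.
#' @param missing_rate Fraction of individuals with a missing medication flag
#'   (and, independently, missing age).
#' @param dbp_re_scale Scaling of the shared random effects in DBP.
#' @param seed Integer seed; if not `NULL`, `set.seed()` is called.
#' @return A `data.frame` of phenotype records (one row per individual) with
#'   device and raw measurement summaries, medication flag, covariates
#'   (age, sex, center, sampling weight, five ancestry PCs), group label and
#'   household/block identifiers. The expected kinship correlation matrix is
#'   attached as attribute `"kinship"` (sparse), and the latent truth as
#'   attribute `"truth"`.
#' @export
simulate_phenotypes <- function(gm, la, vs = variance_spec(),
                                covariate_effects = list(
                                  sbp = c(age = 0.35, sexM = 3),
                                  dbp = c(age = 0.15, sexM = 1.5)),
                                household_size = 2L, sib_prob = 0.5,
                                households_per_block = 10L,
                                med_model = list(threshold = 140, scale = 8),
                                inconsistency_rate = 0.005,
                                missing_rate = 0.003,
                                dbp_re_scale = 0.6,
                                seed = NULL) {
  stopifnot(inherits(la, "local_ancestry"), inherits(vs, "variance_spec"))
  if (!is.null(gm) && !identical(gm$ids, la$ids))
    stop("genotype and local-ancestry objects cover different individuals")
  if (!is.null(seed)) set.seed(seed)
  n <- la$n
  household_size <- max(1L, as.integer(household_size))
  households_per_block <- max(1L, as.integer(households_per_block))
  household <- rep(seq_len(ceiling(n / household_size)),
                   each = household_size)[seq_len(n)]
  n_house <- max(household)
  block <- rep(seq_len(ceiling(n_house / households_per_block)),
               each = households_per_block)[household]

  ## kinship: diag 1; sibling pairs (correlation 0.5) within a random subset
  ## of multi-person households
  sib_first <- which(!duplicated(household) &
                       duplicated(household, fromLast = TRUE))
  sib_first <- sib_first[stats::runif(length(sib_first)) < sib_prob]
  ii <- c(seq_len(n), sib_first)
  jj <- c(seq_len(n), sib_first + 1L)
  xx <- c(rep(1, n), rep(0.5, length(sib_first)))
  kin <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                              symmetric = TRUE)
  dimnames(kin) <- list(la$ids, la$ids)

  age <- round(stats::runif(n, 18, 74))
  sex <- factor(ifelse(stats::runif(n) < 0.5, "F", "M"), levels = c("F", "M"))
  center <- factor(sample(c("Bronx", "Chicago", "Miami", "SanDiego"), n,
                          replace = TRUE))
  weight <- exp(stats::rnorm(n, 0, 0.25))
  weight <- weight / mean(weight)
  ## PCs: first K-1 from centered admixture proportions (the structure the
  ## model adjusts for), remainder pure noise
  K <- ncol(la$admixture)
  pcs <- matrix(stats::rnorm(n * 5, 0, 0.02), n, 5)
  for (k in seq_len(min(K - 1L, 5L)))
    pcs[, k] <- pcs[, k] + scale(la$admixture[, k + 1L])[, 1L]
  colnames(pcs) <- paste0("PC", 1:5)

  draw_re <- function() {
    u_kin <- numeric(n)
    if (vs$kinship > 0) {
      L <- Matrix::expand(Matrix::Cholesky(kin, perm = FALSE, LDL = FALSE))$L
      u_kin <- sqrt(vs$kinship) * as.numeric(L %*% stats::rnorm(n))
    }
    u_house <- sqrt(vs$household) * stats::rnorm(n_house)
    u_block <- sqrt(vs$block) * stats::rnorm(max(block))
    list(kin = u_kin, house = u_house[household], block = u_block[block])
  }
  re <- draw_re()
  eps_s <- sqrt(vs$resid) * stats::rnorm(n)
  ## DBP residual: correlated with the SBP residual, half the variance
  v_d <- 0.5 * vs$resid
  rho <- 0.5
  eps_d <- if (vs$resid > 0)
    rho * sqrt(v_d / vs$resid) * eps_s + sqrt(v_d * (1 - rho^2)) * stats::rnorm(n)
  else numeric(n)

  cov_s <- covariate_effects$sbp["age"] * (age - 46) +
    covariate_effects$sbp["sexM"] * (sex == "M")
  cov_d <- covariate_effects$dbp["age"] * (age - 46) +
    covariate_effects$dbp["sexM"] * (sex == "M")
  gen_s <- if (is.null(gm)) numeric(n) else .genetic_value(la, gm, "sbp")
  gen_d <- if (is.null(gm)) numeric(n) else .genetic_value(la, gm, "dbp")

  shared <- re$kin + re$house + re$block
  latent_sbp <- 120 + cov_s + gen_s + shared + eps_s
  latent_dbp <- 75 + cov_d + gen_d + dbp_re_scale * shared + eps_d

  on_meds <- stats::runif(n) <
    stats::plogis((latent_sbp - med_model$threshold) / med_model$scale)
  sbp_meas <- latent_sbp - 10 * on_meds
  dbp_meas <- latent_dbp - 5 * on_meds

  sbp_raw <- sbp_meas + stats::runif(n, -1, 1)
  dbp_raw <- dbp_meas + stats::runif(n, -1, 1)
  inc <- stats::runif(n) < inconsistency_rate
  if (any(inc)) {
    shift <- stats::runif(sum(inc), 5, 12) * sample(c(-1, 1), sum(inc), TRUE)
    sbp_raw[inc] <- sbp_meas[inc] + shift
  }
  meds_out <- on_meds
  meds_out[stats::runif(n) < missing_rate] <- NA
  age_out <- age
  age_out[stats::runif(n) < missing_rate] <- NA

  pheno <- data.frame(
    id = la$ids, group = la$group,
    sbp_mean = sbp_meas, dbp_mean = dbp_meas,
    sbp_raw_mean = sbp_raw, dbp_raw_mean = dbp_raw,
    on_meds = meds_out, age = age_out, sex = sex, center = center,
    weight = weight, pcs, household = household, block = block,
    stringsAsFactors = FALSE)
  attr(pheno, "kinship") <- kin
  attr(pheno, "truth") <- list(latent_sbp = latent_sbp,
                               latent_dbp = latent_dbp,
                               genetic_sbp = gen_s, genetic_dbp = gen_d,
                               u_kin = re$kin, u_house = re$house,
                               u_block = re$block, vs = vs, seed = seed)
  pheno
}

#' Simulate a complete admixed cohort
#'
#' Convenience wrapper chaining [simulate_local_ancestry()],
#' [simulate_genotypes()] and [simulate_phenotypes()] under a single seed.
#'
#' @param panel,groups,chrom_length,generations,n_intervals,concentration
#'   Passed to [simulate_local_ancestry()].
#' @param variants Passed to [simulate_genotypes()]; if empty, no genotype
#'   matrix is generated.
#' @param vs,... Passed to [simulate_phenotypes()].
#' @param seed Integer master seed.
#' @return List with elements `la`, `gm` (possibly `NULL`), `pheno`,
#'   `kinship` and `seed`.
#' @export
simulate_cohort <- function(panel = ancestry_panel(),
                            groups = default_groups(),
                            variants = list(),
                            vs = variance_spec(),
                            chrom_length = 2, generations = 8,
                            n_intervals = 120, concentration = 30,
                            seed = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  la <- simulate_local_ancestry(panel, groups, chrom_length = chrom_length,
                                generations = generations,
                                n_intervals = n_intervals,
                                concentration = concentration, seed = NULL)
  gm <- if (length(variants)) simulate_genotypes(la, variants, seed = NULL)
  else NULL
  pheno <- simulate_phenotypes(gm, la, vs = vs, seed = NULL, ...)
  list(la = la, gm = gm, pheno = pheno, kinship = attr(pheno, "kinship"),
       seed = seed)
}

#' Default genetic analysis group profiles
#'
#' Two groups contrasting the admixture composition typical of Mainland
#' (high Amerindian, low African) and Caribbean (low Amerindian, higher
#' African) Hispanic/Latino genetic analysis groups.
#'
#' @param n_mainland,n_caribbean Group sizes.
#' @return List of two [group_profile()] objects.
#' @export
default_groups <- function(n_mainland = 600L, n_caribbean = 600L) {
  list(group_profile("Mainland", c(0.45, 0.08, 0.47), n_mainland),
       group_profile("Caribbean", c(0.70, 0.22, 0.08), n_caribbean))
}
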