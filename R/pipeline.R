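#' Pipeline configuration
#'
#' All thresholds and simulation settings for an end-to-end run, with the
#' study defaults: genome-wide admixture threshold 5.68e-5, the candidate
#' ladder with EAF relaxation (0.2, 0.15, 0.1, 0.05), correlation pruning
#' at |r| <= 0.4, and one-sided replication at family level 0.05.
#'
#' @param seed Master seed; every stochastic stage derives from it.
#' @param groups List of [group_profile()]s.
#' @param variants List of [causal_spec()]s (causal and neutral).
#' @param vs A [variance_spec()].
#' @param chrom_length,generations,n_intervals,concentration Simulator
#'   settings (see [simulate_local_ancestry()]).
#' @param traits Traits to scan, among `"SBP"`, `"DBP"`, `"MAP"`, `"PP"`.
#' @param ancestries Ancestry labels to scan (default: all in the panel).
#' @param panel An [ancestry_panel()].
#' @param threshold Genome-wide admixture-mapping significance level.
#' @param ladder A [ladder_spec()].
#' @param r_max Pruning correlation threshold.
#' @param full_cut Conditional-p cutpoint for "fully explained".
#' @param replication_n Size of the simulated replication cohort (0 skips
#'   the replication stage).
#' @param replication_alpha Family-wise replication level.
#' @param prep A [prep_config()].
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            groups = default_groups(),
                            variants = default_variants(),
                            vs = variance_spec(),
                            chrom_length = 2, generations = 8,
                            n_intervals = 120, concentration = 30,
                            traits = c("SBP", "MAP"),
                            ancestries = NULL,
                            panel = ancestry_panel(),
                            threshold = genomewide_threshold(),
                            ladder = ladder_spec(),
                            r_max = 0.4, full_cut = 0.01,
                            replication_n = 500L,
                            replication_alpha = 0.05,
                            prep = prep_config()) {
  stopifnot(threshold > 0, threshold < 1, r_max > 0, r_max < 1)
  traits <- match.arg(traits, c("SBP", "DBP", "MAP", "PP"),
                      several.ok = TRUE)
  if (is.null(ancestries)) ancestries <- panel$labels
  structure(list(seed = as.integer(seed), groups = groups,
                 variants = variants, vs = vs,
                 chrom_length = chrom_length, generations = generations,
                 n_intervals = n_intervals, concentration = concentration,
                 traits = traits, ancestries = ancestries, panel = panel,
                 threshold = threshold, ladder = ladder, r_max = r_max,
                 full_cut = full_cut,
                 replication_n = as.integer(replication_n),
                 replication_alpha = replication_alpha, prep = prep),
            class = "run_config")
}

#' Default planted variants for the demonstration pipeline
#'
#' One strongly Amerindian-differentiated causal variant for SBP plus a
#' handful of neutral variants spread along the chromosome (some inside
#' the causal interval's neighborhood, to exercise the ladder and the
#' pruning step).
#'
#' @param causal_beta Per-allele effect (mmHg) of the planted variant.
#' @return List of [causal_spec()]s.
#' @export
default_variants <- function(causal_beta = 4) {
  set.seed(97)
  causal <- causal_spec(1.0e8, ancestry_afs = c(0.1, 0.1, 0.9),
                        ancestry_effects = rep(causal_beta, 3),
                        id = "rs_causal", traits = "sbp")
  neutral_pos <- sort(round(stats::runif(12, 1e6, 1.99e8)))
  neutral <- lapply(seq_along(neutral_pos), function(i)
    causal_spec(neutral_pos[i],
                ancestry_afs = stats::runif(3, 0.05, 0.95),
                id = sprintf("rs_neutral%02d", i)))
  c(list(causal), neutral)
}

.null_design <- function(traits_df) {
  stats::model.matrix(~ age + sex + center + weight + PC1 + PC2 + PC3 +
                        PC4 + PC5, data = traits_df)
}

.fit_trait_null <- function(trait, tt, kin, ids) {
  df <- tt$traits
  X <- .null_design(df)
  kin_sub <- kin[match(df$id, ids), match(df$id, ids)]
  fit_null_model(df[[trait]], X, kinship = kin_sub,
                 household = df$household, block = df$block,
                 options = null_model_options(compute_se = FALSE))
}

#' Run the full admixture-mapping pipeline on a simulated cohort
#'
#' Stages, in order: cohort simulation, phenotype preparation, per-trait
#' null mixed models, local ancestry scans for each trait x ancestry,
#' significant-region detection, fine-mapping of each region (association
#' tests of region variants overall and within each analysis group,
#' group-EAF candidate ladder, correlation pruning, conditional scan and
#' explained-signal classification, ancestry-specific EAF estimation for
#' the leads), and a replication stage on an independently simulated
#' high-target-ancestry cohort. All stage outputs are written under
#' `outdir` as plain-text tables plus a JSON manifest carrying the seed
#' and a hash of the configuration; a rerun with the same configuration
#' and seed reproduces every table byte for byte. With `resume = TRUE`
#' the simulation and preparation stages are reloaded from existing
#' outputs instead of recomputed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param resume Reuse existing simulation/prep outputs when present.
#' @return Invisibly, a list with the main in-memory results: `cohort`,
#'   `trait_table`, `nulls`, `scans`, `regions`, `finemap`,
#'   `replication`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile(),
                         resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, paste0(...))
  cfg_json <- jsonlite::toJSON(.config_fingerprint(config),
                               auto_unbox = TRUE, digits = NA)
  cfg_hash <- .fnv1a(as.character(cfg_json))

  ## -- simulate ---------------------------------------------------------
  sim_files <- c(pth("local_ancestry.tsv"), pth("dosages.tsv"),
                 pth("phenotypes.csv"), pth("kinship.tsv"))
  if (resume && all(file.exists(sim_files))) {
    la <- read_local_ancestry(sim_files[1])
    gm <- read_dosages(sim_files[2])
    pheno <- utils::read.csv(sim_files[3], stringsAsFactors = TRUE)
    pheno$id <- as.character(pheno$id)
    kin <- read_kinship(sim_files[4], ids = la$ids)
    cohort <- list(la = la, gm = gm, pheno = pheno, kinship = kin,
                   seed = config$seed)
  } else {
    cohort <- simulate_cohort(panel = config$panel, groups = config$groups,
                              variants = config$variants, vs = config$vs,
                              chrom_length = config$chrom_length,
                              generations = config$generations,
                              n_intervals = config$n_intervals,
                              concentration = config$concentration,
                              seed = config$seed)
    write_local_ancestry(cohort$la, sim_files[1])
    write_dosages(cohort$gm, sim_files[2])
    utils::write.csv(cohort$pheno, sim_files[3], row.names = FALSE,
                     quote = FALSE)
    write_kinship(cohort$kinship, sim_files[4])
    write_truth(cohort, pth("truth.json"))
  }

  ## -- phenotype preparation -------------------------------------------
  tt <- prepare_traits(cohort$pheno, config$prep)
  write_trait_table(tt, pth("traits.csv"), pth("exclusions.csv"))
  la_r <- subset_individuals(cohort$la, tt$traits$id)
  gm_r <- subset_individuals(cohort$gm, tt$traits$id)

  ## effective number of independent traits across the four BP traits
  trait_cols <- intersect(c("SBP", "DBP", "MAP", "PP"), names(tt$traits))
  m_eff <- effective_num_tests(stats::cor(tt$traits[, trait_cols]))

  ## -- null models and scans -------------------------------------------
  nulls <- list()
  scans <- list()
  for (tr in config$traits) {
    nulls[[tr]] <- .fit_trait_null(tr, tt, cohort$kinship, cohort$la$ids)
    for (anc in config$ancestries) {
      key <- paste(tr, anc, sep = ".")
      scans[[key]] <- scan_ancestry(la_r, nulls[[tr]], anc, trait = tr)
      write_scan(scans[[key]], pth("scan_", tr, "_", anc, ".tsv"))
    }
  }

  ## -- significant regions ---------------------------------------------
  regions <- do.call(rbind, lapply(scans, significant_regions,
                                   threshold = config$threshold))
  rownames(regions) <- NULL
  utils::write.table(regions, pth("regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(regions)) write_bed(regions, pth("regions.bed"))

  ## -- fine mapping per region -----------------------------------------
  strata <- levels(la_r$group)
  fm <- lapply(seq_len(nrow(regions)), function(i)
    .finemap_region(regions[i, ], la_r, gm_r, tt, cohort, config, nulls,
                    outdir = outdir, tag = i))
  if (nrow(regions)) {
    fm_tab <- do.call(rbind, lapply(fm, function(x) x$summary))
    utils::write.table(fm_tab, pth("finemap_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else fm_tab <- NULL

  ## -- replication on an independent high-target-ancestry cohort -------
  repl <- NULL
  if (config$replication_n > 0 && length(fm) &&
      any(vapply(fm, function(x) nrow(x$leads) > 0, logical(1)))) {
    repl <- .replicate_leads(fm, config)
    if (!is.null(repl))
      utils::write.table(repl, pth("replication.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "admixscan",
                   version = as.character(utils::packageVersion("admixscan")),
                   seed = config$seed, config_hash = cfg_hash,
                   n_input = tt$n_input, n_retained = nrow(tt$traits),
                   effective_num_traits = m_eff,
                   traits = config$traits, ancestries = config$ancestries,
                   threshold = config$threshold,
                   n_regions = nrow(regions),
                   files = list.files(outdir))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, trait_table = tt, nulls = nulls,
                 scans = scans, regions = regions, finemap = fm,
                 replication = repl, manifest = manifest,
                 outdir = outdir))
}

## stable, JSON-serializable view of the configuration for hashing
.config_fingerprint <- function(config) {
  list(seed = config$seed,
       groups = lapply(config$groups, function(g)
         list(g$name, g$admixture_props, g$n_individuals)),
       variants = lapply(config$variants, function(v)
         list(v$id, v$position, v$ancestry_afs, v$ancestry_effects)),
       vs = unlist(config$vs), chrom_length = config$chrom_length,
       generations = config$generations, n_intervals = config$n_intervals,
       traits = config$traits, ancestries = config$ancestries,
       threshold = config$threshold, r_max = config$r_max,
       full_cut = config$full_cut)
}

.finemap_region <- function(region, la_r, gm_r, tt, cohort, config, nulls,
                            outdir, tag) {
  tr <- region$trait
  anc <- region$ancestry
  null <- nulls[[tr]]
  in_region <- gm_r$variants$position >= region$start &
    gm_r$variants$position < region$end
  vids <- gm_r$variants$id[in_region]
  empty <- list(region = region,
                candidates = data.frame(), leads = data.frame(),
                summary = cbind(region, p_conditional = NA_real_,
                                explained = NA_character_,
                                n_candidates = 0L, n_leads = 0L))
  if (!length(vids)) return(empty)

  ## association tests: overall and per analysis group
  assoc <- data.frame(variant = vids, stringsAsFactors = FALSE)
  acol <- function(fitn, ids_sub) t(vapply(vids, function(v) {
    d <- gm_r$dosage[ids_sub, v]
    if (stats::var(d) == 0) return(c(NA_real_, NA_real_, NA_real_))
    tryCatch({
      tst <- test_fixed_effect(fitn, d)
      c(tst$coefficients$effect, tst$coefficients$se, tst$p)
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
  }, numeric(3)))
  ov <- acol(null, seq_len(nrow(tt$traits)))
  assoc$effect_overall <- ov[, 1]
  assoc$se_overall <- ov[, 2]
  assoc$p_overall <- ov[, 3]
  pcol <- function(fitn, ids_sub) acol(fitn, ids_sub)[, 3]
  for (g in levels(la_r$group)) {
    sub <- which(tt$traits$group == g)
    if (length(sub) < 50) next
    df <- tt$traits[sub, , drop = FALSE]
    Xg <- .null_design(df)
    kin_g <- cohort$kinship[match(df$id, cohort$la$ids),
                            match(df$id, cohort$la$ids)]
    fit_g <- fit_null_model(df[[tr]], Xg, kinship = kin_g,
                            household = df$household, block = df$block,
                            options = null_model_options(compute_se = FALSE))
    assoc[[paste0("p_", tolower(g))]] <- pcol(fit_g, sub)
  }

  eafs <- group_eaf(gm_r, tt$traits$group, vids)
  spec <- config$ladder
  if (!all(c(spec$high_group, spec$low_group) %in% unique(eafs$group))) {
    gl <- levels(la_r$group)
    spec$high_group <- gl[1]
    spec$low_group <- gl[length(gl)]
  }
  cand <- suppressWarnings(candidate_ladder(assoc, eafs, spec))
  if (!nrow(cand)) return(empty)
  cand <- prune_by_correlation(cand, gm_r, r_max = config$r_max)
  cand$effect_overall <- assoc$effect_overall[match(cand$variant,
                                                    assoc$variant)]
  leads <- cand[cand$lead, , drop = FALSE]

  cond <- conditional_scan(la_r, null,
                           gm_r$dosage[, leads$variant, drop = FALSE],
                           anc, trait = tr)
  p_cond <- cond$scan$p[cond$scan$interval == region$lead_interval]
  cls <- classify_explained(region$lead_p, p_cond,
                            genomewide = config$threshold,
                            full_cut = config$full_cut)
  anc_eaf <- estimate_ancestry_eaf_batch(gm_r, la_r, leads$variant)

  base <- file.path(outdir, sprintf("region%02d", tag))
  utils::write.table(cbind(assoc,
                           delta = cand$delta[match(assoc$variant,
                                                    cand$variant)]),
                     paste0(base, "_assoc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cand, paste0(base, "_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(anc_eaf, paste0(base, "_ancestry_eaf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_scan(cond$scan, paste0(base, "_conditional_scan.tsv"))
  primary <- scan_ancestry(la_r, null, anc, trait = tr)
  att <- attenuation(primary, cond$scan)
  utils::write.table(att, paste0(base, "_attenuation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grDevices::png(paste0(base, "_plot.png"), width = 800, height = 500)
  plot_region(primary, cond$scan,
              assoc = data.frame(position = gm_r$variants$position[in_region],
                                 p = assoc$p_overall),
              leads = gm_r$variants$position[match(leads$variant,
                                                   gm_r$variants$id)],
              threshold = config$threshold)
  grDevices::dev.off()
  list(region = region, assoc = assoc, candidates = cand, leads = leads,
       conditional = cond$scan, attenuation = att, ancestry_eaf = anc_eaf,
       summary = cbind(region, p_conditional = p_cond, explained = cls,
                       n_candidates = nrow(cand), n_leads = nrow(leads)))
}

.replicate_leads <- function(fm, config) {
  leads_all <- do.call(rbind, lapply(fm, function(x)
    if (nrow(x$leads))
      data.frame(variant = x$leads$variant, trait = x$region$trait,
                 stringsAsFactors = FALSE)))
  leads_all <- unique(leads_all)
  if (is.null(leads_all) || !nrow(leads_all)) return(NULL)
  ## independent cohort dominated by the tested ancestry (replication-
  ## style design): same variant truth, new seed branch
  K <- config$panel$K
  props <- rep(0.02, K)
  props[K] <- 1 - 0.02 * (K - 1)
  rep_group <- group_profile("Replication", props, config$replication_n)
  rep_cohort <- simulate_cohort(panel = config$panel, groups = list(rep_group),
                                variants = config$variants, vs = config$vs,
                                chrom_length = config$chrom_length,
                                generations = config$generations,
                                n_intervals = config$n_intervals,
                                seed = config$seed + 100003L)
  tt2 <- prepare_traits(rep_cohort$pheno, config$prep)
  gm2 <- subset_individuals(rep_cohort$gm, tt2$traits$id)
  X2 <- .null_design(tt2$traits)
  fits2 <- lapply(unique(leads_all$trait), function(tr)
    fit_null_model(tt2$traits[[tr]], X2,
                   household = tt2$traits$household,
                   block = tt2$traits$block,
                   options = null_model_options(compute_se = FALSE)))
  names(fits2) <- unique(leads_all$trait)
  rows <- lapply(seq_len(nrow(leads_all)), function(i) {
    v <- leads_all$variant[i]
    tr <- leads_all$trait[i]
    fit2 <- fits2[[tr]]
    d <- gm2$dosage[, v]
    if (stats::var(d) == 0)
      return(data.frame(variant = v, trait = tr, rep_freq = mean(d) / 2,
                        rep_effect = NA_real_, rep_se = NA_real_,
                        stringsAsFactors = FALSE))
    tst <- test_fixed_effect(fit2, d)
    data.frame(variant = v, trait = tr, rep_freq = mean(d) / 2,
               rep_effect = tst$coefficients$effect,
               rep_se = tst$coefficients$se, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ## discovery direction from the fine-mapping association estimates
  tab$discovery_effect <- vapply(seq_len(nrow(tab)), function(i) {
    for (x in fm) {
      j <- match(tab$variant[i], x$leads$variant)
      if (!is.na(j)) return(x$leads$effect_overall[j])
    }
    NA_real_
  }, numeric(1))
  ok <- !is.na(tab$rep_se)
  out <- tab[ok, , drop = FALSE]
  if (!nrow(out)) return(NULL)
  replication_test(out, family_alpha = config$replication_alpha)
}
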