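#' Phenotype preparation configuration
#'
#' Thresholds for the blood-pressure trait derivation and exclusion rules.
#' Defaults follow common practice for clinic BP measurements in large
#' cohort analyses: a 5 mmHg device/raw inconsistency bound, plausibility
#' range SBP >= 80 and DBP >= 50 (strict `<` drops), and winsorization of
#' pulse pressure at mean + 6 SD of the analyzed sample.
#'
#' @param inconsistency_mmhg Drop when |device mean - raw mean| is at least
#'   this, for either SBP or DBP.
#' @param sbp_min,dbp_min Lower plausibility bounds (strict `<` drops).
#' @param winsor_sd Winsorize PP above mean + `winsor_sd` * SD.
#' @param med_sbp,med_dbp mmHg added to SBP/DBP of treated individuals.
#' @param map_standard If `TRUE` (default) MAP = DBP + PP/3, the standard
#'   mean arterial pressure; `FALSE` uses DBP - PP/3.
#' @param required_covariates Covariate columns that must be non-missing.
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(inconsistency_mmhg = 5, sbp_min = 80, dbp_min = 50,
                        winsor_sd = 6, med_sbp = 10, med_dbp = 5,
                        map_standard = TRUE,
                        required_covariates = c("on_meds", "age", "sex",
                                                "center", "weight")) {
  stopifnot(inconsistency_mmhg > 0, sbp_min > 0, dbp_min > 0, winsor_sd > 0)
  structure(list(inconsistency_mmhg = inconsistency_mmhg, sbp_min = sbp_min,
                 dbp_min = dbp_min, winsor_sd = winsor_sd, med_sbp = med_sbp,
                 med_dbp = med_dbp, map_standard = isTRUE(map_standard),
                 required_covariates = required_covariates),
            class = "prep_config")
}

#' Read a prep configuration from JSON or YAML
#'
#' @param path A JSON (or YAML, requiring the `yaml` package) file whose
#'   fields override [prep_config()] defaults.
#' @return A `prep_config` object.
#' @export
read_prep_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(prep_config, cfg)
}

#' Anti-hypertensive medication adjustment
#'
#' For individuals on anti-hypertensive medication, adds 10 mmHg to measured
#' SBP and 5 mmHg to measured DBP (both device-summary and raw-measure
#' means), the standard additive correction for treated blood pressure.
#' Records with a missing medication flag are left unchanged; they are
#' routed to the missing-covariate exclusion downstream.
#'
#' @param records Phenotype data frame with columns `sbp_mean`, `dbp_mean`
#'   (and optionally `sbp_raw_mean`, `dbp_raw_mean`) and logical `on_meds`.
#' @param sbp_add,dbp_add The additive corrections in mmHg.
#' @return `records` with adjusted pressures.
#' @examples
#' adjust_for_medication(data.frame(sbp_mean = 120, dbp_mean = 80,
#'                                  on_meds = TRUE))
#' @export
adjust_for_medication <- function(records, sbp_add = 10, dbp_add = 5) {
  stopifnot(all(c("sbp_mean", "dbp_mean", "on_meds") %in% names(records)))
  add <- !is.na(records$on_meds) & records$on_meds
  records$sbp_mean <- records$sbp_mean + sbp_add * add
  records$dbp_mean <- records$dbp_mean + dbp_add * add
  if ("sbp_raw_mean" %in% names(records))
    records$sbp_raw_mean <- records$sbp_raw_mean + sbp_add * add
  if ("dbp_raw_mean" %in% names(records))
    records$dbp_raw_mean <- records$dbp_raw_mean + dbp_add * add
  records
}

#' Derive pulse pressure and mean arterial pressure
#'
#' PP = SBP - DBP; MAP = DBP + PP/3 (the physiological standard; set
#' `map_standard = FALSE` for DBP - PP/3).
#'
#' @param sbp,dbp Numeric vectors (mmHg).
#' @param map_standard See [prep_config()].
#' @return Data frame with columns `PP` and `MAP`.
#' @examples
#' derive_traits(120, 80)  # PP 40, MAP 93.33
#' @export
derive_traits <- function(sbp, dbp, map_standard = TRUE) {
  pp <- sbp - dbp
  map <- if (isTRUE(map_standard)) dbp + pp / 3 else dbp - pp / 3
  data.frame(PP = pp, MAP = map)
}

#' Apply exclusion rules and derive the analysis trait table
#'
#' Applies the exclusion rules in documented order, each excluded record
#' receiving the first failing rule as its single reason code:
#' \enumerate{
#'   \item `measurement_inconsistency`: |device mean - raw mean| >= 5 mmHg
#'     for either SBP or DBP;
#'   \item `missing_covariate`: missing outcome or required covariate
#'     (including the medication flag);
#'   \item `bp_out_of_range`: SBP < 80 or DBP < 50 (strict inequalities, so
#'     SBP = 80 / DBP = 50 exactly are retained);
#'   \item `negative_pp`: PP < 0.
#' }
#' PP values of retained records exceeding mean + 6 SD (computed on the
#' retained analysis sample) are then winsorized to exactly that limit.
#' Medication adjustment is *not* performed here; see
#' [adjust_for_medication()] and [prepare_traits()].
#'
#' @param records Phenotype records (one row per individual) with columns
#'   `id`, `sbp_mean`, `dbp_mean`, `sbp_raw_mean`, `dbp_raw_mean`, `on_meds`
#'   and the required covariates.
#' @param config A [prep_config()].
#' @return An object of class `trait_table`: list with `traits` (retained
#'   rows with `SBP`, `DBP`, `PP`, `MAP` and carried covariates),
#'   `records` (retained input rows), `exclusions` (id, reason),
#'   `winsorized` (id, old, new), `winsor_limit` and `n_input`.
#' @export
apply_exclusions <- function(records, config = prep_config()) {
  if (nrow(records) == 0L) stop("no phenotype records supplied")
  needed <- c("sbp_mean", "dbp_mean", "sbp_raw_mean", "dbp_raw_mean")
  if (!all(needed %in% names(records)))
    stop("records must carry both device and raw measurement summaries")
  if (!"id" %in% names(records))
    records$id <- sprintf("rec_%05d", seq_len(nrow(records)))

  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  flag(abs(records$sbp_mean - records$sbp_raw_mean) >=
         config$inconsistency_mmhg |
       abs(records$dbp_mean - records$dbp_raw_mean) >=
         config$inconsistency_mmhg, "measurement_inconsistency")
  req <- intersect(config$required_covariates, names(records))
  missing_any <- is.na(records$sbp_mean) | is.na(records$dbp_mean)
  for (cc in req) missing_any <- missing_any | is.na(records[[cc]])
  flag(missing_any, "missing_covariate")
  flag(records$sbp_mean < config$sbp_min |
         records$dbp_mean < config$dbp_min, "bp_out_of_range")
  flag(records$sbp_mean - records$dbp_mean < 0, "negative_pp")

  keep <- is.na(reason)
  retained <- records[keep, , drop = FALSE]
  traits <- cbind(
    retained[, "id", drop = FALSE],
    SBP = retained$sbp_mean, DBP = retained$dbp_mean,
    derive_traits(retained$sbp_mean, retained$dbp_mean,
                  config$map_standard))
  carry <- setdiff(names(retained),
                   c("id", "sbp_mean", "dbp_mean", "sbp_raw_mean",
                     "dbp_raw_mean"))
  traits <- cbind(traits, retained[, carry, drop = FALSE])
  rownames(traits) <- NULL

  ## winsorization statistics on the analyzed (post-exclusion) sample
  limit <- mean(traits$PP) + config$winsor_sd * stats::sd(traits$PP)
  over <- which(traits$PP > limit)
  winsorized <- data.frame(id = traits$id[over], old = traits$PP[over],
                           new = rep(limit, length(over)),
                           stringsAsFactors = FALSE)
  traits$PP[over] <- limit

  structure(list(
    traits = traits, records = retained,
    exclusions = data.frame(id = records$id[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE),
    winsorized = winsorized, winsor_limit = limit,
    n_input = nrow(records), config = config),
    class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", nrow(x$traits), "retained of", x$n_input,
      "records\n")
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  if (nrow(x$winsorized))
    cat(nrow(x$winsorized), "PP value(s) winsorized at",
        round(x$winsor_limit, 2), "mmHg\n")
  invisible(x)
}

#' Full phenotype preparation
#'
#' Medication adjustment followed by [apply_exclusions()].
#'
#' @inheritParams apply_exclusions
#' @return A `trait_table`.
#' @export
prepare_traits <- function(records, config = prep_config()) {
  records <- adjust_for_medication(records, config$med_sbp, config$med_dbp)
  apply_exclusions(records, config)
}

#' Write the trait table and its exclusion log
#'
#' @param tt A `trait_table`.
#' @param traits_path,exclusions_path Output CSV paths.
#' @return `traits_path`, invisibly.
#' @export
write_trait_table <- function(tt, traits_path, exclusions_path = NULL) {
  utils::write.csv(tt$traits, traits_path, row.names = FALSE, quote = FALSE)
  if (!is.null(exclusions_path))
    utils::write.csv(tt$exclusions, exclusions_path, row.names = FALSE,
                     quote = FALSE)
  invisible(traits_path)
}
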