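## Readers/writers for the plain-text formats used across the pipeline.
## All internal tables use 0-based half-open coordinates; VCF positions are
## converted from 1-based on read.

#' Write / read a local ancestry table
#'
#' Long TSV with one row per individual x interval: `id`, `chrom`, `start`,
#' `end`, then one count column per ancestry (counts sum to 2).
#'
#' @param la A `local_ancestry` object.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `local_ancestry` object (reader).
#' @export
write_local_ancestry <- function(la, path) {
  m <- la$n_intervals
  long <- data.frame(
    id = rep(la$ids, each = m),
    chrom = rep(la$intervals$chrom, times = la$n),
    start = rep(la$intervals$start, times = la$n),
    end = rep(la$intervals$end, times = la$n),
    stringsAsFactors = FALSE)
  for (k in la$ancestries)
    long[[k]] <- as.integer(t(la$counts[[k]]))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_local_ancestry
#' @export
read_local_ancestry <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  fixed <- c("id", "chrom", "start", "end")
  if (!all(fixed %in% names(long)))
    stop("local ancestry table must have columns id, chrom, start, end")
  ancestries <- setdiff(names(long), fixed)
  ids <- unique(long$id)
  key <- paste(long$chrom, long$start, sep = ":")
  ukey <- unique(key)
  m <- length(ukey)
  n <- length(ids)
  ord <- order(match(long$id, ids), match(key, ukey))
  long <- long[ord, ]
  counts <- lapply(ancestries, function(k)
    matrix(as.integer(long[[k]]), nrow = n, ncol = m, byrow = TRUE,
           dimnames = list(ids, NULL)))
  names(counts) <- ancestries
  csum <- Reduce(`+`, counts)
  if (any(csum != 2L))
    stop("ancestry counts must sum to 2 within each individual x interval")
  first <- long[seq_len(m), c("chrom", "start", "end")]
  rownames(first) <- NULL
  structure(list(counts = counts, hap_ancestry = NULL, intervals = first,
                 ancestries = ancestries, ids = ids,
                 group = factor(rep(NA_character_, n)),
                 admixture = NULL, n = n, n_intervals = m,
                 chrom_length = NA_real_, generations = NA_real_,
                 n_switch = NULL),
            class = "local_ancestry")
}

#' Write / read a dosage matrix
#'
#' TSV with variant metadata columns (`id`, `chrom`, `position`, `a1`, `a2`,
#' `type`, `info`) followed by one dosage column per individual.
#'
#' @param gm A `genotype_matrix` object.
#' @param path File path.
#' @return `path`, invisibly (writer); a `genotype_matrix` (reader).
#' @export
write_dosages <- function(gm, path) {
  tab <- cbind(gm$variants[, c("id", "chrom", "position", "a1", "a2",
                               "type", "info")],
               as.data.frame(t(gm$dosage), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- c("id", "chrom", "position", "a1", "a2", "type", "info")
  if (!all(meta_cols %in% names(tab)))
    stop("dosage table is missing metadata columns")
  ids <- setdiff(names(tab), meta_cols)
  dosage <- t(as.matrix(tab[, ids, drop = FALSE]))
  dimnames(dosage) <- list(ids, tab$id)
  meta <- tab[, meta_cols]
  meta$interval <- NA_integer_
  structure(list(dosage = dosage, variants = meta, hap_alleles = NULL,
                 specs = NULL, ids = ids),
            class = "genotype_matrix")
}

#' Read genotype dosages from a VCF file
#'
#' Uses the `vcfR` package. Dosages are taken from the `DS` FORMAT field
#' when present, otherwise computed as alternate-allele counts from `GT`.
#' Positions are converted to 0-based.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A `genotype_matrix` object.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fmt <- unique(unlist(strsplit(unname(v@gt[, "FORMAT"]), ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col)
      vapply(strsplit(gsub("\\|", "/", col), "/"), function(a)
        sum(as.numeric(a) > 0), numeric(1)))
    dim(ds) <- dim(gt)
    dimnames(ds) <- dimnames(gt)
  }
  dosage <- t(ds)
  meta <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], position = as.numeric(fix[, "POS"]) - 1,
    a1 = fix[, "ALT"], a2 = fix[, "REF"], type = "g", info = 1,
    interval = NA_integer_, stringsAsFactors = FALSE)
  colnames(dosage) <- meta$id
  structure(list(dosage = dosage, variants = meta, hap_alleles = NULL,
                 specs = NULL, ids = rownames(dosage)),
            class = "genotype_matrix")
}

#' Write / read a kinship matrix as a sparse triplet TSV
#'
#' Columns `id1`, `id2`, `kinship`; only nonzero upper-triangle entries
#' (including the unit diagonal) are stored.
#'
#' @param kin Symmetric kinship (correlation) matrix, dense or sparse.
#' @param ids Individual identifiers (reader: expected order; defaults to
#'   order of first appearance).
#' @param path File path.
#' @return `path`, invisibly (writer); a sparse symmetric matrix (reader).
#' @export
write_kinship <- function(kin, path) {
  kin <- methods::as(methods::as(Matrix::forceSymmetric(Matrix::Matrix(kin)),
                                 "generalMatrix"), "TsparseMatrix")
  ids <- rownames(kin)
  if (is.null(ids)) ids <- sprintf("ind_%05d", seq_len(nrow(kin)))
  keep <- kin@i <= kin@j & kin@x != 0
  tab <- data.frame(id1 = ids[kin@i[keep] + 1L], id2 = ids[kin@j[keep] + 1L],
                    kinship = kin@x[keep], stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, ids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- unique(c(tab$id1, tab$id2))
  i <- match(tab$id1, ids)
  j <- match(tab$id2, ids)
  if (anyNA(i) || anyNA(j)) stop("kinship table contains unknown ids")
  kin <- Matrix::sparseMatrix(i = i, j = j, x = tab$kinship,
                              dims = c(length(ids), length(ids)),
                              symmetric = TRUE)
  dimnames(kin) <- list(ids, ids)
  kin
}

#' Write regions as a BED file (0-based half-open)
#'
#' @param regions A data frame with columns `chrom`, `start`, `end` and
#'   optionally `trait`, `ancestry`, `lead_p`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- if (all(c("trait", "ancestry") %in% names(regions)))
    paste(regions$trait, regions$ancestry, sep = "_") else "."
  score <- if ("lead_p" %in% names(regions))
    pmin(1000, round(-10 * log10(pmax(regions$lead_p, 1e-300)))) else 0
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = name, score = score, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the planted truth of a simulated cohort as JSON
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  specs <- lapply(cohort$gm$specs %||% list(), function(s)
    list(id = s$id, position = s$position, ancestry_afs = s$ancestry_afs,
         ancestry_effects = s$ancestry_effects, typed = s$typed,
         traits = s$traits))
  truth <- attr(cohort$pheno, "truth")
  out <- list(seed = cohort$seed,
              variance_components = truth$vs[c("kinship", "household",
                                               "block", "resid")],
              variants = specs,
              ancestries = cohort$la$ancestries,
              groups = as.list(table(cohort$la$group)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
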