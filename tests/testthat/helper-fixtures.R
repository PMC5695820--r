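# shared fixture builders; everything is generated in code, no data files

two_anc_panel <- function() ancestry_panel(c("European", "Amerindian"))

# small three-ancestry cohort for generic tests
tiny_cohort <- function(seed = 1, n = 300, variants = list(),
                        vs = variance_spec(), ...) {
  simulate_cohort(groups = default_groups(n %/% 2, n - n %/% 2),
                  variants = variants, vs = vs,
                  n_intervals = 40, seed = seed, ...)
}

# build a local_ancestry object directly from a haplotype ancestry matrix
# (2n x m, entries in 1..K); bypasses the simulator for exact fixtures
manual_la <- function(hap_anc, ancestries, chrom = "1", width = 1e6) {
  n <- nrow(hap_anc) / 2
  m <- ncol(hap_anc)
  K <- length(ancestries)
  odd <- seq(1, 2 * n, by = 2)
  counts <- lapply(seq_len(K), function(k)
    (hap_anc[odd, , drop = FALSE] == k) + (hap_anc[odd + 1, , drop = FALSE] == k))
  names(counts) <- ancestries
  ids <- sprintf("ind_%05d", seq_len(n))
  for (k in seq_len(K)) dimnames(counts[[k]]) <- list(ids, NULL)
  structure(list(counts = counts, hap_ancestry = hap_anc,
                 intervals = data.frame(chrom = chrom,
                                        start = (seq_len(m) - 1) * width,
                                        end = seq_len(m) * width),
                 ancestries = ancestries, ids = ids,
                 group = factor(rep("G", n)), admixture = NULL,
                 n = n, n_intervals = m, chrom_length = NA_real_,
                 generations = NA_real_, n_switch = NULL),
            class = "local_ancestry")
}

# a scan-shaped data frame for region-merging tests
manual_scan <- function(p, chrom = "1") {
  m <- length(p)
  structure(data.frame(chrom = chrom, start = (seq_len(m) - 1) * 1e6,
                       end = seq_len(m) * 1e6, interval = seq_len(m),
                       trait = "SBP", ancestry = "Amerindian",
                       ancestry_freq = 0.3, effect = 0, se = 1,
                       stat = 0, df = 1L, p = p, note = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("admix_scan", "data.frame"))
}

# the six-record phenotype fixture: one measurement inconsistency (delta
# exactly 5), one SBP = 79, one missing age, three clean
toy_records <- function() {
  data.frame(
    id = paste0("r", 1:6),
    sbp_mean     = c(120, 130, 79, 118, 125, 140),
    dbp_mean     = c(80, 85, 60, 75, 82, 90),
    sbp_raw_mean = c(120, 135, 79, 118, 125, 140),
    dbp_raw_mean = c(80, 85, 60, 75, 82, 90),
    on_meds = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    age = c(50, 45, 60, NA, 41, 66),
    sex = factor(c("F", "M", "F", "M", "F", "M")),
    center = factor(rep("Bronx", 6)),
    weight = rep(1, 6),
    stringsAsFactors = FALSE)
}

# iid-structure design shared by several mixed-model tests
sim_lmm_data <- function(n, vs, seed, beta = c(2, 0.5),
                         households = n / 2, hh_per_block = 10,
                         sib_prob = 0.5) {
  set.seed(seed)
  household <- rep(seq_len(households), length.out = n)
  household <- sort(household)
  block <- (household - 1) %/% hh_per_block + 1
  x1 <- rnorm(n)
  X <- cbind(1, x1)
  sib_first <- which(!duplicated(household) &
                       duplicated(household, fromLast = TRUE))
  sib_first <- sib_first[runif(length(sib_first)) < sib_prob]
  kin <- Matrix::sparseMatrix(i = c(seq_len(n), sib_first),
                              j = c(seq_len(n), sib_first + 1L),
                              x = c(rep(1, n), rep(0.5, length(sib_first))),
                              dims = c(n, n), symmetric = TRUE)
  L <- Matrix::expand(Matrix::Cholesky(kin, perm = FALSE, LDL = FALSE))$L
  u_kin <- sqrt(vs[1]) * as.numeric(L %*% rnorm(n))
  u_hh <- sqrt(vs[2]) * rnorm(max(household))[household]
  u_bl <- sqrt(vs[3]) * rnorm(max(block))[block]
  y <- as.numeric(X %*% beta) + u_kin + u_hh + u_bl +
    sqrt(vs[4]) * rnorm(n)
  list(y = y, X = X, kin = kin, household = household, block = block)
}
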