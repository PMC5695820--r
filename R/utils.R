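## small internal helpers

## FNV-1a hash of a string, as 8 hex digits; used to stamp run outputs
.fnv1a <- function(s) {
  xor32 <- function(a, b)
    bitwXor(a %% 65536, b %% 65536) +
      65536 * bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Restrict a cohort object to a subset of individuals
#'
#' @param x A `local_ancestry` or `genotype_matrix` object.
#' @param ids Individual identifiers to keep (order respected).
#' @return The restricted object.
#' @export
subset_individuals <- function(x, ids) UseMethod("subset_individuals")

#' @export
subset_individuals.local_ancestry <- function(x, ids) {
  idx <- match(ids, x$ids)
  if (anyNA(idx)) stop("unknown individual id(s)")
  hap <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  x$counts <- lapply(x$counts, function(m) m[idx, , drop = FALSE])
  if (!is.null(x$hap_ancestry))
    x$hap_ancestry <- x$hap_ancestry[hap, , drop = FALSE]
  if (!is.null(x$n_switch)) x$n_switch <- x$n_switch[hap]
  if (!is.null(x$admixture)) x$admixture <- x$admixture[idx, , drop = FALSE]
  x$group <- x$group[idx]
  x$ids <- x$ids[idx]
  x$n <- length(idx)
  x
}

#' @export
subset_individuals.genotype_matrix <- function(x, ids) {
  idx <- match(ids, x$ids)
  if (anyNA(idx)) stop("unknown individual id(s)")
  x$dosage <- x$dosage[idx, , drop = FALSE]
  if (!is.null(x$hap_alleles)) {
    hap <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    x$hap_alleles <- x$hap_alleles[hap, , drop = FALSE]
  }
  x$ids <- x$ids[idx]
  x
}
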