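#' Manhattan-style plot of an admixture scan
#'
#' -log10 p-values of the local ancestry intervals against genomic
#' position, with the genome-wide significance threshold as a dashed line.
#'
#' @param scan An `admix_scan` data frame.
#' @param threshold Significance threshold to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `scan`.
#' @export
plot_scan <- function(scan, threshold = genomewide_threshold(), ...) {
  ok <- !is.na(scan$p)
  pos <- (scan$start + scan$end) / 2
  graphics::plot(pos[ok] / 1e6, -log10(scan$p[ok]),
                 xlab = "position (Mb)", ylab = expression(-log[10](p)),
                 pch = 16, cex = 0.6,
                 main = paste(scan$trait[1], "~", scan$ancestry[1]), ...)
  graphics::abline(h = -log10(threshold), lty = 2, col = "grey40")
  invisible(scan)
}

#' Region plot of primary versus conditional admixture scans
#'
#' Overlays the primary and conditional interval scans as lines, with
#' single-variant association results as points, in the layout used for
#' fine-mapping figures.
#'
#' @param primary,conditional `admix_scan` data frames over the same
#'   intervals (conditional may be `NULL`).
#' @param assoc Optional data frame with `position` and `p` for variant
#'   association results.
#' @param leads Optional positions of the conditioned lead variants
#'   (drawn as filled triangles).
#' @param threshold Significance threshold to draw.
#' @return Invisibly, `NULL`.
#' @export
plot_region <- function(primary, conditional = NULL, assoc = NULL,
                        leads = NULL, threshold = genomewide_threshold()) {
  pos <- (primary$start + primary$end) / 2 / 1e6
  yl <- range(c(-log10(primary$p), if (!is.null(conditional))
    -log10(conditional$p), if (!is.null(assoc)) -log10(assoc$p),
    -log10(threshold)), na.rm = TRUE, finite = TRUE)
  graphics::plot(pos, -log10(primary$p), type = "l", col = "blue",
                 ylim = yl, xlab = "position (Mb)",
                 ylab = expression(-log[10](p)),
                 main = paste(primary$trait[1], "~", primary$ancestry[1]))
  if (!is.null(conditional))
    graphics::lines(pos, -log10(conditional$p), col = "darkgreen")
  if (!is.null(assoc))
    graphics::points(assoc$position / 1e6, -log10(assoc$p), pch = 1,
                     cex = 0.7)
  if (!is.null(leads))
    graphics::points(leads / 1e6, rep(0, length(leads)), pch = 17)
  graphics::abline(h = -log10(threshold), lty = 2, col = "grey40")
  invisible(NULL)
}
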