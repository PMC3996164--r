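# Recombination summaries, pedigree-error flags and block-image rendering.

#' Per-offspring recombination counts from a block matrix
#'
#' Counts P/M transitions along each offspring row, ignoring unknown cells
#' (a transition is counted between the nearest flanking known codes).
#'
#' @param B Integer block matrix or `hs_blocks` object.
#' @return Named integer vector of counts, one per offspring.
#' @export
recombination_counts <- function(B) {
  if (inherits(B, "hs_blocks")) B <- B$blocks
  apply(B, 1L, function(row) {
    x <- row[row != 0L]
    if (length(x) < 2L) return(0L)
    sum(diff(x) != 0L)
  })
}

#' Flag offspring with implausibly many recombinations
#'
#' On a map of length L Morgans about L crossovers per paternal gamete are
#' expected; offspring whose count exceeds
#' `expected + k * sqrt(expected)` (Poisson-motivated, default k = 4) are
#' flagged. An excessive count signals a pedigree error (the individual is not
#' a half-sib of the others) or a failure of block detection.
#'
#' @param counts Named recombination counts from [recombination_counts()].
#' @param chr_length_cm Map length in cM.
#' @param k Number of Poisson standard deviations above the expectation.
#' @return Tibble with `offspring`, `count`, `expected`, `threshold`,
#'   `flagged`.
#' @export
flag_recombination_outliers <- function(counts, chr_length_cm, k = 4) {
  expected <- chr_length_cm / 100
  threshold <- expected + k * sqrt(expected)
  tibble::tibble(
    offspring = if (is.null(names(counts))) as.character(seq_along(counts)) else names(counts),
    count = unname(as.integer(counts)),
    expected = expected,
    threshold = threshold,
    flagged = unname(counts > threshold)
  )
}

#' Render a block matrix as a PNG image
#'
#' One band of pixel rows per offspring, one colour per sire strand, white for
#' unknown — the standard visual QC for block detection and phasing. Output is
#' deterministic for identical input and parameters.
#'
#' @param B Integer block matrix or `hs_blocks` object.
#' @param path Output PNG path.
#' @param row_px Pixel rows per offspring.
#' @param colors Length-3 vector of hex colours for U, P, M.
#' @return `path`, invisibly.
#' @export
render_block_image <- function(B, path, row_px = 10L,
                               colors = c(U = "#FFFFFF", P = "#1F77B4", M = "#D62728")) {
  if (inherits(B, "hs_blocks")) B <- B$blocks
  rgb3 <- grDevices::col2rgb(colors) / 255
  idx <- B + 1L
  img <- array(0, dim = c(nrow(B) * row_px, ncol(B), 3L))
  for (ch in 1:3) {
    plane <- matrix(rgb3[ch, ][idx], nrow(B), ncol(B))
    img[, , ch] <- plane[rep(seq_len(nrow(B)), each = row_px), , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a block matrix
#'
#' ggplot2 raster of the sire-strand block structure: offspring in rows,
#' markers in columns, one fill per strand, white where unknown.
#'
#' @param object An `hs_blocks` object (or use [plot_blocks()] on a matrix).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hs_blocks
#' @export
autoplot.hs_blocks <- function(object, ...) {
  plot_blocks(object$blocks)
}

#' @rdname autoplot.hs_blocks
#' @param B Integer block matrix.
#' @export
plot_blocks <- function(B) {
  if (inherits(B, "hs_blocks")) B <- B$blocks
  df <- tibble::tibble(
    offspring = factor(rep(rownames(B), times = ncol(B)),
                       levels = rev(rownames(B))),
    marker = rep(seq_len(ncol(B)), each = nrow(B)),
    strand = factor(c("U", "P", "M")[as.integer(B) + 1L], levels = c("P", "M", "U"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$offspring,
                                   fill = .data$strand)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(P = "#1F77B4", M = "#D62728", U = "#FFFFFF"),
                               drop = FALSE) +
    ggplot2::labs(x = "marker index", y = NULL, fill = "sire strand") +
    ggplot2::theme_minimal()
}

#' @method autoplot hs_phase_result
#' @export
autoplot.hs_phase_result <- function(object, ...) {
  plot_blocks(object$blocks$blocks) +
    ggplot2::labs(title = sprintf("Sire-strand blocks (%d recombination events)",
                                  nrow(object$blocks$events)))
}
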