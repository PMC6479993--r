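#' Construct a fingerprint
#'
#' A fingerprint is one sampled one-dimensional signal: a liquid
#' chromatogram (retention time in minutes, ascending) or an ATR-FTIR
#' spectrum (wavenumber in cm^-1, descending), together with its detection
#' channel and sample metadata.
#'
#' @param axis Numeric vector, strictly monotone (ascending for
#'   chromatograms, descending for spectra).
#' @param values Numeric vector of intensities/absorbances, same length as
#'   `axis`.
#' @param channel One of `"LC242"`, `"LC210"` (chromatographic detection at
#'   242/210 nm) or `"FTIR"`.
#' @param meta Optional one-row data frame of sample metadata (see
#'   [make_design()]).
#' @return An object of class `"fingerprint"`: a list with elements `axis`,
#'   `values`, `channel`, `meta`.
#' @examples
#' fp <- fingerprint(seq(0, 60, length.out = 121), rnorm(121), "LC242")
#' length(fp$values)
#' @export
fingerprint <- function(axis, values, channel = c("LC242", "LC210", "FTIR"),
                        meta = NULL) {
  channel <- match.arg(channel)
  axis <- as.numeric(axis)
  values <- as.numeric(values)
  if (length(axis) != length(values)) {
    stop("`axis` and `values` must have the same length")
  }
  if (length(axis) < 1) stop("a fingerprint needs at least one point")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("`axis` must be strictly monotone")
  structure(list(axis = axis, values = values, channel = channel,
                 meta = meta),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s, %d points, axis %.4g .. %.4g\n",
              x$channel, length(x$axis), x$axis[1],
              x$axis[length(x$axis)]))
  invisible(x)
}

# Coerce a fingerprint (or numeric vector) to its value vector.
fp_values <- function(x) {
  if (inherits(x, "fingerprint")) x$values else as.numeric(x)
}

#' Construct a data block
#'
#' A block is a samples-by-variables matrix from one technique and one
#' part, with per-row sample metadata and per-column axis labels. Blocks
#' are the unit of data fusion.
#'
#' @param matrix Numeric matrix, samples in rows.
#' @param row_meta Data frame with one row per matrix row; must contain a
#'   `sample_id` column (and, for paired-part fusion, `sclerotium_id` and
#'   `class_label`).
#' @param col_labels Numeric vector of axis values (retention times or
#'   wavenumbers), one per column.
#' @param block_id Character scalar naming the block, e.g. `"FTIR-inner"`.
#' @return An object of class `"block"`.
#' @export
block <- function(matrix, row_meta, col_labels, block_id) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != nrow(row_meta)) {
    stop("`row_meta` must have one row per sample")
  }
  if (ncol(matrix) != length(col_labels)) {
    stop("`col_labels` must have one entry per column")
  }
  if (!"sample_id" %in% names(row_meta)) {
    stop("`row_meta` must contain a `sample_id` column")
  }
  structure(list(matrix = matrix, row_meta = row_meta,
                 col_labels = as.numeric(col_labels),
                 block_id = as.character(block_id)),
            class = "block")
}

#' @export
print.block <- function(x, ...) {
  cat(sprintf("<block> %s: %d samples x %d variables\n",
              x$block_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# Extract row i of a block as a fingerprint.
block_row <- function(b, i, channel) {
  fingerprint(b$col_labels, b$matrix[i, ], channel,
              meta = b$row_meta[i, , drop = FALSE])
}
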