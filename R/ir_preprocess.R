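# Second-derivative preprocessing of ATR-FTIR spectra and exclusion of the
# diamond-crystal artifact region (2600-1750 cm^-1).

#' Savitzky-Golay second derivative of a spectrum
#'
#' Second derivative with respect to index position (uniform grid), using
#' a polynomial of order `polyorder` fitted over a `window`-point moving
#' window. Edge points are computed from the one-sided polynomial fit.
#' Absorption bands appear as negative peaks in the output; no sign flip
#' is applied.
#'
#' @param spectrum A [fingerprint()] (or numeric vector).
#' @param window Odd window length in points.
#' @param polyorder Polynomial order (< `window`).
#' @return Object of the same type as the input, same length.
#' @export
second_derivative <- function(spectrum, window = 15, polyorder = 2) {
  v <- fp_values(spectrum)
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  if (length(v) < window) stop("signal shorter than `window`")
  d2 <- signal::sgolayfilt(v, p = polyorder, n = window, m = 2)
  if (inherits(spectrum, "fingerprint")) {
    fingerprint(spectrum$axis, d2, spectrum$channel, spectrum$meta)
  } else {
    d2
  }
}

#' Exclude a wavenumber region from a spectrum
#'
#' Removes every point with `low <= wavenumber <= high` (by default the
#' ATR diamond-crystal region 2600-1750 cm^-1) and returns the remaining
#' contiguous runs as separate segments.
#'
#' @param spectrum A [fingerprint()] with wavenumber axis.
#' @param low,high Region bounds in cm^-1 (`low < high`).
#' @return Object of class `"spectrum_segments"`: `segments` (list of
#'   [fingerprint()]s) and `excluded_region = c(low, high)`.
#' @export
exclude_region <- function(spectrum, low = 1750, high = 2600) {
  if (low >= high) stop("`low` must be less than `high`")
  wn <- spectrum$axis
  keep <- !(wn >= low & wn <= high)
  if (!any(keep)) stop("exclusion removes the entire spectrum")
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    idx <- starts[r]:ends[r]
    segs[[length(segs) + 1]] <-
      fingerprint(wn[idx], spectrum$values[idx], spectrum$channel,
                  spectrum$meta)
  }
  structure(list(segments = segs, excluded_region = c(low, high)),
            class = "spectrum_segments")
}

#' @export
print.spectrum_segments <- function(x, ...) {
  cat(sprintf("<spectrum_segments> %d segments, excluded %g-%g cm^-1\n",
              length(x$segments), x$excluded_region[1],
              x$excluded_region[2]))
  for (s in x$segments) {
    cat(sprintf("  %g .. %g (%d points)\n", s$axis[1],
                s$axis[length(s$axis)], length(s$axis)))
  }
  invisible(x)
}

# Flatten segments back to one variable vector plus its labels.
segments_flatten <- function(ss) {
  list(values = unlist(lapply(ss$segments, function(s) s$values)),
       labels = unlist(lapply(ss$segments, function(s) s$axis)))
}

#' Preprocess an FTIR block
#'
#' Applies the Savitzky-Golay second derivative and drops the excluded
#' region. With `order = "derivative_first"` (default) the derivative is
#' taken on the full recorded spectrum and the region removed afterwards;
#' with `"exclude_first"` the region is removed first and the derivative
#' computed per contiguous segment, which avoids differentiating across
#' the splice.
#'
#' @param b A [block()] of raw spectra (columns = wavenumbers, cm^-1).
#' @param window,polyorder See [second_derivative()].
#' @param low,high See [exclude_region()].
#' @param order `"derivative_first"` or `"exclude_first"`.
#' @return The processed [block()], with attribute
#'   `steps = c("derivative", "exclude")` (or the reverse).
#' @export
preprocess_spectra <- function(b, window = 15, polyorder = 2,
                               low = 1750, high = 2600,
                               order = c("derivative_first",
                                         "exclude_first")) {
  stopifnot(inherits(b, "block"))
  order <- match.arg(order)
  n <- nrow(b$matrix)
  rows <- vector("list", n)
  labels <- NULL
  for (i in seq_len(n)) {
    fp <- block_row(b, i, "FTIR")
    if (order == "derivative_first") {
      fp <- second_derivative(fp, window, polyorder)
      fl <- segments_flatten(exclude_region(fp, low, high))
    } else {
      ss <- exclude_region(fp, low, high)
      ss$segments <- lapply(ss$segments, second_derivative,
                            window = window, polyorder = polyorder)
      fl <- segments_flatten(ss)
    }
    rows[[i]] <- fl$values
    labels <- fl$labels
  }
  out <- block(do.call(rbind, rows), b$row_meta, labels, b$block_id)
  attr(out, "steps") <- if (order == "derivative_first") {
    c("derivative", "exclude")
  } else {
    c("exclude", "derivative")
  }
  out
}
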