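# Retention-time alignment of chromatographic fingerprints by correlation
# optimized warping (COW), with automated reference selection, a
# segment/slack grid search, and the data-reduction rules applied after
# alignment (keep one point in three, then discard everything up to and
# including 11 min).

#' Select the reference chromatogram
#'
#' The reference for alignment is the signal most similar to all others:
#' the one maximising the mean Pearson correlation with the remaining
#' signals. Ties break to the lowest index.
#'
#' @param signals A list of [fingerprint()]s on a common axis, or a
#'   samples-by-points numeric matrix.
#' @return Integer index (1-based) of the reference signal.
#' @export
select_reference <- function(signals) {
  M <- signals_matrix(signals)
  n <- nrow(M)
  if (n == 0) stop("empty signal list")
  if (n == 1) return(1L)
  C <- cor(t(M))
  score <- (rowSums(C) - 1) / (n - 1)
  unname(which.max(score))  # ties -> lowest index
}

signals_matrix <- function(signals) {
  if (is.matrix(signals)) return(signals)
  if (inherits(signals, "block")) return(signals$matrix)
  if (inherits(signals, "fingerprint")) signals <- list(signals)
  if (length(signals) == 0) stop("empty signal list")
  axes <- lapply(signals, function(s) s$axis)
  for (a in axes[-1]) {
    if (length(a) != length(axes[[1]]) ||
        max(abs(a - axes[[1]])) > 1e-9) {
      stop("all signals must share a common axis")
    }
  }
  do.call(rbind, lapply(signals, fp_values))
}

#' Align one signal to a reference by COW
#'
#' Divides the reference into segments of roughly `segment_length` points
#' and finds, by dynamic programming, the sample-boundary positions
#' (within `slack` points per segment, endpoints fixed) that maximise the
#' sum of segment-wise Pearson correlations after linear interpolation of
#' each sample segment onto its reference segment. The returned warp is
#' the global optimum of that discretised problem.
#'
#' @param signal,reference [fingerprint()]s (or numeric vectors) on
#'   uniform axes.
#' @param segment_length Nominal segment length in points (`>= slack + 2`).
#' @param slack Maximum boundary displacement per segment, in points.
#' @return An object of class `"cow_result"`: `warped` (a fingerprint on
#'   the reference axis), `segment_length`, `slack`, `boundary_map`
#'   (two-column matrix of source/target segment-boundary indices),
#'   `correlation` (overall Pearson correlation between warped signal and
#'   reference) and `score` (the DP objective, summed segment
#'   correlations).
#' @export
cow_align <- function(signal, reference, segment_length, slack) {
  xv <- fp_values(signal)
  rv <- fp_values(reference)
  if (slack < 0) stop("`slack` must be >= 0")
  if (segment_length < slack + 2) {
    stop("`segment_length` must be at least `slack` + 2")
  }
  if (segment_length > length(xv)) {
    stop("`segment_length` larger than the signal")
  }
  res <- cow_dp_cpp(xv, rv, as.integer(segment_length), as.integer(slack))
  warped <- if (inherits(reference, "fingerprint")) {
    meta <- if (inherits(signal, "fingerprint")) signal$meta else NULL
    fingerprint(reference$axis, res$warped, reference$channel, meta)
  } else {
    res$warped
  }
  structure(list(warped = warped,
                 segment_length = as.integer(segment_length),
                 slack = as.integer(slack),
                 boundary_map = cbind(source = res$source,
                                      target = res$target),
                 correlation = cor(res$warped, rv),
                 score = res$score,
                 n_segments = res$n_segments),
            class = "cow_result")
}

#' @export
print.cow_result <- function(x, ...) {
  cat(sprintf(
    "<cow_result> segment %d, slack %d, %d segments, correlation %.4f\n",
    x$segment_length, x$slack, x$n_segments, x$correlation))
  invisible(x)
}

default_search_grid <- function(segment_range, slack_range, grid) {
  if (grid == "full") {
    segs <- seq(segment_range[1], segment_range[2])
    sls <- seq(slack_range[1], slack_range[2])
  } else {
    segs <- unique(round(exp(seq(log(segment_range[1]),
                                 log(segment_range[2]), length.out = 6))))
    sls <- unique(round(seq(slack_range[1], slack_range[2],
                            length.out = 5)))
  }
  g <- expand.grid(segment = segs, slack = sls)
  g[g$segment >= g$slack + 2, , drop = FALSE]
}

#' Grid search for COW segment length and slack
#'
#' Evaluates candidate (segment length, slack) pairs and picks the one
#' maximising the mean post-warp correlation with the reference, subject
#' to a peak-preservation constraint: no sample's total (trapezoidal) area
#' may change by more than `area_tol` relative to its unwarped area. Ties
#' break to the smaller slack, then the larger segment (the less
#' aggressive warp). By default a coarse subgrid of the full
#' segment 10-200 x slack 1-20 space is scanned; `grid = "full"`
#' enumerates every pair.
#'
#' @param signals List of [fingerprint()]s (or a matrix) to align.
#' @param reference A [fingerprint()] or numeric vector (e.g. picked by
#'   [select_reference()]).
#' @param segment_range,slack_range Integer ranges `c(lo, hi)`.
#' @param area_tol Maximum allowed relative change in total signal area.
#' @param grid `"coarse"` (default) or `"full"`.
#' @param criterion `"correlation"` (default: mean post-warp correlation)
#'   or `"simplicity"`, a variant that discounts aggressive warps by the
#'   factor `1 - slack/segment`.
#' @param max_signals If set, only the first `max_signals` signals are used
#'   to score candidates (the chosen pair is then applied to all).
#' @return An object of class `"warp_search_result"` with `best_segment`,
#'   `best_slack`, and `score_grid` (one row per candidate: segment,
#'   slack, mean correlation, maximum relative area change, feasibility).
#' @export
grid_search_cow <- function(signals, reference,
                            segment_range = c(10, 200),
                            slack_range = c(1, 20),
                            area_tol = 0.05,
                            grid = c("coarse", "full"),
                            criterion = c("correlation", "simplicity"),
                            max_signals = NULL) {
  grid <- match.arg(grid)
  criterion <- match.arg(criterion)
  if (segment_range[1] > segment_range[2] || slack_range[1] > slack_range[2]) {
    stop("empty search range")
  }
  M <- signals_matrix(signals)
  rv <- fp_values(reference)
  if (!is.null(max_signals) && nrow(M) > max_signals) {
    M <- M[seq_len(max_signals), , drop = FALSE]
  }
  cand <- default_search_grid(segment_range, slack_range, grid)
  if (nrow(cand) == 0) stop("no feasible candidate in the search ranges")
  areas0 <- apply(M, 1, function(x) sum(abs(x)))
  cand$mean_correlation <- NA_real_
  cand$max_area_change <- NA_real_
  cand$feasible <- FALSE
  for (ci in seq_len(nrow(cand))) {
    ok <- TRUE
    cors <- numeric(nrow(M))
    dareas <- numeric(nrow(M))
    for (i in seq_len(nrow(M))) {
      r <- tryCatch(
        cow_dp_cpp(M[i, ], rv, cand$segment[ci], cand$slack[ci]),
        error = function(e) NULL)
      if (is.null(r)) { ok <- FALSE; break }
      cors[i] <- cor(r$warped, rv)
      dareas[i] <- abs(sum(abs(r$warped)) - areas0[i]) / areas0[i]
    }
    if (!ok) next
    cand$mean_correlation[ci] <- mean(cors)
    cand$max_area_change[ci] <- max(dareas)
    cand$feasible[ci] <- max(dareas) <= area_tol
  }
  feas <- cand[cand$feasible, , drop = FALSE]
  if (nrow(feas) == 0) {
    stop("search failed: every candidate violates the area-preservation ",
         "constraint (consider relaxing `area_tol`)")
  }
  score <- if (criterion == "correlation") {
    feas$mean_correlation
  } else {
    feas$mean_correlation * (1 - feas$slack / feas$segment)
  }
  # ties: smaller slack, then larger segment
  ord <- order(-score, feas$slack, -feas$segment)
  best <- feas[ord[1], ]
  structure(list(best_segment = best$segment,
                 best_slack = best$slack,
                 score_grid = cand,
                 criterion = criterion,
                 area_tol = area_tol),
            class = "warp_search_result")
}

#' @export
print.warp_search_result <- function(x, ...) {
  cat(sprintf(
    "<warp_search_result> best segment %d, slack %d (%d candidates, %s)\n",
    x$best_segment, x$best_slack, nrow(x$score_grid), x$criterion))
  invisible(x)
}

#' Reduce a fingerprint by keeping one point in three
#'
#' Keeps points 1, 4, 7, ... of both axis and values, so a 7201-point
#' chromatogram reduces to 2401 points and a 7801-point one to 2601.
#'
#' @param fp A [fingerprint()].
#' @return The reduced [fingerprint()], of length `ceiling(n / 3)`.
#' @export
bin_every_third <- function(fp) {
  n <- length(fp$values)
  if (n == 0) stop("empty signal")
  idx <- seq(1, n, by = 3)
  out <- fingerprint(fp$axis[idx], fp$values[idx], fp$channel, fp$meta)
  attributes(out) <- c(attributes(out),
                       attributes(fp)[setdiff(names(attributes(fp)),
                                              c("names", "class"))])
  out
}

#' Discard the initial unresolved region of a chromatogram
#'
#' Removes every point with retention time less than or equal to
#' `cutoff_min` (inclusive threshold), i.e. the early unseparated peaks
#' and baseline front. On the reduced grids this takes 2401 points to 1960
#' and 2601 to 2160.
#'
#' @param fp A [fingerprint()] with ascending time axis (minutes).
#' @param cutoff_min Retention-time cutoff in minutes.
#' @return The cropped [fingerprint()].
#' @export
crop_initial <- function(fp, cutoff_min = 11) {
  if (diff(fp$axis[1:2]) <= 0) stop("`crop_initial` needs an ascending axis")
  keep <- fp$axis > cutoff_min
  if (!any(keep)) stop("cutoff beyond the end of the axis: empty signal")
  fingerprint(fp$axis[keep], fp$values[keep], fp$channel, fp$meta)
}

#' Align, reduce and crop a chromatographic block
#'
#' The fixed preprocessing order for chromatographic data: COW alignment
#' to an automatically selected (or given) reference, then one-in-three
#' point reduction, then removal of the first `cutoff_min` minutes.
#'
#' @param b A [block()] of raw chromatograms (columns = retention times in
#'   minutes).
#' @param segment_length,slack COW parameters, used when `search` is
#'   `NULL`.
#' @param reference `"auto"` (use [select_reference()]) or an integer row
#'   index.
#' @param search Optional list of arguments for [grid_search_cow()] (e.g.
#'   `list(segment_range = c(10, 200), slack_range = c(1, 20),
#'   max_signals = 5)`); when given, the searched optimum replaces
#'   `segment_length`/`slack`.
#' @param cutoff_min Crop threshold in minutes.
#' @return A list of class `"chrom_prep"`: `block` (the processed block,
#'   with attribute `steps = c("align", "bin", "crop")`), `reference`
#'   (index), `segment_length`, `slack`, `correlations` (post-warp
#'   correlation of every sample with the reference), `mean_correlation`,
#'   and `search` (the [grid_search_cow()] result or `NULL`).
#' @export
align_bin_crop <- function(b, segment_length = 100, slack = 5,
                           reference = "auto", search = NULL,
                           cutoff_min = 11) {
  stopifnot(inherits(b, "block"))
  ref_idx <- if (identical(reference, "auto")) {
    select_reference(b$matrix)
  } else {
    as.integer(reference)
  }
  rv <- b$matrix[ref_idx, ]
  sr <- NULL
  if (!is.null(search)) {
    sr <- do.call(grid_search_cow,
                  c(list(signals = b$matrix, reference = rv), search))
    segment_length <- sr$best_segment
    slack <- sr$best_slack
  }
  warped <- matrix(NA_real_, nrow(b$matrix), length(rv))
  cors <- numeric(nrow(b$matrix))
  for (i in seq_len(nrow(b$matrix))) {
    r <- cow_dp_cpp(b$matrix[i, ], rv, as.integer(segment_length),
                    as.integer(slack))
    warped[i, ] <- r$warped
    cors[i] <- cor(r$warped, rv)
  }
  # reduction and crop are column subsets, applied to the whole block
  idx <- seq(1, ncol(warped), by = 3)
  axis <- b$col_labels[idx]
  keep <- axis > cutoff_min
  out <- block(warped[, idx[keep], drop = FALSE], b$row_meta, axis[keep],
               b$block_id)
  attr(out, "steps") <- c("align", "bin", "crop")
  structure(list(block = out, reference = ref_idx,
                 segment_length = as.integer(segment_length),
                 slack = as.integer(slack),
                 correlations = cors,
                 mean_correlation = mean(cors),
                 search = sr),
            class = "chrom_prep")
}

#' @export
print.chrom_prep <- function(x, ...) {
  cat(sprintf(
    "<chrom_prep> %s: segment %d, slack %d, mean r = %.4f, %d variables\n",
    x$block$block_id, x$segment_length, x$slack, x$mean_correlation,
    ncol(x$block$matrix)))
  invisible(x)
}
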