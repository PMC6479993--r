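# Synthetic study-shaped fingerprint generation.
#
# The generator emulates the sampling design of the authentication study:
# 78 sclerotia from 8 origins (10 each for classes 1-7, 8 for class 8),
# each peeled into an inner part and an epidermis, every sample measured on
# three channels (LC at 242 nm and 210 nm, ATR-FTIR). Chromatograms carry a
# per-run rigid retention-time shift (to exercise warping), a baseline
# concentrated before 11 min, and additive noise; spectra carry the band
# positions observed in the real material, two of which occur only in the
# epidermis.

.origins <- c("BC", "TD", "ZH", "DW", "CD", "YP", "MM", "BL")
.class_sizes <- c(10, 10, 10, 10, 10, 10, 10, 8)
.parts <- c("inner", "epidermis")
.channels <- c("LC242", "LC210", "FTIR")

#' Default FTIR band table
#'
#' Band centers follow the absorptions seen in the real material: C-H
#' stretches near 2964/2927/2873, carbonyls at 1704 (esters) and 1643
#' (triterpene C=O), methyl bends at 1452/1373, amide III near 1259, the
#' dominant polysaccharide envelope across 1200-950, and the C=CH2 bend at
#' 891 cm^-1, plus the broad O-H stretch around 3350 and a set of minor
#' unassigned fingerprint-region bands typical of crude botanical
#' material. The 2964 and 1704 bands occur only in the epidermis
#' (`cutis_only`). Widths and relative heights are generator choices, not
#' measured values.
#'
#' @return Data frame with columns `center`, `width` (cm^-1), `height`
#'   (relative), `cutis_only` (logical).
#' @export
default_bands <- function() {
  data.frame(
    center     = c(3350, 2964, 2927, 2873, 1704, 1643, 1560, 1452, 1415,
                   1373, 1315, 1259, 1205, 1150, 1080, 1030, 995, 940,
                   891, 845, 765, 705),
    width      = c(120, 10, 11, 10, 12, 15, 14, 10, 12, 10, 12, 12, 14,
                   40, 25, 18, 16, 12, 10, 12, 14, 12),
    height     = c(0.5, 0.35, 0.45, 0.3, 0.4, 0.5, 0.2, 0.3, 0.22, 0.28,
                   0.2, 0.25, 0.25, 0.85, 1.0, 0.95, 0.8, 0.25, 0.2,
                   0.15, 0.15, 0.12),
    cutis_only = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Simulation parameters for the synthetic study
#'
#' Bundles every knob of the generator. The defaults define the simulated
#' study conditions: run-to-run retention shifts with a 2 s standard
#' deviation, mild within-class intensity variation, and per-channel
#' between-class effects that include deliberately near-identical class
#' pairs, chosen so that each single technique confuses a different pair of
#' origins while their fusion separates all eight.
#'
#' @param rng_seed Integer seed that fixes the class templates (peak
#'   positions, widths, base heights, class effects). Changing it creates a
#'   different but equally structured synthetic study.
#' @param retention_shift_sd Standard deviation (seconds) of the rigid
#'   per-run retention-time shift.
#' @param stretch_sd Standard deviation of an optional mild linear axis
#'   stretch (relative; 0 disables it).
#' @param baseline_amp,baseline_tau Amplitude and decay constant (minutes)
#'   of the chromatographic baseline, an exponential concentrated before
#'   11 min (unresolved front) plus a small linear drift.
#' @param noise_sd Named vector of additive Gaussian noise standard
#'   deviations per channel (`LC242`, `LC210`, `FTIR`).
#' @param n_peaks Named vector: number of chromatographic peaks per LC
#'   channel.
#' @param class_sd Named vector: standard deviation of the log-scale
#'   between-class effect on peak/band heights per channel.
#' @param within_sd Named vector: standard deviation of the log-scale
#'   within-class (per-sample) height jitter per channel.
#' @param confusable Named list of two-column matrices; each row `(a, b)`
#'   makes class `b`'s template a near-copy of class `a`'s on that channel.
#' @param confusable_sd Log-scale standard deviation of the residual
#'   difference between confusable class pairs.
#' @param epidermis_sep_factor Multiplier (< 1) applied to `class_sd` for
#'   epidermis templates, making the epidermis less discriminative than the
#'   inner part.
#' @param intensity_sd Standard deviation of a per-sample global intensity
#'   factor (log scale), emulating loading/pathlength variation.
#' @param peak_shape `"gaussian"` (default) or `"emg"` (exponentially
#'   modified Gaussian) chromatographic peak shape.
#' @param emg_tau Exponential tail constant (minutes) for `"emg"` peaks.
#' @param band_shape `"gaussian"` (default) or `"lorentzian"` FTIR band
#'   shape.
#' @param bands FTIR band table, see [default_bands()].
#' @return An object of class `"sim_params"` (a validated list).
#' @export
sim_params <- function(rng_seed = 42,
                       retention_shift_sd = 2,
                       stretch_sd = 0,
                       baseline_amp = 2.0,
                       baseline_tau = 2.5,
                       noise_sd = c(LC242 = 0.003, LC210 = 0.003,
                                    FTIR = 0.002),
                       n_peaks = c(LC242 = 22, LC210 = 22),
                       class_sd = c(LC242 = 0.09, LC210 = 0.08,
                                    FTIR = 0.30),
                       within_sd = c(LC242 = 0.04, LC210 = 0.045,
                                     FTIR = 0.05),
                       confusable = list(LC242 = rbind(c(7, 8)),
                                         LC210 = rbind(c(2, 3), c(5, 6)),
                                         FTIR = rbind(c(4, 5))),
                       confusable_sd = 0.035,
                       epidermis_sep_factor = 0.6,
                       intensity_sd = 0.03,
                       peak_shape = c("gaussian", "emg"),
                       emg_tau = 0.08,
                       band_shape = c("gaussian", "lorentzian"),
                       bands = default_bands()) {
  peak_shape <- match.arg(peak_shape)
  band_shape <- match.arg(band_shape)
  expand <- function(v) {
    if (length(v) == 1 && is.null(names(v))) {
      v <- stats::setNames(rep(v, 3), .channels)
    }
    stopifnot(all(.channels %in% names(v)))
    v[.channels]
  }
  noise_sd <- expand(noise_sd)
  class_sd <- expand(class_sd)
  within_sd <- expand(within_sd)
  if (retention_shift_sd < 0) stop("`retention_shift_sd` must be >= 0")
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0")
  if (stretch_sd < 0) stop("`stretch_sd` must be >= 0")
  for (m in confusable) {
    if (!is.null(m) && (!is.matrix(m) || ncol(m) != 2)) {
      stop("`confusable` entries must be two-column matrices")
    }
  }
  structure(list(rng_seed = rng_seed,
                 retention_shift_sd = retention_shift_sd,
                 stretch_sd = stretch_sd,
                 baseline_amp = baseline_amp, baseline_tau = baseline_tau,
                 noise_sd = noise_sd, n_peaks = n_peaks,
                 class_sd = class_sd, within_sd = within_sd,
                 confusable = confusable, confusable_sd = confusable_sd,
                 epidermis_sep_factor = epidermis_sep_factor,
                 intensity_sd = intensity_sd,
                 peak_shape = peak_shape, emg_tau = emg_tau,
                 band_shape = band_shape, bands = bands),
            class = "sim_params")
}

#' Build the study design
#'
#' Returns the fixed sampling design: 78 sclerotia across 8 origin classes
#' (10 for classes 1-7, 8 for class 8), each contributing one inner-part
#' and one epidermis sample, 156 samples in total.
#'
#' @param seed Integer; accepted for interface uniformity with the other
#'   generators. The design is fixed, so any seed yields the same table.
#' @return Data frame with columns `sample_id`, `sclerotium_id`, `part`,
#'   `class_label`, `origin_abbrev`; 156 rows.
#' @examples
#' d <- make_design()
#' nrow(d)                          # 156
#' length(unique(d$sclerotium_id))  # 78
#' @export
make_design <- function(seed = 0) {
  rows <- lapply(seq_along(.origins), function(k) {
    n <- .class_sizes[k]
    scl <- sprintf("%s%02d", .origins[k], seq_len(n))
    data.frame(
      sample_id = paste0(rep(scl, each = 2), "-", rep(.parts, n)),
      sclerotium_id = rep(scl, each = 2),
      part = rep(.parts, n),
      class_label = k,
      origin_abbrev = .origins[k],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Axis builders -------------------------------------------------------------

chrom_axis <- function(part) {
  tmax <- if (part == "inner") 60 else 65  # minutes, 0.5 s sampling
  seq(0, tmax, by = 0.5 / 60)
}

ftir_axis <- function() seq(4000, 650, by = -2)

# Class templates ------------------------------------------------------------
# All template quantities derive deterministically from params$rng_seed, so
# two samples of the same class differ only through per-run effects.

part_code <- function(part) match(part, .parts)
channel_code <- function(channel) match(channel, .channels)

chrom_template <- function(channel, part, params) {
  n <- params$n_peaks[[channel]]
  tmax <- if (part == "inner") 60 else 65
  with_seed(child_seed(params$rng_seed, channel_code(channel),
                       part_code(part)), {
    positions <- sort(runif(n, 2, tmax - 2.5))
    widths <- runif(n, 0.12, 0.3)
    heights <- exp(runif(n, log(0.25), log(1)))
    sdc <- params$class_sd[[channel]] *
      if (part == "epidermis") params$epidermis_sep_factor else 1
    E <- matrix(rnorm(8 * n, 0, sdc), 8, n)
    conf <- params$confusable[[channel]]
    if (!is.null(conf)) {
      for (r in seq_len(nrow(conf))) {
        E[conf[r, 2], ] <- E[conf[r, 1], ] +
          rnorm(n, 0, params$confusable_sd)
      }
    }
    list(positions = positions, widths = widths, heights = heights,
         class_effects = E)
  })
}

ftir_template <- function(part, params) {
  bands <- params$bands
  n <- nrow(bands)
  with_seed(child_seed(params$rng_seed, channel_code("FTIR"),
                       part_code(part)), {
    heights <- bands$height
    if (part == "inner") heights[bands$cutis_only] <- 0
    sdc <- params$class_sd[["FTIR"]] *
      if (part == "epidermis") params$epidermis_sep_factor else 1
    E <- matrix(rnorm(8 * n, 0, sdc), 8, n)
    conf <- params$confusable[["FTIR"]]
    if (!is.null(conf)) {
      for (r in seq_len(nrow(conf))) {
        E[conf[r, 2], ] <- E[conf[r, 1], ] +
          rnorm(n, 0, params$confusable_sd)
      }
    }
    # bands absent from a part stay absent in every class
    E[, heights == 0] <- 0
    list(centers = bands$center, widths = bands$width, heights = heights,
         class_effects = E)
  })
}

peak_profile <- function(t, position, width, shape, emg_tau) {
  z <- (t - position) / width
  if (shape == "gaussian") {
    exp(-0.5 * z^2)
  } else {
    # exponentially modified Gaussian (tailing peak), exponent-safe form
    lam <- 1 / emg_tau
    arg <- lam / 2 * (lam * width^2 - 2 * (t - position))
    erfc_arg <- (lam * width^2 - (t - position)) / (sqrt(2) * width)
    0.5 * lam * width * sqrt(2 * pi) *
      exp(pmin(arg + stats::pnorm(erfc_arg, lower.tail = FALSE,
                                  log.p = TRUE), 50))
  }
}

band_profile <- function(w, center, width, shape) {
  z <- (w - center) / width
  if (shape == "gaussian") exp(-0.5 * z^2) else 1 / (1 + z^2)
}

chrom_baseline <- function(t, params, tmax) {
  params$baseline_amp *
    (exp(-t / params$baseline_tau) + 0.01 * (1 - t / tmax))
}

#' Simulate one chromatographic fingerprint
#'
#' Sum of class-templated peaks plus a rigid per-run retention shift, a
#' baseline concentrated before 11 min, and additive Gaussian noise. The
#' inner-part axis spans 0-60 min and the epidermis axis 0-65 min at 0.5 s
#' spacing (7201 and 7801 points).
#'
#' @param meta One row of [make_design()].
#' @param channel `"LC242"` or `"LC210"`.
#' @param params [sim_params()] object.
#' @param seed Integer seed for the per-run effects (shift, jitter, noise).
#' @return A [fingerprint()]; the drawn shift (seconds) and stretch are
#'   attached as attributes `shift_s` and `stretch`.
#' @export
simulate_chromatogram <- function(meta, channel, params = sim_params(),
                                  seed = 1) {
  if (!channel %in% c("LC242", "LC210")) {
    stop("`channel` must be LC242 or LC210; use simulate_spectrum() for FTIR")
  }
  part <- meta$part
  t <- chrom_axis(part)
  tmax <- t[length(t)]
  tpl <- chrom_template(channel, part, params)
  with_seed(seed, {
    shift_s <- rnorm(1, 0, params$retention_shift_sd)
    stretch <- if (params$stretch_sd > 0) rnorm(1, 0, params$stretch_sd) else 0
    scale_f <- exp(rnorm(1, 0, params$intensity_sd))
    h <- tpl$heights * exp(tpl$class_effects[meta$class_label, ] +
                             rnorm(length(tpl$heights), 0,
                                   params$within_sd[[channel]])) * scale_f
    noise <- rnorm(length(t), 0, params$noise_sd[[channel]])
    te <- (t - shift_s / 60) / (1 + stretch)
    v <- chrom_baseline(te, params, tmax)
    for (k in seq_along(h)) {
      v <- v + h[k] * peak_profile(te, tpl$positions[k], tpl$widths[k],
                                   params$peak_shape, params$emg_tau)
    }
    fp <- fingerprint(t, v + noise, channel, meta)
    attr(fp, "shift_s") <- shift_s
    attr(fp, "stretch") <- stretch
    fp
  })
}

#' Simulate one ATR-FTIR spectrum
#'
#' Sum of class- and part-templated absorption bands on a 4000-650 cm^-1
#' axis at 2 cm^-1 spacing (1676 points), plus a gentle sloping baseline
#' and additive noise. Bands flagged `cutis_only` (2964 and 1704 cm^-1)
#' have zero height for inner-part samples.
#'
#' @inheritParams simulate_chromatogram
#' @return A [fingerprint()] with channel `"FTIR"`.
#' @export
simulate_spectrum <- function(meta, params = sim_params(), seed = 1) {
  part <- meta$part
  w <- ftir_axis()
  tpl <- ftir_template(part, params)
  with_seed(seed, {
    scale_f <- exp(rnorm(1, 0, params$intensity_sd))
    jitter <- rnorm(length(tpl$heights), 0, params$within_sd[["FTIR"]])
    h <- tpl$heights *
      exp(tpl$class_effects[meta$class_label, ] + jitter) * scale_f
    h[tpl$heights == 0] <- 0
    noise <- rnorm(length(w), 0, params$noise_sd[["FTIR"]])
    v <- 0.01 * (w / 4000)
    for (k in seq_along(h)) {
      if (h[k] == 0) next
      v <- v + h[k] * band_profile(w, tpl$centers[k], tpl$widths[k],
                                   params$band_shape)
    }
    fingerprint(w, v + noise, "FTIR", meta)
  })
}

#' Simulate the full study
#'
#' Generates all six raw data blocks (LC242/LC210/FTIR for inner part and
#' epidermis). Within a part, all three channel blocks list samples in the
#' same (design) order, and the two LC channels of one sample share one
#' injection, hence one retention shift.
#'
#' @param params [sim_params()] object.
#' @param seed Integer master seed; fans out to per-sample child seeds.
#' @return List of class `"sim_study"` with elements `blocks` (named list
#'   of six [block()] objects, names like `"LC242-inner"`) and `meta` (the
#'   design table). Each chromatographic block carries the drawn per-run
#'   shifts (seconds) as attribute `shift_s`.
#' @export
simulate_study <- function(params = sim_params(), seed = 1) {
  design <- make_design(seed)
  blocks <- list()
  for (part in .parts) {
    rows <- design[design$part == part, , drop = FALSE]
    rownames(rows) <- NULL
    for (channel in .channels) {
      is_chrom <- channel != "FTIR"
      axis <- if (is_chrom) chrom_axis(part) else ftir_axis()
      M <- matrix(NA_real_, nrow(rows), length(axis))
      shifts <- numeric(nrow(rows))
      for (i in seq_len(nrow(rows))) {
        gidx <- match(rows$sample_id[i], design$sample_id)
        if (is_chrom) {
          # the shift seed depends on the sample only: both LC channels of
          # one injection share the shift; remaining draws differ per channel
          sfp <- with_seed(child_seed(seed, gidx, 0),
                           rnorm(1, 0, params$retention_shift_sd))
          fp <- shift_substitute(rows[i, ], channel, params,
                                 child_seed(seed, gidx,
                                            channel_code(channel)), sfp)
          M[i, ] <- fp$values
          shifts[i] <- attr(fp, "shift_s")
        } else {
          fp <- simulate_spectrum(rows[i, ], params,
                                  seed = child_seed(seed, gidx, 3))
          M[i, ] <- fp$values
        }
      }
      b <- block(M, rows, axis, paste0(channel, "-", part))
      if (is_chrom) attr(b, "shift_s") <- shifts
      blocks[[b$block_id]] <- b
    }
  }
  structure(list(blocks = blocks, meta = design), class = "sim_study")
}

# Regenerate a chromatogram with a given injection-level shift while keeping
# every other per-run draw tied to `seed`.
shift_substitute <- function(meta, channel, params, seed, shift_s) {
  part <- meta$part
  t <- chrom_axis(part)
  tmax <- t[length(t)]
  tpl <- chrom_template(channel, part, params)
  with_seed(seed, {
    rnorm(1)  # discard the channel-local shift draw
    stretch <- if (params$stretch_sd > 0) rnorm(1, 0, params$stretch_sd) else 0
    scale_f <- exp(rnorm(1, 0, params$intensity_sd))
    h <- tpl$heights * exp(tpl$class_effects[meta$class_label, ] +
                             rnorm(length(tpl$heights), 0,
                                   params$within_sd[[channel]])) * scale_f
    noise <- rnorm(length(t), 0, params$noise_sd[[channel]])
    te <- (t - shift_s / 60) / (1 + stretch)
    v <- chrom_baseline(te, params, tmax)
    for (k in seq_along(h)) {
      v <- v + h[k] * peak_profile(te, tpl$positions[k], tpl$widths[k],
                                   params$peak_shape, params$emg_tau)
    }
    fp <- fingerprint(t, v + noise, channel, meta)
    attr(fp, "shift_s") <- shift_s
    attr(fp, "stretch") <- stretch
    fp
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d samples, %d blocks:\n", nrow(x$meta),
              length(x$blocks)))
  for (b in x$blocks) {
    cat(sprintf("  %-16s %3d x %d\n", b$block_id, nrow(b$matrix),
                ncol(b$matrix)))
  }
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One CSV per block (first column the axis, one column per sample), a
#' metadata CSV and a JSON manifest.
#'
#' @param study A `"sim_study"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (b in study$blocks) {
    df <- data.frame(axis = b$col_labels, t(b$matrix))
    names(df) <- c("axis", b$row_meta$sample_id)
    f <- file.path(dir, paste0(b$block_id, ".csv"))
    write.csv(df, f, row.names = FALSE)
    files[b$block_id] <- basename(f)
  }
  meta_f <- file.path(dir, "sample_metadata.csv")
  write.csv(study$meta, meta_f, row.names = FALSE)
  manifest <- list(blocks = as.list(files),
                   metadata = basename(meta_f),
                   n_samples = nrow(study$meta))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
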