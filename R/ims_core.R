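# Imaging-MS datacube container and image-level operations. A dataset is one
# spectrum per pixel of a tissue section; an ion image is the spatial map of
# a single m/z signal's intensity, the primary readout used to localise
# injury-responsive proteins to cochlear substructures.

#' Construct an imaging-MS dataset
#'
#' @param coordinates Integer matrix with columns `row`, `col` (0-based,
#'   row-major), one row per pixel.
#' @param mz_axis Strictly increasing m/z values (Da) shared by all pixels
#'   (continuous-mode acquisition).
#' @param intensities Numeric matrix, pixels x m/z points, non-negative,
#'   rows aligned to `coordinates`.
#' @param pixel_pitch Centre-to-centre pixel distance, micrometers.
#' @param condition Condition label (e.g. "control", "112dB", "ouabain").
#' @return An `IMSDataset`.
#' @export
ims_dataset <- function(coordinates, mz_axis, intensities,
                        pixel_pitch = 50, condition = "unspecified") {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == 2L, is.numeric(mz_axis))
  if (any(diff(mz_axis) <= 0)) stop("mz_axis must be strictly increasing")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(coordinates)) {
    stop("one spectrum per coordinate required")
  }
  if (ncol(intensities) != length(mz_axis)) {
    stop("spectra must align to mz_axis")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  colnames(coordinates) <- c("row", "col")
  structure(
    list(coordinates = coordinates, mz_axis = as.numeric(mz_axis),
         intensities = intensities, pixel_pitch = pixel_pitch,
         condition = condition),
    class = "IMSDataset"
  )
}

#' Default acquisition axis
#'
#' Evenly spaced m/z axis over the linear-mode protein acquisition range
#' 2,000-20,000 Da.
#'
#' @param from,to Axis limits, Da.
#' @param step Axis spacing, Da.
#' @export
default_mz_axis <- function(from = 2000, to = 20000, step = 2) {
  seq(from, to, by = step)
}

#' @export
print.IMSDataset <- function(x, ...) {
  cat(sprintf(
    "IMSDataset: %d pixels, %d m/z points [%g, %g] Da, pitch %g um, condition '%s'\n",
    nrow(x$coordinates), length(x$mz_axis), min(x$mz_axis), max(x$mz_axis),
    x$pixel_pitch, x$condition))
  invisible(x)
}

# Grid dimensions implied by the coordinates (0-based).
.grid_shape <- function(dataset) {
  c(max(dataset$coordinates[, "row"]) + 1L,
    max(dataset$coordinates[, "col"]) + 1L)
}

#' Ion-density map at a chosen m/z
#'
#' Sums, for every pixel, the intensities at axis points within
#' `center_mz - tolerance` to `center_mz + tolerance` (closed window). Grid
#' cells with no acquired spectrum are `NA`. The default tolerance is 0.1%
#' of the centre m/z.
#'
#' @param dataset An `IMSDataset`.
#' @param center_mz Signal m/z, Da.
#' @param tolerance Window half-width, Da.
#' @return An `IonImage`: matrix `values` (rows x cols) plus the extraction
#'   parameters and the source condition.
#' @export
ion_image <- function(dataset, center_mz, tolerance = 0.001 * center_mz) {
  stopifnot(inherits(dataset, "IMSDataset"))
  sel <- dataset$mz_axis >= center_mz - tolerance &
    dataset$mz_axis <= center_mz + tolerance
  if (!any(sel)) {
    stop("extraction window [", center_mz - tolerance, ", ",
         center_mz + tolerance, "] is disjoint from the m/z axis")
  }
  pix <- rowSums(dataset$intensities[, sel, drop = FALSE])
  shape <- .grid_shape(dataset)
  values <- matrix(NA_real_, nrow = shape[1], ncol = shape[2])
  values[cbind(dataset$coordinates[, "row"] + 1L,
               dataset$coordinates[, "col"] + 1L)] <- pix
  structure(
    list(values = values, center_mz = center_mz, tolerance = tolerance,
         condition = dataset$condition),
    class = "IonImage"
  )
}

#' @export
print.IonImage <- function(x, ...) {
  cat(sprintf("IonImage: m/z %g +/- %g, %dx%d, condition '%s'\n",
              x$center_mz, x$tolerance, nrow(x$values), ncol(x$values),
              x$condition))
  invisible(x)
}

#' Mean spectrum over all pixels or a region mask
#'
#' @param dataset An `IMSDataset`.
#' @param region_mask Optional logical matrix (grid-shaped) or logical vector
#'   over pixels selecting the pixels to average.
#' @return Numeric vector aligned to `dataset$mz_axis`.
#' @export
mean_spectrum <- function(dataset, region_mask = NULL) {
  stopifnot(inherits(dataset, "IMSDataset"))
  if (is.null(region_mask)) {
    keep <- rep(TRUE, nrow(dataset$intensities))
  } else if (is.matrix(region_mask)) {
    keep <- region_mask[cbind(dataset$coordinates[, "row"] + 1L,
                              dataset$coordinates[, "col"] + 1L)]
  } else {
    keep <- as.logical(region_mask)
  }
  if (sum(keep) < 1L) stop("region mask selects no pixels")
  colMeans(dataset$intensities[keep, , drop = FALSE])
}

# Rolling-minimum baseline over a window expressed in Da.
.rolling_min_baseline <- function(spectrum, mz_axis, window_da = 200) {
  step <- stats::median(diff(mz_axis))
  half <- max(1L, as.integer(round(window_da / step / 2)))
  n <- length(spectrum)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    min(spectrum[lo:hi])
  }, numeric(1))
}

#' Pick peaks from a spectrum
#'
#' Local maxima whose baseline-subtracted height exceeds `snr_threshold`
#' times a robust noise estimate (1.4826 x MAD of the baseline-subtracted
#' spectrum), thinned greedily so retained centres are at least
#' `min_separation_da` apart, keeping the most intense first.
#'
#' @param spectrum Numeric intensity vector.
#' @param mz_axis Matching m/z axis, Da.
#' @param snr_threshold Signal-to-noise cutoff.
#' @param min_separation_da Minimum distance between reported centres, Da.
#' @param baseline_window_da Rolling-minimum baseline window, Da.
#' @param min_rel_intensity Discard peaks below this fraction of the tallest
#'   peak's baseline-subtracted height (0 disables; mean spectra averaged
#'   over many pixels can push spurious local maxima past a pure SNR gate).
#' @return Data frame with columns `mz`, `intensity` (baseline-subtracted),
#'   sorted by m/z; zero rows when nothing exceeds the threshold.
#' @export
pick_peaks <- function(spectrum, mz_axis, snr_threshold = 5,
                       min_separation_da = 10, baseline_window_da = 200,
                       min_rel_intensity = 0) {
  stopifnot(length(spectrum) == length(mz_axis), length(spectrum) > 0L)
  base <- .rolling_min_baseline(spectrum, mz_axis, baseline_window_da)
  sig <- spectrum - base
  noise <- 1.4826 * stats::mad(sig, constant = 1)
  empty <- data.frame(mz = numeric(0), intensity = numeric(0))
  if (noise <= 0) {
    # flat (or noise-free piecewise-flat) spectrum: no statistical support
    # for calling peaks against zero noise unless there is real structure
    noise <- 1.4826 * stats::mad(sig[sig > 0], constant = 1)
    if (!is.finite(noise) || noise <= 0) noise <- Inf
  }
  n <- length(sig)
  is_max <- sig > c(-Inf, sig[-n]) & sig >= c(sig[-1], -Inf)
  cand <- which(is_max & sig > snr_threshold * noise)
  if (length(cand) == 0L) return(empty)
  if (min_rel_intensity > 0) {
    cand <- cand[sig[cand] >= min_rel_intensity * max(sig[cand])]
  }
  cand <- cand[order(sig[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(mz_axis[i] - mz_axis[kept]) >= min_separation_da)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  data.frame(mz = mz_axis[kept], intensity = sig[kept])
}

#' Region-of-interest statistics of an ion image
#'
#' @param image An `IonImage`.
#' @param label_map A `PhantomLabelMap` (or character matrix of region codes
#'   with the image's shape).
#' @param region Region code to summarise.
#' @return An `RoiStats` list: `region`, `mean`, `max`, `n_pixels`.
#' @export
roi_stats <- function(image, label_map, region) {
  stopifnot(inherits(image, "IonImage"))
  labels <- if (inherits(label_map, "PhantomLabelMap")) label_map$labels else label_map
  stopifnot(all(dim(labels) == dim(image$values)))
  sel <- labels == region & !is.na(image$values)
  if (sum(sel) == 0L) stop("region '", region, "' has no pixels in the map")
  vals <- image$values[sel]
  structure(
    list(region = region, mean = mean(vals), max = max(vals),
         n_pixels = sum(sel)),
    class = "RoiStats"
  )
}

#' @export
print.RoiStats <- function(x, ...) {
  cat(sprintf("RoiStats[%s]: mean %.4g, max %.4g over %d pixels\n",
              x$region, x$mean, x$max, x$n_pixels))
  invisible(x)
}

#' Does signal density track injury severity?
#'
#' Spearman rank correlation between the severity ordering of the conditions
#' and the ROI mean ion density, plus a strict-increase flag. A rho of 1
#' with strict increase is the signature of an injury-responsive signal.
#'
#' @param roi_means Named numeric vector of ROI means, one per condition.
#' @param ordering Character vector of condition names from least to most
#'   severe; defaults to the names of `roi_means` in order.
#' @return List with `spearman_rho` and `is_strictly_increasing`.
#' @export
injury_monotonicity <- function(roi_means, ordering = names(roi_means)) {
  if (length(ordering) < 3L) stop("need at least 3 conditions")
  means <- roi_means[ordering]
  if (anyNA(means)) stop("undefined ROI mean for some condition")
  rho <- stats::cor(seq_along(means), means, method = "spearman")
  list(spearman_rho = unname(rho),
       is_strictly_increasing = all(diff(means) > 0))
}

#' Do two observed m/z values name the same signal?
#'
#' Across acquisitions at different spatial resolutions the same protein
#' signal drifts by a few Da (e.g. 5456 in a 50 um scan vs 5458 at 10-15 um).
#' Two values match when their relative difference is within `rel_tolerance`.
#'
#' @param mz_a,mz_b Observed m/z values, Da.
#' @param rel_tolerance Relative tolerance; the default 5e-4 unifies the
#'   cross-run label pairs seen in practice without merging distinct signals.
#' @return Logical.
#' @export
match_signals <- function(mz_a, mz_b, rel_tolerance = 5e-4) {
  if (mz_a <= 0 || mz_b <= 0) stop("m/z values must be positive")
  abs(mz_a - mz_b) / max(mz_a, mz_b) <= rel_tolerance
}

#' An m/z signal of interest with cross-run aliases
#'
#' @param canonical_mz The 50-um-scan m/z value used for querying.
#' @param aliases Values observed for the same signal in other runs; each
#'   must satisfy [match_signals()] against the canonical value.
#' @param delta Window half-width used for the MW query, Da.
#' @param rel_tolerance Alias tolerance, see [match_signals()].
#' @return An `MzSignal` with its `MwWindow`.
#' @export
mz_signal <- function(canonical_mz, aliases = numeric(0), delta = 1000,
                      rel_tolerance = 5e-4) {
  for (a in aliases) {
    if (!match_signals(canonical_mz, a, rel_tolerance)) {
      stop("alias ", a, " is not within tolerance of ", canonical_mz)
    }
  }
  structure(
    list(canonical_mz = canonical_mz, aliases = aliases,
         window = mw_window(canonical_mz, delta)),
    class = "MzSignal"
  )
}

#' Overlay several ion images into an RGB composite
#'
#' Each image is max-normalised to [0, 1], tinted with its assigned colour,
#' and composited by per-channel maximum — the standard multi-signal overlay
#' used to compare the localisation of candidate proteins.
#'
#' @param images List of `IonImage`s sharing one grid.
#' @param colors Colour per image (any form `grDevices::col2rgb` accepts).
#' @return Numeric array rows x cols x 3 with values in [0, 1]; `NA` pixels
#'   are treated as zero.
#' @export
overlay <- function(images, colors) {
  stopifnot(length(images) >= 1L, length(colors) == length(images))
  dims <- dim(images[[1]]$values)
  comp <- array(0, dim = c(dims, 3L))
  for (k in seq_along(images)) {
    v <- images[[k]]$values
    if (!all(dim(v) == dims)) stop("images must share one grid")
    v[is.na(v)] <- 0
    m <- max(v)
    if (m > 0) v <- v / m
    rgb <- grDevices::col2rgb(colors[[k]])[, 1] / 255
    for (ch in 1:3) comp[, , ch] <- pmax(comp[, , ch], v * rgb[ch])
  }
  comp
}
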