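#' Preprocessing configuration
#'
#' Holds the constants of the spectral preprocessing chain.  Defaults
#' follow common 1D 1H NMR practice for biofluids: the analysis window is
#' 0.5--9.5 ppm, the residual water signal at 4.5--5.2 ppm is removed,
#' intensities are averaged into 0.0008-ppm bins, the baseline level is
#' estimated from the signal-free edges of the spectrum (below -3 ppm and
#' above 12.5 ppm), and intensities are normalized to the area of the
#' reference (DSS/TSP) peak at 0 ppm.
#'
#' @param window length-2 numeric, analysis window in ppm (inclusive).
#' @param water_region length-2 numeric, region removed (inclusive).
#' @param bin_width bin width in ppm, > 0.
#' @param baseline_edges length-2 numeric `c(lo, hi)`: points with
#'   ppm < `lo` or ppm > `hi` are treated as signal-free baseline.
#' @param reference_ppm center of the reference peak (ppm).
#' @param reference_halfwindow half-width of the integration window around
#'   `reference_ppm`, in ppm.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(window = c(0.5, 9.5),
                              water_region = c(4.5, 5.2),
                              bin_width = 0.0008,
                              baseline_edges = c(-3, 12.5),
                              reference_ppm = 0,
                              reference_halfwindow = 0.05) {
  stopifnot(length(window) == 2L, window[1] < window[2],
            length(water_region) == 2L,
            is.numeric(bin_width), bin_width > 0,
            length(baseline_edges) == 2L,
            baseline_edges[1] < baseline_edges[2],
            reference_halfwindow > 0)
  structure(list(window = as.numeric(window),
                 water_region = as.numeric(water_region),
                 bin_width = as.numeric(bin_width),
                 baseline_edges = as.numeric(baseline_edges),
                 reference_ppm = as.numeric(reference_ppm),
                 reference_halfwindow = as.numeric(reference_halfwindow)),
            class = "preprocess_config")
}

#' Subtract a constant baseline estimated from the spectrum edges
#'
#' The baseline level is the mean intensity over the pooled signal-free
#' edge regions (up-field of `baseline_edges[1]`, down-field of
#' `baseline_edges[2]`); this single constant is subtracted everywhere.
#' Applying the step twice is a no-op on the second pass, since the edge
#' mean of the output is zero.
#'
#' @param s an [nmr_spectrum()].
#' @param cfg a [preprocess_config()].
#' @return The baseline-corrected spectrum.
#' @export
baseline_correct <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "nmr_spectrum"))
  edge <- s$ppm < cfg$baseline_edges[1] | s$ppm > cfg$baseline_edges[2]
  if (!any(edge))
    stop("no points up-field of ", cfg$baseline_edges[1], " ppm or ",
         "down-field of ", cfg$baseline_edges[2], " ppm; the axis does not ",
         "cover the baseline edge regions -- skip the baseline step for ",
         "this spectrum")
  s$intensity <- s$intensity - mean(s$intensity[edge])
  s
}

#' Normalize a spectrum to the reference-peak area
#'
#' Divides the whole intensity vector by the trapezoidal integral of the
#' window `reference_ppm` +/- `reference_halfwindow` (the DSS/TSP peak at
#' 0 ppm).  After normalization the reference integral equals 1, so
#' spectra acquired at different receiver gains or reference amounts
#' become comparable.  Area is used rather than peak height for noise
#' robustness.
#'
#' @inheritParams baseline_correct
#' @return The normalized spectrum.
#' @export
normalize_to_reference <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "nmr_spectrum"))
  idx <- ppm_window_idx(s, cfg$reference_ppm - cfg$reference_halfwindow,
                        cfg$reference_ppm + cfg$reference_halfwindow)
  if (length(idx) < 2L)
    stop("reference window ", cfg$reference_ppm, " +/- ",
         cfg$reference_halfwindow, " ppm contains fewer than 2 points")
  area <- pracma::trapz(s$ppm[idx], s$intensity[idx])
  if (!is.finite(area) || area <= 0)
    stop("no reference peak detected: integral over ", cfg$reference_ppm,
         " +/- ", cfg$reference_halfwindow, " ppm is ", signif(area, 4))
  s$intensity <- s$intensity / area
  s
}

#' Restrict to the analysis window and remove the water region
#'
#' Keeps points with ppm inside `window` (inclusive) and drops points
#' inside `water_region` (inclusive).
#'
#' @inheritParams baseline_correct
#' @return The masked spectrum.
#' @export
mask_regions <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "nmr_spectrum"))
  keep <- s$ppm >= cfg$window[1] & s$ppm <= cfg$window[2] &
    !(s$ppm >= cfg$water_region[1] & s$ppm <= cfg$water_region[2])
  if (sum(keep) < 2L)
    stop("masking left fewer than 2 points; check `window` and ",
         "`water_region` against the spectrum axis")
  s$ppm <- s$ppm[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Bin a spectrum into fixed-width ppm sections
#'
#' Intensities are averaged over half-open bins `[left, left + bin_width)`
#' anchored at the lowest retained ppm value; the output axis is the bin
#' centers.  A point falling exactly on the upper edge of the last bin is
#' assigned to that bin, and a partial trailing bin is kept when it
#' contains at least one point.  Empty interior bins (possible after water
#' removal) are dropped.
#'
#' @inheritParams baseline_correct
#' @return The binned spectrum.
#' @export
bin_spectrum <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "nmr_spectrum"))
  w <- cfg$bin_width
  step <- min(diff(s$ppm))
  if (w < step - 1e-12)
    stop("bin_width (", w, " ppm) is smaller than the native grid step (",
         signif(step, 6), " ppm)")
  left <- min(s$ppm)
  span <- max(s$ppm) - left
  nbin <- floor(span / w + 1e-9)
  if (span - nbin * w > 1e-9 * w) nbin <- nbin + 1L
  nbin <- max(nbin, 1L)
  idx <- pmin(floor((s$ppm - left) / w + 1e-9), nbin - 1L)
  f <- factor(idx, levels = 0:(nbin - 1L))
  means <- tapply(s$intensity, f, mean)
  centers <- left + (as.numeric(levels(f)) + 0.5) * w
  keep <- !is.na(means)
  nmr_spectrum(centers[keep], as.numeric(means[keep]), meta = s$meta)
}

#' Align a spectrum to a reference by FFT cross-correlation
#'
#' Estimates the global chemical-shift offset between `s` and `reference`
#' as the circular-cross-correlation maximizer within `+/- max_shift` ppm
#' (computed via FFT), then applies the opposite circular shift to `s`.
#' Positive estimated shift means `s` sits at higher ppm than the
#' reference.  Both spectra must share the same grid.
#'
#' @param s spectrum to align.
#' @param reference reference spectrum on the same ppm grid.
#' @param max_shift largest allowed |shift| in ppm.
#' @return A list with `spectrum` (aligned) and `shift_ppm` (the
#'   estimated offset of `s` relative to `reference`).
#' @export
align_fft <- function(s, reference, max_shift = 0.02) {
  stopifnot(inherits(s, "nmr_spectrum"), inherits(reference, "nmr_spectrum"))
  if (length(s$ppm) != length(reference$ppm) ||
      max(abs(s$ppm - reference$ppm)) > 1e-9)
    stop("`s` and `reference` are not on the same ppm grid")
  n <- length(s$intensity)
  step <- mean(diff(s$ppm))
  cc <- Re(fft(fft(s$intensity) * Conj(fft(reference$intensity)),
               inverse = TRUE)) / n
  lags <- 0:(n - 1)
  lags[lags > n / 2] <- lags[lags > n / 2] - n
  ok <- abs(lags) * step <= max_shift + step / 2
  if (!any(ok)) ok <- lags == 0
  cand <- which(ok)
  best <- cand[which.max(cc[cand])]
  lag <- lags[best]
  if (lag != 0) {
    shift_idx <- ((seq_len(n) - 1 + lag) %% n) + 1  # undo the offset
    s$intensity <- s$intensity[shift_idx]
  }
  list(spectrum = s, shift_ppm = lag * step)
}

#' Run the default preprocessing chain
#'
#' Applies, in order: baseline subtraction, reference normalization,
#' optional alignment to a reference spectrum, window/water masking and
#' binning.  The order of the baseline and normalization steps can be
#' swapped via `steps`; both orders give spectra whose reference integral
#' is 1, and each of the two steps is idempotent on a second pass.
#'
#' @param s an [nmr_spectrum()].
#' @param cfg a [preprocess_config()].
#' @param reference optional [nmr_spectrum()] used by the alignment step.
#' @param steps character vector, an ordered subset of
#'   `c("baseline", "normalize", "align", "mask", "bin")`.
#' @param max_shift passed to [align_fft()].
#' @return The preprocessed spectrum.
#' @export
preprocess_spectrum <- function(s, cfg = preprocess_config(),
                                reference = NULL,
                                steps = c("baseline", "normalize", "align",
                                          "mask", "bin"),
                                max_shift = 0.02) {
  allowed <- c("baseline", "normalize", "align", "mask", "bin")
  bad <- setdiff(steps, allowed)
  if (length(bad)) stop("unknown preprocessing step(s): ",
                        paste(bad, collapse = ", "))
  for (st in steps) {
    s <- switch(st,
      baseline = baseline_correct(s, cfg),
      normalize = normalize_to_reference(s, cfg),
      align = if (is.null(reference)) s else
        align_fft(s, reference, max_shift)$spectrum,
      mask = mask_regions(s, cfg),
      bin = bin_spectrum(s, cfg))
  }
  s
}
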