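#' Continuous multichannel EEG recording
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param sfreq Sampling rate in Hz; must exceed twice the highest analysis
#'   frequency (100 Hz).
#' @param labels 10/20-system channel labels, one per row of `samples`.
#' @param condition Recording condition, `"eyes_open"` or `"eyes_closed"`.
#' @param subject Subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sfreq, labels,
                          condition = c("eyes_open", "eyes_closed"),
                          subject = "S1") {
  condition <- match.arg(condition)
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), sfreq > 200,
            length(labels) == nrow(samples), !anyDuplicated(labels))
  rownames(samples) <- labels
  structure(list(samples = samples, sfreq = sfreq, labels = labels,
                 condition = condition, subject = subject),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d channels x %.1f s @ %g Hz\n",
              x$subject, x$condition, nrow(x$samples),
              ncol(x$samples) / x$sfreq, x$sfreq))
  invisible(x)
}

#' Canonical frequency-band scheme
#'
#' The six analysis bands: delta (< 4 Hz), theta (4-8), alpha (9-14),
#' beta (14-30), low gamma (31-55), high gamma (65-100). Bins are assigned by
#' half-open intervals `[low, high)` so the 14 Hz edge belongs to beta;
#' delta starts at the lowest nonzero bin (DC is excluded), and the top band
#' is closed at 100 Hz. The printed 8-9, 30-31 and 55-65 Hz gaps belong to no
#' band.
#'
#' @return Data frame with columns `band`, `low`, `high`.
#' @export
band_scheme <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"),
             low  = c(0, 4, 9, 14, 31, 65),
             high = c(4, 8, 14, 30, 55, 100),
             stringsAsFactors = FALSE)
}

#' Scalp-region scheme for a 32-channel 10/20 cap
#'
#' Default mapping of channel labels to the 8 summary regions (left/middle/
#' right frontal, left/right temporal, central, parietal, occipital). Fully
#' overridable: supply any named list of label vectors to the summarization
#' and pipeline functions.
#'
#' @return Named list mapping region name to channel labels.
#' @export
region_scheme <- function() {
  list(left_frontal   = c("Fp1", "F3", "F7", "FC5"),
       middle_frontal = c("Fz", "FC1", "FC2"),
       right_frontal  = c("Fp2", "F4", "F8", "FC6"),
       left_temporal  = c("T7", "TP9", "CP5"),
       central        = c("C3", "Cz", "C4", "CP1", "CP2"),
       right_temporal = c("T8", "TP10", "CP6"),
       parietal       = c("P3", "Pz", "P4", "P7", "P8"),
       occipital      = c("O1", "Oz", "O2"))
}

#' All channel labels of the default montage
#' @return Character vector of the 30 scalp labels in [region_scheme()].
#' @export
default_montage <- function() unname(unlist(region_scheme()))

#' Filter a continuous recording
#'
#' Zero-phase (forward-backward) filtering: order-2 Butterworth high-pass at
#' `low` Hz, order-4 Butterworth low-pass at `high` Hz, and an order-2
#' Butterworth band-stop over `notch` to suppress mains interference. The
#' stages are applied separately for numerical stability at high sampling
#' rates. Forward-backward application doubles the attenuation and cancels
#' group delay.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band-pass edges in Hz (defaults 0.2 and 150).
#' @param notch Two-element stop band in Hz (default `c(59, 61)`), or `NULL`
#'   to skip.
#' @return The filtered `eeg_recording`.
#' @export
preprocess <- function(rec, low = 0.2, high = 150, notch = c(59, 61)) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (high >= nyq)
    stop(sprintf("sampling rate %g Hz too low for %g Hz low-pass cutoff",
                 rec$sfreq, high))
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  bs <- if (!is.null(notch)) signal::butter(2, notch / nyq, type = "stop")
  x <- rec$samples
  for (ch in seq_len(nrow(x))) {
    y <- signal::filtfilt(hp, x[ch, ])
    y <- signal::filtfilt(lp, y)
    if (!is.null(bs)) y <- signal::filtfilt(bs, y)
    x[ch, ] <- y
  }
  rec$samples <- x
  rec
}

#' Segment a recording into fixed-length epochs
#'
#' @param rec An [eeg_recording()].
#' @param duration_ms Epoch length in milliseconds (default 2500).
#' @return An object of class `eeg_epochs`: array `data`
#'   (trials x channels x samples), `mask` (trials x channels logical,
#'   `TRUE` = rejected), plus sampling metadata. The trailing remainder of
#'   the recording is discarded.
#' @export
epoch <- function(rec, duration_ms = 2500) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(duration_ms / 1000 * rec$sfreq)
  n_trials <- ncol(rec$samples) %/% len
  if (n_trials < 1L)
    stop(sprintf("recording too short for a single %g ms epoch", duration_ms))
  n_ch <- nrow(rec$samples)
  data <- array(NA_real_, dim = c(n_trials, n_ch, len))
  for (tr in seq_len(n_trials))
    data[tr, , ] <- rec$samples[, ((tr - 1L) * len + 1L):(tr * len)]
  structure(list(data = data, sfreq = rec$sfreq, labels = rec$labels,
                 duration_ms = duration_ms,
                 mask = matrix(FALSE, n_trials, n_ch),
                 condition = rec$condition, subject = rec$subject),
            class = "eeg_epochs")
}

#' Statistical artifact rejection
#'
#' Flags trial-channel cells whose amplitude statistics are extreme relative
#' to the rest of the data. Per cell, the mean amplitude and the
#' log-variance are computed; each statistic is z-scored over the surviving
#' cells and a cell is rejected when either `|z|` exceeds `z_thresh`. The
#' procedure runs for `rounds` passes, recomputing the reference mean/SD on
#' survivors, so gross artifacts do not shelter milder ones. A zero-spread
#' guard flags nothing when a statistic is constant. The mask grows
#' monotonically.
#'
#' @param epochs An [epoch()] result.
#' @param z_thresh Rejection threshold in SD units (default 3).
#' @param rounds Number of passes (default 2).
#' @return `epochs` with an updated rejection mask.
#' @export
reject_artifacts <- function(epochs, z_thresh = 3, rounds = 2) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_trials <- dim(epochs$data)[1L]
  if (n_trials < 4L) stop("artifact rejection needs at least 4 epochs")
  mu <- apply(epochs$data, c(1L, 2L), mean)
  lv <- log(apply(epochs$data, c(1L, 2L), stats::var))
  mask <- epochs$mask
  for (r in seq_len(rounds)) {
    for (stat in list(mu, lv)) {
      s <- stat[!mask]
      if (length(s) < 2L) break
      centre <- mean(s); spread <- stats::sd(s)
      if (!is.finite(spread) || spread == 0) next
      mask <- mask | (abs(stat - centre) > z_thresh * spread)
    }
  }
  if (all(mask)) stop("no clean data: every trial/channel rejected")
  epochs$mask <- mask
  epochs
}

## Hann taper; rectangular available for diagnostic use
taper_window <- function(n, taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  else rep(1, n)
}

#' Welch relative power spectral density
#'
#' Splits each clean epoch into non-overlapping windows of half the epoch
#' length (1250 ms for 2500 ms epochs), computes a tapered periodogram per
#' window and channel, and normalizes each window's spectrum so the bins in
#' `(0, fmax]` Hz sum to one (relative PSD). The frequency resolution is the
#' reciprocal of the window duration (0.8 Hz at 1250 ms). Windows do not
#' overlap, so potentially non-adjacent surviving epochs never share samples.
#'
#' @param epochs An [epoch()] (ideally after [reject_artifacts()]).
#' @param n_windows_per_epoch Windows per epoch (default 2 = half-length).
#' @param fmax Normalization ceiling in Hz (default 100).
#' @param taper `"hann"` (default) or `"rectangular"`.
#' @return An object of class `spectral_windows`: `psd` array
#'   (windows x channels x bins; `NA` where the source cell was rejected),
#'   `freqs`, `mean_psd` (channels x bins, the per-subject Welch average),
#'   `bin_resolution`, `window_sec`, `epoch_of_window`.
#' @export
welch_relative_psd <- function(epochs, n_windows_per_epoch = 2, fmax = 100,
                               taper = "hann") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dims <- dim(epochs$data)
  n_trials <- dims[1L]; n_ch <- dims[2L]; n_samp <- dims[3L]
  win_len <- n_samp %/% n_windows_per_epoch
  window_sec <- win_len / epochs$sfreq
  freqs_all <- (0:(win_len %/% 2)) / window_sec
  keep_bins <- freqs_all > 0 & freqs_all <= fmax
  if (!any(keep_bins)) stop("no frequency bins at or below fmax")
  freqs <- freqs_all[keep_bins]
  w <- taper_window(win_len, taper)

  n_win <- n_trials * n_windows_per_epoch
  psd <- array(NA_real_, dim = c(n_win, n_ch, length(freqs)))
  epoch_of_window <- rep(seq_len(n_trials), each = n_windows_per_epoch)
  any_clean <- FALSE
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      if (epochs$mask[tr, ch]) next
      any_clean <- TRUE
      for (k in seq_len(n_windows_per_epoch)) {
        seg <- epochs$data[tr, ch, ((k - 1L) * win_len + 1L):(k * win_len)]
        spec <- Mod(stats::fft((seg - mean(seg)) * w))^2
        pw <- spec[seq_along(freqs_all)][keep_bins]
        tot <- sum(pw)
        psd[(tr - 1L) * n_windows_per_epoch + k, ch, ] <-
          if (tot > 0) pw / tot else pw
      }
    }
  }
  if (!any_clean) stop("no clean epochs to estimate spectra from")
  mean_psd <- apply(psd, c(2L, 3L), mean, na.rm = TRUE)
  rownames(mean_psd) <- epochs$labels
  structure(list(psd = psd, freqs = freqs, mean_psd = mean_psd,
                 bin_resolution = 1 / window_sec, window_sec = window_sec,
                 labels = epochs$labels, epoch_of_window = epoch_of_window,
                 condition = epochs$condition, subject = epochs$subject),
            class = "spectral_windows")
}

## Frequency-bin membership of a band: [low, high), closed at the top for
## the band ending at the normalization ceiling.
band_bins <- function(freqs, low, high, fmax = 100) {
  sel <- freqs >= low & (freqs < high | (high >= fmax & freqs <= high))
  if (!any(sel))
    stop(sprintf("band [%g, %g) contains no frequency bins", low, high))
  sel
}

#' Mean band power
#'
#' Arithmetic mean of the relative PSD bins inside a band, computed from the
#' per-subject mean spectrum, per channel.
#'
#' @param sw A [welch_relative_psd()] result.
#' @param low,high Band edges in Hz (see [band_scheme()] for edge semantics).
#' @return Named numeric vector, one MBP value per channel (`NA` for channels
#'   with no clean windows).
#' @export
mean_band_power <- function(sw, low, high) {
  stopifnot(inherits(sw, "spectral_windows"))
  sel <- band_bins(sw$freqs, low, high)
  stats::setNames(rowMeans(sw$mean_psd[, sel, drop = FALSE]), sw$labels)
}

#' Mean absolute deviation
#'
#' `mean(|x - mean(x)|)` — the dispersion measure used for dominant-frequency
#' variability, chosen over the standard deviation to damp outlier windows.
#'
#' @param x Numeric vector.
#' @return Nonnegative scalar.
#' @export
mean_abs_deviation <- function(x) mean(abs(x - mean(x)))

#' Dominant-frequency variability
#'
#' Per channel: in every clean spectral window, the frequency bin holding
#' maximal power within the band is the dominant frequency; DFV is the mean
#' absolute deviation of those frequencies across windows. It indexes the
#' stability of the band's oscillatory peak and is invariant to positive
#' rescaling of the signal.
#'
#' @inheritParams mean_band_power
#' @return Named numeric vector, one DFV value (Hz) per channel (`NA` for
#'   channels with fewer than 2 clean windows).
#' @export
dominant_frequency_variability <- function(sw, low, high) {
  stopifnot(inherits(sw, "spectral_windows"))
  sel <- band_bins(sw$freqs, low, high)
  f_band <- sw$freqs[sel]
  n_ch <- dim(sw$psd)[2L]
  if (sum(!is.na(sw$psd[, , 1L])) < 2L)
    stop("dominant-frequency variability needs at least 2 clean windows")
  out <- vapply(seq_len(n_ch), function(ch) {
    p <- sw$psd[, ch, sel, drop = FALSE]
    valid <- which(!is.na(p[, 1L, 1L]))
    if (length(valid) < 2L) return(NA_real_)
    dom <- f_band[apply(p[valid, 1L, , drop = FALSE], 1L, which.max)]
    mean_abs_deviation(dom)
  }, numeric(1L))
  stats::setNames(out, sw$labels)
}

#' Average per-channel features over scalp regions
#'
#' @param values Named numeric vector of per-channel feature values (names =
#'   channel labels; `NA` entries — e.g. fully rejected channels — are
#'   excluded from the mean).
#' @param regions Named list mapping region names to channel labels
#'   (default [region_scheme()]).
#' @return Named numeric vector, one value per region.
#' @export
summarize_regions <- function(values, regions = region_scheme()) {
  stopifnot(!is.null(names(values)))
  vapply(regions, function(chs) {
    miss <- setdiff(chs, names(values))
    if (length(miss))
      stop("region channel(s) absent from montage: ",
           paste(miss, collapse = ", "))
    v <- values[chs]
    if (all(is.na(v))) {
      warning("region has no surviving channel; returning NA")
      return(NA_real_)
    }
    mean(v, na.rm = TRUE)
  }, numeric(1L))
}

#' Floor for zero dominant-frequency variability before log transform
#'
#' The smallest nonzero DFV observable from `n_windows` dominant frequencies
#' on a grid of spacing `bin_resolution` is `2 r (n-1) / n^2` (one window one
#' bin away from the rest); the floor is half that, keeping the natural log
#' finite while staying below any observable value.
#'
#' @param bin_resolution Frequency-bin spacing in Hz.
#' @param n_windows Number of spectral windows.
#' @return Positive scalar floor in Hz.
#' @export
dfv_floor <- function(bin_resolution, n_windows) {
  stopifnot(bin_resolution > 0, n_windows >= 2)
  bin_resolution * (n_windows - 1) / n_windows^2
}

#' Extract the qEEG feature table from one recording
#'
#' Runs the spectral stage end to end: band-wise mean band power and
#' dominant-frequency variability per channel, then region averaging.
#'
#' @param sw A [welch_relative_psd()] result.
#' @param bands Band scheme data frame (default [band_scheme()]).
#' @param regions Region scheme (default [region_scheme()]).
#' @return Data frame with columns `subject`, `condition`, `region`, `band`,
#'   `mbp`, `dfv` (linear scale; see [log_transform()]). Attributes
#'   `bin_resolution` and `n_windows` record the spectral grid.
#' @export
feature_table <- function(sw, bands = band_scheme(), regions = region_scheme()) {
  stopifnot(inherits(sw, "spectral_windows"))
  rows <- lapply(seq_len(nrow(bands)), function(bi) {
    mbp <- summarize_regions(
      mean_band_power(sw, bands$low[bi], bands$high[bi]), regions)
    dfv <- summarize_regions(
      dominant_frequency_variability(sw, bands$low[bi], bands$high[bi]),
      regions)
    data.frame(subject = sw$subject, condition = sw$condition,
               region = names(regions), band = bands$band[bi],
               mbp = unname(mbp), dfv = unname(dfv),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "bin_resolution") <- sw$bin_resolution
  attr(out, "n_windows") <- sum(!is.na(sw$psd[, , 1L])) /
    max(1L, sum(apply(!is.na(sw$psd[, , 1L]), 2L, any)))
  attr(out, "log_transformed") <- FALSE
  out
}

#' Natural-log transform of a feature table
#'
#' Applied before FBAT testing to better approximate normality. Relative MBP
#' lies in (0, 1) and is logged directly; a DFV of exactly 0 (a perfectly
#' stable peak) is floored via [dfv_floor()] so the log stays finite.
#'
#' @param features A [feature_table()] data frame.
#' @param floor DFV floor in Hz; default derived from the table's spectral
#'   grid attributes.
#' @return The table with `mbp` and `dfv` replaced by their natural logs and
#'   the `log_transformed` attribute set.
#' @export
log_transform <- function(features, floor = NULL) {
  stopifnot(is.data.frame(features), all(c("mbp", "dfv") %in% names(features)))
  if (isTRUE(attr(features, "log_transformed")))
    stop("feature table is already log transformed")
  if (any(features$mbp <= 0, na.rm = TRUE))
    stop("mean band power must be positive before log transform")
  if (is.null(floor)) {
    r <- attr(features, "bin_resolution")
    n <- attr(features, "n_windows")
    if (is.null(r) || is.null(n))
      stop("supply `floor` when the table lacks spectral-grid attributes")
    floor <- dfv_floor(r, max(2, round(n)))
  }
  features$mbp <- log(features$mbp)
  features$dfv <- log(pmax(features$dfv, floor))
  attr(features, "log_transformed") <- TRUE
  features
}
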