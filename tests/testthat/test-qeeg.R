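# Build a spectral_windows object directly from a matrix of per-window,
# per-channel power spectra (windows x channels x bins). Lets feature
# operations be tested against hand-constructed spectra.
make_windows <- function(psd, freqs, labels = paste0("ch", seq_len(dim(psd)[2]))) {
  rel <- psd
  for (w in seq_len(dim(psd)[1])) for (ch in seq_len(dim(psd)[2])) {
    tot <- sum(psd[w, ch, ])
    if (is.finite(tot) && tot > 0) rel[w, ch, ] <- psd[w, ch, ] / tot
  }
  mean_psd <- apply(rel, c(2, 3), mean, na.rm = TRUE)
  rownames(mean_psd) <- labels
  structure(list(psd = rel, freqs = freqs, mean_psd = mean_psd,
                 bin_resolution = freqs[2] - freqs[1],
                 window_sec = 1 / (freqs[2] - freqs[1]), labels = labels,
                 epoch_of_window = seq_len(dim(psd)[1]),
                 condition = "eyes_open", subject = "T1"),
            class = "spectral_windows")
}

rms <- function(x) sqrt(mean(x^2))

test_that("filtering notches mains, preserves the passband, kills DC", {
  fs <- 1000
  t <- seq(1 / fs, 10, by = 1 / fs)
  mid <- (2 * fs):(8 * fs)  # steady-state portion, away from edge transients
  mk <- function(x) eeg_recording(matrix(x, 1), fs, "Cz")

  x60 <- sin(2 * pi * 60 * t)
  y60 <- preprocess(mk(x60))$samples[1, ]
  expect_lt(rms(y60[mid]) / rms(x60[mid]), 0.01)   # >= 40 dB attenuation

  x10 <- sin(2 * pi * 10 * t)
  y10 <- preprocess(mk(x10))$samples[1, ]
  expect_lt(abs(rms(y10[mid]) / rms(x10[mid]) - 1), 0.05)

  # DC transient of the 0.2 Hz high-pass decays over seconds; judge the centre
  ydc <- preprocess(mk(rep(1, length(t))))$samples[1, ]
  expect_lt(rms(ydc[(4.5 * fs):(5.5 * fs)]), 0.01)

  expect_error(preprocess(eeg_recording(matrix(rnorm(500), 1), 250, "Cz")),
               "too low")
})

test_that("epoching yields floor(T/duration) non-overlapping segments", {
  fs <- 500
  mk <- function(secs) eeg_recording(matrix(seq_len(secs * fs), 1), fs, "Cz")
  expect_identical(dim(epoch(mk(120))$data)[1], 48L)
  ep <- epoch(mk(5))
  expect_identical(dim(ep$data)[1], 2L)
  # contiguous, non-overlapping: concatenated epochs reproduce the prefix
  expect_equal(as.vector(t(ep$data[, 1, ])), seq_len(2 * 2.5 * fs))
  expect_error(epoch(eeg_recording(matrix(rnorm(1200), 1), fs, "Cz")),
               "too short")
})

test_that("artifact rejection flags variance outliers but not clean data", {
  set.seed(21)
  fs <- 500
  n_ep <- 41
  x <- rnorm(n_ep * 1250)
  bad_idx <- 17
  sel <- ((bad_idx - 1) * 1250 + 1):(bad_idx * 1250)
  x[sel] <- x[sel] * 10  # 100x variance burst
  ep <- reject_artifacts(epoch(eeg_recording(matrix(x, 1), fs, "Cz")))
  expect_true(ep$mask[bad_idx, 1])

  # identical epochs: zero spread, nothing flagged
  const <- rep(sin(2 * pi * 10 * seq_len(1250) / fs), 10)
  ep0 <- reject_artifacts(epoch(eeg_recording(matrix(const, 1), fs, "Cz")))
  expect_false(any(ep0$mask))

  # i.i.d. Gaussian epochs: null rejection rate stays low
  xg <- rnorm(200 * 1250)
  epg <- reject_artifacts(epoch(eeg_recording(matrix(xg, 1), fs, "Cz")))
  expect_lt(mean(epg$mask), 0.10)

  expect_error(reject_artifacts(epoch(eeg_recording(matrix(rnorm(3 * 1250), 1),
                                                    fs, "Cz"))),
               "at least 4")
})

test_that("relative PSD windows normalize to one and locate spectral peaks", {
  set.seed(31)
  fs <- 500
  t <- seq(1 / fs, 30, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + rnorm(length(t), sd = sqrt(0.1))
  ep <- epoch(eeg_recording(matrix(x, 1), fs, "Cz"))
  sw <- welch_relative_psd(ep)
  sums <- apply(sw$psd, c(1, 2), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
  expect_equal(sw$bin_resolution, 0.8)
  expect_true(all(sw$freqs > 0 & sw$freqs <= 100))
  # global argmax within half a bin of 10 Hz (10 Hz lies midway between the
  # 9.6 and 10.4 Hz bins, so either neighbour is the FFT peak)
  peak <- sw$freqs[which.max(sw$mean_psd[1, ])]
  expect_lte(abs(peak - 10), sw$bin_resolution / 2 + 1e-9)

  # white noise: approximately flat mean relative spectrum
  nwin <- 10000
  xw <- rnorm(nwin / 2 * 2.5 * fs)
  swf <- welch_relative_psd(epoch(eeg_recording(matrix(xw, 1), fs, "Cz")))
  expect_lt(max(swf$mean_psd) / min(swf$mean_psd), 2)
})

test_that("mean band power averages relative bins within printed band edges", {
  freqs <- seq(0.8, 100, by = 0.8)
  p <- array(0, dim = c(2, 1, length(freqs)))
  p[, 1, which.min(abs(freqs - 6))] <- 1  # all energy near 6 Hz
  sw <- make_windows(p, freqs)
  bands <- band_scheme()
  mbp <- sapply(seq_len(nrow(bands)), function(i)
    mean_band_power(sw, bands$low[i], bands$high[i])[1])
  names(mbp) <- bands$band
  expect_identical(names(which.max(mbp)), "theta")

  # uniform spectrum: every band mean equals the common bin value
  pu <- array(1, dim = c(2, 1, length(freqs)))
  swu <- make_windows(pu, freqs)
  for (i in seq_len(nrow(bands)))
    expect_equal(unname(mean_band_power(swu, bands$low[i], bands$high[i])[1]),
                 1 / length(freqs))

  expect_error(mean_band_power(sw, 8.1, 8.7), "no frequency bins")
})

test_that("band edges are half-open with the printed gaps unassigned", {
  freqs <- seq(0.8, 100, by = 0.8)
  covered <- rep(FALSE, length(freqs))
  bands <- band_scheme()
  for (i in seq_len(nrow(bands))) {
    sel <- freqs >= bands$low[i] &
      (freqs < bands$high[i] | (bands$high[i] >= 100 & freqs <= 100))
    covered <- covered | sel
  }
  # 8-9, 30-31, 55-65 Hz gap bins belong to no band; 14 Hz edge to beta only
  expect_true(all(freqs[!covered] >= 8 & freqs[!covered] < 9 |
                    freqs[!covered] >= 30 & freqs[!covered] < 31 |
                    freqs[!covered] >= 55 & freqs[!covered] < 65))
  expect_false(8.0 %in% freqs[covered])
})

test_that("DFV is the mean absolute deviation of dominant frequencies", {
  freqs <- 1:100
  doms <- c(9, 10, 11, 10)
  p <- array(0, dim = c(4, 1, length(freqs)))
  for (w in seq_along(doms)) {
    p[w, 1, ] <- 0.001
    p[w, 1, doms[w]] <- 1
  }
  sw <- make_windows(p, freqs)
  expect_equal(unname(dominant_frequency_variability(sw, 4, 30)[1]), 0.5)

  # constant dominant frequency
  pc <- array(0, dim = c(3, 1, length(freqs)))
  pc[, 1, 10] <- 1
  expect_equal(unname(dominant_frequency_variability(make_windows(pc, freqs),
                                                     9, 14)[1]), 0)

  # brute-force equality on random dominant-frequency sequences
  set.seed(77)
  for (rep in 1:25) {
    d <- sample(5:25, sample(4:12, 1), replace = TRUE)
    pr <- array(stats::runif(length(d) * length(freqs), 0, 0.01),
                dim = c(length(d), 1, length(freqs)))
    for (w in seq_along(d)) pr[w, 1, d[w]] <- 1
    got <- unname(dominant_frequency_variability(make_windows(pr, freqs),
                                                 min(freqs), max(freqs))[1])
    expect_equal(got, sum(abs(d - mean(d))) / length(d))
  }

  # scaling the signal cannot move a power-monotone argmax
  sw2 <- make_windows(p * 13.7, freqs)
  expect_equal(dominant_frequency_variability(sw2, 4, 30),
               dominant_frequency_variability(sw, 4, 30))

  p1 <- array(0, dim = c(1, 1, length(freqs))); p1[1, 1, 10] <- 1
  expect_error(dominant_frequency_variability(make_windows(p1, freqs), 9, 14),
               "at least 2")
})

test_that("region summaries are masked channel means", {
  vals <- c(Fp1 = 1, F3 = 3, F7 = 2, FC5 = 2, Fz = 5, FC1 = 5, FC2 = 5)
  regions <- list(left_frontal = c("Fp1", "F3", "F7", "FC5"),
                  middle_frontal = c("Fz", "FC1", "FC2"))
  out <- summarize_regions(vals, regions)
  expect_equal(out, c(left_frontal = 2, middle_frontal = 5))

  vals["F3"] <- NA  # rejected channel: mean over survivors
  expect_equal(summarize_regions(vals, regions)[["left_frontal"]],
               mean(c(1, 2, 2)))
  expect_error(summarize_regions(vals, list(r = "Oz")), "absent")
})

test_that("log transform floors zero DFV and maps MBP to natural logs", {
  ft <- data.frame(subject = "s", condition = "eyes_open", region = "central",
                   band = c("theta", "alpha", "beta"),
                   mbp = c(1, exp(-1), 0.5), dfv = c(0, 1, 2))
  out <- log_transform(ft, floor = dfv_floor(0.8, 12))
  expect_equal(out$mbp, c(0, -1, log(0.5)))
  expect_equal(out$dfv[1], log(dfv_floor(0.8, 12)))
  expect_equal(out$dfv[2:3], log(c(1, 2)))
  expect_true(all(is.finite(out$dfv)))
  expect_error(log_transform(out, floor = 0.1), "already")
  # floor sits strictly below the smallest observable nonzero deviation
  expect_lt(dfv_floor(0.8, 12), 2 * 0.8 * 11 / 144)
})

test_that("the spectral pipeline is deterministic for identical input", {
  set.seed(41)
  fs <- 500
  labels <- default_montage()
  x <- matrix(rnorm(length(labels) * 15 * fs), length(labels))
  rec <- eeg_recording(x, fs, labels, subject = "D1")
  run <- function() {
    ep <- reject_artifacts(epoch(preprocess(rec)))
    log_transform(feature_table(welch_relative_psd(ep)))
  }
  expect_identical(run(), run())
})
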