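#' Scenario configuration for synthetic family studies
#'
#' Describes a simulated study: nuclear families segregating a biallelic
#' variant (allele `"2"` = target/minor allele, `"1"` = wild type), and a
#' linear genotype effect on quantitative phenotypes. Defaults emulate the
#' kind of cohort the pipeline targets: a small set of nuclear families
#' segregating a rare recessive-acting variant (minor-allele frequency
#' 0.165), with phenotypes on the natural-log scale.
#'
#' @param n_families Number of nuclear families (default 8).
#' @param offspring_per_family Offspring per family (default 3).
#' @param target_allele_freq Founder frequency of the target allele, in
#'   (0, 1) (default 0.165).
#' @param model A [genetic_model()] used to translate genotype into phenotype
#'   shift (default recessive on allele `"2"`).
#' @param effect_sizes Named numeric vector of phenotype shifts per unit coded
#'   genotype, keyed `"<band>.<measure>"` (e.g. `theta.mbp`); cells not named
#'   get 0. A single unnamed value applies to every cell.
#' @param noise_sd Residual SD of each phenotype (> 0, default 1).
#' @param family_sd SD of a shared per-family random intercept (default 0.5).
#' @param seed Integer seed; every generator draws reproducibly from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_families = 8, offspring_per_family = 3,
                            target_allele_freq = 0.165,
                            model = genetic_model("recessive", "2"),
                            effect_sizes = numeric(0),
                            noise_sd = 1, family_sd = 0.5, seed = 1) {
  stopifnot(n_families >= 1, offspring_per_family >= 1,
            target_allele_freq >= 0, target_allele_freq <= 1,
            inherits(model, "genetic_model"), noise_sd > 0, family_sd >= 0)
  structure(list(n_families = as.integer(n_families),
                 offspring_per_family = as.integer(offspring_per_family),
                 target_allele_freq = target_allele_freq, model = model,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 family_sd = family_sd, seed = as.integer(seed)),
            class = "scenario_config")
}

count_to_alleles <- function(g, target = "2", other = "1") {
  cbind(ifelse(g >= 1L, target, other), ifelse(g == 2L, target, other))
}

#' Simulate a pedigree of genotyped nuclear families
#'
#' Founders draw their target-allele counts i.i.d. Binomial(2, freq)
#' (Hardy-Weinberg); offspring genotypes follow [mating_distribution()].
#' Families are retained regardless of informativeness — filtering on
#' informative mating types is the analysis pipeline's job, mirroring how a
#' real study narrows its sample.
#'
#' @param cfg A [scenario_config()].
#' @param parent_counts Optional length-2 integer vector fixing every
#'   family's parental target-allele counts (e.g. `c(1, 1)` for het-by-het
#'   trios when a known number of informative families is wanted); default
#'   `NULL` draws founders from Hardy-Weinberg.
#' @return A [pedigree()] (fathers `F<i>_dad`, mothers `F<i>_mum`, offspring
#'   `F<i>_k<j>`).
#' @export
simulate_pedigree <- function(cfg, parent_counts = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  rows <- list()
  for (i in seq_len(cfg$n_families)) {
    if (is.null(parent_counts)) {
      gf <- stats::rbinom(1L, 2L, cfg$target_allele_freq)
      gm <- stats::rbinom(1L, 2L, cfg$target_allele_freq)
    } else {
      gf <- parent_counts[1L]; gm <- parent_counts[2L]
    }
    p <- mating_distribution(gf, gm)
    gk <- sample(0:2, cfg$offspring_per_family, replace = TRUE, prob = p)
    fa <- count_to_alleles(gf); ma <- count_to_alleles(gm)
    ka <- count_to_alleles(gk)
    fid <- sprintf("FAM%03d", i)
    dad <- sprintf("F%d_dad", i); mum <- sprintf("F%d_mum", i)
    kid <- sprintf("F%d_k%d", i, seq_len(cfg$offspring_per_family))
    rows[[i]] <- data.frame(
      fid = fid,
      id = c(dad, mum, kid),
      father = c("0", "0", rep(dad, length(kid))),
      mother = c("0", "0", rep(mum, length(kid))),
      sex = c("1", "2", rep("0", length(kid))),
      phen = "0",
      a1 = c(fa[1L], ma[1L], ka[, 1L]),
      a2 = c(fa[2L], ma[2L], ka[, 2L]),
      stringsAsFactors = FALSE)
  }
  pedigree(do.call(rbind, rows))
}

#' Simulate a raw offspring trait matrix
#'
#' The fast, feature-level generator: each phenotype column is
#' `beta * x + family effect + noise` with `x` the coded offspring genotype.
#' Used for statistical calibration (type-I error, power) where the signal
#' path is not under test.
#'
#' @param ped A [pedigree()] with genotypes.
#' @param model A [genetic_model()].
#' @param beta Effect size(s), recycled over the `m` columns.
#' @param m Number of phenotype columns.
#' @param noise_sd,family_sd Residual and family-intercept SDs.
#' @param seed Integer seed.
#' @return A [trait_matrix()] over all offspring (default grand-mean offset).
#' @export
simulate_trait_matrix <- function(ped, model, beta = 0, m = 1,
                                  noise_sd = 1, family_sd = 0, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(as.integer(seed))
  beta <- rep_len(beta, m)
  fam_of <- character(0); ids <- character(0)
  for (fi in seq_along(ped$families)) {
    ids <- c(ids, ped$families[[fi]]$offspring)
    fam_of <- c(fam_of, rep.int(as.character(fi),
                                length(ped$families[[fi]]$offspring)))
  }
  x <- code_genotype(allele_count(ped, ids, model$target_allele), model)
  u <- stats::setNames(stats::rnorm(length(unique(fam_of)), 0, family_sd),
                       unique(fam_of))
  vals <- sapply(seq_len(m), function(j)
    beta[j] * x + u[fam_of] + stats::rnorm(length(ids), 0, noise_sd))
  vals <- matrix(vals, ncol = m, dimnames = list(ids, paste0("P", seq_len(m))))
  trait_matrix(vals)
}

#' Simulate a genotype-linked qEEG feature table
#'
#' Feature-level shortcut past the signal path: for every offspring,
#' condition, region, band and measure, the (log-scale) phenotype is drawn as
#' `beta(band, measure) * x + family effect + noise`. Effect sizes are read
#' from `cfg$effect_sizes` (names `"<band>.<measure>"`, measures `mbp`/`dfv`).
#'
#' @param ped A [pedigree()] (typically from [simulate_pedigree()]).
#' @param cfg A [scenario_config()].
#' @param bands Band names (default those of [band_scheme()]).
#' @param regions Region names (default those of [region_scheme()]).
#' @param conditions Conditions to emit.
#' @return A feature-table data frame (`subject`, `condition`, `region`,
#'   `band`, `mbp`, `dfv`) on the log scale, covering all offspring, with
#'   `log_transformed` attribute set.
#' @export
simulate_phenotypes <- function(ped, cfg, bands = band_scheme()$band,
                                regions = names(region_scheme()),
                                conditions = c("eyes_open", "eyes_closed")) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 1L)
  ids <- unlist(lapply(ped$families, `[[`, "offspring"))
  fam_of <- rep(seq_along(ped$families),
                vapply(ped$families, function(f) length(f$offspring), 1L))
  x <- code_genotype(allele_count(ped, ids, cfg$model$target_allele),
                     cfg$model)
  beta_of <- function(band, measure) {
    es <- cfg$effect_sizes
    if (length(es) == 1L && is.null(names(es))) return(es)
    key <- paste(band, measure, sep = ".")
    if (key %in% names(es)) es[[key]] else 0
  }
  grid <- expand.grid(condition = conditions, band = bands,
                      stringsAsFactors = FALSE)
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    u <- stats::rnorm(length(ped$families), 0, cfg$family_sd)
    for (ms in c("mbp", "dfv")) {
      b <- beta_of(grid$band[gi], ms)
      vals <- sapply(seq_along(regions), function(rj)
        b * x + u[fam_of] + stats::rnorm(length(ids), 0, cfg$noise_sd))
      df <- data.frame(subject = rep(ids, times = length(regions)),
                       condition = grid$condition[gi],
                       region = rep(regions, each = length(ids)),
                       band = grid$band[gi],
                       measure = ms, value = as.vector(vals),
                       stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- df
    }
  }
  long <- do.call(rbind, out)
  wide <- stats::reshape(long, direction = "wide",
                         idvar = c("subject", "condition", "region", "band"),
                         timevar = "measure")
  names(wide)[names(wide) == "value.mbp"] <- "mbp"
  names(wide)[names(wide) == "value.dfv"] <- "dfv"
  rownames(wide) <- NULL
  attr(wide, "log_transformed") <- TRUE
  attr(wide, "reshapeWide") <- NULL
  wide
}

#' Parameters for raw oscillatory EEG simulation
#'
#' @param bands Data frame with columns `band`, `center`, `amplitude`,
#'   `jitter_sd`: each band contributes, per 2500 ms segment, a sinusoid at
#'   `center + N(0, jitter_sd)` Hz with the given amplitude (microvolts).
#'   Default: alpha 10 Hz / 10 uV and theta 6 Hz / 5 uV with 0.5 Hz jitter.
#' @param background_scale Amplitude scale of the 1/f background noise.
#' @param background_exponent Spectral exponent of the background (power
#'   ~ 1/f^exponent, default 1).
#' @param duration Recording length in seconds (default 120, i.e. a 2-minute
#'   resting run).
#' @param sfreq Sampling rate in Hz (>= 500; default 1000).
#' @param labels Channel labels (default the 30-channel montage).
#' @return An object of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(bands = data.frame(
                             band = c("theta", "alpha"),
                             center = c(6, 10),
                             amplitude = c(5, 10),
                             jitter_sd = c(0.5, 0.5),
                             stringsAsFactors = FALSE),
                           background_scale = 1, background_exponent = 1,
                           duration = 120, sfreq = 1000,
                           labels = default_montage()) {
  stopifnot(sfreq >= 500, duration > 0, all(bands$jitter_sd >= 0),
            all(bands$amplitude >= 0))
  structure(list(bands = bands, background_scale = background_scale,
                 background_exponent = background_exponent,
                 duration = duration, sfreq = sfreq, labels = labels),
            class = "eeg_sim_params")
}

## 1/f^a background: white Gaussian spectrum shaped by f^(-a/2), real ifft
one_over_f_noise <- function(n, sfreq, exponent) {
  freqs <- seq(0, sfreq / 2, by = sfreq / n)
  n_pos <- length(freqs) - 1L
  amp <- c(0, freqs[-1L]^(-exponent / 2))
  half <- amp * (stats::rnorm(n_pos + 1L) + 1i * stats::rnorm(n_pos + 1L))
  spec <- complex(real = numeric(n))
  spec[seq_len(n_pos + 1L)] <- half
  spec[n - seq_len(n_pos - 1L) + 1L] <- Conj(half[2L:n_pos])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a raw resting-EEG recording
#'
#' Sum of band-limited sinusoids with per-segment frequency jitter plus 1/f
#' background noise. Jitter draws are shared across channels within a
#' segment (one global rhythm, as scalp rhythms are spatially coherent);
#' phases and background noise are independent per channel.
#'
#' @param params An [eeg_sim_params()].
#' @param seed Integer seed.
#' @param condition,subject Passed to the recording.
#' @return An [eeg_recording()].
#' @export
simulate_eeg <- function(params, seed = 1, condition = "eyes_open",
                         subject = "SIM1") {
  stopifnot(inherits(params, "eeg_sim_params"))
  set.seed(as.integer(seed))
  fs <- params$sfreq
  n <- round(params$duration * fs)
  seg_len <- round(2.5 * fs)
  n_seg <- ceiling(n / seg_len)
  n_ch <- length(params$labels)
  x <- matrix(0, n_ch, n)
  tt <- seq_len(seg_len) / fs
  for (bi in seq_len(nrow(params$bands))) {
    b <- params$bands[bi, ]
    if (b$amplitude == 0) next
    f_seg <- b$center + stats::rnorm(n_seg, 0, b$jitter_sd)
    for (s in seq_len(n_seg)) {
      idx <- ((s - 1L) * seg_len + 1L):min(s * seg_len, n)
      ph <- stats::runif(n_ch, 0, 2 * pi)
      for (ch in seq_len(n_ch))
        x[ch, idx] <- x[ch, idx] +
          b$amplitude * sin(2 * pi * f_seg[s] * tt[seq_along(idx)] + ph[ch])
    }
  }
  if (params$background_scale > 0)
    for (ch in seq_len(n_ch))
      x[ch, ] <- x[ch, ] + params$background_scale *
        one_over_f_noise(n, fs, params$background_exponent)
  eeg_recording(x, fs, params$labels, condition = condition,
                subject = subject)
}

#' Inject artifacts into a recording
#'
#' Corrupts a random fraction of 2500 ms epochs to exercise artifact
#' rejection: `"burst"` multiplies the segment by a factor giving ~100x
#' variance; `"blink"` adds a large low-frequency half-sine transient on the
#' frontal-most channels.
#'
#' @param rec An [eeg_recording()].
#' @param rate Fraction of epochs to corrupt, in `[0, 1]`.
#' @param kind `"burst"` or `"blink"`.
#' @param seed Integer seed.
#' @param epoch_ms Epoch length used for indexing (default 2500).
#' @return List with `recording` (modified) and `epochs` (sorted indices of
#'   the corrupted epochs).
#' @export
inject_artifacts <- function(rec, rate, kind = c("burst", "blink"), seed = 1,
                             epoch_ms = 2500) {
  stopifnot(inherits(rec, "eeg_recording"), rate >= 0, rate <= 1)
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  seg_len <- round(epoch_ms / 1000 * rec$sfreq)
  n_seg <- ncol(rec$samples) %/% seg_len
  n_bad <- round(rate * n_seg)
  if (n_bad == 0L) return(list(recording = rec, epochs = integer(0)))
  bad <- sort(sample(seq_len(n_seg), n_bad))
  for (s in bad) {
    idx <- ((s - 1L) * seg_len + 1L):(s * seg_len)
    if (kind == "burst") {
      rec$samples[, idx] <- rec$samples[, idx] * 10
    } else {
      blink <- 200 * sin(pi * seq_along(idx) / length(idx))
      frontal <- seq_len(min(4L, nrow(rec$samples)))
      rec$samples[frontal, idx] <- rec$samples[frontal, idx] +
        rep(blink, each = length(frontal))
    }
  }
  list(recording = rec, epochs = bad)
}
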