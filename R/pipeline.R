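#' Extract qEEG features from a batch of recordings
#'
#' Chains the signal path for every recording: band-pass + notch filtering,
#' 2500 ms epoching, two-round statistical artifact rejection, Welch relative
#' PSD, band-wise MBP and DFV, region averaging, and (by default) the
#' natural-log transform. A recording that fails (unreadable, too short, all
#' trials rejected) is skipped with a warning and named in the run log; the
#' batch continues.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param bands,regions Schemes (defaults [band_scheme()], [region_scheme()]).
#' @param z_thresh,rounds Artifact-rejection parameters.
#' @param log_features Apply [log_transform()] (default `TRUE`).
#' @param filter_low,filter_high,notch Passed to [preprocess()].
#' @return Feature data frame (rows: subject x condition x region x band)
#'   with a `run_log` attribute: per-recording status and rejected-cell
#'   counts.
#' @export
run_features <- function(recordings, bands = band_scheme(),
                         regions = region_scheme(), z_thresh = 3, rounds = 2,
                         log_features = TRUE, filter_low = 0.2,
                         filter_high = 150, notch = c(59, 61)) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  tables <- list()
  log_rows <- list()
  for (rec in recordings) {
    label <- paste(rec$subject, rec$condition, sep = "/")
    res <- tryCatch({
      pp <- preprocess(rec, low = filter_low, high = filter_high,
                       notch = notch)
      ep <- reject_artifacts(epoch(pp), z_thresh = z_thresh, rounds = rounds)
      sw <- welch_relative_psd(ep)
      ft <- feature_table(sw, bands = bands, regions = regions)
      if (log_features) ft <- log_transform(ft)
      list(table = ft, n_rejected = sum(ep$mask),
           n_cells = length(ep$mask), error = NA_character_)
    }, error = function(e) list(table = NULL, n_rejected = NA_integer_,
                                n_cells = NA_integer_,
                                error = conditionMessage(e)))
    if (is.null(res$table))
      warning(sprintf("recording %s skipped: %s", label, res$error))
    else
      tables[[length(tables) + 1L]] <- res$table
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(subject = rec$subject, condition = rec$condition,
                 n_rejected_cells = res$n_rejected, n_cells = res$n_cells,
                 status = if (is.null(res$table)) res$error else "ok",
                 stringsAsFactors = FALSE)
  }
  if (!length(tables)) stop("no recording produced features")
  out <- do.call(rbind, lapply(tables, function(t) {
    attr(t, "bin_resolution") <- attr(t, "n_windows") <- NULL
    t
  }))
  rownames(out) <- NULL
  attr(out, "log_transformed") <- log_features
  attr(out, "run_log") <- do.call(rbind, log_rows)
  out
}

#' Family-based association tests over a feature table
#'
#' For every combination of condition, measure (MBP, DFV), frequency band,
#' genetic model and marker allele, runs the multivariate FBAT-GEE with the
#' scalp regions as the multivariate dimension, and univariate FBATs within
#' each region. Tests are evaluated at `alpha` uncorrected by default (a
#' hypothesis-generating convention); `p_adjust` enables Bonferroni/FDR.
#' Offspring in uninformative families contribute nothing to the statistics;
#' their count is reported in a message.
#'
#' @param features Feature data frame (log scale) as from [run_features()] or
#'   [simulate_phenotypes()].
#' @param ped A [pedigree()] sharing subject ids with `features`.
#' @param models Genetic models to run (default recessive and additive).
#' @param alleles Marker alleles to test (default: both alleles present in
#'   the pedigree, highest founder frequency first).
#' @param conditions,measures Subsets to analyze (defaults: all present).
#' @param offset Trait offset strategy (default `"grand_mean"`).
#' @param alpha Significance level for the star flag (default 0.05).
#' @param p_adjust Multiplicity correction applied to each table's p-values
#'   before starring: `"none"` (default), `"bonferroni"` or `"fdr"`.
#' @return List with data frames `multivariate` (columns condition, measure,
#'   band, model, allele, frequency, chi2, df, p, star) and `univariate`
#'   (condition, measure, band, model, allele, region, Z, p, star).
#' @export
run_fbat <- function(features, ped,
                     models = c("recessive", "additive"), alleles = NULL,
                     conditions = unique(features$condition),
                     measures = c("mbp", "dfv"),
                     offset = "grand_mean", alpha = 0.05,
                     p_adjust = c("none", "bonferroni", "fdr")) {
  stopifnot(is.data.frame(features), inherits(ped, "pedigree"))
  p_adjust <- match.arg(p_adjust)
  shared <- intersect(unique(features$subject), ped$members$id)
  if (!length(shared))
    stop("features and pedigree share no subject ids")
  if (is.null(alleles)) {
    alleles <- stats::na.omit(unique(c(ped$members$a1, ped$members$a2)))
    frq <- vapply(alleles, function(a) founder_allele_frequency(ped, a), 0)
    alleles <- alleles[order(-frq)]
  }
  regions <- unique(features$region)
  bands <- unique(features$band)
  mv <- list(); uv <- list()
  for (cond in conditions) for (ms in measures) for (bd in bands) {
    sub <- features[features$condition == cond & features$band == bd, ]
    wide <- stats::reshape(
      sub[, c("subject", "region", ms)], direction = "wide",
      idvar = "subject", timevar = "region")
    ids <- wide$subject
    mat <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(mat) <- sub("^.*\\.", "", colnames(mat))
    mat <- mat[, regions, drop = FALSE]
    rownames(mat) <- ids
    for (mode in models) for (al in alleles) {
      model <- genetic_model(mode, target_allele = al)
      freq <- founder_allele_frequency(ped, al)
      tm <- trait_matrix(mat, offset = offset)
      res <- tryCatch(
        suppressWarnings(multivariate_fbat_gee(ped, tm, model)),
        error = function(e) NULL)
      if (!is.null(res))
        mv[[length(mv) + 1L]] <- data.frame(
          condition = cond, measure = ms, band = bd, model = mode,
          allele = al, frequency = freq, chi2 = res$chi2, df = res$df,
          p = res$p, stringsAsFactors = FALSE)
      for (rg in regions) {
        tm1 <- trait_matrix(mat[, rg, drop = FALSE], offset = offset)
        r1 <- tryCatch(suppressWarnings(univariate_fbat(ped, tm1, model)),
                       error = function(e) NULL)
        if (!is.null(r1))
          uv[[length(uv) + 1L]] <- data.frame(
            condition = cond, measure = ms, band = bd, model = mode,
            allele = al, region = rg, Z = r1$Z, p = r1$p,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(mv)) stop("no testable (condition, measure, band) cell")
  star <- function(df) {
    padj <- stats::p.adjust(df$p, method = p_adjust)
    df$star <- ifelse(padj < alpha, "*", "")
    df
  }
  info <- suppressWarnings(informative_families(
    ped, genetic_model(models[1L], target_allele = alleles[1L])))
  n_outside <- length(unlist(lapply(
    ped$families[!info %in% TRUE], `[[`, "offspring")))
  if (n_outside > 0L)
    message(sprintf(
      "%d offspring outside informative families (excluded from %s/%s tests)",
      n_outside, models[1L], alleles[1L]))
  list(multivariate = star(do.call(rbind, mv)),
       univariate = star(do.call(rbind, uv)))
}

#' Write / read a feature table as TSV
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @return `path` invisibly (`write_features`); the table (`read_features`).
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @param log_transformed Whether the stored values are natural-log scale.
#' @export
read_features <- function(path, log_transformed = TRUE) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(out, "log_transformed") <- log_transformed
  out
}
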