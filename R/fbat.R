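#' Phenotype matrix for family-based testing
#'
#' Bundles an offspring-by-phenotype matrix of quantitative traits
#' \eqn{t_i} with the offset strategy used before the FBAT sums. With the
#' multivariate statistic the columns are typically the 8 scalp regions of a
#' single (band, measure, condition) cell.
#'
#' @param values Numeric matrix (or vector for a single phenotype), rows named
#'   by individual id, no missing cells for tested offspring.
#' @param ids Individual ids; default `rownames(values)`.
#' @param offset Offset strategy: `"grand_mean"` (default) subtracts each
#'   phenotype's mean over tested offspring, `"none"` leaves traits unchanged,
#'   `"user_value"` subtracts `offset_value` per phenotype. Centering affects
#'   power, not validity, of the test.
#' @param offset_value Numeric vector (length 1 or `ncol(values)`), required
#'   for `offset = "user_value"`.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, ids = rownames(values),
                         offset = c("grand_mean", "none", "user_value"),
                         offset_value = NULL) {
  offset <- match.arg(offset)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) stop("trait rows must be named by individual id")
  stopifnot(length(ids) == nrow(values), ncol(values) >= 1L)
  rownames(values) <- as.character(ids)
  if (offset == "user_value") {
    if (is.null(offset_value)) stop("offset_value required for user_value offset")
    offset_value <- rep_len(as.numeric(offset_value), ncol(values))
  }
  structure(list(values = values, offset = offset, offset_value = offset_value),
            class = "trait_matrix")
}

#' Apply the trait offset
#'
#' @param traits A [trait_matrix()].
#' @return A `trait_matrix` with the offset subtracted and strategy reset to
#'   `"none"` (idempotent).
#' @export
apply_offset <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  v <- traits$values
  v <- switch(traits$offset,
              none       = v,
              grand_mean = sweep(v, 2L, colMeans(v)),
              user_value = sweep(v, 2L, traits$offset_value))
  trait_matrix(v, offset = "none")
}

## Resolve, per tested offspring, the coded genotype, its conditional moments
## and the (offset) trait vector. Families with a missing parental genotype
## are excluded with a warning; offspring with missing genotype or phenotype
## are dropped listwise. Informativeness is a property of the mating type.
prepare_fbat <- function(ped, traits, model) {
  stopifnot(inherits(ped, "pedigree"), inherits(traits, "trait_matrix"),
            inherits(model, "genetic_model"))
  avail <- rownames(traits$values)[stats::complete.cases(traits$values)]
  n_pheno_dropped <- nrow(traits$values) - length(avail)

  fam_idx <- integer(0); off_ids <- character(0)
  g <- integer(0); E_x <- numeric(0); Var_x <- numeric(0)
  probs <- matrix(numeric(0), ncol = 3L)
  n_fam_missing_parent <- 0L; n_geno_dropped <- 0L

  for (fi in seq_along(ped$families)) {
    fam <- ped$families[[fi]]
    gf <- allele_count(ped, fam$father, model$target_allele)
    gm <- allele_count(ped, fam$mother, model$target_allele)
    if (is.na(gf) || is.na(gm)) {
      n_fam_missing_parent <- n_fam_missing_parent + 1L
      next
    }
    mom <- conditional_moments(gf, gm, model)
    p <- mating_distribution(gf, gm)
    kids <- intersect(fam$offspring, avail)
    gk <- allele_count(ped, kids, model$target_allele)
    n_geno_dropped <- n_geno_dropped + sum(is.na(gk))
    kids <- kids[!is.na(gk)]
    gk <- gk[!is.na(gk)]
    if (!length(kids)) next
    fam_idx <- c(fam_idx, rep.int(fi, length(kids)))
    off_ids <- c(off_ids, kids)
    g <- c(g, gk)
    E_x <- c(E_x, rep.int(mom$E_x, length(kids)))
    Var_x <- c(Var_x, rep.int(mom$Var_x, length(kids)))
    probs <- rbind(probs, matrix(rep(p, each = length(kids)), ncol = 3L))
  }
  if (n_fam_missing_parent > 0L)
    warning(sprintf("%d famil%s with missing parental genotype excluded",
                    n_fam_missing_parent,
                    if (n_fam_missing_parent == 1L) "y" else "ies"))
  if (!length(off_ids)) stop("no testable offspring (after exclusions)")

  ## offset over the offspring actually tested
  tm <- trait_matrix(traits$values[off_ids, , drop = FALSE],
                     offset = traits$offset,
                     offset_value = traits$offset_value)
  t_mat <- apply_offset(tm)$values
  list(t = t_mat, x = code_genotype(g, model), g = g,
       E_x = E_x, Var_x = Var_x, probs = probs, fam = fam_idx,
       ids = off_ids,
       n_informative_families = length(unique(fam_idx[Var_x > 0])),
       n_dropped = c(phenotype = n_pheno_dropped, genotype = n_geno_dropped))
}

#' Univariate family-based association test
#'
#' The classical quantitative-trait FBAT for a single phenotype:
#' \deqn{S = \sum_i t_i x_i, \quad E(S) = \sum_i t_i E(x_i | p_{i1}, p_{i2}),
#'   \quad V_S = \sum_i t_i^2 Var(x_i | p_{i1}, p_{i2}),}
#' with \eqn{Z = (S - E(S)) / \sqrt{V_S}}, \eqn{\chi^2 = Z^2}, and a
#' two-sided normal p-value. Conditioning on parental genotypes makes the
#' null distribution immune to population stratification; only families whose
#' mating type has \eqn{Var(x_i) > 0} contribute.
#'
#' @param ped A [pedigree()].
#' @param traits A [trait_matrix()] with exactly one phenotype column.
#' @param model A [genetic_model()].
#' @return List of class `fbat_result`: `S`, `E_S`, `V_S`, `Z`, `chi2`, `p`,
#'   `n_informative_families`, `n_offspring`.
#' @export
univariate_fbat <- function(ped, traits, model) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (ncol(traits$values) != 1L)
    stop("univariate_fbat requires a single phenotype; see multivariate_fbat_gee")
  d <- prepare_fbat(ped, traits, model)
  t_i <- drop(d$t)
  S <- sum(t_i * d$x)
  E_S <- sum(t_i * d$E_x)
  V_S <- sum(t_i^2 * d$Var_x)
  if (d$n_informative_families == 0L)
    stop("uninformative: no family contributes variance in the coded genotype")
  ## informative transmissions but all their traits zero: the score is
  ## degenerate at 0, not an error
  Z <- if (V_S > 0) (S - E_S) / sqrt(V_S) else 0
  structure(list(S = S, E_S = E_S, V_S = V_S, Z = Z, chi2 = Z^2,
                 p = normal_two_sided_p(Z),
                 n_informative_families = d$n_informative_families,
                 n_offspring = length(t_i)),
            class = "fbat_result")
}

#' @export
print.fbat_result <- function(x, ...) {
  cat(sprintf(paste0("Univariate FBAT: S=%.4g, E(S)=%.4g, V_S=%.4g, ",
                     "Z=%.3f, p=%.4g (%d informative families)\n"),
              x$S, x$E_S, x$V_S, x$Z, x$p, x$n_informative_families))
  invisible(x)
}

#' Multivariate FBAT-GEE
#'
#' Joint test of an m-dimensional phenotype vector (e.g. one band's power
#' over the 8 scalp regions):
#' \deqn{\tilde S = \sum_i t_i (x_i - E(x_i | p_{i1}, p_{i2})), \quad
#'   V = \sum_i t_i t_i^t Var(x_i | p_{i1}, p_{i2}), \quad
#'   \chi^2 = \tilde S^t V^{-} \tilde S,}
#' asymptotically chi-squared with df = rank(V). A generalized inverse
#' (eigendecomposition with thresholded reciprocal eigenvalues) replaces the
#' plain inverse because correlated region phenotypes make V near-singular;
#' the statistic is then invariant under invertible linear recombinations of
#' the phenotypes.
#'
#' @inheritParams univariate_fbat
#' @param traits A [trait_matrix()] (m >= 1 phenotype columns).
#' @param rel_tol Relative eigenvalue threshold for the rank / generalized
#'   inverse (default `1e-8`).
#' @return List of class `fbat_gee_result`: `S_tilde` (m-vector), `V` (m x m),
#'   `chi2`, `df`, `p`, `n_informative_families`, `n_offspring`.
#' @export
multivariate_fbat_gee <- function(ped, traits, model, rel_tol = 1e-8) {
  d <- prepare_fbat(ped, traits, model)
  m <- ncol(d$t)
  S_tilde <- drop(crossprod(d$t, d$x - d$E_x))
  V <- crossprod(d$t * sqrt(d$Var_x))
  V <- (V + t(V)) / 2
  eg <- eigen(V, symmetric = TRUE)
  keep <- eg$values > rel_tol * max(eg$values, 0)
  df <- sum(keep)
  if (df == 0L)
    stop("uninformative: covariance matrix of the score vector has rank 0")
  U <- eg$vectors[, keep, drop = FALSE]
  y <- drop(crossprod(U, S_tilde))
  chi2 <- sum(y^2 / eg$values[keep])
  structure(list(S_tilde = S_tilde, V = V, chi2 = chi2, df = df,
                 p = chi2_upper_tail(chi2, df),
                 n_informative_families = d$n_informative_families,
                 n_offspring = nrow(d$t)),
            class = "fbat_gee_result")
}

#' @export
print.fbat_gee_result <- function(x, ...) {
  cat(sprintf("FBAT-GEE: chi2=%.3f, df=%d, p=%.4g (%d informative families)\n",
              x$chi2, x$df, x$p, x$n_informative_families))
  invisible(x)
}

#' Upper tail of the chi-square distribution
#'
#' @param x Nonnegative statistic value.
#' @param df Degrees of freedom (integer >= 1).
#' @return `P(X >= x)` for `X ~ chi-square(df)`.
#' @export
chi2_upper_tail <- function(x, df) {
  stopifnot(all(x >= 0))
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Two-sided normal p-value
#'
#' @param Z A Z statistic (sign is retained by the caller for directional
#'   interpretation; the p-value is two-sided).
#' @return `2 * (1 - Phi(|Z|))`.
#' @export
normal_two_sided_p <- function(Z) {
  2 * stats::pnorm(-abs(Z))
}

#' Numerical rank of a symmetric positive semidefinite matrix
#'
#' @param V Symmetric matrix.
#' @param rel_tol Relative threshold: singular values greater than
#'   `rel_tol * max(singular value)` are counted.
#' @return Integer rank.
#' @export
rank_psd <- function(V, rel_tol = 1e-8) {
  V <- as.matrix(V)
  stopifnot(nrow(V) == ncol(V))
  scale <- max(abs(V), 1e-300)
  if (max(abs(V - t(V))) > 1e-8 * scale)
    stop("matrix is not symmetric within tolerance")
  d <- svd((V + t(V)) / 2, nu = 0, nv = 0)$d
  if (max(d) == 0) return(0L)
  sum(d > rel_tol * max(d))
}

#' Monte-Carlo transmission null for the FBAT statistics
#'
#' Re-draws offspring genotypes from the Mendelian mating distribution of
#' each family (holding the phenotypes fixed) and recomputes the test
#' statistic, giving the exact conditional null distribution the analytic
#' chi-square approximates. Intended as a testing/validation oracle rather
#' than the reported inference.
#'
#' @inheritParams multivariate_fbat_gee
#' @param n_draws Number of null draws (>= 100).
#' @param seed Integer seed (required; draws are reproducible).
#' @param statistic `"auto"` (univariate chi-square if m = 1, FBAT-GEE
#'   otherwise), `"univariate"` or `"multivariate"`.
#' @return Numeric vector of `n_draws` null chi-square values.
#' @export
empirical_null <- function(ped, traits, model, n_draws = 1000L, seed,
                           statistic = c("auto", "univariate", "multivariate")) {
  statistic <- match.arg(statistic)
  stopifnot(n_draws >= 100L)
  d <- prepare_fbat(ped, traits, model)
  if (statistic == "auto")
    statistic <- if (ncol(d$t) == 1L) "univariate" else "multivariate"
  set.seed(as.integer(seed))
  n <- length(d$g)
  cum <- t(apply(d$probs, 1L, cumsum))
  codes <- vapply(0:2, function(k) code_genotype(rep.int(k, n), model),
                  numeric(n))
  vapply(seq_len(n_draws), function(rep) {
    u <- stats::runif(n)
    k <- 1L + (u > cum[, 1L]) + (u > cum[, 2L])
    x <- codes[cbind(seq_len(n), k)]
    if (statistic == "univariate") {
      t_i <- drop(d$t)
      V_S <- sum(t_i^2 * d$Var_x)
      (sum(t_i * (x - d$E_x)))^2 / V_S
    } else {
      S_tilde <- drop(crossprod(d$t, x - d$E_x))
      V <- crossprod(d$t * sqrt(d$Var_x))
      eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
      keep <- eg$values > 1e-8 * max(eg$values, 0)
      y <- drop(crossprod(eg$vectors[, keep, drop = FALSE], S_tilde))
      sum(y^2 / eg$values[keep])
    }
  }, numeric(1L))
}
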