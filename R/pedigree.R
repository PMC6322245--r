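#' Genetic model for coding offspring genotypes
#'
#' Defines how an offspring's count of the target allele is mapped to the
#' coded genotype \eqn{x_i} entering the FBAT statistics: under the recessive
#' model homozygous carriers (count 2) are coded 1 and all others 0; under the
#' additive model the allele count itself (0/1/2) is used; under the dominant
#' model any carrier (count >= 1) is coded 1.
#'
#' @param mode One of `"recessive"`, `"additive"`, `"dominant"`.
#' @param target_allele Character label of the marker allele being counted
#'   (PED alleles are arbitrary strings; either allele of a biallelic marker
#'   may be designated).
#' @return An object of class `genetic_model`.
#' @examples
#' genetic_model("recessive", target_allele = "2")
#' @export
genetic_model <- function(mode = c("recessive", "additive", "dominant"),
                          target_allele = "2") {
  mode <- match.arg(mode)
  stopifnot(is.character(target_allele), length(target_allele) == 1L,
            nzchar(target_allele), target_allele != "0")
  structure(list(mode = mode, target_allele = target_allele),
            class = "genetic_model")
}

#' @export
print.genetic_model <- function(x, ...) {
  cat(sprintf("<genetic_model> mode=%s, target allele=%s\n",
              x$mode, x$target_allele))
  invisible(x)
}

#' Construct a pedigree of nuclear families
#'
#' A pedigree is a set of individuals grouped into nuclear families, the
#' conditioning unit of family-based association tests. Individuals are
#' supplied as a data frame in linkage-PED column order; multi-generation or
#' half-sib structures are decomposed into nuclear families keyed by the
#' (father, mother) pair, so an individual may appear as offspring in one
#' family and as a parent in another.
#'
#' @param members Data frame with columns `fid`, `id`, `father`, `mother`,
#'   `sex`, `phen`, `a1`, `a2`. Parent ids and alleles use `"0"` (or `NA`) for
#'   missing; `a1`/`a2` are arbitrary allele labels.
#' @return An object of class `pedigree` with elements `members` (normalized
#'   data frame) and `families` (list with `father`, `mother`, `offspring` id
#'   vectors).
#' @export
pedigree <- function(members) {
  required <- c("fid", "id", "father", "mother", "sex", "phen", "a1", "a2")
  if (!all(required %in% names(members)))
    stop("members must have columns: ", paste(required, collapse = ", "))
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  for (col in c("fid", "id", "father", "mother", "a1", "a2"))
    members[[col]] <- as.character(members[[col]])
  members$father[members$father %in% "0"] <- NA_character_
  members$mother[members$mother %in% "0"] <- NA_character_
  members$a1[members$a1 %in% "0"] <- NA_character_
  members$a2[members$a2 %in% "0"] <- NA_character_

  if (anyDuplicated(members$id))
    stop("individual ids must be unique across the pedigree: duplicated ",
         paste(unique(members$id[duplicated(members$id)]), collapse = ", "))
  one_parent <- xor(is.na(members$father), is.na(members$mother))
  if (any(one_parent))
    stop("individuals must have both parents or neither: ",
         paste(members$id[one_parent], collapse = ", "))
  alleles <- stats::na.omit(unique(c(members$a1, members$a2)))
  if (length(alleles) > 2L)
    stop("marker must be biallelic; saw alleles: ",
         paste(alleles, collapse = ", "))
  kids <- members[!is.na(members$father), , drop = FALSE]
  missing_parents <- setdiff(unique(c(kids$father, kids$mother)), members$id)
  if (length(missing_parents))
    stop("parent id(s) referenced but absent from pedigree: ",
         paste(missing_parents, collapse = ", "))

  families <- list()
  if (nrow(kids)) {
    key <- paste(kids$father, kids$mother, sep = "\r")
    for (k in unique(key)) {
      rows <- kids[key == k, , drop = FALSE]
      families[[length(families) + 1L]] <-
        list(father = rows$father[1L], mother = rows$mother[1L],
             offspring = rows$id)
    }
  }
  structure(list(members = members, families = families), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals, %d nuclear families, %d founders\n",
              nrow(x$members), length(x$families), sum(is_founder(x))))
  invisible(x)
}

#' Founder indicator
#'
#' @param ped A [pedigree()].
#' @return Logical vector over `ped$members` rows: `TRUE` for individuals with
#'   no recorded parents.
#' @export
is_founder <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  is.na(ped$members$father) & is.na(ped$members$mother)
}

#' Count copies of the target allele
#'
#' @param ped A [pedigree()].
#' @param ids Individual ids (default: all members).
#' @param target_allele Allele label to count.
#' @return Named integer vector in `{0, 1, 2}`, `NA` where the genotype is
#'   missing.
#' @export
allele_count <- function(ped, ids = ped$members$id, target_allele) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- match(ids, ped$members$id)
  if (anyNA(idx))
    stop("unknown individual id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  a1 <- ped$members$a1[idx]
  a2 <- ped$members$a2[idx]
  g <- (a1 == target_allele) + (a2 == target_allele)
  g[is.na(a1) | is.na(a2)] <- NA_integer_
  stats::setNames(as.integer(g), ids)
}

#' Read a linkage PED file
#'
#' Parses the whitespace-delimited linkage pedigree format: six leading
#' columns (family, individual, father, mother, sex, phenotype) followed by
#' two allele columns for a single biallelic marker; `"0"` marks a missing
#' parent id or allele.
#'
#' @param path Path to a PED file.
#' @return A [pedigree()].
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 8L)
  if (length(bad))
    stop(sprintf("malformed PED line %d: expected 8 columns, found %d",
                 bad[1L], lengths(fields)[bad[1L]]))
  m <- do.call(rbind, fields)
  members <- data.frame(fid = m[, 1L], id = m[, 2L], father = m[, 3L],
                        mother = m[, 4L], sex = m[, 5L], phen = m[, 6L],
                        a1 = m[, 7L], a2 = m[, 8L],
                        stringsAsFactors = FALSE)
  pedigree(members)
}

#' Write a pedigree in linkage PED format
#'
#' Emits the same dialect [read_ped()] consumes; a write/read round trip
#' reproduces the pedigree exactly.
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  m <- ped$members
  enc <- function(x) ifelse(is.na(x), "0", x)
  lines <- paste(m$fid, m$id, enc(m$father), enc(m$mother), m$sex, m$phen,
                 enc(m$a1), enc(m$a2))
  writeLines(lines, path)
  invisible(path)
}

#' Mendelian offspring-genotype distribution
#'
#' Probability distribution of an offspring's target-allele count given the
#' two parental counts, under Mendelian transmission: each parent transmits
#' the target allele independently with probability `g/2`.
#'
#' @param gf,gm Parental target-allele counts in `{0, 1, 2}`.
#' @return Numeric vector of length 3, names `"0","1","2"`, summing to 1.
#' @examples
#' mating_distribution(1, 1)  # 0.25 0.50 0.25
#' @export
mating_distribution <- function(gf, gm) {
  if (length(gf) != 1L || length(gm) != 1L || is.na(gf) || is.na(gm))
    stop("parental genotypes must be single non-missing allele counts ",
         "(families with a missing parent are excluded from testing)")
  if (!gf %in% 0:2 || !gm %in% 0:2)
    stop("parental allele counts must be 0, 1 or 2")
  pf <- gf / 2
  pm <- gm / 2
  p <- c((1 - pf) * (1 - pm),
         pf * (1 - pm) + (1 - pf) * pm,
         pf * pm)
  stats::setNames(p, c("0", "1", "2"))
}

#' Code a genotype under a genetic model
#'
#' Maps target-allele counts to the coded value \eqn{x_i}: recessive
#' `1[g == 2]`, additive `g`, dominant `1[g >= 1]`.
#'
#' @param g Integer vector of allele counts in `{0, 1, 2}`.
#' @param model A [genetic_model()].
#' @return Numeric vector of coded genotypes.
#' @export
code_genotype <- function(g, model) {
  stopifnot(inherits(model, "genetic_model"))
  if (anyNA(g)) stop("cannot code a missing genotype")
  if (!all(g %in% 0:2)) stop("allele counts must be 0, 1 or 2")
  x <- switch(model$mode,
              recessive = as.numeric(g == 2L),
              additive  = as.numeric(g),
              dominant  = as.numeric(g >= 1L))
  names(x) <- names(g)
  x
}

#' Conditional moments of the coded offspring genotype
#'
#' Mean and variance of the coded genotype \eqn{x_i} conditional on the
#' parental genotypes, i.e. the moments of [code_genotype()] under
#' [mating_distribution()]. These are the \eqn{E(x_i | p_{i1}, p_{i2})} and
#' \eqn{Var(x_i | p_{i1}, p_{i2})} terms of the FBAT statistics.
#'
#' @inheritParams mating_distribution
#' @param model A [genetic_model()].
#' @return List with elements `E_x` and `Var_x` (`Var_x >= 0`).
#' @examples
#' conditional_moments(1, 1, genetic_model("recessive"))  # E 0.25, Var 0.1875
#' @export
conditional_moments <- function(gf, gm, model) {
  p <- mating_distribution(gf, gm)
  x <- code_genotype(0:2, model)
  E_x <- sum(p * x)
  Var_x <- sum(p * x^2) - E_x^2
  list(E_x = E_x, Var_x = max(Var_x, 0))
}

#' Which nuclear families are informative for a marker?
#'
#' A family is informative when its parental mating type yields nonzero
#' variance in the coded offspring genotype, i.e. when it can contribute to
#' the FBAT statistic. Families with a missing parental genotype are reported
#' `NA` (they are excluded from testing with a warning downstream).
#'
#' @param ped A [pedigree()].
#' @param model A [genetic_model()].
#' @return Logical vector, one element per family in `ped$families`.
#' @export
informative_families <- function(ped, model) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "genetic_model"))
  vapply(ped$families, function(fam) {
    gf <- allele_count(ped, fam$father, model$target_allele)
    gm <- allele_count(ped, fam$mother, model$target_allele)
    if (is.na(gf) || is.na(gm)) return(NA)
    conditional_moments(gf, gm, model)$Var_x > 0
  }, logical(1L))
}

#' Founder allele frequency
#'
#' Frequency of an allele among genotyped founders (individuals with no
#' recorded parents). Founders are used because offspring allele frequencies
#' in family-ascertained samples are confounded by the ascertainment itself.
#'
#' @param ped A [pedigree()].
#' @param allele Allele label.
#' @return Frequency in `[0, 1]`.
#' @export
founder_allele_frequency <- function(ped, allele) {
  stopifnot(inherits(ped, "pedigree"))
  f <- ped$members[is_founder(ped), , drop = FALSE]
  typed <- !is.na(f$a1) & !is.na(f$a2)
  if (!any(typed)) stop("no genotyped founders in pedigree")
  sum(f$a1[typed] == allele, f$a2[typed] == allele) / (2 * sum(typed))
}
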