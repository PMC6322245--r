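# Builders for small pedigrees used across tests.

counts_to_allele_pair <- function(g, target = "2", other = "1") {
  cbind(ifelse(g >= 1L, target, other), ifelse(g == 2L, target, other))
}

# n nuclear trio families with fixed parental allele counts; offspring counts
# drawn from the Mendelian mating distribution unless supplied.
trio_ped <- function(n, gf = 1L, gm = 1L, kid_counts = NULL) {
  if (is.null(kid_counts))
    kid_counts <- sample(0:2, n, replace = TRUE,
                         prob = mating_distribution(gf, gm))
  i <- seq_len(n)
  dad <- sprintf("d%d", i); mum <- sprintf("m%d", i); kid <- sprintf("k%d", i)
  fa <- counts_to_allele_pair(rep(gf, n))
  ma <- counts_to_allele_pair(rep(gm, n))
  ka <- counts_to_allele_pair(kid_counts)
  pedigree(data.frame(
    fid = rep(sprintf("F%d", i), 3L),
    id = c(dad, mum, kid),
    father = c(rep("0", 2L * n), dad),
    mother = c(rep("0", 2L * n), mum),
    sex = "0", phen = "0",
    a1 = c(fa[, 1L], ma[, 1L], ka[, 1L]),
    a2 = c(fa[, 2L], ma[, 2L], ka[, 2L]),
    stringsAsFactors = FALSE))
}

# Single-family pedigree with arbitrary parental/offspring allele counts.
one_family_ped <- function(gf, gm, kid_counts) {
  ka <- counts_to_allele_pair(kid_counts)
  fa <- counts_to_allele_pair(gf); ma <- counts_to_allele_pair(gm)
  kid <- sprintf("k%d", seq_along(kid_counts))
  pedigree(data.frame(
    fid = "F1", id = c("dad", "mum", kid),
    father = c("0", "0", rep("dad", length(kid))),
    mother = c("0", "0", rep("mum", length(kid))),
    sex = "0", phen = "0",
    a1 = c(fa[1L], ma[1L], ka[, 1L]),
    a2 = c(fa[2L], ma[2L], ka[, 2L]),
    stringsAsFactors = FALSE))
}

# Brute-force conditional moments: enumerate the 4 equiprobable parental
# transmissions (independent oracle for conditional_moments / FBAT terms).
enumerate_moments <- function(gf, gm, model) {
  f_alleles <- rep(c(1L, 0L), c(gf, 2L - gf))
  m_alleles <- rep(c(1L, 0L), c(gm, 2L - gm))
  counts <- as.vector(outer(f_alleles, m_alleles, "+"))
  x <- code_genotype(counts, model)
  list(E_x = mean(x), Var_x = mean(x^2) - mean(x)^2, codes = x,
       counts = counts)
}

all_models <- function() list(
  genetic_model("recessive"), genetic_model("additive"),
  genetic_model("dominant"))
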