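# Marker validation: KASP/PARMS-style fluorescence genotype calling by
# rectangular gating, cosegregation against phenotypes, and Mendelian
# segregation chi-square tests.

#' Call a genotype from FAM/HEX fluorescence intensities
#'
#' Rectangular gating: FAM detected and HEX not -> AA (wild-type allele
#' homozygote); HEX detected and FAM not -> BB (mutant homozygote); both
#' detected -> AB; neither -> NN (no call). Ties at a threshold count as
#' detected.
#'
#' @param fam,hex Non-negative intensities (vectorized).
#' @param fam_thresh,hex_thresh Positive detection thresholds.
#' @return Character vector over `{"AA","AB","BB","NN"}`.
#' @export
call_genotype <- function(fam, hex, fam_thresh, hex_thresh) {
  stopifnot(fam_thresh > 0, hex_thresh > 0)
  if (any(fam < 0 | hex < 0)) abort_("intensities must be >= 0")
  f <- fam >= fam_thresh; h <- hex >= hex_thresh
  ifelse(f & h, "AB", ifelse(f, "AA", ifelse(h, "BB", "NN")))
}

#' Cosegregation of a marker with a phenotype
#'
#' Expected mapping AA<->WT, AB<->HET, BB<->MUT. NN calls are excluded from
#' the concordance check but counted.
#'
#' @param genotypes Named character vector of calls (AA/AB/BB/NN).
#' @param phenotypes Named character vector of classes (WT/HET/MUT).
#' @return List `perfect` (logical), `discordant` (ids), `n_called` (non-NN
#'   among shared samples), `n_no_call`.
#' @export
cosegregation_check <- function(genotypes, phenotypes) {
  ids <- intersect(names(genotypes), names(phenotypes))
  if (length(ids) == 0L) abort_("no overlapping samples")
  g <- genotypes[ids]; p <- phenotypes[ids]
  called <- g != "NN"
  expected <- c(AA = "WT", AB = "HET", BB = "MUT")
  disc <- ids[called & expected[g] != p]
  list(perfect = length(disc) == 0L, discordant = unname(disc),
       n_called = sum(called), n_no_call = sum(!called))
}

#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit of observed AA/AB/BB counts against an expected
#' ratio (1:2:1 for a codominant marker in an F2 by default); df = 2.
#'
#' @param counts Integer vector `c(n_AA, n_AB, n_BB)` with positive total.
#' @param ratio Expected ratio (length 3).
#' @return List `chi2`, `df`, `pvalue`.
#' @examples
#' segregation_chi2(c(25, 50, 25))  # exact fit: chi2 = 0, p = 1
#' @export
segregation_chi2 <- function(counts, ratio = c(1, 2, 1)) {
  stopifnot(length(counts) == 3L, length(ratio) == 3L)
  if (any(counts < 0)) abort_("counts must be >= 0")
  n <- sum(counts)
  if (n == 0) abort_("zero total count")
  expected <- n * ratio / sum(ratio)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = 2L, pvalue = pchisq(chi2, 2, lower.tail = FALSE))
}

#' Simulate well-separated fluorescence clusters for genotypes
#'
#' Generates FAM/HEX intensities for known genotype calls, emulating a clean
#' PARMS plate read: homozygotes light one dye, heterozygotes both, no-calls
#' neither.
#'
#' @param genotypes Named character vector over `{"AA","AB","BB","NN"}`.
#' @param seed Integer seed.
#' @param noise SD of the Gaussian intensity noise.
#' @return data.frame `sample`, `fam`, `hex`.
#' @export
simulate_fluorescence <- function(genotypes, seed, noise = 0.08) {
  local_seed(seed)
  hi <- 2; lo <- 0.15
  fam_mu <- c(AA = hi, AB = hi, BB = lo, NN = lo)[genotypes]
  hex_mu <- c(AA = lo, AB = hi, BB = hi, NN = lo)[genotypes]
  n <- length(genotypes)
  data.frame(sample = names(genotypes),
             fam = pmax(rnorm(n, fam_mu, noise), 0),
             hex = pmax(rnorm(n, hex_mu, noise), 0),
             stringsAsFactors = FALSE)
}
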