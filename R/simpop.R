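# Forward simulation of an F2 mapping population segregating for one
# incompletely dominant EMS allele, phenotype-selected bulks, and pooled
# sequencing depths. Also builds the deterministic worked-example fixtures
# (fine-mapping genotype matrix, candidate-interval gene table).

#' Genetic map of SNP loci on one chromosome
#'
#' A map is an ordered set of loci, each with a physical (bp, 1-based) and a
#' genetic (cM) position. Both coordinates must be strictly increasing.
#'
#' @param chrom Chromosome label.
#' @param pos_bp Integer vector of 1-based physical positions.
#' @param pos_cM Numeric vector of genetic positions (cM, >= 0).
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `pos_bp`, `pos_cM` and attribute `chrom`.
#' @examples
#' genetic_map("A03", c(1e4, 2e4), c(0.04, 0.08))
#' @export
genetic_map <- function(chrom, pos_bp, pos_cM) {
  stopifnot(length(chrom) == 1L, length(pos_bp) == length(pos_cM),
            length(pos_bp) >= 1L)
  pos_bp <- as.integer(round(pos_bp))
  pos_cM <- as.numeric(pos_cM)
  if (any(pos_bp < 1L)) abort_("physical positions must be >= 1")
  if (any(pos_cM < 0)) abort_("genetic positions must be >= 0")
  if (length(pos_bp) > 1L &&
      (any(diff(pos_bp) <= 0L) || any(diff(pos_cM) <= 0)))
    abort_("map positions must be strictly increasing in bp and cM")
  out <- data.frame(pos_bp = pos_bp, pos_cM = pos_cM)
  attr(out, "chrom") <- as.character(chrom)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d loci on %s (%.0f bp..%.0f bp, %.2f cM)\n",
              nrow(x), attr(x, "chrom"), min(x$pos_bp), max(x$pos_bp),
              max(x$pos_cM) - min(x$pos_cM)))
  invisible(x)
}

#' Default SNP panel map
#'
#' One SNP every `spacing_bp` along a chromosome with a uniform recombination
#' rate. The 10 kb default spacing matches the window step of [window_scan()]
#' so every window holds sites.
#'
#' @param chrom Chromosome label.
#' @param length_bp Chromosome length (bp).
#' @param spacing_bp Distance between consecutive SNPs (bp).
#' @param cM_per_Mb Uniform genetic:physical rate (centimorgan per megabase).
#' @return A [genetic_map()].
#' @export
default_map <- function(chrom = "A03", length_bp = 30e6, spacing_bp = 1e4,
                        cM_per_Mb = 4) {
  pos <- seq(spacing_bp, length_bp, by = spacing_bp)
  genetic_map(chrom, pos, pos * cM_per_Mb / 1e6)
}

#' SPAD phenotype model for an incompletely dominant chlorophyll mutation
#'
#' Class means must respect the diagnostic thresholds (mutant < 10,
#' heterozygote in \[10, 20\], wild type > 20) so that at sigma = 0
#' classification is perfect. Defaults 30/15/5 with sigma 2 give essentially
#' zero misclassification; raise `sigma` to study bulk contamination.
#'
#' @param mu_wt,mu_het,mu_mut SPAD class means.
#' @param sigma Gaussian noise SD (>= 0).
#' @return An object of class `pheno_model`.
#' @export
pheno_model <- function(mu_wt = 30, mu_het = 15, mu_mut = 5, sigma = 2) {
  stopifnot(sigma >= 0)
  if (!(mu_mut < 10 && mu_het > 10 && mu_het < 20 && mu_wt > 20))
    abort_("class means must satisfy mu_mut < 10 < mu_het < 20 < mu_wt")
  structure(list(mu_wt = mu_wt, mu_het = mu_het, mu_mut = mu_mut,
                 sigma = sigma), class = "pheno_model")
}

#' Bulk design for pooled sequencing
#'
#' Defaults follow the common design of 25 plants per phenotype bulk with the
#' wild-type (G) pool at ~40x and the mutant (Y) pool at ~34x coverage.
#'
#' @param n_per_bulk Plants per bulk (>= 1).
#' @param coverage_g,coverage_y Mean sequencing depth per pool (> 0).
#' @return An object of class `bulk_spec`.
#' @export
bulk_spec <- function(n_per_bulk = 25, coverage_g = 39.82, coverage_y = 33.75) {
  stopifnot(n_per_bulk >= 1, coverage_g > 0, coverage_y > 0)
  structure(list(n_per_bulk = as.integer(n_per_bulk),
                 coverage_g = coverage_g, coverage_y = coverage_y),
            class = "bulk_spec")
}

# interpolate cM at arbitrary bp within the map span (linear between loci)
map_bp_to_cM <- function(map, bp) {
  if (bp < min(map$pos_bp) || bp > max(map$pos_bp))
    abort_("causal locus off map")
  stats::approx(map$pos_bp, map$pos_cM, xout = bp, ties = "ordered")$y
}

# one recombinant gamete: crossovers are a Poisson process on the cM axis
# (Haldane, no interference); the parental phase at the left map end is
# Bernoulli(1/2). Stored as phase + breakpoints so the gamete can be
# genotyped later at any position (e.g. newly designed markers).
sim_gamete <- function(span_lo, span_hi) {
  n_xo <- rpois(1L, (span_hi - span_lo) / 100)
  list(phase0 = sample(0:1, 1L),
       xo = if (n_xo) sort(runif(n_xo, span_lo, span_hi)) else numeric(0))
}

# allele (0 = reference parent, 1 = mutant parent) of a gamete at cM positions
gamete_alleles <- function(g, pos_cM) {
  (g$phase0 + findInterval(pos_cM, g$xo)) %% 2L
}

#' Simulate an F2 population with one causal locus
#'
#' Each individual is the union of two independently recombined gametes drawn
#' under the Haldane model (crossovers Poisson on the cM axis, no
#' interference). The SPAD phenotype is the class mean selected by the dosage
#' at `causal_bp` plus Gaussian noise, truncated at zero; the phenotype class
#' is then re-derived from SPAD via [classify_spad()], so misclassification
#' across the 10/20 thresholds is possible when `model$sigma` is large.
#'
#' @param n Number of individuals (>= 0).
#' @param map A [genetic_map()].
#' @param causal_bp Physical position of the causal locus; must lie within the
#'   map span (interpolated to cM if not itself a mapped locus).
#' @param model A [pheno_model()].
#' @param seed Integer seed.
#' @param n_readings SPAD instrument readings averaged per plant (>= 1). The
#'   recorded SPAD is the mean of `n_readings` independent draws, as in field
#'   practice where a SPAD meter is read several times per leaf; the effective
#'   noise SD is `sigma / sqrt(n_readings)`.
#' @return An object of class `f2_pop`: list with `dosage` (n x loci integer
#'   matrix of mutant-allele counts 0/1/2, rownames individual ids), `spad`,
#'   `pheno_class`, `causal_dosage`, plus the `map`, `causal_bp` and `seed`.
#' @examples
#' pop <- simulate_f2(20, default_map(length_bp = 1e6), 5e5, seed = 1)
#' table(pop$pheno_class)
#' @export
simulate_f2 <- function(n, map, causal_bp, model = pheno_model(), seed,
                        n_readings = 1) {
  stopifnot(inherits(map, "genetic_map"), n >= 0, n_readings >= 1)
  causal_cM <- map_bp_to_cM(map, causal_bp)
  local_seed(seed)
  n <- as.integer(n)
  span <- range(map$pos_cM)
  L <- nrow(map)
  dosage <- matrix(0L, nrow = n, ncol = L)
  causal_dosage <- integer(n)
  gametes <- vector("list", n)
  for (i in seq_len(n)) {
    g1 <- sim_gamete(span[1], span[2])
    g2 <- sim_gamete(span[1], span[2])
    gametes[[i]] <- list(g1, g2)
    d <- gamete_alleles(g1, map$pos_cM) + gamete_alleles(g2, map$pos_cM)
    dosage[i, ] <- d
    causal_dosage[i] <- gamete_alleles(g1, causal_cM) +
                        gamete_alleles(g2, causal_cM)
  }
  ids <- sprintf("F2_%04d", seq_len(n))
  rownames(dosage) <- ids
  colnames(dosage) <- paste0(attr(map, "chrom"), "_", map$pos_bp)
  mu <- c(model$mu_wt, model$mu_het, model$mu_mut)[causal_dosage + 1L]
  spad <- pmax(rnorm(n, mu, model$sigma / sqrt(n_readings)), 0)
  structure(list(id = ids, dosage = dosage, spad = spad,
                 pheno_class = if (n) classify_spad(spad) else character(0),
                 causal_dosage = causal_dosage, gametes = gametes, map = map,
                 causal_bp = causal_bp, model = model, seed = seed),
            class = "f2_pop")
}

#' Genotype simulated individuals at arbitrary positions
#'
#' Uses the stored gamete breakpoints, so individuals can be genotyped at
#' markers designed after the population was simulated (as in iterative fine
#' mapping). Positions are interpolated to cM through the population's map.
#'
#' @param pop An [simulate_f2()] population.
#' @param bp Physical positions within the map span.
#' @return Integer dosage matrix, individuals x positions.
#' @export
genotype_at <- function(pop, bp) {
  stopifnot(inherits(pop, "f2_pop"))
  cM <- vapply(bp, map_bp_to_cM, 0, map = pop$map)
  d <- vapply(pop$gametes, function(g)
    gamete_alleles(g[[1L]], cM) + gamete_alleles(g[[2L]], cM),
    integer(length(cM)))
  d <- if (length(cM) == 1L) matrix(d, ncol = 1L) else t(d)
  dimnames(d) <- list(pop$id, paste0(attr(pop$map, "chrom"), "_", bp))
  d
}

#' @export
print.f2_pop <- function(x, ...) {
  cat(sprintf("f2_pop: %d individuals, %d loci on %s, causal at %s bp (seed %s)\n",
              length(x$id), ncol(x$dosage), attr(x$map, "chrom"),
              format(x$causal_bp, big.mark = ","), x$seed))
  if (length(x$id)) print(table(x$pheno_class))
  invisible(x)
}

#' @export
as.data.frame.f2_pop <- function(x, ...) {
  data.frame(id = x$id, spad = x$spad, pheno_class = x$pheno_class,
             causal_dosage = x$causal_dosage)
}

#' Draw phenotype-selected bulks from an F2 population
#'
#' The wild-type (G) bulk samples only WT-class individuals (SPAD > 20) and
#' the mutant (Y) bulk only MUT-class individuals (SPAD < 10); heterozygotes
#' enter neither bulk.
#'
#' @param pop An [simulate_f2()] population.
#' @param spec A [bulk_spec()].
#' @param seed Integer seed.
#' @return List with character id vectors `G` and `Y`, each of length
#'   `spec$n_per_bulk`.
#' @export
build_bulks <- function(pop, spec = bulk_spec(), seed) {
  stopifnot(inherits(pop, "f2_pop"), inherits(spec, "bulk_spec"))
  wt <- pop$id[pop$pheno_class == "WT"]
  mut <- pop$id[pop$pheno_class == "MUT"]
  if (length(wt) < spec$n_per_bulk)
    abort_(sprintf("insufficient WT-class individuals: need %d, have %d",
                   spec$n_per_bulk, length(wt)))
  if (length(mut) < spec$n_per_bulk)
    abort_(sprintf("insufficient MUT-class individuals: need %d, have %d",
                   spec$n_per_bulk, length(mut)))
  local_seed(seed)
  list(G = sort(sample(wt, spec$n_per_bulk)),
       Y = sort(sample(mut, spec$n_per_bulk)))
}

#' Pooled sequencing depths for one bulk
#'
#' At each site the pool's mutant-allele frequency is the mean dosage of the
#' bulk divided by two; the total depth is Poisson(coverage) and the
#' mutant-allele (alt) depth Binomial(depth, p).
#'
#' @param bulk_ids Ids of the pooled individuals (must exist in `pop`).
#' @param pop An [simulate_f2()] population.
#' @param sites_bp Physical positions to sample; must be mapped loci of `pop`.
#' @param coverage Mean depth (> 0).
#' @param seed Integer seed.
#' @return data.frame with `pos`, `p` (true pool allele frequency), `depth`,
#'   `ref_depth`, `alt_depth`.
#' @export
sample_pool_depths <- function(bulk_ids, pop, sites_bp, coverage, seed) {
  stopifnot(inherits(pop, "f2_pop"), coverage > 0)
  if (length(bulk_ids) == 0L) abort_("empty bulk")
  if (!all(bulk_ids %in% pop$id)) abort_("unknown individual ids in bulk")
  j <- match(sites_bp, pop$map$pos_bp)
  if (anyNA(j)) abort_("sites_bp must be mapped loci of the population")
  local_seed(seed)
  d <- pop$dosage[bulk_ids, j, drop = FALSE]
  p <- colSums(d) / (2 * length(bulk_ids))
  depth <- rpois(length(j), coverage)
  alt <- rbinom(length(j), depth, p)
  data.frame(pos = pop$map$pos_bp[j], p = p, depth = depth,
             ref_depth = depth - alt, alt_depth = alt)
}

#' Pooled variant sites for two bulks
#'
#' Combines [sample_pool_depths()] for the G and Y bulks into the standard
#' site table consumed by the scan stage, with EMS-style ref/alt alleles
#' (G>A or C>T drawn per site).
#'
#' @inheritParams sample_pool_depths
#' @param bulks List with `G` and `Y` id vectors (see [build_bulks()]).
#' @param spec A [bulk_spec()] supplying the two coverages.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `g_ref`,
#'   `g_alt`, `y_ref`, `y_alt`.
#' @export
pool_sites <- function(bulks, pop, sites_bp, spec = bulk_spec(), seed) {
  g <- sample_pool_depths(bulks$G, pop, sites_bp, spec$coverage_g, seed)
  y <- sample_pool_depths(bulks$Y, pop, sites_bp, spec$coverage_y, seed + 1L)
  local_seed(seed + 2L)
  ref <- sample(c("G", "C"), length(sites_bp), replace = TRUE)
  data.frame(chrom = attr(pop$map, "chrom"), pos = g$pos,
             ref = ref, alt = ifelse(ref == "G", "A", "T"),
             g_ref = g$ref_depth, g_alt = g$alt_depth,
             y_ref = y$ref_depth, y_alt = y$alt_depth,
             stringsAsFactors = FALSE)
}

#' Marker panel for fine mapping
#'
#' @param marker Marker names (unique).
#' @param chrom Chromosome label.
#' @param pos_bp Strictly increasing physical positions.
#' @return data.frame of class `marker_panel` with columns `marker`, `chrom`,
#'   `pos_bp`, ordered by position.
#' @export
marker_panel <- function(marker, chrom, pos_bp) {
  stopifnot(length(marker) == length(pos_bp), !anyDuplicated(marker))
  o <- order(pos_bp)
  marker <- as.character(marker)[o]; pos_bp <- as.numeric(pos_bp)[o]
  if (length(pos_bp) > 1L && any(diff(pos_bp) <= 0))
    abort_("marker positions must be strictly increasing")
  out <- data.frame(marker = marker, chrom = as.character(chrom),
                    pos_bp = pos_bp, stringsAsFactors = FALSE)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Nine-marker ladder spanning the scan candidate region
#'
#' M1 and M9 sit at the published flanking positions on chromosome A03
#' (1,499,657 and 5,194,567 bp); the interior marker positions are synthetic,
#' spaced so that the M5–M7 interval is 304.7 kb wide.
#'
#' @return A [marker_panel()] of markers M1..M9.
#' @export
default_marker_panel <- function() {
  marker_panel(paste0("M", 1:9), "A03",
               c(1499657, 2300000, 3200000, 3900000, 4550000,
                 4702350, 4854700, 5000000, 5194567))
}

#' Deterministic fine-mapping fixture from per-marker recombinant counts
#'
#' Builds a genotype matrix of phenotype-selected (MUT-class) individuals in
#' which every recombinant carries exactly one breakpoint, placed so that the
#' recomputed per-marker recombinant counts equal `counts_by_marker` exactly.
#' Recombinant stretches are heterozygous (H) — the single-crossover state in
#' a selected homozygous-mutant plant — and all other calls are B.
#'
#' The count profile must be realizable with single breakpoints: at least one
#' marker with zero recombinants, and counts non-increasing from each end of
#' the panel toward the zero-count (cosegregating) block.
#'
#' @param counts_by_marker Named integer vector, one count per panel marker.
#' @param n_individuals Total number of selected individuals (>= total
#'   recombinants).
#' @param markers A [marker_panel()].
#' @param seed Integer seed (row shuffling and SPAD noise).
#' @return List with `genotypes` (character matrix individuals x markers),
#'   `phenotypes` (data.frame id, spad, pheno_class — all MUT) and `markers`.
#' @examples
#' fx <- make_finemap_fixture(
#'   c(M1 = 55, M2 = 15, M3 = 6, M4 = 4, M5 = 2, M6 = 0, M7 = 9, M8 = 17,
#'     M9 = 21), 1524, default_marker_panel(), seed = 1)
#' colSums(fx$genotypes != "B")
#' @export
make_finemap_fixture <- function(counts_by_marker, n_individuals, markers,
                                 seed) {
  stopifnot(inherits(markers, "marker_panel"))
  m <- markers$marker
  if (!setequal(names(counts_by_marker), m))
    abort_("counts_by_marker names must match the marker panel")
  cnt <- as.integer(counts_by_marker[m])      # panel (positional) order
  k <- length(cnt)
  zero <- which(cnt == 0L)
  if (length(zero) == 0L && any(cnt > 0L))
    abort_("not realizable with single breakpoints: no zero-count marker")
  z1 <- if (length(zero)) min(zero) else k
  z2 <- if (length(zero)) max(zero) else 1L
  if (length(zero) && any(cnt[z1:z2] != 0L))
    abort_("not realizable with single breakpoints: zero block not contiguous")
  left <- cnt[seq_len(z1)]                     # ..down to 0
  right <- rev(cnt[z2:k])                      # ..down to 0 from right
  if (any(diff(left) > 0L) || any(diff(right) > 0L))
    abort_("not realizable with single breakpoints")
  n_rec <- if (z1 > 1L) left[1L] else 0L
  n_rec <- n_rec + if (z2 < k) right[1L] else 0L
  if (n_individuals < n_rec)
    abort_("n_individuals smaller than total recombinants")
  geno <- matrix("B", nrow = n_individuals, ncol = k,
                 dimnames = list(sprintf("R_%04d", seq_len(n_individuals)), m))
  row <- 1L
  # left-side recombinants: breakpoint between marker j and j+1 -> H at 1..j
  for (j in seq_len(max(z1 - 1L, 0L))) {
    n_j <- left[j] - left[j + 1L]
    for (r in seq_len(n_j)) { geno[row, seq_len(j)] <- "H"; row <- row + 1L }
  }
  # right-side recombinants, mirrored
  for (j in seq_len(max(k - z2, 0L))) {
    n_j <- right[j] - right[j + 1L]
    for (r in seq_len(n_j)) { geno[row, (k - j + 1L):k] <- "H"; row <- row + 1L }
  }
  local_seed(seed)
  geno <- geno[sample(n_individuals), , drop = FALSE]
  rownames(geno) <- sprintf("R_%04d", seq_len(n_individuals))
  spad <- pmin(pmax(rnorm(n_individuals, 5, 1.5), 0), 9.9)
  list(genotypes = geno,
       phenotypes = data.frame(id = rownames(geno), spad = spad,
                               pheno_class = classify_spad(spad),
                               stringsAsFactors = FALSE),
       markers = markers)
}

# random non-stop codons, used to pad synthetic CDS sequences
.codons_nostop <- setdiff(names(Biostrings::GENETIC_CODE),
                          names(Biostrings::GENETIC_CODE)[
                            Biostrings::GENETIC_CODE == "*"])

random_cds <- function(n_codons) {
  body <- sample(.codons_nostop, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Candidate-interval gene/variant/expression fixture
#'
#' Emulates the worked example of a 56-gene candidate interval: 15 genes carry
#' exonic variants — 2 frameshift deletions, 3 nonsynonymous SNVs (2 of which
#' are expressed in neither line) and 10 synonymous SNVs — so that the triage
#' cascade retains exactly one candidate. The designated candidate (`g*` id in
#' `$candidate`) has a 4149-bp CDS with codon 1349 = GAA and a G>A SNV at CDS
#' position 4045 (Glu1349Lys). A handful of non-exonic variants are included
#' so the exonic filter is exercised. All identifiers and sequences are
#' synthetic.
#'
#' @param seed Integer seed.
#' @param chrom Chromosome label.
#' @param interval_bp Length-2 genomic span over which the 56 genes are laid.
#' @param candidate_bp Optional genomic position; when given, the gene whose
#'   span covers (or is nearest to) it is designated the true candidate, so a
#'   pipeline can tie the candidate to a simulated causal locus.
#' @return List with `genes` (data.frame: id, chrom, start, end, strand,
#'   annotation, expressed_wt, expressed_mut), `variants` (data.frame: gene,
#'   cds_pos, ref, alt, exonic), `cds` (named character vector of CDS
#'   sequences for the variant-bearing genes) and `candidate` (the id the
#'   triage cascade should return).
#' @export
make_gene_table_fixture <- function(seed, chrom = "A03",
                                    interval_bp = c(4550000, 4854700),
                                    candidate_bp = NULL) {
  local_seed(seed)
  n_genes <- 56L
  ids <- sprintf("g%03d", seq_len(n_genes))
  width <- max(floor(diff(interval_bp) / n_genes), 2L)
  gap <- min(100L, max(width %/% 5L, 1L))
  start <- as.integer(interval_bp[1] + (seq_len(n_genes) - 1L) * width)
  end <- as.integer(start + width - gap)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  # roles: 2 frameshift-del, 1 expressed nonsyn (the candidate),
  # 2 unexpressed nonsyn, 10 synonymous, 41 variant-free
  if (is.null(candidate_bp)) {
    pick <- sample(n_genes, 15L)
    cand_idx <- pick[3L]
  } else {
    cand_idx <- which.min(pmax(start - candidate_bp, 0) +
                          pmax(candidate_bp - end, 0))
    # the designated candidate must cover the position it is tied to
    start[cand_idx] <- min(start[cand_idx], as.integer(candidate_bp))
    end[cand_idx] <- max(end[cand_idx], as.integer(candidate_bp))
    others <- sample(setdiff(seq_len(n_genes), cand_idx), 14L)
    pick <- c(others[1:2], cand_idx, others[3:14])
  }
  fs_genes <- ids[pick[1:2]]
  cand_gene <- ids[cand_idx]
  ns_unexpr <- ids[pick[4:5]]
  syn_genes <- ids[pick[6:15]]

  expressed_wt <- rep(TRUE, n_genes); expressed_mut <- rep(TRUE, n_genes)
  off <- ids %in% ns_unexpr
  expressed_wt[off] <- FALSE; expressed_mut[off] <- FALSE

  annotation <- rep("hypothetical protein", n_genes)
  annotation[ids == cand_gene] <- "magnesium chelatase H subunit (ChlH)"
  annotation[ids %in% fs_genes] <- "unknown function, no chlorophyll link"

  genes <- data.frame(id = ids, chrom = chrom, start = start, end = end,
                      strand = strand, annotation = annotation,
                      expressed_wt = expressed_wt,
                      expressed_mut = expressed_mut,
                      stringsAsFactors = FALSE)

  cds <- character(0); variants <- NULL
  add_var <- function(gene, cds_pos, ref, alt, exonic = TRUE) {
    variants <<- rbind(variants, data.frame(
      gene = gene, cds_pos = as.integer(cds_pos), ref = ref, alt = alt,
      exonic = exonic, stringsAsFactors = FALSE))
  }
  put_codon <- function(s, codon_index, codon) {
    a <- (codon_index - 1L) * 3L + 1L
    paste0(substr(s, 1L, a - 1L), codon, substr(s, a + 3L, nchar(s)))
  }

  # candidate: 1383 codons (4149 bp); codon 1349 GAA, SNV G>A at 4045 (= codon
  # 1349 base 1) -> AAA, Glu->Lys
  s <- random_cds(1383L)
  s <- put_codon(s, 1349L, "GAA")
  cds[cand_gene] <- s
  add_var(cand_gene, 4045L, "G", "A")

  # two unexpressed nonsynonymous genes: GCT -> GTT (C>T, Ala->Val) at codon 20
  for (g in ns_unexpr) {
    s <- put_codon(random_cds(200L), 20L, "GCT")
    cds[g] <- s
    add_var(g, 59L, "C", "T")          # codon 20 base 2
  }
  # ten synonymous genes: GGG -> GGA (G>A at third base, Gly->Gly) at codon 30
  for (g in syn_genes) {
    s <- put_codon(random_cds(200L), 30L, "GGG")
    cds[g] <- s
    add_var(g, 90L, "G", "A")
  }
  # two frameshift-deletion genes: 1-nt deletion at codon 25 (AG -> A)
  for (g in fs_genes) {
    s <- put_codon(random_cds(200L), 25L, "AGT")
    cds[g] <- s
    add_var(g, 73L, "AG", "A")
  }
  # non-exonic (promoter/intron) variants on variant-free genes: must not
  # count toward the exonic filter
  for (g in sample(setdiff(ids, names(cds)), 5L)) add_var(g, 1L, "G", "A", FALSE)

  list(genes = genes, variants = variants[order(variants$gene), ],
       cds = cds, candidate = cand_gene)
}
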