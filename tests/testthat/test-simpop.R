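test_that("genetic_map validates its invariants", {
  expect_s3_class(genetic_map("c", c(10, 20), c(0.1, 0.2)), "genetic_map")
  expect_error(genetic_map("c", c(20, 10), c(0.1, 0.2)), "increasing")
  expect_error(genetic_map("c", c(10, 20), c(0.2, 0.1)), "increasing")
  expect_error(genetic_map("c", integer(0), numeric(0)))
})

test_that("simulate_f2 handles edge cases and determinism", {
  map <- default_map(length_bp = 1e6)
  p0 <- simulate_f2(0, map, 5e5, seed = 1)
  expect_length(p0$id, 0)
  expect_error(simulate_f2(5, map, 5e7, seed = 1), "off map")
  a <- simulate_f2(30, map, 5e5, seed = 42)
  b <- simulate_f2(30, map, 5e5, seed = 42)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$spad, b$spad)
  expect_true(all(a$dosage %in% 0:2))
  # phenotype class always consistent with classify_spad
  expect_identical(a$pheno_class, classify_spad(a$spad))
})

test_that("causal-locus genotypes segregate 1:2:1 (chi-square, alpha=0.01)", {
  map <- default_map(length_bp = 1e6, spacing_bp = 1e5)
  pop <- simulate_f2(4000, map, 5e5, seed = 7)
  tab <- tabulate(pop$causal_dosage + 1L, 3L)
  p <- stats::chisq.test(tab, p = c(1, 2, 1) / 4)$p.value
  expect_gt(p, 0.01)
})

test_that("recombinant-gamete fraction matches the Haldane closed form", {
  # two loci 10 cM apart: r = (1 - exp(-0.2)) / 2 = 0.0906
  map <- genetic_map("c", c(1e4, 2e4), c(0, 10))
  pop <- simulate_f2(5000, map, 1e4, seed = 3)
  rec <- vapply(pop$gametes, function(gs) {
    a1 <- bsamap:::gamete_alleles(gs[[1]], map$pos_cM)
    a2 <- bsamap:::gamete_alleles(gs[[2]], map$pos_cM)
    c(a1[1] != a1[2], a2[1] != a2[2])
  }, logical(2))
  r_hat <- mean(rec)
  r_exp <- (1 - exp(-2 * 0.1)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / (2 * 5000))
  expect_lt(abs(r_hat - r_exp), 3 * se)
})

test_that("genotype_at agrees with the dosage matrix at mapped loci", {
  map <- default_map(length_bp = 5e5, spacing_bp = 5e4)
  pop <- simulate_f2(50, map, 2.5e5, seed = 9)
  d <- genotype_at(pop, map$pos_bp)
  expect_equal(unname(d), unname(pop$dosage))
})

test_that("build_bulks samples the phenotype classes, deterministically", {
  map <- default_map(length_bp = 1e6, spacing_bp = 1e5)
  pop <- simulate_f2(300, map, 5e5, pheno_model(sigma = 0.5), seed = 5)
  spec <- bulk_spec(n_per_bulk = 25)
  b1 <- build_bulks(pop, spec, seed = 8)
  b2 <- build_bulks(pop, spec, seed = 8)
  expect_identical(b1, b2)
  expect_length(b1$G, 25)
  expect_length(intersect(b1$G, b1$Y), 0)
  expect_true(all(pop$pheno_class[match(b1$G, pop$id)] == "WT"))
  expect_true(all(pop$pheno_class[match(b1$Y, pop$id)] == "MUT"))
  # forced sample: exactly 25 WT and 25 MUT available
  wt <- pop$id[pop$pheno_class == "WT"][1:25]
  mut <- pop$id[pop$pheno_class == "MUT"][1:25]
  keep <- c(wt, mut, pop$id[pop$pheno_class == "HET"])
  pop2 <- pop
  for (f in c("id", "spad", "pheno_class", "causal_dosage")) {
    i <- match(keep, pop$id)
    pop2[[f]] <- pop[[f]][i]
  }
  pop2$dosage <- pop$dosage[match(keep, pop$id), ]
  pop2$gametes <- pop$gametes[match(keep, pop$id)]
  b3 <- build_bulks(pop2, spec, seed = 1)
  expect_setequal(b3$G, wt)
  expect_setequal(b3$Y, mut)
  # missing class errors name the class
  pop3 <- pop2
  drop <- pop3$pheno_class != "MUT"
  pop3$id <- pop3$id[drop]; pop3$pheno_class <- pop3$pheno_class[drop]
  expect_error(build_bulks(pop3, spec, seed = 1), "MUT")
})

test_that("pool depths follow the selected allele frequencies", {
  map <- default_map(length_bp = 2e7, spacing_bp = 1e4)
  pop <- simulate_f2(400, map, 1e7, pheno_model(sigma = 0.5), seed = 11)
  spec <- bulk_spec()
  b <- build_bulks(pop, spec, seed = 12)
  # fixation in the mutant bulk at the causal site
  y <- sample_pool_depths(b$Y, pop, 1e7, spec$coverage_y, seed = 13)
  expect_equal(y$alt_depth, y$depth)
  # wild-type bulk carries no mutant alleles at the causal site
  g <- sample_pool_depths(b$G, pop, 1e7, spec$coverage_g, seed = 14)
  expect_equal(g$alt_depth, 0L)
  expect_error(sample_pool_depths(character(0), pop, 1e7, 30, seed = 1),
               "empty bulk")
})

test_that("unselected bulk has mean SNP-index 0.5 over unlinked sites", {
  map <- default_map(length_bp = 2e7, spacing_bp = 1e4)  # 2000 sites
  pop <- simulate_f2(60, map, 1e7, seed = 21)
  ids <- pop$id[1:50]                 # arbitrary plants, no selection
  d <- sample_pool_depths(ids, pop, map$pos_bp, 40, seed = 22)
  idx <- snp_index(d$ref_depth, d$alt_depth)
  # conditional on the bulk's true frequencies the per-site indexes are
  # independent and unbiased; sites on one chromosome are linked, so the
  # marginal 0.5 check uses a loose bound
  err <- idx - d$p
  expect_lt(abs(mean(err)), 3 * stats::sd(err) / sqrt(length(err)))
  expect_lt(abs(mean(idx) - 0.5), 0.06)
})

test_that("non-mutant 1:2 dosage mix gives pool frequency 1/3", {
  # dominant-style selection arithmetic: dosage 0 and 1 mixed 1:2
  dos <- c(rep(0, 10), rep(1, 20))
  expect_equal(sum(dos) / (2 * length(dos)), 1 / 3)
})

test_that("finemap fixture reproduces requested counts exactly", {
  fx <- make_finemap_fixture(example_counts, 1524, default_marker_panel(),
                             seed = 1)
  ni <- narrow_interval(fx$markers, fx$genotypes, fx$phenotypes)
  expect_identical(unname(ni$counts), unname(example_counts))
  expect_equal(sum(rowSums(fx$genotypes != "B") > 0), 76)
  # involution under write -> read -> recount
  tmp_g <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(fx$genotypes, tmp_g)
  expect_identical(read_genotype_matrix(tmp_g), fx$genotypes)
  # all-zero counts: an all-B matrix
  z <- setNames(rep(0L, 9), paste0("M", 1:9))
  fx0 <- make_finemap_fixture(z, 10, default_marker_panel(), seed = 2)
  expect_true(all(fx0$genotypes == "B"))
  # increasing profile toward the target is not realizable
  p2 <- marker_panel(c("M1", "M2", "M3"), "c", c(10, 20, 30))
  expect_error(
    make_finemap_fixture(c(M1 = 1, M2 = 2, M3 = 0), 10, p2, seed = 1),
    "not realizable")
  # identical seeds give identical fixtures
  fxa <- make_finemap_fixture(example_counts, 100, default_marker_panel(), seed = 5)
  fxb <- make_finemap_fixture(example_counts, 100, default_marker_panel(), seed = 5)
  expect_identical(fxa, fxb)
})

test_that("gene-table fixture carries the stated variant-type counts", {
  tbl <- make_gene_table_fixture(seed = 4)
  expect_equal(nrow(tbl$genes), 56)
  ex <- tbl$variants[tbl$variants$exonic, ]
  expect_equal(length(unique(ex$gene)), 15)
  res <- triage_gene_table(tbl)
  tt <- table(res$effects$effect[res$effects$exonic])
  expect_equal(as.integer(tt[c("frameshift", "nonsynonymous", "synonymous")]),
               c(2L, 3L, 10L))
  # exactly two nonsynonymous genes unexpressed in both lines
  ns <- unique(res$effects$gene[res$effects$effect == "nonsynonymous"])
  g <- tbl$genes[match(ns, tbl$genes$id), ]
  expect_equal(sum(!g$expressed_wt & !g$expressed_mut), 2)
  expect_identical(res$triage$candidates, tbl$candidate)
  # byte-identical under equal seeds
  expect_identical(make_gene_table_fixture(seed = 4),
                   make_gene_table_fixture(seed = 4))
})
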