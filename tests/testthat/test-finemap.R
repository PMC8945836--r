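test_that("classify_spad thresholds and boundary rule", {
  expect_equal(classify_spad(c(25, 5, 10, 20, 15)),
               c("WT", "MUT", "HET", "HET", "HET"))
  expect_error(classify_spad(-1), ">= 0")
})

test_that("recombinants_at finds non-B calls among selected plants", {
  fx <- make_finemap_fixture(example_counts, 1524, default_marker_panel(),
                             seed = 1)
  r1 <- recombinants_at("M1", fx$genotypes, fx$phenotypes)
  expect_length(r1, 55)
  expect_length(recombinants_at("M9", fx$genotypes, fx$phenotypes), 21)
  expect_length(recombinants_at("M6", fx$genotypes, fx$phenotypes), 0)
  expect_error(recombinants_at("M99", fx$genotypes, fx$phenotypes), "absent")
  # brute-force oracle on a constructed column with H and NN calls
  g <- matrix("B", 100, 2, dimnames = list(sprintf("i%03d", 1:100), c("x", "y")))
  g[c(3, 50, 99), "x"] <- "H"
  g[c(10, 11), "x"] <- "NN"
  ph <- data.frame(id = rownames(g), spad = 5,
                   pheno_class = "MUT", stringsAsFactors = FALSE)
  r <- recombinants_at("x", g, ph)
  expect_setequal(r, rownames(g)[c(3, 50, 99)])
  expect_equal(attr(r, "n_NN"), 2L)
  # non-MUT individuals are rejected
  ph$pheno_class[1] <- "HET"
  expect_error(recombinants_at("x", g, ph), "MUT")
})

test_that("narrow_interval reproduces the nine-marker worked example", {
  fx <- make_finemap_fixture(example_counts, 1524, default_marker_panel(),
                             seed = 3)
  ni <- narrow_interval(fx$markers, fx$genotypes, fx$phenotypes)
  expect_equal(ni$left_flank, "M5")
  expect_equal(ni$right_flank, "M7")
  expect_equal(ni$cosegregating, "M6")
  expect_equal(sum(ni$counts), 76 + 53)  # each recombinant counted per marker
})

test_that("narrow_interval edge behaviour", {
  ph <- function(g) data.frame(id = rownames(g), spad = 4,
                               pheno_class = "MUT", stringsAsFactors = FALSE)
  p2 <- marker_panel(c("a", "b"), "c", c(100, 200))
  g <- matrix(c("H", "B", "B", "B"), 2, 2, byrow = TRUE,
              dimnames = list(c("i1", "i2"), c("a", "b")))
  ni <- narrow_interval(p2, g, ph(g))
  expect_equal(ni$cosegregating, "b")
  expect_equal(ni$left_flank, "a")
  expect_true(is.na(ni$right_flank))
  # all cosegregating -> unresolved
  gb <- matrix("B", 2, 2, dimnames = list(c("i1", "i2"), c("a", "b")))
  expect_error(narrow_interval(p2, gb, ph(gb)), "unresolved")
  # no cosegregating marker -> minimal adjacent pair, with a warning
  p3 <- marker_panel(c("a", "b", "c"), "c", c(100, 200, 300))
  g3 <- matrix(c("H", "B", "B",
                 "B", "H", "B",
                 "B", "B", "H",
                 "B", "H", "B",
                 "H", "B", "B"), 5, 3, byrow = TRUE,
               dimnames = list(sprintf("i%d", 1:5), c("a", "b", "c")))
  expect_warning(ni3 <- narrow_interval(p3, g3, ph(g3)), "no cosegregating")
  expect_equal(c(ni3$left_flank, ni3$right_flank), c("b", "c"))
})

test_that("narrow_interval matches the per-individual constraint oracle", {
  set.seed(11)
  n_ok <- 0
  for (i in 1:100) {
    prof <- random_count_profile(sample(4:9, 1))
    fx <- make_finemap_fixture(prof$counts, sum(prof$counts) + 30,
                               prof$panel, seed = i)
    ni <- suppressWarnings(
      narrow_interval(prof$panel, fx$genotypes, fx$phenotypes))
    o <- oracle_narrow(prof$panel, fx$genotypes[, prof$panel$marker,
                                                drop = FALSE])
    expect_identical(ni$left_flank, o$left)
    expect_identical(ni$right_flank, o$right)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("narrow_interval is invariant to individual order", {
  fx <- make_finemap_fixture(example_counts, 300, default_marker_panel(),
                             seed = 9)
  ni1 <- narrow_interval(fx$markers, fx$genotypes, fx$phenotypes)
  perm <- sample(nrow(fx$genotypes))
  ni2 <- narrow_interval(fx$markers, fx$genotypes[perm, ],
                         fx$phenotypes[perm, ])
  expect_identical(ni1[c("left_flank", "right_flank", "cosegregating",
                         "counts")],
                   ni2[c("left_flank", "right_flank", "cosegregating",
                         "counts")])
})

test_that("counts are non-increasing toward a cosegregating marker", {
  set.seed(13)
  for (i in 1:25) {
    prof <- random_count_profile(7)
    fx <- make_finemap_fixture(prof$counts, sum(prof$counts) + 10,
                               prof$panel, seed = i)
    ni <- suppressWarnings(
      narrow_interval(prof$panel, fx$genotypes, fx$phenotypes))
    cnt <- ni$counts
    z <- which(cnt == 0)[1]
    if (z > 1) expect_true(all(diff(cnt[1:z]) <= 0))
    if (z < length(cnt)) expect_true(all(diff(cnt[z:length(cnt)]) >= 0))
  }
})

test_that("interval from simulated F2 data contains the causal position", {
  map <- default_map(length_bp = 6e6, spacing_bp = 1e4)
  pop <- simulate_f2(800, map, 3e6, pheno_model(sigma = 0.5), seed = 31)
  panel <- marker_panel(paste0("m", 1:9), "A03",
                        seq(2.2e6, 3.8e6, length.out = 9))
  sel <- pop$pheno_class == "MUT"
  d <- genotype_at(pop, panel$pos_bp)[sel, , drop = FALSE]
  geno <- matrix(c("A", "H", "B")[d + 1L], nrow = nrow(d),
                 dimnames = dimnames(d))
  colnames(geno) <- panel$marker
  ph <- data.frame(id = rownames(geno), spad = pop$spad[sel][seq_len(nrow(geno))],
                   pheno_class = "MUT", stringsAsFactors = FALSE)
  ni <- suppressWarnings(narrow_interval(panel, geno, ph))
  if (length(ni$cosegregating) > 0) {
    lo <- if (is.na(ni$left_flank)) -Inf else
      panel$pos_bp[panel$marker == ni$left_flank]
    hi <- if (is.na(ni$right_flank)) Inf else
      panel$pos_bp[panel$marker == ni$right_flank]
    expect_true(lo <= 3e6 && 3e6 <= hi)
  }
})
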