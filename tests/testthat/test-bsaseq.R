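test_that("snp_index and delta arithmetic, bounds and undefined sites", {
  expect_equal(snp_index(10, 10), 0.5)
  expect_equal(snp_index(0, 20), 1.0)
  expect_equal(snp_index(7, 3), 0.3)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(-1, 5), ">= 0")
  s <- data.frame(g_ref = c(10, 5, 0), g_alt = c(10, 5, 20),
                  y_ref = c(0, 5, 20), y_alt = c(20, 5, 0))
  expect_equal(delta_snp_index(s), c(0.5, 0, -1))
  # always within [-1, 1] / [0, 1]
  set.seed(1)
  r <- random_sites(500, 1e6)
  expect_true(all(delta_snp_index(r) >= -1 & delta_snp_index(r) <= 1))
  ix <- snp_index(r$g_ref, r$g_alt)
  expect_true(all(ix >= 0 & ix <= 1))
})

test_that("window_scan matches the brute-force oracle exactly", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    chrom_len <- sample(2000:10000, 1)
    cfg <- scan_config(window_bp = sample(500:1500, 1),
                       step_bp = sample(100:400, 1),
                       min_depth = sample(0:10, 1), n_null_reps = 100)
    sites <- random_sites(n, chrom_len, depth = 8)
    w <- window_scan(sites, cfg, chrom_len)
    o <- oracle_window_scan(sites, cfg, chrom_len)
    expect_equal(nrow(w), nrow(o))
    expect_equal(w$n_snps, unname(o[, "n"]))
    expect_equal(w$idx_g, unname(o[, "idx_g"]), tolerance = 1e-12)
    expect_equal(w$idx_y, unname(o[, "idx_y"]), tolerance = 1e-12)
    expect_equal(w$delta, unname(o[, "delta"]), tolerance = 1e-12)
  }
})

test_that("window layout: count of full windows and partial flagging", {
  cfg <- scan_config(window_bp = 1e6, step_bp = 1e4, n_null_reps = 100)
  sites <- data.frame(chrom = "c1", pos = 1.5e6, ref = "G", alt = "A",
                      g_ref = 20, g_alt = 20, y_ref = 20, y_alt = 20)
  w <- window_scan(sites, cfg, chrom_len = 3e6)
  full <- w[!w$partial, ]
  expect_equal(nrow(full), 201)                  # floor((L - W)/s) + 1
  expect_true(all(full$start <= 2000001))
  expect_true(all(w$end - w$start <= 1e6))
  # single site in a window -> window mean equals that site's index
  hit <- w[w$n_snps == 1, ][1, ]
  expect_equal(hit$idx_g, 0.5)
  expect_error(window_scan(sites[c(1, 1), ][2:1, ] |>
                 transform(pos = c(2e6, 1e6)), cfg, 3e6), "sorted")
})

test_that("null_band is centred, depth-monotone and alpha-monotone", {
  cfg <- scan_config(n_null_reps = 10000)
  set.seed(10)
  d <- bsamap:::null_delta_draws(34, 40, 25, 10000)
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(10000))
  b10 <- null_band(10, 10, cfg, seed = 1)
  b100 <- null_band(100, 100, cfg, seed = 1)
  expect_lt(diff(b100), diff(b10))
  wide <- null_band(40, 34, scan_config(alpha = 0.999, n_null_reps = 10000),
                    seed = 2)
  expect_lt(diff(wide), 0.05)                    # collapses toward median 0
  tight <- null_band(40, 34, cfg, seed = 2)
  expect_gt(diff(tight), diff(wide))
})

test_that("site_null_bands broadcasts over unique depth pairs", {
  set.seed(5)
  sites <- random_sites(50, 1e5, depth = 20)
  cfg <- scan_config(n_null_reps = 500)
  b <- site_null_bands(sites, cfg, seed = 3)
  expect_equal(nrow(b), 50)
  key <- paste(sites$y_ref + sites$y_alt, sites$g_ref + sites$g_alt)
  expect_true(all(tapply(b$band_hi, key, function(x) length(unique(x))) == 1))
  expect_true(all(b$band_lo <= b$band_hi, na.rm = TRUE))
})

test_that("call_regions finds runs, merges, and handles empty input", {
  w <- data.frame(chrom = "c1", start = c(1, 101, 201, 301, 401),
                  end = c(251, 351, 451, 551, 651), n_snps = c(5, 5, 0, 5, 5),
                  delta = c(0.5, 0.5, NA, 0.5, 0.5),
                  band_hi = 0.2, band_lo = -0.2)
  r <- call_regions(w)
  # the no-data window breaks the run but the two spans overlap -> merged
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1)
  expect_equal(r$end, 651)
  expect_equal(r$n_windows, 4)
  none <- transform(w, delta = 0)
  expect_equal(nrow(call_regions(none)), 0)
})

test_that("null calibration: about alpha of unlinked sites exceed the band", {
  # 2000 unlinked sites at fixed depths; independent site generator
  cfg <- scan_config()
  band <- null_band(34, 40, cfg, seed = 101)
  set.seed(202)
  n_sites <- 2000
  delta <- vapply(seq_len(n_sites), function(i) {
    py <- mean(sample(0:2, 25, TRUE, prob = c(1, 2, 1) / 4)) / 2
    pg <- mean(sample(0:2, 25, TRUE, prob = c(1, 2, 1) / 4)) / 2
    ay <- rbinom(1, 34, py); ag <- rbinom(1, 40, pg)
    snp_index(34 - ay, ay) - snp_index(40 - ag, ag)
  }, 0)
  out <- mean(delta < band[1] | delta > band[2])
  tol <- 2.576 * sqrt(0.05 * 0.95 / n_sites)
  expect_lt(abs(out - 0.05), tol + 1e-9)
})

test_that("scan recovers a simulated causal region", {
  map <- default_map(length_bp = 2e7, spacing_bp = 1e4)
  pop <- simulate_f2(400, map, 5e6, seed = 77, n_readings = 3)
  spec <- bulk_spec()
  b <- build_bulks(pop, spec, seed = 78)
  sites <- pool_sites(b, pop, map$pos_bp, spec, seed = 79)
  cfg <- scan_config(n_null_reps = 2000)
  bands <- site_null_bands(sites, cfg, seed = 80)
  w <- window_scan(sites, cfg, 2e7, bands)
  r <- call_regions(w)
  expect_gt(nrow(r), 0)
  top <- r[which.max(r$mean_delta), ]
  expect_true(top$start <= 5e6 && 5e6 < top$end)
})
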