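# Bulked-segregant scan statistics: per-site SNP-index and delta(SNP-index),
# sliding-window averaging, a Monte-Carlo null confidence band conditional on
# pool depths, and candidate-region calling.

#' Scan configuration
#'
#' @param window_bp Sliding-window width (bp). Default 1 Mb.
#' @param step_bp Window step (bp, <= window). Default 10 kb.
#' @param alpha Significance level of the null band (0 < alpha < 1).
#' @param min_depth Minimum read depth per pool for a site to enter the scan.
#' @param n_null_reps Monte-Carlo replicates per null band.
#' @param bulk_size Individuals per bulk assumed by the null model.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(window_bp = 1e6, step_bp = 1e4, alpha = 0.05,
                        min_depth = 7, n_null_reps = 10000, bulk_size = 25) {
  stopifnot(step_bp <= window_bp, alpha > 0, alpha < 1, min_depth >= 0,
            bulk_size >= 1)
  if (n_null_reps < 100)
    warning("n_null_reps < 100: null band quantiles will be unstable")
  structure(list(window_bp = as.numeric(window_bp),
                 step_bp = as.numeric(step_bp), alpha = alpha,
                 min_depth = as.integer(min_depth),
                 n_null_reps = as.integer(n_null_reps),
                 bulk_size = as.integer(bulk_size)), class = "scan_config")
}

#' Per-pool SNP-index
#'
#' Fraction of reads carrying the mutant-parent (alt) allele. A site with zero
#' total depth has no defined index and returns `NA` (distinct from 0).
#'
#' @param ref_depth,alt_depth Non-negative integer depths (vectorized).
#' @return Numeric in \[0, 1\], `NA` where total depth is zero.
#' @examples
#' snp_index(10, 10)  # 0.5
#' @export
snp_index <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0 | alt_depth < 0, na.rm = TRUE))
    abort_("depths must be >= 0")
  tot <- ref_depth + alt_depth
  ifelse(tot > 0, alt_depth / tot, NA_real_)
}

#' Per-site delta(SNP-index)
#'
#' `snp_index(Y) - snp_index(G)`: near 0 at unlinked sites, approaching 1 at a
#' locus fully selected in the mutant pool.
#'
#' @param sites data.frame with `g_ref`, `g_alt`, `y_ref`, `y_alt`.
#' @return Numeric vector in \[-1, 1\] (`NA` where a pool has zero depth).
#' @export
delta_snp_index <- function(sites) {
  snp_index(sites$y_ref, sites$y_alt) - snp_index(sites$g_ref, sites$g_alt)
}

# sites passing the per-pool depth filter
sites_pass <- function(sites, cfg) {
  (sites$g_ref + sites$g_alt) >= cfg$min_depth &
  (sites$y_ref + sites$y_alt) >= cfg$min_depth
}

#' Monte-Carlo null band for delta(SNP-index) at given pool depths
#'
#' Simulates unlinked F2 bulks: per replicate each pool's allele frequency is
#' the mean of `bulk_size` dosages drawn 0/1/2 with probabilities 1/4, 1/2,
#' 1/4 (equivalently Binomial(2 * bulk_size, 1/2) mutant alleles), alt depths
#' are Binomial(depth, p) per pool, and delta is the difference of the two
#' indexes. Returns the empirical alpha/2 and 1 - alpha/2 quantiles.
#'
#' @param depth_y,depth_g Total pool depths at the site.
#' @param cfg A [scan_config()].
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
null_band <- function(depth_y, depth_g, cfg = scan_config(), seed) {
  stopifnot(depth_y >= 1, depth_g >= 1)
  local_seed(seed)
  d <- null_delta_draws(depth_y, depth_g, cfg$bulk_size, cfg$n_null_reps)
  unname(quantile(d, c(cfg$alpha / 2, 1 - cfg$alpha / 2)))
}

# vector of n null delta draws at fixed depths (RNG state of the caller)
null_delta_draws <- function(depth_y, depth_g, bulk_size, n) {
  p_y <- rbinom(n, 2L * bulk_size, 0.5) / (2 * bulk_size)
  p_g <- rbinom(n, 2L * bulk_size, 0.5) / (2 * bulk_size)
  rbinom(n, depth_y, p_y) / depth_y - rbinom(n, depth_g, p_g) / depth_g
}

#' Per-site null bands for a site table
#'
#' Bands depend on depths only, so they are computed once per unique
#' (depth_y, depth_g) pair and broadcast; sites failing the depth filter get
#' `NA` bands.
#'
#' @param sites Site table (see [delta_snp_index()]).
#' @param cfg A [scan_config()].
#' @param seed Integer seed.
#' @return data.frame `band_lo`, `band_hi`, one row per site.
#' @export
site_null_bands <- function(sites, cfg = scan_config(), seed) {
  dy <- sites$y_ref + sites$y_alt
  dg <- sites$g_ref + sites$g_alt
  ok <- sites_pass(sites, cfg)
  key <- paste(dy, dg)
  uk <- sort(unique(key[ok]))
  local_seed(seed)
  lo <- hi <- rep(NA_real_, length(key))
  for (k in uk) {
    i <- which(ok & key == k)
    d <- null_delta_draws(dy[i[1L]], dg[i[1L]], cfg$bulk_size, cfg$n_null_reps)
    q <- quantile(d, c(cfg$alpha / 2, 1 - cfg$alpha / 2), names = FALSE)
    lo[i] <- q[1L]; hi[i] <- q[2L]
  }
  data.frame(band_lo = lo, band_hi = hi)
}

#' Sliding-window scan of SNP-index statistics
#'
#' Windows are 1-based half-open \[start, start + window), anchored at 1 and
#' advanced by `step_bp`; trailing partial windows are retained and flagged.
#' Window values are unweighted means over the member sites that pass the
#' per-pool depth filter; windows without such sites carry `NA` and
#' `n_snps = 0`. When `bands` is supplied (per-site, from
#' [site_null_bands()]), the window band is the mean of the member sites'
#' bands, mirroring the averaging of the observed statistic.
#'
#' @param sites Site table sorted by `pos` (error otherwise).
#' @param cfg A [scan_config()].
#' @param chrom_len Chromosome length (>= max site position).
#' @param bands Optional data.frame `band_lo`/`band_hi` parallel to `sites`.
#' @return data.frame of class `window_stats`: `chrom`, `start`, `end`
#'   (half-open), `n_snps`, `idx_g`, `idx_y`, `delta`, `band_lo`, `band_hi`,
#'   `partial`.
#' @export
window_scan <- function(sites, cfg = scan_config(), chrom_len,
                        bands = NULL) {
  if (is.unsorted(sites$pos, strictly = FALSE)) abort_("sites must be sorted by pos")
  if (nrow(sites) && chrom_len < max(sites$pos))
    abort_("chrom_len smaller than max site position")
  ok <- sites_pass(sites, cfg)
  pos <- sites$pos[ok]
  ig <- snp_index(sites$g_ref, sites$g_alt)[ok]
  iy <- snp_index(sites$y_ref, sites$y_alt)[ok]
  dl <- iy - ig
  blo <- if (!is.null(bands)) bands$band_lo[ok]
  bhi <- if (!is.null(bands)) bands$band_hi[ok]

  starts <- seq(1, chrom_len, by = cfg$step_bp)
  ends <- pmin(starts + cfg$window_bp, chrom_len + 1)
  # prefix sums over sorted kept sites -> O(1) per window
  cs <- function(v) cumsum(c(0, v))
  Sg <- cs(ig); Sy <- cs(iy); Sd <- cs(dl)
  Sl <- if (!is.null(bands)) cs(blo); Sh <- if (!is.null(bands)) cs(bhi)
  i0 <- findInterval(starts - 1, pos)        # sites with pos < start
  i1 <- findInterval(ends - 1, pos)          # sites with pos < end
  n <- i1 - i0
  mean_rng <- function(S) ifelse(n > 0, (S[i1 + 1] - S[i0 + 1]) / n, NA_real_)
  chrom <- if (nrow(sites)) sites$chrom[1L] else NA_character_
  out <- data.frame(chrom = chrom, start = starts, end = ends, n_snps = n,
                    idx_g = mean_rng(Sg), idx_y = mean_rng(Sy),
                    delta = mean_rng(Sd),
                    band_lo = if (is.null(bands)) NA_real_ else mean_rng(Sl),
                    band_hi = if (is.null(bands)) NA_real_ else mean_rng(Sh),
                    partial = (ends - starts) < cfg$window_bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Call candidate regions from a window scan
#'
#' A window is significant when it holds sites and its delta exceeds its upper
#' band. Maximal runs of consecutive significant windows become regions
#' (no-data windows break runs); regions whose genomic spans overlap are
#' merged. Each region reports the mean delta over its member windows.
#'
#' @param windows A [window_scan()] result carrying bands.
#' @return data.frame `chrom`, `start`, `end` (half-open), `n_windows`,
#'   `mean_delta`; zero rows when nothing is significant.
#' @export
call_regions <- function(windows) {
  if (!all(c("delta", "band_hi") %in% names(windows)))
    abort_("windows must carry delta and band_hi")
  sig <- !is.na(windows$delta) & !is.na(windows$band_hi) &
         windows$n_snps > 0 & windows$delta > windows$band_hi
  if (!any(sig)) return(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), n_windows = integer(0),
                                   mean_delta = numeric(0)))
  r <- rle(sig)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- data.frame(i = idx_start[r$values], j = idx_end[r$values])
  reg <- data.frame(chrom = windows$chrom[runs$i],
                    start = windows$start[runs$i],
                    end = windows$end[runs$j],
                    n_windows = runs$j - runs$i + 1L,
                    mean_delta = mapply(function(i, j)
                      mean(windows$delta[i:j]), runs$i, runs$j))
  # merge overlapping spans (possible across a no-data break)
  if (nrow(reg) > 1L) {
    keep <- reg[1L, ]
    for (k in 2L:nrow(reg)) {
      last <- nrow(keep)
      if (reg$start[k] <= keep$end[last]) {
        n1 <- keep$n_windows[last]; n2 <- reg$n_windows[k]
        keep$end[last] <- max(keep$end[last], reg$end[k])
        keep$mean_delta[last] <-
          (keep$mean_delta[last] * n1 + reg$mean_delta[k] * n2) / (n1 + n2)
        keep$n_windows[last] <- n1 + n2
      } else keep <- rbind(keep, reg[k, ])
    }
    reg <- keep
  }
  rownames(reg) <- NULL
  reg
}
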