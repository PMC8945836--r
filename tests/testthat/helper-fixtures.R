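# Shared fixtures and independent oracles used across test files.

# per-marker recombinant counts of the nine-marker worked example
# (positional order M1..M9)
example_counts <- c(M1 = 55L, M2 = 15L, M3 = 6L, M4 = 4L, M5 = 2L, M6 = 0L,
                    M7 = 9L, M8 = 17L, M9 = 21L)

# a 4149-bp CDS whose codon 1349 is GAA (worked-example candidate gene)
example_cds <- local({
  s <- strrep("GCT", 1383)
  substr(s, 4045, 4047) <- "GAA"
  s
})

make_read <- function(seq, qual = rep(30L, nchar(seq)), id = "r") {
  seq_read(id, seq, qual)
}

# random site table on [1, chrom_len]
random_sites <- function(n, chrom_len, depth = 30) {
  pos <- sort(sample(chrom_len, n))
  data.frame(chrom = "c1", pos = pos, ref = "G", alt = "A",
             g_ref = rpois(n, depth), g_alt = rpois(n, depth),
             y_ref = rpois(n, depth), y_alt = rpois(n, depth))
}

# brute-force window means, O(windows x sites)
oracle_window_scan <- function(sites, cfg, chrom_len) {
  keep <- (sites$g_ref + sites$g_alt) >= cfg$min_depth &
          (sites$y_ref + sites$y_alt) >= cfg$min_depth
  s <- sites[keep, , drop = FALSE]
  ig <- s$g_alt / (s$g_ref + s$g_alt)
  iy <- s$y_alt / (s$y_ref + s$y_alt)
  starts <- seq(1, chrom_len, by = cfg$step_bp)
  t(vapply(starts, function(st) {
    en <- min(st + cfg$window_bp, chrom_len + 1)
    inw <- s$pos >= st & s$pos < en
    if (!any(inw)) return(c(n = 0, idx_g = NA, idx_y = NA, delta = NA))
    c(n = sum(inw), idx_g = mean(ig[inw]), idx_y = mean(iy[inw]),
      delta = mean(iy[inw] - ig[inw]))
  }, c(n = 0, idx_g = 0, idx_y = 0, delta = 0)))
}

# independent set-algebra recomputation of the four triage filters
oracle_triage <- function(genes, effects) {
  ex <- effects[effects$exonic, , drop = FALSE]
  by_gene <- split(ex, ex$gene)
  s1 <- genes$id[genes$id %in% names(by_gene)]
  s2 <- Filter(function(g) any(by_gene[[g]]$ems_consistent), s1)
  s3 <- Filter(function(g) any(by_gene[[g]]$effect != "synonymous"), s2)
  expr <- genes$expressed_wt | genes$expressed_mut
  s4 <- Filter(function(g) expr[genes$id == g], s3)
  as.character(s4)
}

# random gene/effect tables for triage property tests
random_triage_tables <- function(n_genes = 12, n_eff = 20) {
  ids <- sprintf("G%02d", seq_len(n_genes))
  genes <- data.frame(id = ids,
                      expressed_wt = sample(c(TRUE, FALSE), n_genes, TRUE),
                      expressed_mut = sample(c(TRUE, FALSE), n_genes, TRUE))
  effects <- data.frame(
    gene = sample(ids, n_eff, replace = TRUE),
    effect = sample(c("synonymous", "nonsynonymous", "frameshift"), n_eff,
                    replace = TRUE),
    ems_consistent = sample(c(TRUE, FALSE), n_eff, replace = TRUE),
    exonic = sample(c(TRUE, FALSE), n_eff, replace = TRUE, prob = c(.8, .2)))
  effects$ems_consistent[effects$effect == "frameshift"] <- FALSE
  list(genes = genes, effects = effects)
}

# random realizable per-marker recombinant count profile (V-shaped around a
# zero-count marker), plus a matching panel
random_count_profile <- function(n_markers = 7) {
  z <- sample(n_markers, 1L)
  left <- if (z > 1) sort(sample(1:30, z - 1L, TRUE), decreasing = TRUE)
          else integer(0)
  right <- if (z < n_markers) sort(sample(1:30, n_markers - z, TRUE))
           else integer(0)
  cnt <- c(left, 0L, right)
  panel <- marker_panel(sprintf("m%d", seq_len(n_markers)), "c1",
                        sort(sample(1e6, n_markers)))
  list(counts = setNames(as.integer(cnt), panel$marker), panel = panel)
}

# exhaustive per-individual oracle for interval narrowing on single-breakpoint
# data: each recombinant whose non-B stretch touches the left (right) panel
# edge places the gene right (left) of its innermost non-B marker; the flanks
# are the tightest such constraints.
oracle_narrow <- function(panel, geno) {
  k <- nrow(panel)
  lf <- 0L; rf <- k + 1L
  for (i in seq_len(nrow(geno))) {
    cols <- which(geno[i, ] != "B")
    if (length(cols) == 0L) next
    if (cols[1L] == 1L) lf <- max(lf, max(cols))
    else if (cols[length(cols)] == k) rf <- min(rf, min(cols))
  }
  list(left = if (lf >= 1L) panel$marker[lf] else NA_character_,
       right = if (rf <= k) panel$marker[rf] else NA_character_)
}
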