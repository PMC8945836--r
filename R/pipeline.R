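# End-to-end pipeline: simulate -> scan -> region call -> fine map -> triage
# -> marker validation, with every stage's seed and outputs logged.

#' Run the full simulated mapping pipeline
#'
#' Chains every stage on a simulated world defined by `config`: an F2
#' population with one causal locus is bulked and pool-sequenced; the
#' delta(SNP-index) scan calls candidate regions; a second, phenotype-selected
#' population is genotyped at a marker ladder across the top region and the
#' interval is narrowed; a gene table over the narrowed interval is triaged to
#' candidates; and a marker at the causal SNP is validated by fluorescence
#' genotyping, cosegregation and a 1:2:1 segregation test. Each stage derives
#' its seed from `config$seed` by a fixed offset, so a rerun of the same
#' config reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param write_outputs Write VCF/TSV/BED/JSON artifacts under
#'   `config$out_dir` (default TRUE).
#' @return List of class `pipeline_report` — see the `stages` element for
#'   per-stage results and `seeds` for the seeds actually used.
#' @export
run_pipeline <- function(config = pipeline_config(), write_outputs = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- as.list(config$seed + 0:7)
  names(seeds) <- c("simulate", "bulks", "pools", "bands", "finemap_pop",
                    "gene_table", "validate_pop", "fluorescence")
  out_dir <- config$out_dir
  if (write_outputs) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  map <- default_map(config$chrom, config$chrom_len, config$spacing_bp,
                     config$cM_per_Mb)
  model <- pheno_model(config$mu_wt, config$mu_het, config$mu_mut,
                       config$sigma)
  spec <- bulk_spec(config$n_per_bulk, config$coverage_g, config$coverage_y)
  cfg <- scan_config(config$window_bp, config$step_bp, config$alpha,
                     config$min_depth, config$n_null_reps, config$n_per_bulk)

  pop <- simulate_f2(config$n_f2, map, config$causal_bp, model,
                     seeds$simulate, config$n_spad_readings)
  bulks <- build_bulks(pop, spec, seeds$bulks)
  sites <- pool_sites(bulks, pop, map$pos_bp, spec, seeds$pools)
  bands <- site_null_bands(sites, cfg, seeds$bands)
  windows <- window_scan(sites, cfg, config$chrom_len, bands)
  regions <- call_regions(windows)
  if (nrow(regions) == 0L)
    abort_("scan stage: no candidate region called")
  top <- regions[which.max(regions$mean_delta), ]
  scan_hit <- top$start <= config$causal_bp & config$causal_bp < top$end

  # fine mapping: iterative marker ladders, as in map-based cloning practice.
  # One phenotype-selected population is simulated on the full map; each round
  # designs a fresh ladder inside the current interval, genotypes the selected
  # individuals there (stored gamete breakpoints), and narrows the interval,
  # stopping once a cosegregating marker is found.
  fm_causal <- min(max(config$causal_bp, min(map$pos_bp)), max(map$pos_bp))
  fpop <- simulate_f2(config$n_finemap, map, fm_causal, model,
                      seeds$finemap_pop, config$n_spad_readings)
  sel <- fpop$pheno_class == "MUT"
  phen <- data.frame(id = fpop$id[sel], spad = fpop$spad[sel],
                     pheno_class = fpop$pheno_class[sel],
                     stringsAsFactors = FALSE)
  int_lo <- max(top$start, min(map$pos_bp))
  int_hi <- min(top$end - 1, max(map$pos_bp))
  ni <- NULL; panel <- NULL; geno <- NULL
  for (round in seq_len(8L)) {
    mk_bp <- unique(round(seq(int_lo, int_hi,
                              length.out = config$n_markers)))
    if (length(mk_bp) < 2L) break
    panel <- marker_panel(sprintf("R%d_M%d", round, seq_along(mk_bp)),
                          config$chrom, mk_bp)
    geno <- matrix(c("A", "H", "B")[genotype_at(fpop, mk_bp)[sel, , drop = FALSE] + 1L],
                   nrow = sum(sel),
                   dimnames = list(fpop$id[sel], panel$marker))
    # phenotype-consistency filter: a selected plant with no mutant-homozygote
    # call anywhere in the interval is a SPAD misclassification (e.g. a
    # heterozygote reading below 10), not a recombinant; drop it.
    ok_row <- rowSums(geno == "B") > 0L
    geno_r <- geno[ok_row, , drop = FALSE]
    phen_r <- phen[match(rownames(geno_r), phen$id), , drop = FALSE]
    ni <- tryCatch(
      withCallingHandlers(
        narrow_interval(panel, geno_r, phen_r),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(ni)) {       # every marker cosegregates: interval exhausted
      ni <- list(left_flank = NA_character_, right_flank = NA_character_,
                 cosegregating = panel$marker,
                 counts = setNames(integer(nrow(panel)), panel$marker),
                 n_NN = setNames(integer(nrow(panel)), panel$marker))
      break
    }
    done <- length(ni$cosegregating) > 0L
    if (done) {
      new_lo <- if (is.na(ni$left_flank)) int_lo else
        panel$pos_bp[panel$marker == ni$left_flank]
      new_hi <- if (is.na(ni$right_flank)) int_hi else
        panel$pos_bp[panel$marker == ni$right_flank]
    } else {
      # no cosegregating marker yet: bracket all markers tied at the minimal
      # count (late rounds leave few recombinants, so counts tie and picking
      # one marker would bias the interval) with one neighbour on each side
      j <- which(ni$counts == min(ni$counts))
      new_lo <- panel$pos_bp[max(min(j) - 1L, 1L)]
      new_hi <- panel$pos_bp[min(max(j) + 1L, nrow(panel))]
    }
    if (new_lo == int_lo && new_hi == int_hi && !done) break
    int_lo <- new_lo; int_hi <- new_hi
    if (done) break
  }
  finemap_hit <- int_lo <= config$causal_bp && config$causal_bp <= int_hi

  # candidate-gene triage over the narrowed interval
  tbl <- make_gene_table_fixture(seeds$gene_table, config$chrom,
                                 c(int_lo, int_hi),
                                 candidate_bp = config$causal_bp)
  tri <- triage_gene_table(tbl)
  g <- tbl$genes[tbl$genes$id == tbl$candidate, ]
  triage_hit <- identical(tri$triage$candidates, tbl$candidate) &&
    g$start <= config$causal_bp && config$causal_bp <= g$end

  # marker validation on an independent F2 population
  vpop <- simulate_f2(config$n_validate, map, fm_causal, model,
                      seeds$validate_pop, config$n_spad_readings)
  true_calls <- setNames(c("AA", "AB", "BB")[vpop$causal_dosage + 1L],
                         vpop$id)
  sig <- simulate_fluorescence(true_calls, seeds$fluorescence)
  calls <- setNames(call_genotype(sig$fam, sig$hex, config$fam_thresh,
                                  config$hex_thresh), sig$sample)
  coseg <- cosegregation_check(calls, setNames(vpop$pheno_class, vpop$id))
  seg <- segregation_chi2(c(sum(calls == "AA"), sum(calls == "AB"),
                            sum(calls == "BB")))

  report <- structure(list(
    seeds = seeds,
    stages = list(
      scan = list(regions = regions, top_region = top, scan_hit = scan_hit,
                  n_windows = nrow(windows)),
      finemap = list(counts = ni$counts, left_flank = ni$left_flank,
                     right_flank = ni$right_flank,
                     cosegregating = ni$cosegregating,
                     interval = c(int_lo, int_hi), finemap_hit = finemap_hit,
                     n_selected = sum(sel)),
      triage = list(candidates = tri$triage$candidates,
                    true_candidate = tbl$candidate,
                    n_removed = nrow(tri$triage$audit),
                    triage_hit = triage_hit),
      validate = list(perfect = coseg$perfect, n_called = coseg$n_called,
                      n_no_call = coseg$n_no_call, chi2 = seg$chi2,
                      pvalue = seg$pvalue)),
    success = scan_hit && finemap_hit && triage_hit),
    class = "pipeline_report")

  if (write_outputs) {
    write_pool_vcf(sites, file.path(out_dir, "pools.vcf"),
                   config$chrom_len, seed = seeds$pools)
    data.table::fwrite(windows, file.path(out_dir, "windows.tsv"), sep = "\t")
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    write_genotype_matrix(geno, file.path(out_dir, "finemap_genotypes.tsv"))
    write_phenotypes(phen, file.path(out_dir, "finemap_phenotypes.tsv"))
    write_marker_panel(panel, file.path(out_dir, "markers.tsv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

# JSON-safe view of the report (data.frames flattened)
report_to_json <- function(report) {
  r <- unclass(report)
  r$stages$scan$regions <- NULL
  r$stages$scan$top_region <- as.list(r$stages$scan$top_region)
  r$stages$finemap$counts <- as.list(r$stages$finemap$counts)
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$stages
  cat("bsamap pipeline report\n")
  cat(sprintf("  scan: %d region(s); top %s:%.0f-%.0f (mean delta %.3f)%s\n",
              nrow(s$scan$regions), s$scan$top_region$chrom,
              s$scan$top_region$start, s$scan$top_region$end,
              s$scan$top_region$mean_delta,
              if (s$scan$scan_hit) " [contains causal]" else ""))
  cat(sprintf("  finemap: flanks (%s, %s), cosegregating {%s}, %d selected\n",
              s$finemap$left_flank, s$finemap$right_flank,
              paste(s$finemap$cosegregating, collapse = ","),
              s$finemap$n_selected))
  cat(sprintf("  triage: %d candidate(s): %s\n",
              length(s$triage$candidates),
              paste(s$triage$candidates, collapse = ",")))
  cat(sprintf("  validate: perfect=%s, n_called=%d, chi2=%.3f (p=%.3f)\n",
              s$validate$perfect, s$validate$n_called, s$validate$chi2,
              s$validate$pvalue))
  cat(sprintf("  success: %s\n", x$success))
  invisible(x)
}
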