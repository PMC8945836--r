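# File-format plumbing: VCF with per-pool allele depths, TSV tables
# (phenotypes, genotype matrices, marker panels, counts, Ct), GFF3/FASTA for
# gene models, BED for called regions, and the plain-text pipeline config.

#' Write pooled variant sites as VCF 4.2 with per-sample AD
#'
#' Two sample columns carry the G (wild-type) and Y (mutant) pool depths in
#' the AD FORMAT field. Reading back through [read_vcf_pools()] is an exact
#' inverse.
#'
#' @param sites Site table (see [pool_sites()]).
#' @param path Output path.
#' @param chrom_len Optional contig length for the header.
#' @param g_sample,y_sample Sample column names.
#' @param seed Optional seed to record in the header.
#' @export
write_pool_vcf <- function(sites, path, chrom_len = NULL,
                           g_sample = "G", y_sample = "Y", seed = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsamap",
           if (!is.null(seed)) sprintf("##bsamap_seed=%d", as.integer(seed)),
           if (!is.null(chrom_len))
             sprintf("##contig=<ID=%s,length=%d>", sites$chrom[1L],
                     as.integer(chrom_len)),
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
           sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s\t%s",
                   g_sample, y_sample))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                  sites$chrom, as.integer(sites$pos), sites$ref, sites$alt,
                  sites$g_ref, sites$g_alt, sites$y_ref, sites$y_alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled allele depths from a VCF
#'
#' Keeps biallelic SNVs only; multi-allelic or indel records are skipped and
#' counted (attribute `n_skipped`). Parsing is backed by
#' `VariantAnnotation::readVcf`.
#'
#' @param path VCF path (plain or bgzipped).
#' @param g_sample,y_sample Names of the wild-type and mutant pool samples.
#' @return Site table (`chrom`, `pos`, `ref`, `alt`, `g_ref`, `g_alt`,
#'   `y_ref`, `y_alt`) with attribute `n_skipped`.
#' @export
read_vcf_pools <- function(path, g_sample = "G", y_sample = "Y") {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  smp <- colnames(v)
  for (s in c(g_sample, y_sample))
    if (!s %in% smp) abort_("sample missing from VCF: ", s)
  if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(v))))
    abort_("FORMAT field missing from VCF: AD")
  rr <- SummarizedExperiment::rowRanges(v)
  alt_n <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
  ref <- as.character(VariantAnnotation::ref(v))
  alt1 <- rep(NA_character_, length(v))
  alt1[alt_n == 1L] <- as.character(unlist(VariantAnnotation::alt(v)[alt_n == 1L]))
  keep <- alt_n == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  ad <- VariantAnnotation::geno(v)$AD
  get2 <- function(sample, k) vapply(ad[keep, sample], `[`, 0L, k)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                    pos = GenomicRanges::start(rr)[keep],
                    ref = ref[keep], alt = alt1[keep],
                    g_ref = get2(g_sample, 1L), g_alt = get2(g_sample, 2L),
                    y_ref = get2(y_sample, 1L), y_alt = get2(y_sample, 2L),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Write / read a phenotype table (id, spad, pheno_class)
#' @param phenotypes data.frame `id`, `spad`, `pheno_class`.
#' @param path TSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes[, c("id", "spad", "pheno_class")], path,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = c("id", "pheno_class"))))
}

#' Write / read a genotype matrix (individuals x markers, calls A/H/B/NN)
#' @param genotypes Character matrix with rownames (individual ids).
#' @param path TSV path.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  dt <- data.table::data.table(id = rownames(genotypes))
  for (m in colnames(genotypes)) dt[[m]] <- genotypes[, m]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1L]]
  m
}

#' Write / read a marker panel (marker, chrom, pos_bp)
#' @param panel A [marker_panel()].
#' @param path TSV path.
#' @export
write_marker_panel <- function(panel, path) {
  data.table::fwrite(as.data.frame(panel), path, sep = "\t")
  invisible(path)
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  marker_panel(d$marker, d$chrom[1L], d$pos_bp)
}

#' Write called regions as BED (0-based half-open)
#'
#' Internal coordinates are 1-based with half-open ends; BED conversion
#' happens only here.
#'
#' @param regions A [call_regions()] result.
#' @param path BED path.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\tregion_%d\t%.4f", regions$chrom,
                   as.integer(regions$start) - 1L,
                   as.integer(regions$end) - 1L,
                   seq_len(nrow(regions)), regions$mean_delta)
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene-table fixture to standard formats
#'
#' GFF3 gene models (via rtracklayer), FASTA CDS sequences (via Biostrings),
#' and TSVs for variants and expression flags.
#'
#' @param tbl A [make_gene_table_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of the four file paths.
#' @export
write_gene_tables <- function(tbl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- tbl$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$start, g$end),
                               strand = g$strand, type = "gene",
                               ID = g$id, annotation = g$annotation)
  paths <- list(gff = file.path(dir, "genes.gff3"),
                cds = file.path(dir, "cds.fasta"),
                variants = file.path(dir, "variants.tsv"),
                expression = file.path(dir, "expression.tsv"))
  rtracklayer::export(gr, paths$gff, format = "gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tbl$cds), paths$cds)
  data.table::fwrite(tbl$variants, paths$variants, sep = "\t")
  data.table::fwrite(g[, c("id", "expressed_wt", "expressed_mut")],
                     paths$expression, sep = "\t")
  paths
}

#' Read gene models back from GFF3 + expression flags
#'
#' @param gff_path GFF3 of gene features (ID and annotation attributes).
#' @param expression_path TSV `id`, `expressed_wt`, `expressed_mut`.
#' @return data.frame in the layout of `make_gene_table_fixture()$genes`.
#' @export
read_gene_models <- function(gff_path, expression_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  g <- data.frame(id = gr$ID,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  annotation = gr$annotation,
                  stringsAsFactors = FALSE)
  ex <- as.data.frame(data.table::fread(expression_path, sep = "\t"))
  merge(g, ex, by = "id", sort = TRUE)
}

# ---- pipeline configuration ------------------------------------------------

pipeline_defaults <- function() {
  list(chrom = "A03", chrom_len = 30e6, spacing_bp = 1e4, cM_per_Mb = 4,
       n_f2 = 400, n_finemap = 2000, n_validate = 368, causal_bp = 5e6,
       n_per_bulk = 25, coverage_g = 39.82, coverage_y = 33.75,
       mu_wt = 30, mu_het = 15, mu_mut = 5, sigma = 2, n_spad_readings = 3,
       window_bp = 1e6, step_bp = 1e4, alpha = 0.05, min_depth = 7,
       n_null_reps = 10000, n_markers = 9, fam_thresh = 1, hex_thresh = 1,
       seed = 1, out_dir = "bsamap_out")
}

#' Pipeline configuration
#'
#' Flat key set covering every stage parameter; unknown keys are rejected.
#'
#' @param ... Overrides of [pipeline_defaults]; see
#'   `names(bsamap:::pipeline_defaults())`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  def <- pipeline_defaults()
  unknown <- setdiff(names(over), names(def))
  if (length(unknown))
    abort_("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, over)
  stopifnot(cfg$n_f2 >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$causal_bp > 0, cfg$n_markers >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline config as plain "key: value" text
#'
#' The format is YAML-compatible flat text; `#` starts a comment.
#'
#' @param path Config file path.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  if (any(vapply(kv, length, 0L) != 3L)) abort_("malformed config line")
  vals <- lapply(kv, function(x) {
    v <- x[[3L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(pipeline_config, setNames(vals, vapply(kv, `[[`, "", 2L)))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(v) format(v, scientific = FALSE),
                            character(1))), path)
  invisible(path)
}
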