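# Candidate-gene stage: CDS-level variant-effect annotation and the
# EMS-consistency candidate-filter cascade for genes in a mapped interval.

#' Annotate a variant on a coding sequence
#'
#' For single-nucleotide substitutions the affected codon is
#' `ceiling(cds_pos / 3)`; reference and alternate codons are translated with
#' the standard genetic code. Length-changing variants are frameshift when the
#' length difference is not a multiple of three, in-frame indels otherwise.
#' Coordinates are 1-based along the CDS (i.e. along the mRNA, so minus-strand
#' genes must be reverse-complemented into CDS space by the caller or via
#' [genomic_to_cds()]).
#'
#' @param cds_sequence CDS string, length divisible by 3.
#' @param cds_pos 1-based position of the first affected base.
#' @param ref,alt Reference/alternate alleles (strings; unequal lengths
#'   describe an indel in VCF style).
#' @return List of class `variant_effect`: `cds_pos`, `ref`, `alt`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `effect` (one of synonymous,
#'   nonsynonymous, stop_gained, stop_lost, frameshift, inframe_indel),
#'   `ems_consistent`.
#' @examples
#' annotate_variant("ATGGATTAA", 6, "T", "C")$effect  # synonymous GAT->GAC
#' @export
annotate_variant <- function(cds_sequence, cds_pos, ref, alt) {
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L) abort_("CDS length must be divisible by 3")
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > n) abort_("cds_pos outside the CDS")
  ref <- toupper(ref); alt <- toupper(alt)
  if (substr(cds_sequence, cds_pos, cds_pos + nchar(ref) - 1L) != ref)
    abort_("reference allele disagrees with CDS")
  snv <- nchar(ref) == 1L && nchar(alt) == 1L
  if (snv) {
    ci <- as.integer(ceiling(cds_pos / 3))
    a <- (ci - 1L) * 3L + 1L
    ref_codon <- substr(cds_sequence, a, a + 2L)
    off <- cds_pos - a + 1L
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    effect <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gained"
      else if (ref_aa == "*") "stop_lost"
      else "nonsynonymous"
    ve <- list(cds_pos = cds_pos, ref = ref, alt = alt, codon_index = ci,
               ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
               ems_consistent = ref != alt)
  } else {
    shift <- (nchar(ref) - nchar(alt)) %% 3L != 0L
    ve <- list(cds_pos = cds_pos, ref = ref, alt = alt,
               codon_index = as.integer(ceiling(cds_pos / 3)),
               ref_aa = NA_character_, alt_aa = NA_character_,
               effect = if (shift) "frameshift" else "inframe_indel",
               ems_consistent = FALSE)
  }
  class(ve) <- "variant_effect"
  ve
}

#' @export
print.variant_effect <- function(x, ...) {
  cat(sprintf("variant_effect: %s>%s at CDS %d | codon %d %s->%s | %s%s\n",
              x$ref, x$alt, x$cds_pos, x$codon_index,
              x$ref_aa %||% "-", x$alt_aa %||% "-", x$effect,
              if (x$ems_consistent) " (EMS-consistent)" else ""))
  invisible(x)
}

#' EMS-consistency of a variant effect
#'
#' EMS mutagenesis produces single-base substitutions (overwhelmingly G/C to
#' A/T transitions, occasionally transversions); any indel — including the
#' frameshift deletions the cascade removes — is inconsistent with EMS origin.
#'
#' @param effect A [annotate_variant()] result (or any list with `ref`/`alt`).
#' @return Logical.
#' @export
ems_consistent <- function(effect) {
  nchar(effect$ref) == 1L && nchar(effect$alt) == 1L && effect$ref != effect$alt
}

#' Candidate-filter cascade
#'
#' Applies the four filters in order, logging the genes each removes:
#' (1) keep genes with at least one exonic variant; (2) drop genes whose
#' variants are all EMS-inconsistent; (3) drop genes whose variants are all
#' synonymous; (4) drop genes expressed in neither line.
#'
#' @param genes data.frame with `id`, `expressed_wt`, `expressed_mut`.
#' @param effects data.frame with `gene`, `effect`, `ems_consistent` and an
#'   optional logical `exonic` (default all TRUE).
#' @return List with `candidates` (character vector, panel order) and `audit`
#'   (data.frame `gene`, `step`, `reason` for every removed gene).
#' @export
triage <- function(genes, effects) {
  stopifnot(is.data.frame(genes), is.data.frame(effects))
  if (nrow(effects) && !all(effects$gene %in% genes$id))
    abort_("effects reference unknown genes: ",
           paste(setdiff(effects$gene, genes$id), collapse = ","))
  if (is.null(effects$exonic)) effects$exonic <- rep(TRUE, nrow(effects))
  ex <- effects[effects$exonic, , drop = FALSE]
  audit <- data.frame(gene = character(0), step = integer(0),
                      reason = character(0), stringsAsFactors = FALSE)
  note <- function(gene, step, reason) {
    if (length(gene))
      audit <<- rbind(audit, data.frame(gene = gene, step = step,
                                        reason = reason,
                                        stringsAsFactors = FALSE))
  }
  alive <- genes$id
  has_exonic <- alive %in% ex$gene
  note(alive[!has_exonic], 1L, "no exonic variant")
  alive <- alive[has_exonic]

  any_ems <- vapply(alive, function(g)
    any(ex$ems_consistent[ex$gene == g]), TRUE)
  note(alive[!any_ems], 2L, "all variants EMS-inconsistent")
  alive <- alive[any_ems]

  any_nonsyn <- vapply(alive, function(g)
    any(ex$effect[ex$gene == g] != "synonymous"), TRUE)
  note(alive[!any_nonsyn], 3L, "all variants synonymous")
  alive <- alive[any_nonsyn]

  expressed <- genes$expressed_wt | genes$expressed_mut
  expr_ok <- expressed[match(alive, genes$id)]
  note(alive[!expr_ok], 4L, "expressed in neither line")
  alive <- alive[expr_ok]

  list(candidates = alive, audit = audit)
}

#' Map a genomic position into CDS coordinates
#'
#' CDS segments are 1-based inclusive genomic intervals ordered 5'->3' along
#' the transcript; for minus-strand genes that is decreasing genomic order and
#' the CDS coordinate runs along the reverse complement.
#'
#' @param genomic_pos 1-based genomic position.
#' @param cds_segments data.frame with `start`, `end` (1-based inclusive),
#'   in transcription order.
#' @param strand `"+"` or `"-"`.
#' @return 1-based CDS position, or `NA` if the position is not coding.
#' @export
genomic_to_cds <- function(genomic_pos, cds_segments, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  offset <- 0L
  for (i in seq_len(nrow(cds_segments))) {
    s <- cds_segments$start[i]; e <- cds_segments$end[i]
    if (genomic_pos >= s && genomic_pos <= e) {
      within <- if (strand == "+") genomic_pos - s else e - genomic_pos
      return(offset + within + 1L)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' Annotate a gene-table fixture and run the cascade
#'
#' Convenience wrapper: annotates every exonic variant of
#' [make_gene_table_fixture()] output (or equivalently structured data) on its
#' CDS and triages the gene set.
#'
#' @param tbl List with `genes`, `variants`, `cds` as produced by
#'   [make_gene_table_fixture()].
#' @return List with `effects` (data.frame) and the [triage()] result.
#' @export
triage_gene_table <- function(tbl) {
  v <- tbl$variants
  eff <- lapply(seq_len(nrow(v)), function(i) {
    if (!v$exonic[i])
      return(list(effect = "noncoding", ems_consistent = ems_consistent(v[i, ])))
    annotate_variant(tbl$cds[[v$gene[i]]], v$cds_pos[i], v$ref[i], v$alt[i])
  })
  effects <- data.frame(gene = v$gene,
                        effect = vapply(eff, `[[`, "", "effect"),
                        ems_consistent = vapply(eff, `[[`, TRUE, "ems_consistent"),
                        exonic = v$exonic, stringsAsFactors = FALSE)
  list(effects = effects, triage = triage(tbl$genes, effects))
}
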