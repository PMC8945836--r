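# Fine mapping: SPAD phenotype classification, recombinant screening among
# phenotype-selected individuals, and marker-by-marker interval narrowing.

#' Classify a SPAD chlorophyll reading into phenotype classes
#'
#' Mutant (MUT) below 10, wild type (WT) above 20, heterozygote (HET)
#' in between; the boundary values 10 and 20 themselves classify as HET.
#'
#' @param spad Numeric SPAD value(s), >= 0.
#' @return Character vector over `{"WT","HET","MUT"}`.
#' @examples
#' classify_spad(c(5, 10, 15, 20, 25))
#' @export
classify_spad <- function(spad) {
  if (any(spad < 0)) abort_("SPAD values must be >= 0")
  ifelse(spad < 10, "MUT", ifelse(spad > 20, "WT", "HET"))
}

# shared validation: genotype matrix (individuals x markers, calls A/H/B/NN)
# and a phenotype table restricted to MUT-class individuals
check_geno <- function(genotypes, phenotypes) {
  if (is.null(rownames(genotypes))) abort_("genotype matrix needs rownames")
  bad <- setdiff(unique(as.vector(genotypes)), c("A", "H", "B", "NN"))
  if (length(bad)) abort_("invalid genotype calls: ", paste(bad, collapse = ","))
  cls <- setNames(phenotypes$pheno_class, phenotypes$id)[rownames(genotypes)]
  if (anyNA(cls)) abort_("phenotype missing for some genotyped individuals")
  if (any(cls != "MUT"))
    abort_("recombinant screening requires MUT-class individuals only")
  invisible(TRUE)
}

#' Recombinants at one marker
#'
#' Among phenotype-selected (MUT-class) individuals, a recombinant at a marker
#' is one whose call there is not the mutant-parent homozygote B. Missing (NN)
#' calls contribute no evidence; their count is attached as attribute `n_NN`.
#'
#' @param marker Marker name (must be a column of `genotypes`).
#' @param genotypes Character matrix individuals x markers (A/H/B/NN).
#' @param phenotypes data.frame with `id`, `pheno_class` covering all rows.
#' @return Character vector of recombinant ids, with attribute `n_NN`.
#' @export
recombinants_at <- function(marker, genotypes, phenotypes) {
  if (!marker %in% colnames(genotypes))
    abort_("marker absent from panel: ", marker)
  check_geno(genotypes, phenotypes)
  calls <- genotypes[, marker]
  ids <- rownames(genotypes)[calls %in% c("A", "H")]
  attr(ids, "n_NN") <- sum(calls == "NN")
  ids
}

#' Narrow the candidate interval from recombinant counts
#'
#' Markers with zero recombinants cosegregate with the causal gene; the flanks
#' are the nearest markers on either side of the cosegregating block that
#' still show recombinants. With no cosegregating marker the adjacent marker
#' pair with the minimal recombinant-count sum is returned with a warning;
#' with every marker cosegregating the interval is unresolved (error).
#'
#' @param panel A [marker_panel()] whose markers are the genotype columns.
#' @param genotypes Character matrix individuals x markers (A/H/B/NN).
#' @param phenotypes data.frame with `id`, `pheno_class` (all MUT).
#' @return List: `left_flank`, `right_flank` (marker names, `NA` when the
#'   cosegregating block touches the panel edge), `cosegregating` (character
#'   vector), `counts` (named per-marker recombinant counts), `n_NN` (named
#'   per-marker missing-call counts).
#' @export
narrow_interval <- function(panel, genotypes, phenotypes) {
  stopifnot(inherits(panel, "marker_panel"))
  if (nrow(panel) < 2L) abort_("need at least two markers")
  if (!all(panel$marker %in% colnames(genotypes)))
    abort_("genotype matrix lacks panel markers")
  genotypes <- genotypes[, panel$marker, drop = FALSE]  # positional order
  check_geno(genotypes, phenotypes)
  rec <- lapply(panel$marker, recombinants_at, genotypes, phenotypes)
  counts <- setNames(vapply(rec, length, 0L), panel$marker)
  n_NN <- setNames(vapply(rec, attr, 0L, "n_NN"), panel$marker)
  zero <- which(counts == 0L)
  if (length(zero) == length(counts))
    abort_("interval unresolved, add markers")
  if (length(zero) == 0L) {
    sums <- counts[-length(counts)] + counts[-1L]
    j <- which.min(sums)
    warning("no cosegregating marker; returning adjacent pair with minimal counts")
    return(list(left_flank = panel$marker[j], right_flank = panel$marker[j + 1L],
                cosegregating = character(0), counts = counts, n_NN = n_NN))
  }
  list(left_flank = if (min(zero) > 1L) panel$marker[min(zero) - 1L] else NA_character_,
       right_flank = if (max(zero) < nrow(panel)) panel$marker[max(zero) + 1L] else NA_character_,
       cosegregating = panel$marker[zero],
       counts = counts, n_NN = n_NN)
}
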