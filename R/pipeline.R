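#' Discover target-private SNP markers across a genome panel
#'
#' End-to-end composition: each comparator is aligned pairwise against
#' the target ([align_pair()]), SNPs are extracted ([call_snps()]),
#' private positions are intersected across the panel
#' ([intersect_private()]) and filtered/ranked ([select_markers()]).
#'
#' @param target Target [genome].
#' @param comparators Named list of comparator genomes.
#' @param params [align_params()].
#' @param criteria [marker_criteria()].
#' @param genes Optional gene intervals ([read_gff_genes()]).
#' @return A list: `markers` (ranked data.frame), `candidates` (before
#'   filtering), `snp_sets`, `coverage`, `blocks` (per comparator).
#' @export
discover_markers <- function(target, comparators, params = align_params(),
                             criteria = marker_criteria(), genes = NULL) {
  stopifnot(length(comparators) >= 1L)
  if (is.null(names(comparators)))
    names(comparators) <- vapply(comparators, `[[`, character(1), "id")
  blocks <- list(); snp_sets <- list(); coverage <- list()
  for (cid in names(comparators)) {
    b <- align_pair(target, comparators[[cid]], params)
    blocks[[cid]] <- b
    snp_sets[[cid]] <- call_snps(target, comparators[[cid]], b)
    coverage[[cid]] <- block_coverage(b)
  }
  candidates <- intersect_private(target$id, snp_sets, coverage)
  markers <- select_markers(candidates, target, genes = genes,
                            criteria = criteria)
  list(markers = markers, candidates = candidates, snp_sets = snp_sets,
       coverage = coverage, blocks = blocks)
}

#' Explain why a reference position is not a reported marker
#'
#' Classifies a position against a [discover_markers()] result:
#' `multi-copy` when the flank k-mer around the position is not unique in
#' the target (repeat content also destroys unique anchoring, so a
#' multi-copy locus may additionally lose coverage); otherwise
#' `uncovered` when at least one comparator has no aligned base there;
#' otherwise `shared` when only a subset of comparators carries a variant;
#' otherwise `filtered` when it was a candidate that failed the selection
#' criteria; `marker` when it is reported.
#'
#' @param result A [discover_markers()] result.
#' @param target The target [genome].
#' @param pos 0-based reference position(s).
#' @param flank_k Flank window size (odd bp).
#' @return Character vector of classifications.
#' @export
explain_position <- function(result, target, pos, flank_k = 61L) {
  vapply(pos, function(p) {
    if (p %in% result$markers$ref_pos) return("marker")
    half <- (flank_k - 1L) %/% 2L
    if (p - half >= 0L && p + half < target$length &&
        !flank_unique(target, p, flank_k)) return("multi-copy")
    covered <- vapply(result$coverage, function(cov)
      IRanges::overlapsAny(IRanges::IRanges(start = p + 1L, width = 1L), cov),
      logical(1))
    if (!all(covered)) return("uncovered")
    n_var <- sum(vapply(result$snp_sets, function(s) p %in% s$ref_pos,
                        logical(1)))
    if (n_var < length(result$snp_sets)) return("shared")
    "filtered"
  }, character(1))
}
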