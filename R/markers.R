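#' Intersect per-comparator SNP sets to find target-private positions
#'
#' A reference position is a marker candidate only when every comparator
#' in the panel (i) covers the position with an aligned base in a retained
#' block and (ii) carries a variant call there. An unaligned or deleted
#' position is "unknown", never "different", so assembly gaps cannot
#' masquerade as strain-specific markers. Comparators are not required to
#' agree on the alternative allele unless `require_consistent_alt = TRUE`.
#'
#' @param target_id Id of the target genome (bookkeeping only).
#' @param snp_sets Named list, one SNP call data.frame
#'   ([call_snps()]) per comparator.
#' @param coverage Named list, one [IRanges::IRanges] of covered reference
#'   positions ([block_coverage()]) per comparator.
#' @param require_consistent_alt Require all comparators to share one
#'   alternative allele.
#' @return A data.frame of candidates: `ref_pos` (0-based), `ref_allele`,
#'   `n_variant`, `covered_in_all`, `alt_alleles` (comma-joined, one per
#'   comparator), `alt_consistent`, `buff_min`, `dist_min`.
#' @export
intersect_private <- function(target_id, snp_sets, coverage,
                              require_consistent_alt = FALSE) {
  comparators <- names(coverage)
  missing <- setdiff(comparators, names(snp_sets))
  if (length(missing) > 0L)
    stop("comparator(s) present in coverage but missing from snp_sets: ",
         paste(missing, collapse = ", "))
  comparators <- sort(comparators)
  all_pos <- sort(unique(unlist(lapply(snp_sets[comparators],
                                       function(s) s$ref_pos))))
  if (length(all_pos) == 0L)
    return(empty_candidates())
  per <- lapply(comparators, function(cid) {
    s <- snp_sets[[cid]]
    cov <- coverage[[cid]]
    hit <- match(all_pos, s$ref_pos)
    covered <- IRanges::overlapsAny(
      IRanges::IRanges(start = all_pos + 1L, width = 1L), cov)
    list(alt = s$qry_allele[hit], ref = s$ref_allele[hit],
         buff = s$buff[hit], dist = s$dist[hit], covered = covered)
  })
  names(per) <- comparators
  n_variant <- Reduce(`+`, lapply(per, function(p) !is.na(p$alt)))
  covered_in_all <- Reduce(`&`, lapply(per, `[[`, "covered"))
  is_cand <- n_variant == length(comparators) & covered_in_all
  if (!any(is_cand)) return(empty_candidates())
  idx <- which(is_cand)
  alt_mat <- vapply(per, function(p) p$alt[idx],
                    character(length(idx)))
  alt_mat <- matrix(alt_mat, nrow = length(idx),
                    dimnames = list(NULL, comparators))
  ref_allele <- per[[1]]$ref[idx]
  buff_mat <- matrix(vapply(per, function(p) p$buff[idx],
                            numeric(length(idx))), nrow = length(idx))
  dist_mat <- matrix(vapply(per, function(p) p$dist[idx],
                            numeric(length(idx))), nrow = length(idx))
  buff_min <- apply(buff_mat, 1, min)
  dist_min <- apply(dist_mat, 1, min)
  alt_consistent <- apply(alt_mat, 1, function(r) length(unique(r)) == 1L)
  out <- data.frame(
    ref_pos = all_pos[idx], ref_allele = ref_allele,
    n_variant = n_variant[idx], covered_in_all = TRUE,
    alt_alleles = apply(alt_mat, 1, paste, collapse = ","),
    alt_consistent = alt_consistent,
    buff_min = as.integer(buff_min), dist_min = as.integer(dist_min),
    stringsAsFactors = FALSE
  )
  if (require_consistent_alt) out <- out[out$alt_consistent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target_id") <- target_id
  attr(out, "comparators") <- comparators
  out
}

empty_candidates <- function() {
  data.frame(ref_pos = integer(), ref_allele = character(),
             n_variant = integer(), covered_in_all = logical(),
             alt_alleles = character(), alt_consistent = logical(),
             buff_min = integer(), dist_min = integer(),
             stringsAsFactors = FALSE)
}

#' Is the k-mer window around a position unique in the genome?
#'
#' Computational surrogate for the "single-copy" requirement: the k-mer
#' centered on the position must occur exactly once in the genome,
#' counting forward and reverse-complement occurrences together. A marker
#' in a duplicated segment fails this test.
#'
#' @param genome A [genome] object.
#' @param pos 0-based position.
#' @param k Window size (odd).
#' @return `TRUE` iff the window occurs exactly once.
#' @export
flank_unique <- function(genome, pos, k = 61L) {
  if (k %% 2L == 0L) stop("k must be odd")
  half <- (k - 1L) %/% 2L
  s <- pos - half; e <- pos + half            # 0-based inclusive
  if (s < 0L || e >= genome$length)
    stop(sprintf("window [%d,%d] out of range for genome of length %d",
                 s, e, genome$length))
  subject <- Biostrings::DNAString(genome$seq)
  kmer <- Biostrings::DNAString(substr(genome$seq, s + 1L, e + 1L))
  n_fwd <- Biostrings::countPattern(kmer, subject)
  n_rev <- Biostrings::countPattern(Biostrings::reverseComplement(kmer),
                                    subject)
  (n_fwd + n_rev) == 1L
}

#' Filter and rank marker candidates
#'
#' Applies isolation (`min_buff`, `min_dist`), flank-uniqueness and gene
#' containment criteria, then ranks deterministically by
#' (`flank_unique` desc, `buff_min` desc, `dist_min` desc, `ref_pos` asc).
#'
#' @param candidates Data.frame from [intersect_private()].
#' @param target The target [genome] (needed for flank uniqueness).
#' @param genes Optional gene intervals ([read_gff_genes()]).
#' @param criteria List of `min_buff`, `min_dist`, `require_flank_unique`,
#'   `require_gene`, `flank_k`.
#' @return The filtered, ranked candidate data.frame with added columns
#'   `flank_unique` and `gene`.
#' @export
select_markers <- function(candidates, target, genes = NULL,
                           criteria = marker_criteria()) {
  cr <- utils::modifyList(marker_criteria(), criteria)
  out <- candidates
  if (nrow(out) == 0L) {
    out$flank_unique <- logical()
    out$gene <- character()
    return(out)
  }
  out$flank_unique <- vapply(out$ref_pos, function(p) {
    half <- (cr$flank_k - 1L) %/% 2L
    if (p - half < 0L || p + half >= target$length) return(FALSE)
    flank_unique(target, p, cr$flank_k)
  }, logical(1))
  out$gene <- NA_character_
  if (!is.null(genes) && nrow(genes) > 0L) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = out$ref_pos + 1L, width = 1L),
      IRanges::IRanges(start = genes$start + 1L, end = genes$end))
    first <- !duplicated(S4Vectors::queryHits(hits))
    out$gene[S4Vectors::queryHits(hits)[first]] <-
      genes$name[S4Vectors::subjectHits(hits)[first]]
  }
  keep <- out$buff_min >= cr$min_buff & out$dist_min >= cr$min_dist
  if (cr$require_flank_unique) keep <- keep & out$flank_unique
  if (cr$require_gene) keep <- keep & !is.na(out$gene)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$flank_unique, -out$buff_min, -out$dist_min,
                   out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default marker selection criteria
#'
#' @param min_buff Minimum isolation from other variants (bp).
#' @param min_dist Minimum distance from block edges (bp).
#' @param require_flank_unique Require the flank k-mer to be single-copy.
#' @param require_gene Require gene containment (only with annotation).
#' @param flank_k Flank window size (odd bp).
#' @return Named list of criteria.
#' @export
marker_criteria <- function(min_buff = 20L, min_dist = 100L,
                            require_flank_unique = TRUE,
                            require_gene = FALSE, flank_k = 61L) {
  list(min_buff = as.integer(min_buff), min_dist = as.integer(min_dist),
       require_flank_unique = require_flank_unique,
       require_gene = require_gene, flank_k = as.integer(flank_k))
}

#' Write a marker report (TSV + BED)
#'
#' @param markers Data.frame from [select_markers()].
#' @param path Output TSV path; `<path>.bed` gets the BED intervals.
#' @param ref_id Reference sequence id for the BED file.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(markers, path, ref_id = "ref") {
  out <- markers
  out$ref_pos <- out$ref_pos + 1L  # report convention: 1-based
  con <- file(path, "w")
  writeLines("# strainmarker marker report; ref_pos is 1-based", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  bed <- sprintf("%s\t%d\t%d\tmarker_%d", ref_id, markers$ref_pos,
                 markers$ref_pos + 1L, seq_len(nrow(markers)))
  writeLines(bed, paste0(path, ".bed"))
  invisible(path)
}
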