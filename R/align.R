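#' Default alignment parameters
#'
#' MUM anchoring and chaining defaults in the spirit of classical
#' whole-genome aligners: anchors of at least 20 bp, clusters of at least
#' 65 anchored bp, at most 90 bp between chained anchors, and a 200 bp
#' band for gap closure. Gap closure scores match +1 / mismatch -1 /
#' gap open -5 / gap extend -1.
#'
#' @param min_len Minimum MUM anchor length (bp).
#' @param min_cluster Minimum total anchored length of a cluster (bp).
#' @param max_gap Maximum inter-anchor gap and diagonal drift (bp).
#' @param band Maximum gap length difference closed by alignment (bp).
#' @param match,mismatch,gap_open,gap_extend Gap-closure scores.
#' @return A named list of parameters.
#' @export
align_params <- function(min_len = 20L, min_cluster = 65L, max_gap = 90L,
                         band = 200L, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  list(min_len = as.integer(min_len), min_cluster = as.integer(min_cluster),
       max_gap = as.integer(max_gap), band = as.integer(band),
       match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Find maximal unique matches (MUMs) between two genomes
#'
#' A MUM is an exact match that occurs exactly once in the reference and
#' exactly once in the query (strict two-way uniqueness) and cannot be
#' extended in either direction. Both query strands are searched; minus
#' strand anchors carry query coordinates on the reverse-complemented
#' query. N never matches anything, including N, so anchors are split at
#' ambiguous positions.
#'
#' @param ref,qry [genome] objects.
#' @param min_len Minimum match length (bp, >= 8).
#' @param strands Strands to search.
#' @return A data.frame with columns `ref_start`, `qry_start` (0-based),
#'   `length`, `strand`.
#' @export
find_mums <- function(ref, qry, min_len = 20L, strands = c("+", "-")) {
  stopifnot(inherits(ref, "genome"), inherits(qry, "genome"))
  if (min_len < 8L) stop("min_len must be >= 8")
  if (ref$length == 0L || qry$length == 0L) stop("sequences must be non-empty")
  out <- list()
  for (st in strands) {
    qseq <- if (st == "+") qry$seq else revcomp(qry$seq)
    er <- encode_seq(ref$seq, offset = 5L)
    eq <- encode_seq(qseq, offset = er$next_free)
    m <- cpp_find_mums(er$codes, eq$codes, as.integer(min_len),
                       sep_code = eq$next_free)
    if (nrow(m) > 0L) {
      out[[st]] <- data.frame(ref_start = m[, 1], qry_start = m[, 2],
                              length = m[, 3], strand = st,
                              stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(ref_start = integer(), qry_start = integer(),
               length = integer(), strand = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$strand, res$ref_start, res$qry_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chain co-linear anchors into clusters
#'
#' Per strand, anchors are chained by a weighted longest-increasing-
#' subsequence: a chain may link anchor a to anchor b when both reference
#' and query starts strictly increase, the inter-anchor gap on each
#' sequence is at most `max_gap`, and the diagonal drift is at most
#' `max_gap`. Chains are extracted greedily by total anchored length;
#' chains below `min_cluster` anchored bp are dropped.
#'
#' @param anchors Anchor data.frame from [find_mums()].
#' @param max_gap Maximum inter-anchor gap / diagonal drift (bp).
#' @param min_cluster Minimum total anchored length (bp).
#' @return A list of clusters; each cluster is a data.frame of anchors
#'   ordered by `ref_start` with a `strand` attribute.
#' @export
chain_anchors <- function(anchors, max_gap = 90L, min_cluster = 65L) {
  clusters <- list()
  for (st in unique(anchors$strand)) {
    a <- anchors[anchors$strand == st, , drop = FALSE]
    a <- a[order(a$ref_start, a$qry_start), , drop = FALSE]
    n <- nrow(a)
    if (n == 0L) next
    alive <- rep(TRUE, n)
    repeat {
      idx <- which(alive)
      if (length(idx) == 0L) break
      b <- a[idx, , drop = FALSE]
      k <- nrow(b)
      score <- b$length
      parent <- rep(NA_integer_, k)
      for (j in seq_len(k)) {
        if (j == 1L) next
        for (i in seq_len(j - 1L)) {
          if (b$ref_start[j] <= b$ref_start[i]) next
          if (b$qry_start[j] <= b$qry_start[i]) next
          rgap <- b$ref_start[j] - (b$ref_start[i] + b$length[i])
          qgap <- b$qry_start[j] - (b$qry_start[i] + b$length[i])
          if (rgap > max_gap || qgap > max_gap) next
          diag_drift <- abs((b$qry_start[j] - b$ref_start[j]) -
                            (b$qry_start[i] - b$ref_start[i]))
          if (diag_drift > max_gap) next
          cand <- score[i] + b$length[j]
          if (cand > score[j]) { score[j] <- cand; parent[j] <- i }
        }
      }
      end <- which.max(score)
      chain <- integer()
      cur <- end
      while (!is.na(cur)) { chain <- c(cur, chain); cur <- parent[cur] }
      members <- idx[chain]
      alive[members] <- FALSE
      cl <- a[members, , drop = FALSE]
      rownames(cl) <- NULL
      if (sum(cl$length) >= min_cluster) {
        attr(cl, "strand") <- st
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
  }
  # deterministic order: by strand then first anchor position
  if (length(clusters) > 1L) {
    key <- vapply(clusters, function(cl)
      sprintf("%s|%012d|%012d", attr(cl, "strand"),
              cl$ref_start[1], cl$qry_start[1]), character(1))
    clusters <- clusters[order(key)]
  }
  clusters
}

new_block <- function(ref_start, ref_end, qry_start, qry_end, strand,
                      transcript) {
  ops <- strsplit(transcript, "", fixed = TRUE)[[1]]
  nM <- sum(ops == "M")
  structure(list(ref_start = ref_start, ref_end = ref_end,
                 qry_start = qry_start, qry_end = qry_end,
                 strand = strand, transcript = transcript,
                 identity = if (length(ops) > 0) nM / length(ops) else 0),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> ref %d-%d qry %d-%d (%s) identity %.4f\n",
              x$ref_start, x$ref_end, x$qry_start, x$qry_end, x$strand,
              x$identity))
  invisible(x)
}

# Check the transcript consumption invariants of a block.
validate_block <- function(block) {
  ops <- strsplit(block$transcript, "", fixed = TRUE)[[1]]
  ref_used <- sum(ops %in% c("M", "X", "D"))
  qry_used <- sum(ops %in% c("M", "X", "I"))
  stopifnot(ref_used == block$ref_end - block$ref_start,
            qry_used == block$qry_end - block$qry_start)
  invisible(TRUE)
}

#' Close inter-anchor gaps into alignment blocks
#'
#' Anchors contribute runs of M; the gap between consecutive anchors is
#' aligned globally with affine gap scores. A gap whose length difference
#' between reference and query exceeds `band` is left unaligned and splits
#' the cluster into separate blocks. For minus-strand clusters `qry` must
#' be the reverse-complemented query sequence (anchor convention of
#' [find_mums()]).
#'
#' @param ref,qry [genome] objects (`qry` reverse-complemented for minus
#'   strand clusters).
#' @param cluster One cluster from [chain_anchors()].
#' @param params [align_params()].
#' @return A list of `alignment_block` objects.
#' @export
close_gaps <- function(ref, qry, cluster, params = align_params()) {
  st <- attr(cluster, "strand")
  if (is.null(st)) st <- cluster$strand[1]
  a <- cluster[order(cluster$ref_start), , drop = FALSE]
  # trim anchor overlaps so coordinates stay strictly increasing
  keep <- rep(TRUE, nrow(a))
  for (j in seq_len(nrow(a))) {
    if (j == 1L) next
    prev <- max(which(keep[seq_len(j - 1L)]))
    d <- max(a$ref_start[prev] + a$length[prev] - a$ref_start[j],
             a$qry_start[prev] + a$length[prev] - a$qry_start[j], 0L)
    if (d >= a$length[j]) { keep[j] <- FALSE; next }
    a$ref_start[j] <- a$ref_start[j] + d
    a$qry_start[j] <- a$qry_start[j] + d
    a$length[j] <- a$length[j] - d
  }
  a <- a[keep, , drop = FALSE]
  qseq <- qry$seq

  blocks <- list()
  cur_rs <- a$ref_start[1]; cur_qs <- a$qry_start[1]
  parts <- character()
  prev_re <- NA_integer_; prev_qe <- NA_integer_
  flush <- function(re, qe) {
    if (length(parts) > 0L)
      blocks[[length(blocks) + 1L]] <<- new_block(cur_rs, re, cur_qs, qe, st,
                                                  paste(parts, collapse = ""))
    parts <<- character()
  }
  for (j in seq_len(nrow(a))) {
    if (j > 1L) {
      rgap_s <- prev_re; rgap_e <- a$ref_start[j]
      qgap_s <- prev_qe; qgap_e <- a$qry_start[j]
      rlen <- rgap_e - rgap_s; qlen <- qgap_e - qgap_s
      if (abs(rlen - qlen) > params$band ||
          (rlen + 1) * (qlen + 1) > 25e6) {
        # unclosable gap: split into a new block
        flush(prev_re, prev_qe)
        cur_rs <- a$ref_start[j]; cur_qs <- a$qry_start[j]
      } else if (rlen > 0L || qlen > 0L) {
        er <- encode_seq(substr(ref$seq, rgap_s + 1L, rgap_e), offset = 5L)
        eq <- encode_seq(substr(qseq, qgap_s + 1L, qgap_e),
                         offset = er$next_free)
        parts <- c(parts,
                   cpp_affine_global(er$codes, eq$codes, params$match,
                                     params$mismatch, params$gap_open,
                                     params$gap_extend))
      }
    }
    parts <- c(parts, strrep("M", a$length[j]))
    prev_re <- a$ref_start[j] + a$length[j]
    prev_qe <- a$qry_start[j] + a$length[j]
  }
  flush(prev_re, prev_qe)
  for (b in blocks) validate_block(b)
  blocks
}

#' One-to-one filtering of alignment blocks
#'
#' Greedy weighted selection by score = transcript length x identity such
#' that retained blocks overlap neither on the reference nor on the query
#' intervals (the classical "1-to-1" filtering mode). Ties break
#' deterministically by (ref_start, qry_start).
#'
#' @param blocks List of `alignment_block` objects from one genome pair.
#' @return The retained subset, sorted by `ref_start`.
#' @export
filter_one_to_one <- function(blocks) {
  if (length(blocks) == 0L) return(blocks)
  len <- vapply(blocks, function(b) nchar(b$transcript), numeric(1))
  idy <- vapply(blocks, `[[`, numeric(1), "identity")
  rs <- vapply(blocks, `[[`, numeric(1), "ref_start")
  qs <- vapply(blocks, `[[`, numeric(1), "qry_start")
  ord <- order(-len * idy, rs, qs)
  kept <- list()
  for (i in ord) {
    b <- blocks[[i]]
    clash <- any(vapply(kept, function(k)
      (b$ref_start < k$ref_end && k$ref_start < b$ref_end) ||
      (b$qry_start < k$qry_end && k$qry_start < b$qry_end), logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- b
  }
  kept[order(vapply(kept, `[[`, numeric(1), "ref_start"),
             vapply(kept, `[[`, numeric(1), "qry_start"))]
}

#' Pairwise whole-genome alignment
#'
#' Composition of [find_mums()], [chain_anchors()], [close_gaps()] and
#' [filter_one_to_one()]. On identical inputs it returns a single block
#' spanning both sequences with identity 1.
#'
#' @param ref,qry [genome] objects.
#' @param params [align_params()].
#' @return A list of `alignment_block` objects (possibly empty).
#' @export
align_pair <- function(ref, qry, params = align_params()) {
  anchors <- find_mums(ref, qry, min_len = params$min_len)
  if (nrow(anchors) == 0L) return(list())
  clusters <- chain_anchors(anchors, max_gap = params$max_gap,
                            min_cluster = params$min_cluster)
  qry_rc <- genome(qry$id, revcomp(qry$seq), accession = qry$accession)
  blocks <- list()
  for (cl in clusters) {
    q <- if (attr(cl, "strand") == "+") qry else qry_rc
    blocks <- c(blocks, close_gaps(ref, q, cl, params))
  }
  filter_one_to_one(blocks)
}

#' Reference intervals covered by aligned query bases
#'
#' Coverage counts reference positions aligned to an actual query base
#' (M or X transcript columns); positions deleted from the query (D) are
#' not covered. Used by the marker intersection to distinguish "identical"
#' from "unknown".
#'
#' @param blocks List of `alignment_block` objects.
#' @return An [IRanges::IRanges] of covered reference positions
#'   (1-based, as IRanges requires; convert with `start - 1` for 0-based).
#' @export
block_coverage <- function(blocks) {
  if (length(blocks) == 0L) return(IRanges::IRanges())
  starts <- integer(); ends <- integer()
  for (b in blocks) {
    ops <- strsplit(b$transcript, "", fixed = TRUE)[[1]]
    consume <- ops %in% c("M", "X", "D")
    ref_pos <- b$ref_start + cumsum(consume) - 1L  # 0-based, valid where consume
    covered <- ref_pos[consume & ops %in% c("M", "X")]
    if (length(covered) > 0L) {
      r <- IRanges::reduce(IRanges::IRanges(start = covered + 1L, width = 1L))
      starts <- c(starts, IRanges::start(r))
      ends <- c(ends, IRanges::end(r))
    }
  }
  IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
}

#' Export alignment blocks as a tab-separated table
#'
#' @param blocks List of `alignment_block` objects.
#' @param path Optional output path; if `NULL` the data.frame is returned.
#' @return A data.frame with one row per block (0-based half-open
#'   coordinates), invisibly if written to `path`.
#' @export
blocks_as_table <- function(blocks, path = NULL) {
  df <- data.frame(
    ref_start = vapply(blocks, `[[`, numeric(1), "ref_start"),
    ref_end = vapply(blocks, `[[`, numeric(1), "ref_end"),
    qry_start = vapply(blocks, `[[`, numeric(1), "qry_start"),
    qry_end = vapply(blocks, `[[`, numeric(1), "qry_end"),
    strand = vapply(blocks, `[[`, character(1), "strand"),
    identity = vapply(blocks, `[[`, numeric(1), "identity"),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
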