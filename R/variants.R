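#' Call SNPs from one-to-one alignment blocks
#'
#' Emits one call per mismatch (X) column whose reference and query bases
#' are both unambiguous (A/C/G/T). Indel columns are never reported as
#' SNPs, but they do reset the `buff` isolation distance. For minus-strand
#' blocks, query positions are reported on the original (forward) query
#' sequence while the query allele stays in reference orientation, so
#' `complement(qry$seq[qry_pos]) == qry_allele`.
#'
#' @param ref,qry [genome] objects (`qry` the original forward query).
#' @param blocks One-to-one filtered blocks from [align_pair()].
#' @param context_k Half-width of the reference context window.
#' @return A data.frame sorted by (`ref_id`, `ref_pos`): `ref_id`,
#'   `ref_pos` (0-based), `ref_allele`, `qry_allele`, `qry_id`, `qry_pos`
#'   (0-based, forward query), `strand`, `buff` (bp to the nearest other
#'   mismatch/indel or block edge), `dist` (bp to the nearest block edge),
#'   `ref_context`. The number of indel columns skipped is attached as
#'   attribute `n_indel_columns`.
#' @export
call_snps <- function(ref, qry, blocks, context_k = 20L) {
  rows <- list()
  n_indel <- 0L
  ref_chars <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  qry_rc <- revcomp(qry$seq)
  for (b in blocks) {
    if (b$ref_end > ref$length || b$qry_end > qry$length)
      stop("alignment block exceeds genome bounds")
    ops <- strsplit(b$transcript, "", fixed = TRUE)[[1]]
    n_col <- length(ops)
    ref_consume <- ops %in% c("M", "X", "D")
    qry_consume <- ops %in% c("M", "X", "I")
    ref_pos <- b$ref_start + cumsum(ref_consume) - 1L
    qry_pos <- b$qry_start + cumsum(qry_consume) - 1L
    qseq <- if (b$strand == "+") qry$seq else qry_rc
    x_cols <- which(ops == "X")
    n_indel <- n_indel + sum(ops %in% c("I", "D"))
    if (length(x_cols) == 0L) next
    ra <- ref_chars[ref_pos[x_cols] + 1L]
    qa <- substring(qseq, qry_pos[x_cols] + 1L, qry_pos[x_cols] + 1L)
    ok <- ra %in% c("A", "C", "G", "T") & qa %in% c("A", "C", "G", "T") &
      ra != qa
    x_cols <- x_cols[ok]; ra <- ra[ok]; qa <- qa[ok]
    if (length(x_cols) == 0L) next
    # distances in alignment columns to the nearest other variant column
    # (mismatch or indel) or to the block edge
    var_cols <- which(ops != "M")
    buff <- vapply(x_cols, function(cc) {
      others <- var_cols[var_cols != cc]
      min(c(abs(others - cc), cc - 1L, n_col - cc))
    }, numeric(1))
    dist <- pmin(x_cols - 1L, n_col - x_cols)
    # report qry_pos on the forward query strand
    qp <- qry_pos[x_cols]
    if (b$strand == "-") qp <- qry$length - 1L - qp
    ctx_s <- pmax(ref_pos[x_cols] - context_k, 0L)
    ctx_e <- pmin(ref_pos[x_cols] + context_k, ref$length - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      ref_id = ref$id, ref_pos = ref_pos[x_cols], ref_allele = ra,
      qry_allele = qa, qry_id = qry$id, qry_pos = qp, strand = b$strand,
      buff = as.integer(buff), dist = as.integer(dist),
      ref_context = substring(ref$seq, ctx_s + 1L, ctx_e + 1L),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(ref_id = character(), ref_pos = integer(),
               ref_allele = character(), qry_allele = character(),
               qry_id = character(), qry_pos = integer(),
               strand = character(), buff = integer(), dist = integer(),
               ref_context = character(), stringsAsFactors = FALSE)
  out <- out[order(out$ref_id, out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_indel_columns") <- n_indel
  out
}

SNP_TABLE_COLUMNS <- c("ref_id", "ref_pos", "ref_allele", "qry_allele",
                       "qry_id", "qry_pos", "strand", "buff", "dist",
                       "ref_context")

#' Write a SNP call table
#'
#' Positions are written 1-based (the community convention for SNP
#' reports); a header comment names the convention. [read_snp_table()]
#' restores the internal 0-based representation, so the pair round-trips.
#'
#' @param calls Data.frame from [call_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(calls, path) {
  out <- calls[, SNP_TABLE_COLUMNS, drop = FALSE]
  out$ref_pos <- out$ref_pos + 1L
  out$qry_pos <- out$qry_pos + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# strainmarker SNP table; ref_pos/qry_pos are 1-based", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP call table written by [write_snp_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame with 0-based positions.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c(ref_pos = "integer",
                                         qry_pos = "integer"),
                          stringsAsFactors = FALSE)
  df$ref_pos <- df$ref_pos - 1L
  df$qry_pos <- df$qry_pos - 1L
  for (col in c("ref_id", "ref_allele", "qry_allele", "qry_id", "strand",
                "ref_context"))
    df[[col]] <- as.character(df[[col]])
  df
}

#' Write SNP calls as a minimal VCF 4.2 file
#'
#' Only CHROM/POS/REF/ALT are populated (plus ID/QUAL/FILTER/INFO
#' placeholders); one record per call, positions 1-based.
#'
#' @param calls Data.frame from [call_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       calls$ref_id, calls$ref_pos + 1L,
                       calls$ref_allele, calls$qry_allele), con)
  }
  invisible(path)
}
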